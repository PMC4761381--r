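# apmstools

Identification of bona fide protein–protein interaction partners from
quantitative affinity-purification mass-spectrometry (AP-MS) data.

## What it is for

AP-MS and co-IP experiments co-purify a tagged bait protein with its true
partners *and* with large numbers of nonspecifically binding background
proteins. For single-bait (or few-bait) studies — where large-scale scoring
models such as SAINT or CompPASS have little to train on — the practical
workflow is: quantify every captured protein relative to a control pull-down,
test the enrichment statistically, discard known contaminants, and confront
the survivors with curated interaction databases. apmstools implements that
workflow end to end, for analysts of SILAC-style (or any ratio-based)
pull-down experiments:

* **Template-driven parsing** of arbitrary column-separated search-engine
  exports (ProteomeDiscoverer, MaxQuant, …) into a uniform dataset; templates
  are YAML, reusable, and support regular-expression field extraction.
* **Enrichment statistics.** For protein *i* and experiment *j* with
  log2-scale replicate values *V′ᵢⱼₖ*:
  ratio *rᵢⱼ* = mean over *k* of *V′ᵢⱼₖ*, and
  *pᵢⱼ* from a one-sided paired t-test against the zero vector,
  *t* = mean / (sd / √n), df = n − 1, one-sided in the direction of the
  observed mean. Proteins with fewer than two quantified samples are marked
  *insufficient* (no ratio, no p). Optional normalisation
  *V′ = log2(V · Ṽᵢⱼ / S̄ⱼₖ)* uses per-protein medians and per-sample means.
* **Contaminant filtering** against bead-proteome / frequency-library / user
  marker lists, plus a minimum-quantification filter; every removal is
  reported, positive markers are never dropped.
* **PPI database integration**: PSI-MI TAB (MITAB 2.5/2.7) parsing,
  identifier completion against UniProt-style mapping tables, and a
  nonredundant merged network with noisy-OR–combined confidence scores.
* **Bait-centric network views**: focused (BFS ball around the bait),
  specialized (experimental evidence overlaid; nodes classed
  bait / confirmed / database-only / experiment-only), truncated
  (database-only leaves pruned), score thresholds, deterministic
  radial/hierarchic/force layouts, GraphML export.
* **Volcano selection and differential binding**: strict-threshold
  significance regions, condition-dependent binding calls, known-partner
  annotation.
* **Synthetic data and packaged example** so the whole pipeline is testable
  offline: a seeded AP-MS generator with ground truth, a MITAB generator, and
  a 30-candidate STAT1 pull-down summary table.

## Worked example

The packaged example is a triple-SILAC pull-down of biotin-tagged STAT1
(with and without phospho-activation, against a GFP control; three biological
replicates):

```r
library(apmstools)

st  <- stat1_stat_table()                     # 30 proteins x 3 comparisons
sel <- select_significant(st, "pSTAT1_vs_GFP", min_log2_ratio = 1, max_p = 0.005)
head(sel[, c("accession", "log2_ratio", "sd", "p_value")], 5)
#>   accession log2_ratio   sd p_value
#> 1     STAT1       5.61 0.53 8.1e-07
#> 2     KPNA1       3.90 0.31 1.0e-03
#> 3     STAT3       3.45 0.05 3.9e-05
#> 4     STAT2       3.35 0.38 2.0e-04
#> 5       INA       3.28 0.52 4.1e-03
nrow(sel)
#> [1] 15
```

15 proteins are enriched more than two-fold over the GFP control at
p < 0.005 in the activated-bait pull-down — the bait itself on top, followed
by the importin subunit that carries phosphorylated STATs into the nucleus
and the known heterodimerisation partners STAT3 and STAT2.

```r
d <- differential_binding(st, "pSTAT1_vs_STAT1")   # |log2| > 1, p < 0.05
table(d$class)
#> enriched_condition_A enriched_condition_B            unchanged
#>                   10                    6                   14
```

16 of the 30 candidates bind phosphorylation-dependently: 10 more strongly
after activation (condition A, e.g. STAT3), 6 more strongly without
(condition B, e.g. UCHL1).

```r
fx <- stat1_candidates()
a  <- annotate_known(sel, fx$gene_name[fx$known_from_literature])
attr(a, "summary")
#> $n_known
#> [1] 8
#> $fraction
#> [1] 0.5333333
```

More than half of the activated-bait candidates are already literature-known
STAT1 partners — the expected signature of a clean pull-down.

For the database side, `parse_mitab()` + `build_raw_network()` merge MITAB
dumps into one nonredundant scored network, and
`focused_network() |> specialize() |> truncate_network()` produce the
bait-centric views (see the vignette in `vignettes/apms-analysis.Rmd`).
A thin command-line front end over the same functions is installed at
`system.file("cli", "apmstools.R", package = "apmstools")`.

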