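---
title: "Identifying bona fide interaction partners from quantitative AP-MS data"
author: "apmstools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying bona fide interaction partners from quantitative AP-MS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apmstools)
```

## The problem

Affinity purification coupled to quantitative mass spectrometry (AP-MS)
enriches a tagged bait protein together with its binding partners, but beads,
tags and abundant cellular machinery co-purify hundreds to thousands of
nonspecific background proteins. In a SILAC-style multiplexed design the
abundance of every captured protein is quantified *relative to a control
pull-down* (e.g. a tagged GFP), so true partners appear as proteins
reproducibly enriched over the control, while background proteins scatter
around a ratio of one. apmstools implements the full desk-side analysis of
such experiments for single-bait (or few-bait) studies: parsing arbitrary
search-engine exports, enrichment statistics, contaminant filtering,
comparison against curated interaction databases, bait-centric network views,
and condition-dependent binding calls.

## The data model and statistics

A parsed experiment is a value tensor $V_{i,j,k}$: protein $i$, experiment
(comparison) $j$, sample (replicate) $k$, holding nonnegative abundance
ratios with missing measurements kept explicit (`NA`, never zero).

The statistics chain per protein and experiment is:

1. **Technical replicates** are combined by the arithmetic mean of observed
   raw values (`combine_technical_replicates()`), before any transform.
2. **Normalisation statistics**: the per-sample mean over proteins
   $\bar S_{j,k}$ and the per-protein median over samples
   $\tilde V_{i,j}$, both over observed values only.
3. **Log2 transform** (`log2_transform()`): with normalisation on,
   $V'_{i,j,k} = \log_2\!\big(V_{i,j,k} \cdot \tilde V_{i,j} \cdot \bar S_{j,k}^{-1}\big)$.
   Dividing by the sample mean removes sample-to-sample loading differences.
   The protein median entering *multiplicatively* is deliberate — it is how
   this normalisation is conventionally written in the workflow this package
   implements — but because a reader may equally expect the median to act as a
   per-protein reference (dividing), `median_action = "divide"` switches to
   $\log_2(V / \tilde V / \bar S)$. The default is the multiplicative form.
   Normalisation is optional (`normalize = FALSE` gives plain $\log_2 V$);
   it should be off when the upstream software already reports
   ratio-normalised values, as in the packaged example and the synthetic
   generator.
4. **Enrichment ratio** $r_{i,j}$: the arithmetic mean of the observed
   $V'_{i,j,k}$.
5. **Significance** $p_{i,j}$: a one-sided paired t-test of the $V'$ vector
   against the zero vector, which reduces to the one-sample statistic
   $t = \bar V' / (s/\sqrt n)$ with sample SD ($n-1$ denominator) and
   $\mathrm{df} = n - 1$.

**One-sidedness.** The test is one-sided *in the direction of the observed
mean*: $p = P(T_{n-1} > |t|)$, i.e. half the two-sided p-value. Depleted
proteins (negative means) therefore also receive small p-values on their own
side — necessary because the condition-difference comparison is symmetric:
enrichment without activation is as meaningful as enrichment with it. The
price is that under the null the p-values are super-uniform on $(0, 0.5]$
(twice the density of a uniform below 0.5), so a directional false-positive —
a protein called *enriched* at $p < 0.05$ — occurs at the nominal 5% rate,
while the rate of small p-values regardless of sign is twice that. Candidate
selection always combines the p threshold with a ratio threshold, which is
what controls background admission in practice.

**Insufficiency rule.** A protein quantified in fewer than two samples of an
experiment carries no information about reproducibility: no ratio or p-value
is computed and the record is marked `insufficient`. Degenerate spreads are
handled explicitly: zero SD with nonzero mean yields the smallest
representable positive p (with a warning); an all-zero vector yields
$p = 0.5$.

## Parsing templates

Search engines export wildly different column layouts. A `parse_template`
(YAML) declares the header size, the field delimiter, the experiment × sample
layout, and how source columns map to the data model — whole fields or
fragments captured by a one-group regular expression (e.g. `GN=(.*) P` pulls
the gene name out of a FASTA-style description). Fixed values cover fields
absent from the export (e.g. taxonomy 9606 for a single-species study).
Unparseable numeric cells become missing values with a warning; structurally
broken rows are flagged in the parse report, never silently dropped;
duplicated accessions keep their first occurrence. `preview_conversion()`
shows the converted head of the file so a template can be checked cheaply
before a full import.

## Contaminant handling

Marker lists are categorised identifier sets: the bead proteome (nonspecific
bead binders), a protein frequency library (proteins recurrently observed
across unrelated pull-downs), and user-defined negative, positive and general
markers. Flagging (`apply_flags()`) is non-destructive and auditable;
`drop_flagged()` removes selected categories, with one hard precedence rule:
a protein carrying a *positive* marker is never dropped, and the conflict is
reported. `min_quantification_filter()` removes proteins quantified in fewer
than a chosen number of measurements (default 3, technical replicates
included). The two filters commute, and every removal appears in a report, so
`retained + removed` always accounts for the input. Frequency-library
exclusion is implemented as plain list membership, not as a threshold on an
observation frequency — the lists themselves encode the frequency judgement.

## The interaction-database layer

Database dumps in PSI-MI TAB (MITAB 2.5/2.7) are parsed line-wise:
`uniprotkb:` identifiers become accessions, alias entries tagged
`(gene name)` provide gene names, `taxid:` entries the taxonomy, and the
confidence column is searched for an `intact-miscore` (or any key:number in
[0, 1]). Identifiers from other namespaces are kept verbatim and completed
against a UniProt idmapping-style table (`resolve_identifiers()`); an
interaction that still lacks an accession, gene name or taxonomy on either
side is discarded with the first applicable reason code (`NO_ACCESSION`,
`NO_GENE_NAME`, `NO_TAXONOMY`).

`build_raw_network()` merges all sources into one nonredundant undirected
network: self-interactions and cross-taxonomy pairs are dropped (with reason
codes), edges are keyed by the lexicographically ordered accession pair,
deduplicated *within* each source first (best score wins), then combined
*across* sources. The combined confidence uses a noisy-OR,
$1 - \prod_s (1 - s)$: if each database score is read as an independent
probability that the interaction is real, the combined score is the
probability that at least one source is right. It is monotone in every
argument, never below the best single source, normalized to [0, 1], and 1 is
absorbing. `method = "max"` is available for users who prefer the
best-single-source reading. Sources without confidence values contribute
provenance but no score; a score-free edge sorts below any scored edge and is
removed by any score filter.

## Bait-centric network views

* **Focused network**: all nodes within a breadth-first (unweighted
  shortest-path) distance `depth` of the bait, with every database edge among
  them — including edges between same-depth nodes.
* **Specialized network**: the focused network overlaid with the experimental
  candidate set. Nodes are `confirmed` (database + experiment),
  `database_only`, or `experiment_only`; experimental proteins absent from
  the database are attached to the bait by an explicitly flagged
  *provisional* evidence edge, since the experiment asserts partnership with
  the bait but no database topology exists for them.
* **Truncated network**: iterative removal of every degree-1 `database_only`
  node until a fixpoint. Confirmed, experiment-only and bait nodes are never
  pruned. This reading — prune the unconfirmed periphery, keep the
  experimentally supported one — is the one under which the truncated view is
  informative exactly when unconfirmed proteins are present; the inverse
  (pruning confirmed leaves) would delete the evidence the tool exists to
  surface. Truncation is idempotent and order-independent.
* **Score threshold** (`score_filter()`): database edges below the threshold
  (or score-free) are removed, provisional evidence edges are exempt, and
  nodes left without a path to the bait are dropped.

Layouts are static and deterministic: `radial` places depth-$d$ nodes on a
circle of radius $d$ (the bait at the origin), `hierarchic` stacks depth
layers, `force` runs Fruchterman–Reingold under a fixed seed so coordinates
reproduce bit-for-bit. Networks export to GraphML (via igraph) with status,
depth and coordinates as attributes.

## Candidate selection and differential binding

The volcano view plots $r_{i,j}$ against $-\log_{10} p_{i,j}$ (raw p
available as an option). `select_significant()` takes the upper-right region
with *strict* inequalities — ratio above, p below their thresholds; boundary
values are excluded — and orders the result by descending ratio, ties broken
by accession, so output is deterministic. The defaults (ratio > 1, i.e.
two-fold, and p < 0.005) are the thresholds used in the packaged example.

`differential_binding()` classifies a condition-versus-condition comparison:
$|r| > 1$ and $p < 0.05$ calls a protein enriched in the condition the sign
points to; everything else is `unchanged`; the three classes partition the
computed records. The p threshold is looser than in candidate selection
because the call is made *within* the already-selected candidate set, where
the prior for a real effect is much higher. `annotate_known()` flags
candidates with an edge to the bait in the merged network — or with
membership in a plain identifier set, which accommodates curated literature
lists (and, via set membership rather than graph edges, bait homodimers that
a self-loop-free network cannot represent).

## The packaged example

`stat1_candidates()` ships the 30-candidate summary table of a triple-SILAC
STAT1 pull-down (activated bait, resting bait, and their direct difference;
three biological replicates), with a curated known-partner flag. At the
default thresholds the activated-bait comparison yields 15 candidates and the
resting-bait comparison 17; their union covers all 30; 16 candidates bind
phosphorylation-dependently (6 stronger without activation, 10 with); 2 of
the 17 and more than half of the 15 carry the literature flag.

`expand_replicates()` reconstructs replicate-level data from a (mean, SD)
pair exactly: the centred ladder $1..n$ is rescaled to unit sample SD, giving
$(\bar x - s, \bar x, \bar x + s)$ for $n = 3$. This is deterministic, so
fixture-driven tests need no tolerance on means or SDs.

**A known limitation.** Recomputing the example's p-values from such
mean/SD-exact triples reproduces many rows essentially exactly (e.g. STAT3,
KPNA1, PTBP2) but not all: about a third of the rows — most prominently the
bait's own rows — have published p-values far smaller than any
three-replicate t-test on the published mean and SD can produce, and no
single alternative sample size fits the remaining rows either. Summary tables
of this kind evidently mix per-row effective sample sizes (proteins
quantified in up to six measurements) without printing them. The package
therefore treats published summary statistics as *inputs* for selection and
annotation (which are threshold comparisons and reproduce exactly), while
replicate-level recomputation is validated against its own independent
oracles rather than against such tables row-by-row; the acceptance script
reports the observed agreement fraction instead of asserting one.

## The synthetic generator

`generate_apms_dataset()` emulates the quantitative outcome of a single-bait
versus control comparison: background proteins with log2 ratios
$\mathcal N(0, \sigma)$ per biological replicate, true binders shifted by a
planted effect, technical replicates adding measurement noise with SD
$\sigma/2$, independent per-cell missingness, and a fraction of background
proteins carrying bead-proteome / frequency-library identities with matching
marker lists. Defaults mirror the study design the package targets: 3
biological × 2 technical replicates, effect 2 log2 units, biological SD 0.2;
desk-scale sizes (200 background, 25 binders, 5% missingness, 10%
contaminants) keep every simulation in the test suite in the seconds range.
Ground truth is recorded before noise and everything is a deterministic
function of the seed.

What the generator does **not** emulate: intensity-dependent ratio variance,
correlated missingness (censoring of low-abundance proteins), shared-peptide
ambiguity, and compositional coupling between proteins. Passing recovery
tests therefore demonstrate that the statistics and selection machinery is
correct under the declared noise model, not that the thresholds are optimal
for any particular instrument or design.

`generate_mitab_fixture()` plays the same role for the database layer:
a random truth graph serialised as well-formed MITAB 2.5 lines, with
optional injected self-interaction and cross-taxonomy lines to exercise the
merge's reason codes.

## Numerical and design notes

* Missing values are excluded pairwise everywhere; `n_used` records the
  effective count entering each test.
* Nonpositive raw values cannot be log-transformed: set to missing with a
  warning, the row flagged.
* All set-valued outputs are deterministically ordered (ratio descending,
  then accession; canonical accession pairs for edges), so file exports are
  stable across runs.
* Problem sizes in the test suite: 1,000-triple oracle comparisons for the
  t-test, 1,000-edge merge fixtures, 50-node BFS oracles, 20-seed recovery
  runs of 225 proteins each — all chosen so the full suite runs in well under
  a minute per file.
* The raw-data-scale protein counts of a full pull-down (thousands of
  proteins before filtering) are properties of a particular instrument run
  and database snapshot; the filtering rules are validated on synthetic
  datasets with known per-protein counts instead.
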