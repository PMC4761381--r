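STAT1_EXPERIMENTS <- c("pSTAT1_vs_GFP", "STAT1_vs_GFP", "pSTAT1_vs_STAT1")

#' Packaged STAT1 pull-down candidate table
#'
#' Summary statistics for the 30 putative STAT1 interaction partners from a
#' triple-label SILAC pull-down of biotin-tagged STAT1 in HEK 293T cells, with
#' and without phospho-activation: per protein and comparison the mean log2
#' enrichment ratio, its standard deviation across three biological
#' replicates, the one-sided paired t-test p-value, and a curated
#' known-STAT1-partner flag. The three comparisons are activated bait versus
#' control (`pSTAT1_vs_GFP`), resting bait versus control (`STAT1_vs_GFP`)
#' and the direct condition difference (`pSTAT1_vs_STAT1`).
#'
#' @return Data frame with 30 rows; columns `gene_name`,
#'   `<experiment>_log2` / `_sd` / `_p` for each of the three comparisons, and
#'   logical `known_from_literature`.
#' @seealso [stat1_stat_table()] for the long-format statistics view;
#'   [expand_to_replicates()] to reconstruct replicate-level data.
#' @export
stat1_candidates <- function() {
  path <- system.file("extdata", "stat1_apms_candidates.tsv",
                      package = "apmstools", mustWork = TRUE)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  tab$known_from_literature <- tab$known_from_literature == "Yes"
  tab
}

#' Long-format statistics table of the STAT1 example
#'
#' Reshapes [stat1_candidates()] into the `stat_table` layout used by the
#' selection and annotation tools: one row per (protein, comparison) with the
#' published summary statistics (gene names double as accessions, n = 3
#' biological replicates).
#'
#' @param fixture output of [stat1_candidates()] (loaded when omitted).
#' @return A `stat_table` with 90 rows (30 proteins x 3 comparisons).
#' @export
stat1_stat_table <- function(fixture = stat1_candidates()) {
  rows <- lapply(STAT1_EXPERIMENTS, function(exp) {
    data.frame(accession = fixture$gene_name,
               gene_name = fixture$gene_name,
               experiment = exp,
               n_used = 3L,
               log2_ratio = fixture[[paste0(exp, "_log2")]],
               sd = fixture[[paste0(exp, "_sd")]],
               p_value = fixture[[paste0(exp, "_p")]],
               status = "computed",
               stringsAsFactors = FALSE)
  })
  stat_table(do.call(rbind, rows))
}

#' Deterministic replicate expansion matching a mean/SD pair
#'
#' Reconstructs `n` log2 replicate values whose sample mean and sample
#' standard deviation (n - 1 denominator) equal a given summary pair exactly.
#' The construction is symmetric and deterministic (no randomness): the
#' centred integer ladder `1..n` is rescaled to unit sample SD and shifted.
#' For n = 3 this yields `(mean - sd, mean, mean + sd)`. It enables end-to-end
#' recomputation of statistics from published summary tables.
#'
#' @param mean target sample mean.
#' @param sd target sample standard deviation (must be >= 0).
#' @param n number of replicates (>= 2).
#' @return Numeric vector of length `n`.
#' @examples
#' expand_replicates(3.45, 0.05, 3)  # 3.40 3.45 3.50
#' @export
expand_replicates <- function(mean, sd, n = 3L) {
  if (!is_count(n, min = 2L)) config_error("'n' must be an integer >= 2")
  if (is.na(sd) || sd < 0) config_error("'sd' must be nonnegative")
  z <- seq_len(n) - (n + 1) / 2
  z <- z / stats::sd(z)
  mean + sd * z
}

#' Expand the summary fixture to a replicate-level dataset
#'
#' Converts a summary table like [stat1_candidates()] into a full
#' [quant_dataset()] by reconstructing, for every protein and comparison, `n`
#' replicate values with exactly the published mean and SD (see
#' [expand_replicates()]), stored on the raw ratio scale (`2^log2value`) so
#' that [compute_stats()] with `normalize = FALSE` reproduces the summary
#' statistics from scratch.
#'
#' @param fixture a summary table with `gene_name` and `<experiment>_log2` /
#'   `_sd` column pairs; defaults to [stat1_candidates()].
#' @param n replicates to generate per (protein, experiment).
#' @return A [quant_dataset()] of dimension `nrow(fixture) x 3 x n`.
#' @export
expand_to_replicates <- function(fixture = stat1_candidates(), n = 3L) {
  exps <- STAT1_EXPERIMENTS
  values <- array(NA_real_, dim = c(nrow(fixture), length(exps), n))
  for (j in seq_along(exps)) {
    m <- fixture[[paste0(exps[j], "_log2")]]
    s <- fixture[[paste0(exps[j], "_sd")]]
    for (i in seq_len(nrow(fixture))) {
      values[i, j, ] <- 2^expand_replicates(m[i], s[i], n)
    }
  }
  proteins <- data.frame(accession = fixture$gene_name,
                         gene_name = fixture$gene_name,
                         taxonomy = 9606L,
                         description = NA_character_,
                         stringsAsFactors = FALSE)
  quant_dataset(proteins, values, exps)
}

#' Synthetic AP-MS dataset with known ground truth
#'
#' Simulates the quantitative outcome of a single-bait pull-down compared to a
#' control channel, emulating a SILAC-style design: background proteins whose
#' log2 ratios scatter around 0, true binders shifted by a positive log2
#' effect, a biological x technical replicate structure, missing values, and
#' a fraction of background proteins carrying contaminant identities
#' (bead proteome / frequency library). Ratios are stored on the raw scale
#' (`2^log2`), so the standard pipeline — [combine_technical_replicates()]
#' then [compute_stats()] — applies directly. The generator is fully
#' determined by `seed`.
#'
#' Per protein and biological replicate the log2 ratio is drawn from
#' `N(effect, noise_sd)` (effect 0 for background); each technical replicate
#' adds measurement noise with SD `noise_sd / 2`. Cells go missing
#' independently with probability `missing_rate`.
#'
#' @param n_background number of background (non-binding) proteins.
#' @param n_true number of true binders.
#' @param effect_log2 true log2 enrichment of the binders.
#' @param noise_sd biological replicate SD on the log2 scale.
#' @param n_bio,n_tech biological / technical replicates (samples per
#'   experiment = `n_bio * n_tech`).
#' @param missing_rate per-cell missingness probability in [0, 1].
#' @param contaminant_fraction fraction of background proteins assigned a
#'   contaminant identity, split evenly between the bead proteome and the
#'   frequency library.
#' @param seed integer seed.
#' @return List with `dataset` (a [quant_dataset()]), `truth` (data frame:
#'   `accession`, `gene_name`, `is_true_binder`, `true_log2_effect`,
#'   `contaminant` — `NA`, `"bead_proteome"` or `"frequency_library"`),
#'   `tech_grouping` (vector mapping sample slots to biological replicates)
#'   and `marker_lists` (the matching [marker_list()]s, possibly empty).
#' @export
generate_apms_dataset <- function(n_background = 200L, n_true = 25L,
                                  effect_log2 = 2, noise_sd = 0.2,
                                  n_bio = 3L, n_tech = 2L,
                                  missing_rate = 0.05,
                                  contaminant_fraction = 0.1,
                                  seed = 1L) {
  if (n_background < 0 || n_true < 0) config_error("counts must be nonnegative")
  for (rate in c(missing_rate, contaminant_fraction)) {
    if (is.na(rate) || rate < 0 || rate > 1) {
      config_error("rates must lie in [0, 1]")
    }
  }
  if (!is_count(n_bio) || !is_count(n_tech)) {
    config_error("'n_bio' and 'n_tech' must be positive integers")
  }
  set.seed(seed)
  n <- n_background + n_true
  accession <- sprintf("SYN%04d", seq_len(n))
  gene_name <- sprintf("GENE%04d", seq_len(n))
  is_true <- c(rep(FALSE, n_background), rep(TRUE, n_true))
  effect <- ifelse(is_true, effect_log2, 0)

  contaminant <- rep(NA_character_, n)
  n_cont <- round(contaminant_fraction * n_background)
  if (n_cont > 0) {
    cont_idx <- seq_len(n_cont)  # deterministic: first background proteins
    contaminant[cont_idx] <- rep(c("bead_proteome", "frequency_library"),
                                 length.out = n_cont)
  }

  n_samp <- n_bio * n_tech
  tech_grouping <- rep(seq_len(n_bio), each = n_tech)
  values <- array(NA_real_, dim = c(n, 1L, n_samp))
  for (i in seq_len(n)) {
    bio <- rnorm(n_bio, mean = effect[i], sd = noise_sd)
    tech <- bio[tech_grouping] + rnorm(n_samp, sd = noise_sd / 2)
    tech[runif(n_samp) < missing_rate] <- NA_real_
    values[i, 1L, ] <- 2^tech
  }
  proteins <- data.frame(accession = accession, gene_name = gene_name,
                         taxonomy = 9606L, description = NA_character_,
                         stringsAsFactors = FALSE)
  dataset <- quant_dataset(proteins, values, "bait_vs_control")
  truth <- data.frame(accession = accession, gene_name = gene_name,
                      is_true_binder = is_true, true_log2_effect = effect,
                      contaminant = contaminant, stringsAsFactors = FALSE)
  marker_lists <- list()
  for (cat in c("bead_proteome", "frequency_library")) {
    ids <- truth$accession[!is.na(truth$contaminant) & truth$contaminant == cat]
    if (length(ids)) {
      marker_lists[[cat]] <- marker_list(ids, cat, name = paste0("synthetic_", cat))
    }
  }
  list(dataset = dataset, truth = truth, tech_grouping = tech_grouping,
       marker_lists = marker_lists)
}

#' Synthetic MITAB 2.5 interaction file with truth graph
#'
#' Generates a random undirected interaction network (each unordered protein
#' pair becomes an edge independently with probability `edge_density`), writes
#' it as well-formed 15-column MITAB 2.5 lines and returns the truth edge
#' list, so MITAB parsing and network merging can be checked against a known
#' answer. Optional self-interaction and cross-taxonomy lines can be injected
#' to exercise the merge-validation reason codes.
#'
#' @param n_proteins number of proteins.
#' @param edge_density probability of each unordered pair interacting.
#' @param score_range range the per-edge confidence scores are drawn from.
#' @param seed integer seed.
#' @param path file to write; a temporary file when `NULL`.
#' @param source database name stamped on the lines.
#' @param taxonomy taxon identifier of all proteins.
#' @param n_self,n_cross number of self-interaction / cross-taxonomy lines to
#'   inject.
#' @return List with `path`, `truth` (data frame `acc_a`, `acc_b`, `score`,
#'   canonically ordered) and `accessions`.
#' @export
generate_mitab_fixture <- function(n_proteins = 20L, edge_density = 0.2,
                                   score_range = c(0.3, 0.95), seed = 1L,
                                   path = NULL, source = "syndb",
                                   taxonomy = 9606L, n_self = 0L, n_cross = 0L) {
  if (edge_density < 0 || edge_density > 1) {
    config_error("'edge_density' must lie in [0, 1]")
  }
  set.seed(seed)
  acc <- sprintf("Q%05d", seq_len(n_proteins))
  genes <- sprintf("GN%05d", seq_len(n_proteins))
  pairs <- which(upper.tri(matrix(0, n_proteins, n_proteins)), arr.ind = TRUE)
  take <- runif(nrow(pairs)) < edge_density
  pairs <- pairs[take, , drop = FALSE]
  score <- runif(nrow(pairs), score_range[1], score_range[2])
  truth <- data.frame(acc_a = acc[pairs[, 1]], acc_b = acc[pairs[, 2]],
                      score = score, stringsAsFactors = FALSE)

  mitab_line <- function(a, b, ga, gb, ta, tb, sc) {
    paste(
      paste0("uniprotkb:", a),
      paste0("uniprotkb:", b),
      "-", "-",
      sprintf("uniprotkb:%s(gene name)", ga),
      sprintf("uniprotkb:%s(gene name)", gb),
      "psi-mi:\"MI:0004\"(affinity chromatography technology)",
      "-", "pubmed:00000000",
      sprintf("taxid:%d(synthetic)", ta),
      sprintf("taxid:%d(synthetic)", tb),
      "psi-mi:\"MI:0915\"(physical association)",
      sprintf("psi-mi:\"MI:0000\"(%s)", source),
      "-",
      if (is.na(sc)) "-" else sprintf("intact-miscore:%.4f", sc),
      sep = "\t")
  }
  lines <- character(0)
  if (nrow(truth)) {
    lines <- vapply(seq_len(nrow(truth)), function(i) {
      ia <- match(truth$acc_a[i], acc)
      ib <- match(truth$acc_b[i], acc)
      mitab_line(acc[ia], acc[ib], genes[ia], genes[ib],
                 taxonomy, taxonomy, truth$score[i])
    }, character(1))
  }
  if (n_self > 0) {
    lines <- c(lines, vapply(seq_len(n_self), function(i) {
      mitab_line(acc[i], acc[i], genes[i], genes[i], taxonomy, taxonomy, 0.5)
    }, character(1)))
  }
  if (n_cross > 0) {
    lines <- c(lines, vapply(seq_len(n_cross), function(i) {
      j <- (i %% n_proteins) + 1L
      mitab_line(acc[i], acc[j], genes[i], genes[j], taxonomy, taxonomy + 1L, 0.5)
    }, character(1)))
  }
  path <- path %||% tempfile(fileext = ".mitab")
  writeLines(lines, path)
  list(path = path, truth = truth, accessions = acc)
}
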