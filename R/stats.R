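#' Combine technical replicates into biological replicates
#'
#' Replaces each group of technical replicate samples by the arithmetic mean
#' of its observed (non-missing) raw values, per protein and experiment. A
#' group whose members are all missing stays missing. Combination happens on
#' the raw ratio scale, before any log transform.
#'
#' @param dataset a [quant_dataset()].
#' @param grouping vector of length `n_samples` assigning each sample slot of
#'   every experiment to a biological replicate (any labels; e.g.
#'   `c(1, 1, 2, 2, 3, 3)` for three biological x two technical replicates).
#' @return A [quant_dataset()] with one sample slot per biological replicate.
#' @export
combine_technical_replicates <- function(dataset, grouping) {
  stopifnot(inherits(dataset, "quant_dataset"))
  d <- dim(dataset$values)
  if (length(grouping) != d[3]) {
    config_error(sprintf(
      "grouping has %d entries but each experiment has %d samples",
      length(grouping), d[3]))
  }
  if (anyNA(grouping)) config_error("grouping must not contain NA")
  groups <- unique(grouping)
  values <- array(NA_real_, dim = c(d[1], d[2], length(groups)))
  for (g in seq_along(groups)) {
    sel <- which(grouping == groups[g])
    block <- dataset$values[, , sel, drop = FALSE]
    values[, , g] <- apply(block, c(1, 2), function(v) {
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    })
  }
  dimnames(values)[[3]] <- paste0("bio_", groups)
  quant_dataset(dataset$proteins, values, dataset$experiment_names)
}

#' Normalisation statistics: per-sample means and per-protein medians
#'
#' `sample_means()` returns, for every experiment `j` and sample `k`, the mean
#' of the observed raw values over all proteins. `protein_medians()` returns,
#' for every protein `i` and experiment `j`, the median of its observed raw
#' sample values. Both quantities feed the optional normalisation inside
#' [log2_transform()]; a sample (or protein/experiment cell) without any
#' observed value has an undefined statistic, returned as `NA`.
#'
#' @param dataset a [quant_dataset()].
#' @return `sample_means()`: an `n_experiments x n_samples` matrix.
#'   `protein_medians()`: an `n_proteins x n_experiments` matrix.
#' @export
sample_means <- function(dataset) {
  stopifnot(inherits(dataset, "quant_dataset"))
  if (n_proteins(dataset) == 0L) config_error("dataset has no proteins")
  out <- apply(dataset$values, c(2, 3), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  matrix(out, nrow = dim(dataset$values)[2],
         dimnames = list(dataset$experiment_names, NULL))
}

#' @rdname sample_means
#' @export
protein_medians <- function(dataset) {
  stopifnot(inherits(dataset, "quant_dataset"))
  if (n_proteins(dataset) == 0L) config_error("dataset has no proteins")
  out <- apply(dataset$values, c(1, 2), function(v) {
    if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE)
  })
  matrix(out, nrow = dim(dataset$values)[1],
         dimnames = list(dataset$proteins$accession, dataset$experiment_names))
}

#' Log2 transform with optional normalisation
#'
#' Transforms every raw value to the log2 scale. With `normalize = TRUE` each
#' value is first scaled by the protein/experiment median and the inverse of
#' the sample mean, `V' = log2(V * med[i, j] / smean[j, k])`, which centres
#' samples relative to each other while preserving each protein's own level
#' (the protein median enters multiplicatively; set
#' `median_action = "divide"` to use `V' = log2(V / med[i, j] / smean[j, k])`
#' instead — see the methods vignette for why both readings exist). With
#' `normalize = FALSE` the transform is a plain `log2(V)`.
#'
#' Nonpositive values cannot be log-transformed; they are set to missing with
#' a warning and recorded in the `"flagged_nonpositive"` attribute.
#'
#' @param dataset a [quant_dataset()] of raw (ratio-scale) values.
#' @param stats optional list with elements `sample_means` and
#'   `protein_medians` as returned by the accessors; computed from `dataset`
#'   when omitted.
#' @param normalize logical; apply the median/mean scaling?
#' @param median_action `"multiply"` (default) or `"divide"`; how the protein
#'   median enters the normalisation.
#' @return A [quant_dataset()]-shaped object whose values are on the log2
#'   scale (they may be negative, so it is a plain list with the same fields,
#'   class `log2_dataset`).
#' @export
log2_transform <- function(dataset, stats = NULL, normalize = TRUE,
                           median_action = c("multiply", "divide")) {
  stopifnot(inherits(dataset, "quant_dataset"))
  median_action <- match.arg(median_action)
  v <- dataset$values
  nonpos <- !is.na(v) & v <= 0
  if (any(nonpos)) {
    warning(sprintf("%d nonpositive value(s) set to missing before log2", sum(nonpos)),
            call. = FALSE)
    v[nonpos] <- NA_real_
  }
  if (normalize) {
    if (is.null(stats)) {
      tmp <- dataset
      tmp$values <- v
      stats <- list(sample_means = sample_means(tmp), protein_medians = protein_medians(tmp))
    }
    sm <- stats$sample_means
    pm <- stats$protein_medians
    d <- dim(v)
    for (j in seq_len(d[2])) {
      for (k in seq_len(d[3])) {
        col <- v[, j, k]
        need <- !is.na(col)
        if (!any(need)) next
        if (is.na(sm[j, k])) {
          config_error(sprintf("sample mean undefined for experiment %d sample %d", j, k))
        }
        if (anyNA(pm[need, j])) {
          config_error("protein median undefined for an observed value")
        }
        scale <- if (median_action == "multiply") pm[, j] else 1 / pm[, j]
        v[, j, k] <- log2(col * scale / sm[j, k])
      }
    }
  } else {
    v <- log2(v)
  }
  out <- list(proteins = dataset$proteins, values = v,
              experiment_names = dataset$experiment_names)
  class(out) <- "log2_dataset"
  attr(out, "flagged_nonpositive") <- which(nonpos, arr.ind = TRUE)
  attr(out, "normalized") <- normalize
  attr(out, "median_action") <- if (normalize) median_action else NA_character_
  out
}

#' Mean log2 enrichment ratio of one protein/experiment
#'
#' The enrichment ratio is the arithmetic mean of the observed log2-scale
#' sample values of one protein in one experiment. Fewer than two observed
#' values constitute an insufficient measurement and raise a condition of
#' class `apms_insufficiency` (within [compute_stats()] such records are
#' marked `insufficient` instead of erroring).
#'
#' @param values numeric vector of log2-scale sample values (`NA` = missing).
#' @return The mean of the observed values.
#' @export
enrichment_ratio <- function(values) {
  obs <- values[!is.na(values)]
  if (length(obs) < 2L) insufficiency_error()
  mean(obs)
}

#' One-sided paired t-test of log2 values against zero
#'
#' Tests whether the observed log2 sample values of one protein/experiment
#' deviate from zero (no enrichment). The paired test against the zero vector
#' reduces to a one-sample t statistic `t = mean / (sd / sqrt(n))` with sample
#' standard deviation (n - 1 denominator) and `df = n - 1`. The test is
#' one-sided in the direction of the observed mean, i.e. the reported p-value
#' is the upper-tail probability of `|t|`, which equals half the two-sided
#' p-value; depleted proteins (negative mean) therefore also obtain small
#' p-values on their own side.
#'
#' Degenerate cases: zero spread with nonzero mean yields the smallest
#' representable positive p with a warning; all values exactly zero carries no
#' evidence in either direction and yields p = 0.5 with a warning. Fewer than
#' two observed values raise an `apms_insufficiency` condition.
#'
#' @param values numeric vector of log2-scale sample values (`NA` = missing).
#' @return A p-value in (0, 1]; in (0, 0.5] whenever the mean is nonzero.
#' @export
one_sided_paired_t <- function(values) {
  obs <- values[!is.na(values)]
  n <- length(obs)
  if (n < 2L) insufficiency_error()
  m <- mean(obs)
  s <- sd(obs)
  if (s == 0) {
    if (m == 0) {
      warning("all values identical and zero: p = 0.5", call. = FALSE)
      return(0.5)
    }
    warning("zero spread with nonzero mean: p set to smallest positive value",
            call. = FALSE)
    return(.Machine$double.xmin)
  }
  t_stat <- m / (s / sqrt(n))
  pt(abs(t_stat), df = n - 1, lower.tail = FALSE)
}

#' Per-protein enrichment statistics for all experiments
#'
#' Runs the full statistics chain on a parsed dataset: optional normalisation
#' statistics, log2 transform, then per (protein, experiment) the number of
#' observed samples, the mean log2 enrichment ratio, its standard deviation
#' and the one-sided paired t-test p-value. Records with fewer than two
#' observed samples are marked `insufficient` and carry no ratio or p-value;
#' a single bad record never aborts the computation.
#'
#' @inheritParams log2_transform
#' @return A `stat_table`: data frame with columns `accession`, `gene_name`,
#'   `experiment`, `n_used`, `log2_ratio`, `sd`, `p_value`, `status`
#'   (`"computed"` or `"insufficient"`), one row per (protein, experiment).
#'   Provenance (normalisation flag, median action) is kept in attributes.
#' @export
compute_stats <- function(dataset, normalize = TRUE,
                          median_action = c("multiply", "divide")) {
  stopifnot(inherits(dataset, "quant_dataset"))
  median_action <- match.arg(median_action)
  n <- n_proteins(dataset)
  n_exp <- dim(dataset$values)[2]
  if (n == 0L) {
    out <- stat_table(data.frame(
      accession = character(), gene_name = character(), experiment = character(),
      n_used = integer(), log2_ratio = numeric(), sd = numeric(),
      p_value = numeric(), status = character(), stringsAsFactors = FALSE))
    attr(out, "normalized") <- normalize
    return(out)
  }
  lg <- suppressWarnings(log2_transform(dataset, normalize = normalize,
                                        median_action = median_action))
  rows <- vector("list", n * n_exp)
  idx <- 0L
  for (j in seq_len(n_exp)) {
    vj <- matrix(lg$values[, j, ], nrow = n)
    for (i in seq_len(n)) {
      obs <- vj[i, !is.na(vj[i, ])]
      idx <- idx + 1L
      if (length(obs) < 2L) {
        rows[[idx]] <- data.frame(
          accession = dataset$proteins$accession[i],
          gene_name = dataset$proteins$gene_name[i],
          experiment = dataset$experiment_names[j],
          n_used = length(obs), log2_ratio = NA_real_, sd = NA_real_,
          p_value = NA_real_, status = "insufficient", stringsAsFactors = FALSE)
      } else {
        rows[[idx]] <- data.frame(
          accession = dataset$proteins$accession[i],
          gene_name = dataset$proteins$gene_name[i],
          experiment = dataset$experiment_names[j],
          n_used = length(obs), log2_ratio = mean(obs), sd = sd(obs),
          p_value = suppressWarnings(one_sided_paired_t(obs)),
          status = "computed", stringsAsFactors = FALSE)
      }
    }
  }
  out <- stat_table(do.call(rbind, rows))
  attr(out, "normalized") <- normalize
  attr(out, "median_action") <- if (normalize) median_action else NA_character_
  out
}

#' Construct a statistics table from precomputed summaries
#'
#' Validates and classes a data frame of per-(protein, experiment) statistics.
#' Useful both internally and to analyse published summary tables (mean log2
#' ratio, SD, p-value) with the selection and annotation tools.
#'
#' @param df data frame with at least `accession`, `experiment`, `log2_ratio`,
#'   `p_value`; `gene_name`, `sd`, `n_used` and `status` are filled with
#'   defaults when absent.
#' @return The data frame with class `stat_table` prepended.
#' @export
stat_table <- function(df) {
  stopifnot(is.data.frame(df))
  for (col in c("accession", "experiment", "log2_ratio", "p_value")) {
    if (!col %in% names(df)) config_error(sprintf("stat table lacks column '%s'", col))
  }
  if (!"gene_name" %in% names(df)) df$gene_name <- df$accession
  if (!"sd" %in% names(df)) df$sd <- NA_real_
  if (!"n_used" %in% names(df)) df$n_used <- NA_integer_
  if (!"status" %in% names(df)) {
    df$status <- ifelse(is.na(df$p_value) | is.na(df$log2_ratio),
                        "insufficient", "computed")
  }
  bad_p <- df$status == "computed" & !is.na(df$p_value) &
    (df$p_value <= 0 | df$p_value > 1)
  if (any(bad_p)) config_error("computed p-values must lie in (0, 1]")
  rownames(df) <- NULL
  class(df) <- c("stat_table", class(df))
  df
}
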