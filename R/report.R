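stats_for_experiment <- function(stats, experiment) {
  stopifnot(inherits(stats, "stat_table"))
  if (!experiment %in% stats$experiment) {
    config_error(sprintf("experiment '%s' not present in the stat table (has: %s)",
                         experiment, paste(unique(stats$experiment), collapse = ", ")))
  }
  stats[stats$experiment == experiment, , drop = FALSE]
}

#' Volcano-plot table for one experiment
#'
#' Prepares the per-protein points of a volcano plot: the mean log2 enrichment
#' ratio on the abscissa against `-log10(p)` on the ordinate (the log scale
#' spreads the significant tail; set `log10_p = FALSE` to keep raw p-values).
#' Insufficient records carry no ratio or p-value and are excluded; their
#' number is reported in the `"n_insufficient"` attribute.
#'
#' @param stats a `stat_table` (see [compute_stats()]).
#' @param experiment experiment name to plot.
#' @param log10_p transform the ordinate to `-log10(p)`?
#' @return Data frame with `accession`, `gene_name`, `log2_ratio`, `p_value`
#'   and `y` (the ordinate value).
#' @export
volcano_table <- function(stats, experiment, log10_p = TRUE) {
  s <- stats_for_experiment(stats, experiment)
  n_insufficient <- sum(s$status != "computed")
  s <- s[s$status == "computed", , drop = FALSE]
  out <- data.frame(accession = s$accession, gene_name = s$gene_name,
                    log2_ratio = s$log2_ratio, p_value = s$p_value,
                    y = if (log10_p) -log10(s$p_value) else s$p_value,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_insufficient") <- n_insufficient
  out
}

#' Select proteins in the volcano significance region
#'
#' Returns every computed record of one experiment with
#' `log2_ratio > min_log2_ratio` and `p_value < max_p` (strict inequalities:
#' boundary values are excluded). This is the enriched/significant region in
#' the upper right of the volcano plot. The result is ordered by descending
#' ratio, ties broken by ascending accession, so output is deterministic.
#'
#' @param stats a `stat_table`.
#' @param experiment experiment name.
#' @param min_log2_ratio ratio threshold (e.g. 1 for 2-fold enrichment).
#' @param max_p p-value threshold in (0, 1].
#' @return Data frame of the selected records (subset of the stat table).
#' @export
select_significant <- function(stats, experiment, min_log2_ratio = 1,
                               max_p = 0.005) {
  if (!is.numeric(max_p) || length(max_p) != 1L || is.na(max_p) ||
      max_p <= 0 || max_p > 1) {
    config_error("'max_p' must lie in (0, 1]")
  }
  s <- stats_for_experiment(stats, experiment)
  s <- s[s$status == "computed" &
           s$log2_ratio > min_log2_ratio &
           s$p_value < max_p, , drop = FALSE]
  s <- s[order(-s$log2_ratio, s$accession), , drop = FALSE]
  rownames(s) <- NULL
  s
}

#' Condition-dependent (differential) binding calls
#'
#' Classifies every computed record of a condition-versus-condition
#' experiment (e.g. activated versus resting bait, quantified directly in a
#' multiplexed labelling design): proteins with `|log2_ratio| > min_abs_log2`
#' and `p_value < max_p` are called enriched in the condition the sign points
#' to (`enriched_condition_A` for positive ratios, i.e. the numerator
#' condition; `enriched_condition_B` for negative), all others `unchanged`.
#' The three classes partition the computed records.
#'
#' @param stats a `stat_table`.
#' @param experiment name of the condition-difference experiment.
#' @param min_abs_log2 absolute ratio threshold.
#' @param max_p p-value threshold.
#' @return Data frame with `accession`, `gene_name`, `diff_log2_ratio`,
#'   `diff_p` and `class`.
#' @export
differential_binding <- function(stats, experiment, min_abs_log2 = 1,
                                 max_p = 0.05) {
  s <- stats_for_experiment(stats, experiment)
  s <- s[s$status == "computed", , drop = FALSE]
  class <- ifelse(abs(s$log2_ratio) > min_abs_log2 & s$p_value < max_p,
                  ifelse(s$log2_ratio > 0, "enriched_condition_A",
                         "enriched_condition_B"),
                  "unchanged")
  out <- data.frame(accession = s$accession, gene_name = s$gene_name,
                    diff_log2_ratio = s$log2_ratio, diff_p = s$p_value,
                    class = class, stringsAsFactors = FALSE)
  out <- out[order(-out$diff_log2_ratio, out$accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate candidates with known-partner evidence
#'
#' Flags each candidate protein as "known" when the reference evidence lists
#' it as a partner of the bait: either an edge (bait, candidate) exists in a
#' merged `ppi_network`, or — when `reference` is a plain character vector of
#' identifiers, e.g. a curated literature set — the candidate is a member of
#' that set. The flags are independent of candidate ordering.
#'
#' @param candidates character vector of accessions, or a data frame with an
#'   `accession` column (e.g. the output of [select_significant()]).
#' @param reference a `ppi_network`, or a character vector of known-partner
#'   identifiers.
#' @param bait bait accession (needed for the network form; if absent from
#'   the network all flags are `FALSE` with a warning).
#' @return Data frame with `accession` and logical `known`; attribute
#'   `"summary"` holds `n_known` and `fraction` (`NA` for an empty candidate
#'   set).
#' @export
annotate_known <- function(candidates, reference, bait = NULL) {
  acc <- identity_frame(candidates)$accession
  if (inherits(reference, "ppi_network")) {
    if (is.null(bait)) config_error("'bait' is required with a network reference")
    if (!bait %in% reference$nodes$accession) {
      warning(sprintf("bait '%s' absent from the network: all flags FALSE", bait),
              call. = FALSE)
      partners <- character()
    } else {
      e <- reference$edges
      partners <- c(e$acc_b[e$acc_a == bait], e$acc_a[e$acc_b == bait])
    }
  } else if (is.character(reference)) {
    partners <- reference
  } else {
    config_error("'reference' must be a ppi_network or a character vector")
  }
  known <- acc %in% partners
  out <- data.frame(accession = acc, known = known, stringsAsFactors = FALSE)
  attr(out, "summary") <- list(
    n_known = sum(known),
    fraction = if (length(acc)) sum(known) / length(acc) else NA_real_)
  out
}

#' Export analysis objects to standard file formats
#'
#' Writes results to re-importable files: `"tsv"` for tabular objects (header
#' always written, so an empty selection yields a header-only file), `"json"`
#' for any serialisable object, and `"graphml"` for networks (via
#' \pkg{igraph}, readable by standard graph tools; node attributes include
#' status and depth, and layout coordinates when present).
#'
#' @param x a data frame, list, `ppi_network` or `annotated_network`.
#' @param format `"tsv"`, `"graphml"` or `"json"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_results <- function(x, format, path) {
  if (!is.character(format) || length(format) != 1L ||
      !format %in% c("tsv", "graphml", "json")) {
    config_error(sprintf("unknown export format '%s'",
                         paste(format, collapse = ",")))
  }
  if (format == "tsv") {
    if (inherits(x, "ppi_network") || inherits(x, "annotated_network")) {
      x <- x$edges
    }
    if (!is.data.frame(x)) config_error("tsv export needs a tabular object")
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  } else if (format == "graphml") {
    if (!(inherits(x, "ppi_network") || inherits(x, "annotated_network"))) {
      config_error("graphml export needs a network object")
    }
    g <- as_igraph(x)
    # igraph cannot serialise NA edge attributes reliably; encode as -1
    if (igraph::ecount(g) > 0 && "score" %in% igraph::edge_attr_names(g)) {
      sc <- igraph::E(g)$score
      sc[is.na(sc)] <- -1
      igraph::E(g)$score <- sc
    }
    igraph::write_graph(g, path, format = "graphml")
  } else {
    if (inherits(x, "ppi_network") || inherits(x, "annotated_network")) {
      x <- list(nodes = x$nodes, edges = x$edges)
    }
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' Static volcano plot
#'
#' Draws the volcano of one experiment with the significance region marked:
#' points inside the region (ratio and p-value passing the thresholds) are
#' highlighted. Uses base graphics; direct the device to PNG/SVG for file
#' output.
#'
#' @inheritParams select_significant
#' @param ... passed to [plot()].
#' @return The [volcano_table()] used, invisibly.
#' @export
plot_volcano <- function(stats, experiment, min_log2_ratio = 1, max_p = 0.005,
                         ...) {
  vt <- volcano_table(stats, experiment)
  sel <- vt$log2_ratio > min_log2_ratio & vt$p_value < max_p
  plot(vt$log2_ratio, vt$y, xlab = "log2 enrichment ratio",
       ylab = "-log10(p)", main = experiment,
       col = ifelse(sel, "red", "grey40"), pch = 19, ...)
  graphics::abline(v = min_log2_ratio, h = -log10(max_p), lty = 2, col = "grey60")
  invisible(vt)
}
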