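MARKER_CATEGORIES <- c("bead_proteome", "frequency_library", "negative",
                       "positive", "general")

#' Marker lists of known contaminants and reference proteins
#'
#' A marker list is a categorised set of identifiers (UniProt-style accessions
#' and/or gene names) used to flag proteins in a dataset: bead-proteome lists
#' (nonspecific bead binders), frequency libraries (proteins recurrently seen
#' across many pull-downs), and user-defined negative, positive and general
#' markers. Accessions match case-insensitively; gene names match exactly.
#'
#' `load_marker_list()` reads a plain-text file with one identifier per line;
#' `#` starts a comment and blank lines are ignored. Lines with embedded
#' whitespace are malformed and skipped with a warning. `marker_list()`
#' constructs the same object from a character vector.
#'
#' @param path text file with one identifier per line.
#' @param category one of `"bead_proteome"`, `"frequency_library"`,
#'   `"negative"`, `"positive"`, `"general"`.
#' @param name label for the list; defaults to the file name.
#' @return An object of class `marker_list`.
#' @export
load_marker_list <- function(path, category, name = NULL) {
  if (!file.exists(path)) config_error(sprintf("marker list file not found: %s", path))
  lines <- read_text_lines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  malformed <- grepl("[[:space:]]", lines)
  if (any(malformed)) {
    warning(sprintf("%d malformed line(s) skipped in %s", sum(malformed), path),
            call. = FALSE)
    lines <- lines[!malformed]
  }
  if (!length(lines)) config_error(sprintf("marker list %s contains no identifiers", path))
  marker_list(lines, category, name %||% basename(path))
}

#' @rdname load_marker_list
#' @param identifiers character vector of accessions and/or gene names.
#' @export
marker_list <- function(identifiers, category, name = "user") {
  category <- match.arg(category, MARKER_CATEGORIES)
  identifiers <- unique(trimws(as.character(identifiers)))
  identifiers <- identifiers[nzchar(identifiers)]
  if (!length(identifiers)) config_error("marker list must contain identifiers")
  structure(list(name = name, category = category, identifiers = identifiers),
            class = "marker_list")
}

#' @export
print.marker_list <- function(x, ...) {
  cat(sprintf("<marker_list> '%s' (%s): %d identifier(s)\n",
              x$name, x$category, length(x$identifiers)))
  invisible(x)
}

# accession / gene columns from the objects flags operate on
identity_frame <- function(x) {
  if (inherits(x, "quant_dataset")) {
    data.frame(accession = x$proteins$accession,
               gene_name = x$proteins$gene_name, stringsAsFactors = FALSE)
  } else if (is.data.frame(x) && "accession" %in% names(x)) {
    data.frame(accession = x$accession,
               gene_name = if ("gene_name" %in% names(x)) x$gene_name else NA_character_,
               stringsAsFactors = FALSE)
  } else if (is.character(x)) {
    data.frame(accession = x, gene_name = rep(NA_character_, length(x)),
               stringsAsFactors = FALSE)
  } else {
    config_error("cannot extract accession/gene identifiers from this object")
  }
}

#' Remove sparsely quantified proteins
#'
#' Drops every protein quantified in fewer than `min_measurements` samples
#' (technical replicates included, counted across all experiments). The
#' removal is reported per protein so every decision is auditable.
#'
#' @param dataset a [quant_dataset()].
#' @param min_measurements minimum number of observed values to retain a
#'   protein (e.g. 3 for "quantified in at least three measurements").
#' @param counts optional precomputed per-protein counts (defaults to
#'   [quantification_counts()] of `dataset`).
#' @return A list with `retained` (the filtered [quant_dataset()]) and
#'   `removed` (data frame of accession and count for every dropped protein).
#' @export
min_quantification_filter <- function(dataset, min_measurements = 3L, counts = NULL) {
  stopifnot(inherits(dataset, "quant_dataset"))
  if (!is_count(min_measurements)) {
    config_error("'min_measurements' must be a positive integer")
  }
  counts <- counts %||% quantification_counts(dataset)
  if (length(counts) != n_proteins(dataset)) {
    config_error("counts length must equal the number of proteins")
  }
  keep <- counts >= min_measurements
  list(
    retained = subset_dataset(dataset, keep),
    removed = data.frame(accession = dataset$proteins$accession[!keep],
                         n_quantified = as.integer(counts[!keep]),
                         stringsAsFactors = FALSE)
  )
}

#' Flag proteins that occur in marker lists
#'
#' Matches every protein of a dataset (or stat table, or plain accession
#' vector) against one or more [marker_list()]s and records all matching
#' (list, category) flags. Flagging is non-destructive; combine with
#' [drop_flagged()] to remove categories. Accessions are compared
#' case-insensitively, gene names exactly; the accession is tried first and
#' the gene name is the fallback key.
#'
#' @param x a [quant_dataset()], `stat_table`, data frame with an `accession`
#'   column, or character vector of accessions.
#' @param lists a single [marker_list()] or a list of them.
#' @return A `flag_state`: data frame with one row per (protein, matching
#'   list), columns `accession`, `list_name`, `category`, `matched_by`.
#' @export
apply_flags <- function(x, lists) {
  if (inherits(lists, "marker_list")) lists <- list(lists)
  stopifnot(all(vapply(lists, inherits, logical(1), "marker_list")))
  ids <- identity_frame(x)
  hits <- list()
  for (ml in lists) {
    upper_ids <- toupper(ml$identifiers)
    by_acc <- toupper(ids$accession) %in% upper_ids
    by_gene <- !by_acc & !is.na(ids$gene_name) & ids$gene_name %in% ml$identifiers
    matched <- by_acc | by_gene
    if (any(matched)) {
      hits[[length(hits) + 1L]] <- data.frame(
        accession = ids$accession[matched],
        list_name = ml$name,
        category = ml$category,
        matched_by = ifelse(by_acc[matched], "accession", "gene_name"),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(accession = character(), list_name = character(),
               category = character(), matched_by = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("flag_state", class(out))
  out
}

#' Drop flagged proteins by category
#'
#' Removes every protein carrying at least one flag whose category is in
#' `categories_to_drop`. Proteins flagged `positive` are never dropped —
#' positive markers are trusted identifications — and any such conflict is
#' reported. The operation is idempotent and order-independent with respect to
#' [min_quantification_filter()].
#'
#' @param x the object the flags were computed on (see [apply_flags()]).
#' @param flags a `flag_state` from [apply_flags()].
#' @param categories_to_drop character vector of categories to remove (subset
#'   of the marker categories); empty means no removal.
#' @return A list with `retained` (same type as `x`), `removed` (data frame of
#'   accession and justifying category) and `conflicts` (accessions protected
#'   by a positive flag).
#' @export
drop_flagged <- function(x, flags, categories_to_drop) {
  stopifnot(inherits(flags, "flag_state"))
  bad <- setdiff(categories_to_drop, MARKER_CATEGORIES)
  if (length(bad)) {
    config_error(sprintf("unknown categories: %s", paste(bad, collapse = ", ")))
  }
  ids <- identity_frame(x)
  droppable <- flags$accession[flags$category %in% categories_to_drop]
  positives <- flags$accession[flags$category == "positive"]
  conflicts <- intersect(droppable, positives)
  if (length(conflicts)) {
    message(sprintf("positive-marker precedence kept %d protein(s): %s",
                    length(conflicts), paste(conflicts, collapse = ", ")))
  }
  to_drop <- setdiff(droppable, positives)
  keep <- !(ids$accession %in% to_drop)

  retained <- if (inherits(x, "quant_dataset")) {
    subset_dataset(x, keep)
  } else if (is.data.frame(x)) {
    out <- x[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    x[keep]
  }
  removed_flags <- flags[flags$accession %in% ids$accession[!keep] &
                           flags$category %in% categories_to_drop, , drop = FALSE]
  removed <- unique(data.frame(accession = removed_flags$accession,
                               category = removed_flags$category,
                               stringsAsFactors = FALSE))
  rownames(removed) <- NULL
  list(retained = retained, removed = removed, conflicts = conflicts)
}
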