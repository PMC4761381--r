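#' The uniform quantitative AP-MS dataset
#'
#' A `quant_dataset` holds the parsed content of one quantification export:
#' per-protein identity metadata and a three-dimensional value tensor
#' `values[i, j, k]` of nonnegative abundance ratios for protein `i`,
#' experiment `j` and sample (replicate) `k`. Missing measurements are
#' represented explicitly as `NA`, never as zero.
#'
#' @param proteins data frame with columns `accession`, `gene_name`,
#'   `taxonomy`, `description`; accessions must be nonempty and unique.
#' @param values numeric array of dimension
#'   `nrow(proteins) x n_experiments x n_samples`; `NA` marks missing values.
#' @param experiment_names character vector naming the experiments.
#'
#' @return An object of class `quant_dataset`.
#' @seealso [parse_table()] which constructs these from delimited text.
#' @export
quant_dataset <- function(proteins, values, experiment_names = NULL) {
  stopifnot(is.data.frame(proteins), is.array(values), length(dim(values)) == 3L)
  required <- c("accession", "gene_name", "taxonomy", "description")
  missing_cols <- setdiff(required, names(proteins))
  if (length(missing_cols)) {
    config_error(sprintf("proteins table lacks column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  if (dim(values)[1] != nrow(proteins)) {
    config_error("first dimension of 'values' must match nrow(proteins)")
  }
  acc <- proteins$accession
  if (anyNA(acc) || any(!nzchar(acc))) config_error("accessions must be nonempty")
  if (anyDuplicated(acc)) config_error("accessions must be unique")
  if (any(values < 0, na.rm = TRUE)) config_error("values must be nonnegative")
  experiment_names <- experiment_names %||%
    dimnames(values)[[2]] %||%
    paste0("experiment_", seq_len(dim(values)[2]))
  if (length(experiment_names) != dim(values)[2]) {
    config_error("experiment_names length must equal the experiment dimension")
  }
  dimnames(values) <- list(acc, experiment_names, dimnames(values)[[3]])
  structure(
    list(proteins = proteins, values = values, experiment_names = experiment_names),
    class = "quant_dataset"
  )
}

#' @export
print.quant_dataset <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<quant_dataset> %d proteins x %d experiments x %d samples\n",
              d[1], d[2], d[3]))
  cat("experiments:", paste(x$experiment_names, collapse = ", "), "\n")
  n_missing <- sum(is.na(x$values))
  cat(sprintf("missing cells: %d of %d\n", n_missing, length(x$values)))
  invisible(x)
}

#' @export
dim.quant_dataset <- function(x) dim(x$values)

n_proteins <- function(dataset) dim(dataset$values)[1]

# row subset preserving structure and attributes of interest
subset_dataset <- function(dataset, keep) {
  proteins <- dataset$proteins[keep, , drop = FALSE]
  rownames(proteins) <- NULL
  values <- dataset$values[keep, , , drop = FALSE]
  quant_dataset(proteins, values, dataset$experiment_names)
}

#' Per-protein quantification counts
#'
#' Counts, for every protein, the number of observed (non-missing) sample
#' values across all experiments, i.e. the number of measurements in which the
#' protein was quantified (technical replicates included).
#'
#' @param dataset a [quant_dataset()].
#' @return Named integer vector (names are accessions).
#' @export
quantification_counts <- function(dataset) {
  apply(dataset$values, 1, function(v) sum(!is.na(v)))
}

#' Write and re-read the uniform dataset as TSV
#'
#' `write_dataset()` serialises a [quant_dataset()] to a tab-separated file
#' with one row per protein: the four identity columns followed by one value
#' column per (experiment, sample) slot, named `<experiment>|S<k>`. Missing
#' values are written as `NA`. `read_dataset()` reads such a file back;
#' the two functions round-trip identifiers and values exactly.
#'
#' @param dataset a [quant_dataset()].
#' @param path file path.
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()` a
#'   [quant_dataset()].
#' @export
write_dataset <- function(dataset, path) {
  d <- dim(dataset$values)
  # columns ordered experiment-major: E1|S1..E1|Sk, E2|S1..
  flat <- do.call(cbind, lapply(seq_len(d[2]), function(j) {
    matrix(dataset$values[, j, ], nrow = d[1])
  }))
  colnames(flat) <- as.vector(t(outer(dataset$experiment_names,
                                      paste0("S", seq_len(d[3])),
                                      paste, sep = "|")))
  out <- cbind(dataset$proteins[, c("accession", "gene_name", "taxonomy", "description")],
               as.data.frame(flat, check.names = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  tab <- read.delim(path, check.names = FALSE, na.strings = "NA",
                    colClasses = "character")
  value_cols <- grep("\\|S[0-9]+$", names(tab), value = TRUE)
  exps <- unique(sub("\\|S[0-9]+$", "", value_cols))
  ks <- sort(unique(as.integer(sub("^.*\\|S", "", value_cols))))
  values <- array(NA_real_, dim = c(nrow(tab), length(exps), length(ks)))
  for (j in seq_along(exps)) {
    for (k in ks) {
      col <- paste0(exps[j], "|S", k)
      if (col %in% names(tab)) values[, j, k] <- as.numeric(tab[[col]])
    }
  }
  proteins <- data.frame(
    accession = tab$accession,
    gene_name = tab$gene_name,
    taxonomy = as.integer(tab$taxonomy),
    description = tab$description,
    stringsAsFactors = FALSE
  )
  quant_dataset(proteins, values, exps)
}
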