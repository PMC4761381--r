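VALID_TARGETS <- c("accession", "gene_name", "description", "taxonomy", "sample_value")

#' Parse templates for column-separated quantification exports
#'
#' A parse template describes how one vendor or search-engine export maps onto
#' the uniform data model: how many header rows to skip, the field delimiter,
#' the experiment/sample layout, which source columns feed which target fields
#' (optionally through a regular expression with one capture group), and target
#' fields set to a fixed value (e.g. the taxonomy of a single-species study).
#' Templates are stored as human-editable YAML and can be reused for every
#' upcoming import of the same data source.
#'
#' `load_template()` accepts either a path to a YAML file or an equivalent
#' named list. The YAML schema is:
#'
#' \preformatted{
#' name: proteome_discoverer_3x6
#' header_rows: 1
#' field_delimiter: "\t"
#' n_experiments: 3
#' n_samples_per_experiment: 6
#' experiment_names: [pSTAT1_vs_GFP, STAT1_vs_GFP, pSTAT1_vs_STAT1]
#' fixed_values:
#'   taxonomy: 9606
#' mappings:
#'   - {source: Accession, target: accession}
#'   - {source: Description, target: gene_name, pattern: "GN=(.*) P"}
#'   - {source: "Ratio E1 S1", target: sample_value, experiment: 1, sample: 1}
#' }
#'
#' `source` is a header label (or, for headerless files, a 1-based column
#' index). Valid targets are `accession`, `gene_name`, `description`,
#' `taxonomy` and `sample_value`; the latter requires `experiment` and
#' `sample` indices and each (experiment, sample) slot may be mapped at most
#' once. The default extraction pattern `"(.*)"` takes the whole field.
#'
#' @param config path to a YAML template file, or a named list with the same
#'   structure.
#' @return A validated object of class `parse_template`.
#' @examples
#' tpl <- load_template(list(
#'   name = "minimal", header_rows = 0, field_delimiter = ",",
#'   n_experiments = 1, n_samples_per_experiment = 1,
#'   mappings = list(
#'     list(source = 1, target = "accession"),
#'     list(source = 2, target = "sample_value", experiment = 1, sample = 1)
#'   )
#' ))
#' @export
load_template <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) config_error(sprintf("template file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) config_error("template config must be a list or a YAML path")

  for (fld in c("header_rows", "field_delimiter", "n_experiments",
                "n_samples_per_experiment", "mappings")) {
    if (is.null(config[[fld]])) {
      config_error(sprintf("template is missing mandatory field '%s'", fld), field = fld)
    }
  }
  if (!is_count(config$header_rows, min = 0L)) {
    config_error("'header_rows' must be a nonnegative integer", field = "header_rows")
  }
  assert_scalar_string(config$field_delimiter, "field_delimiter")
  if (nchar(config$field_delimiter) != 1L) {
    config_error("'field_delimiter' must be a single character", field = "field_delimiter")
  }
  if (!is_count(config$n_experiments)) {
    config_error("'n_experiments' must be a positive integer", field = "n_experiments")
  }
  if (!is_count(config$n_samples_per_experiment)) {
    config_error("'n_samples_per_experiment' must be a positive integer",
                 field = "n_samples_per_experiment")
  }

  n_exp <- as.integer(config$n_experiments)
  n_samp <- as.integer(config$n_samples_per_experiment)
  exp_names <- config$experiment_names %||% paste0("experiment_", seq_len(n_exp))
  if (length(exp_names) != n_exp) {
    config_error("'experiment_names' length must equal n_experiments",
                 field = "experiment_names")
  }

  maps <- lapply(config$mappings, function(m) {
    if (is.null(m$source) || is.null(m$target)) {
      config_error("every mapping needs 'source' and 'target'", field = "mappings")
    }
    if (!m$target %in% VALID_TARGETS) {
      config_error(sprintf("unknown mapping target '%s'", m$target), field = "mappings")
    }
    pattern <- m$pattern %||% "(.*)"
    if (n_capture_groups(pattern) != 1L) {
      config_error(sprintf("extraction pattern '%s' must have exactly one capture group",
                           pattern), field = "mappings")
    }
    exp_i <- samp_k <- NA_integer_
    if (m$target == "sample_value") {
      if (!is_count(m$experiment %||% NA) || !is_count(m$sample %||% NA)) {
        config_error("sample_value mappings need 'experiment' and 'sample' indices",
                     field = "mappings")
      }
      exp_i <- as.integer(m$experiment)
      samp_k <- as.integer(m$sample)
      if (exp_i > n_exp || samp_k > n_samp) {
        config_error(sprintf("sample slot (%d, %d) outside the declared %d x %d layout",
                             exp_i, samp_k, n_exp, n_samp), field = "mappings")
      }
    }
    data.frame(source = as.character(m$source), target = m$target,
               pattern = pattern, experiment = exp_i, sample = samp_k,
               stringsAsFactors = FALSE)
  })
  column_map <- do.call(rbind, maps)

  slots <- column_map[column_map$target == "sample_value", c("experiment", "sample")]
  if (anyDuplicated(slots)) {
    dup <- slots[duplicated(slots), , drop = FALSE][1, ]
    config_error(sprintf("sample slot (%d, %d) is mapped more than once",
                         dup$experiment, dup$sample), field = "mappings")
  }

  fixed <- config$fixed_values %||% list()
  bad_fixed <- setdiff(names(fixed), setdiff(VALID_TARGETS, "sample_value"))
  if (length(bad_fixed)) {
    config_error(sprintf("fixed_values for unknown target(s): %s",
                         paste(bad_fixed, collapse = ", ")), field = "fixed_values")
  }

  structure(
    list(
      name = config$name %||% "unnamed",
      header_rows = as.integer(config$header_rows),
      field_delimiter = config$field_delimiter,
      n_experiments = n_exp,
      n_samples_per_experiment = n_samp,
      experiment_names = as.character(exp_names),
      column_map = column_map,
      fixed_values = fixed
    ),
    class = "parse_template"
  )
}

#' @export
print.parse_template <- function(x, ...) {
  cat(sprintf("<parse_template> '%s': %d header row(s), delimiter %s, %d experiment(s) x %d sample(s)\n",
              x$name, x$header_rows, deparse(x$field_delimiter),
              x$n_experiments, x$n_samples_per_experiment))
  cat(sprintf("%d column mapping(s), %d fixed value(s)\n",
              nrow(x$column_map), length(x$fixed_values)))
  invisible(x)
}

#' Save a parse template to YAML
#'
#' Writes a [load_template()] object back to its YAML representation so it can
#' be reused for later imports of the same data source. `load_template()` on
#' the written file reproduces the template.
#'
#' @param template a `parse_template`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_template <- function(template, path) {
  stopifnot(inherits(template, "parse_template"))
  cm <- template$column_map
  mappings <- lapply(seq_len(nrow(cm)), function(i) {
    m <- list(source = cm$source[i], target = cm$target[i], pattern = cm$pattern[i])
    if (cm$target[i] == "sample_value") {
      m$experiment <- cm$experiment[i]
      m$sample <- cm$sample[i]
    }
    m
  })
  out <- list(
    name = template$name,
    header_rows = template$header_rows,
    field_delimiter = template$field_delimiter,
    n_experiments = template$n_experiments,
    n_samples_per_experiment = template$n_samples_per_experiment,
    experiment_names = as.list(template$experiment_names),
    mappings = mappings
  )
  if (length(template$fixed_values)) out$fixed_values <- template$fixed_values
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Extract a field fragment with a one-group regular expression
#'
#' Applies an extraction pattern to one raw cell value and returns the content
#' of the single capture group of the first match. This is the primitive used
#' by [parse_table()] when a column mapping carries a pattern, e.g. pulling
#' the gene name out of a FASTA-style description with `"GN=(.*) P"`.
#'
#' @param raw_value the cell content (single string).
#' @param pattern regular expression with exactly one capture group; the
#'   default `"(.*)"` returns the whole field.
#' @return The captured substring.
#' @examples
#' extract_field("P42224", "(.*)")
#' extract_field("STAT1_HUMAN ... GN=STAT1 PE=1 SV=2", "GN=(.*) P")
#' @export
extract_field <- function(raw_value, pattern = "(.*)") {
  assert_scalar_string(raw_value, "raw_value")
  if (n_capture_groups(pattern) != 1L) {
    config_error(sprintf("pattern '%s' must have exactly one capture group", pattern))
  }
  m <- regexec(pattern, raw_value)[[1]]
  if (m[1] == -1L) {
    extraction_error(sprintf("pattern '%s' does not match '%s'", pattern, raw_value),
                     pattern = pattern)
  }
  substr(raw_value, m[2], m[2] + attr(m, "match.length")[2] - 1L)
}

# vectorised variant: NA where no match, attribute "failed" marks them
extract_field_vec <- function(raw_values, pattern) {
  m <- regexec(pattern, raw_values)
  out <- vapply(seq_along(raw_values), function(i) {
    mi <- m[[i]]
    if (is.na(raw_values[i]) || mi[1] == -1L) return(NA_character_)
    substr(raw_values[i], mi[2], mi[2] + attr(mi, "match.length")[2] - 1L)
  }, character(1))
  out
}

read_text_lines <- function(text) {
  if (length(text) == 1L && !grepl("[\n\t,;]", text) && file.exists(text)) {
    lines <- readLines(text, encoding = "UTF-8", warn = FALSE)
  } else if (length(text) == 1L && grepl("\n", text)) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- text
  }
  # tolerate a UTF-8 byte-order mark and DOS line endings
  if (length(lines)) lines[1] <- sub("^\ufeff", "", lines[1])
  sub("\r$", "", lines)
}

#' Parse delimited text into the uniform dataset
#'
#' Converts a column-separated quantification export into a [quant_dataset()]
#' using a [load_template()]. Header rows are skipped (the last header row
#' provides the column labels that mapping sources refer to); each content row
#' becomes one protein record. Cells that cannot be parsed as nonnegative
#' numbers become explicit missing values; rows with structural problems
#' (too few columns, empty or duplicate accession, failed mandatory
#' extraction) are flagged in the parse report rather than silently dropped,
#' although rows without a usable accession cannot be retained.
#'
#' @param text path to a delimited file, a single string with embedded
#'   newlines, or a character vector of lines.
#' @param template a `parse_template`.
#' @return A [quant_dataset()]; the parse report (rows read / retained /
#'   flagged with reasons, number of missing cells) is available via
#'   [parse_report()].
#' @export
parse_table <- function(text, template) {
  stopifnot(inherits(template, "parse_template"))
  lines <- read_text_lines(text)
  lines <- lines[seq_along(lines) > 0]
  if (length(lines) && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]  # trailing newline artefact
  }

  if (length(lines) < template$header_rows) {
    config_error("file has fewer lines than the declared header size")
  }
  header_labels <- NULL
  if (template$header_rows > 0L) {
    header_labels <- strsplit(lines[template$header_rows],
                              template$field_delimiter, fixed = TRUE)[[1]]
  }
  content <- lines[seq_along(lines) > template$header_rows]
  content <- content[nzchar(content)]

  cm <- template$column_map
  # resolve mapping sources to column indices
  col_idx <- vapply(cm$source, function(src) {
    if (!is.null(header_labels)) {
      hit <- which(header_labels == src)
      if (length(hit)) return(hit[1])
    }
    idx <- suppressWarnings(as.integer(src))
    if (!is.na(idx) && idx >= 1L) return(idx)
    config_error(sprintf("mapping source '%s' matches no header column", src))
  }, integer(1))
  max_col <- max(col_idx)

  n <- length(content)
  n_exp <- template$n_experiments
  n_samp <- template$n_samples_per_experiment
  values <- array(NA_real_, dim = c(n, n_exp, n_samp))
  meta <- data.frame(accession = rep(NA_character_, n),
                     gene_name = rep(NA_character_, n),
                     taxonomy = rep(NA_integer_, n),
                     description = rep(NA_character_, n),
                     stringsAsFactors = FALSE)
  for (fld in names(template$fixed_values)) {
    val <- template$fixed_values[[fld]]
    meta[[fld]] <- rep(if (fld == "taxonomy") as.integer(val) else
      as.character(val), n)
  }

  flags <- list()
  flag <- function(row, reason) flags[[length(flags) + 1L]] <<- data.frame(row = row, reason = reason)

  cells <- strsplit(content, template$field_delimiter, fixed = TRUE)
  short_rows <- which(vapply(cells, length, integer(1)) < max_col)
  for (r in short_rows) flag(r, "fewer columns than the template references")

  for (mi in seq_len(nrow(cm))) {
    raw <- vapply(cells, function(cc) {
      if (length(cc) >= col_idx[mi]) cc[[col_idx[mi]]] else NA_character_
    }, character(1))
    extracted <- extract_field_vec(raw, cm$pattern[mi])
    failed <- !is.na(raw) & nzchar(raw) & is.na(extracted)
    for (r in which(failed)) {
      flag(r, sprintf("pattern '%s' failed on column '%s'", cm$pattern[mi], cm$source[mi]))
    }
    if (cm$target[mi] == "sample_value") {
      num <- suppressWarnings(as.numeric(extracted))
      bad <- !is.na(extracted) & nzchar(extracted) & (is.na(num) | num < 0)
      if (any(bad)) {
        warning(sprintf("%d unparseable numeric cell(s) in column '%s' set to missing",
                        sum(bad), cm$source[mi]), call. = FALSE)
      }
      num[!is.na(num) & num < 0] <- NA_real_
      values[, cm$experiment[mi], cm$sample[mi]] <- num
    } else if (cm$target[mi] == "taxonomy") {
      meta$taxonomy <- suppressWarnings(as.integer(extracted))
    } else {
      meta[[cm$target[mi]]] <- extracted
    }
  }

  # rows must carry a nonempty accession; duplicates keep the first occurrence
  no_acc <- is.na(meta$accession) | !nzchar(meta$accession)
  for (r in which(no_acc)) flag(r, "missing accession")
  dup <- duplicated(meta$accession) & !no_acc
  for (r in which(dup)) flag(r, sprintf("duplicate accession '%s'", meta$accession[r]))
  keep <- !no_acc & !dup

  report <- list(
    rows_read = n,
    rows_retained = sum(keep),
    rows_flagged = if (length(flags)) do.call(rbind, flags) else
      data.frame(row = integer(), reason = character()),
    cells_missing = sum(is.na(values[keep, , , drop = FALSE]))
  )

  ds <- quant_dataset(meta[keep, , drop = FALSE],
                      values[keep, , , drop = FALSE],
                      template$experiment_names)
  attr(ds, "parse_report") <- report
  ds
}

#' @rdname parse_table
#' @param dataset a dataset returned by `parse_table()`.
#' @export
parse_report <- function(dataset) attr(dataset, "parse_report")

#' Preview the conversion of the first rows
#'
#' Runs the template conversion on the first `n_rows` content rows only, so a
#' template can be checked against a new export before committing to a full
#' parse. The result is identical to [parse_table()] restricted to those rows.
#'
#' @inheritParams parse_table
#' @param n_rows number of content rows to convert (clamped to the file size).
#' @return A [quant_dataset()] with at most `n_rows` records.
#' @export
preview_conversion <- function(text, template, n_rows = 5L) {
  if (!is_count(n_rows)) config_error("'n_rows' must be a positive integer")
  lines <- read_text_lines(text)
  keep <- min(length(lines), template$header_rows + n_rows)
  parse_table(lines[seq_len(keep)], template)
}
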