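INVALID_REASONS <- c("NO_ACCESSION", "NO_GENE_NAME", "NO_TAXONOMY",
                     "SELF_INTERACTION", "CROSS_TAXONOMY")

# "uniprotkb:P42224" -> P42224; anything else -> NA (preserved in raw_*)
mitab_uniprot <- function(field) {
  m <- regmatches(field, regexec("uniprotkb:([A-Za-z0-9_.-]+)", field))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, character(1))
}

# first "taxid:<int>" in the field
mitab_taxid <- function(field) {
  m <- regmatches(field, regexec("taxid:(-?[0-9]+)", field))
  vapply(m, function(x) if (length(x) == 2L) as.integer(x[2]) else NA_integer_,
         integer(1))
}

# alias column entry tagged "(gene name)"
mitab_gene <- function(field) {
  m <- regmatches(field, regexec("[a-z]+:([^|()]+)\\(gene name\\)", field))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, character(1))
}

# confidence column: prefer intact-miscore, else first key:number in [0,1]
mitab_score <- function(field) {
  vapply(field, function(f) {
    if (is.na(f) || f == "-" || !nzchar(f)) return(NA_real_)
    mi <- regmatches(f, regexec("intact-miscore:([0-9.eE+-]+)", f))[[1]]
    if (length(mi) == 2L) return(as.numeric(mi[2]))
    any_num <- regmatches(f, regexec("[a-zA-Z-]+:([0-9]*\\.?[0-9]+)", f))[[1]]
    if (length(any_num) == 2L) {
      v <- as.numeric(any_num[2])
      if (!is.na(v) && v >= 0 && v <= 1) return(v)
    }
    NA_real_
  }, numeric(1), USE.NAMES = FALSE)
}

# source database from column 13, e.g. "psi-mi:\"MI:0471\"(mentha)"
mitab_source <- function(field, fallback) {
  out <- vapply(field, function(f) {
    m <- regmatches(f, regexec("\\(([^()]+)\\)", f))[[1]]
    if (length(m) == 2L) m[2] else NA_character_
  }, character(1), USE.NAMES = FALSE)
  ifelse(is.na(out) | !nzchar(out), fallback, out)
}

#' Parse a PSI-MI TAB (MITAB 2.5/2.7) interaction file
#'
#' Reads tab-separated MITAB lines into a raw interaction table. Interactor
#' identifiers in the `uniprotkb` namespace become accessions; other
#' namespaces are kept verbatim in `raw_id_a`/`raw_id_b` for the identifier
#' mapping step. Gene names are taken from the alias columns (entries tagged
#' `(gene name)`), taxonomy from the first `taxid:` entry of columns 10/11,
#' and the confidence column is searched for an `intact-miscore` (or any
#' key:number in [0, 1]). Lines with fewer than 15 columns are malformed and
#' skipped (counted in the attached report).
#'
#' @param path MITAB file path.
#' @param source default database name for lines whose source-database column
#'   is uninformative; defaults to the file name without extension.
#' @return Data frame with columns `accession_a`, `accession_b`, `gene_a`,
#'   `gene_b`, `taxonomy_a`, `taxonomy_b`, `source`, `score`, `raw_id_a`,
#'   `raw_id_b`; the parse report is in attribute `"mitab_report"`.
#' @export
parse_mitab <- function(path, source = NULL) {
  if (!file.exists(path)) config_error(sprintf("MITAB file not found: %s", path))
  source <- source %||% sub("\\.[^.]*$", "", basename(path))
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  n_read <- length(lines)
  if (!n_read) {
    out <- empty_interactions()
    attr(out, "mitab_report") <- list(lines_read = 0L, parsed = 0L, skipped = 0L)
    return(out)
  }
  cells <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(cells, length, integer(1)) >= 15L
  n_skipped <- sum(!ok)
  cells <- cells[ok]
  if (!length(cells)) {
    out <- empty_interactions()
    attr(out, "mitab_report") <- list(lines_read = n_read, parsed = 0L,
                                      skipped = n_skipped)
    return(out)
  }
  col <- function(i) vapply(cells, `[[`, character(1), i)
  out <- data.frame(
    accession_a = mitab_uniprot(col(1)),
    accession_b = mitab_uniprot(col(2)),
    gene_a = mitab_gene(col(5)),
    gene_b = mitab_gene(col(6)),
    taxonomy_a = mitab_taxid(col(10)),
    taxonomy_b = mitab_taxid(col(11)),
    source = mitab_source(col(13), source),
    score = mitab_score(col(15)),
    raw_id_a = col(1),
    raw_id_b = col(2),
    stringsAsFactors = FALSE
  )
  attr(out, "mitab_report") <- list(lines_read = n_read, parsed = nrow(out),
                                    skipped = n_skipped)
  out
}

empty_interactions <- function() {
  data.frame(accession_a = character(), accession_b = character(),
             gene_a = character(), gene_b = character(),
             taxonomy_a = integer(), taxonomy_b = integer(),
             source = character(), score = numeric(),
             raw_id_a = character(), raw_id_b = character(),
             stringsAsFactors = FALSE)
}

#' Complete and validate interaction identifiers against a mapping table
#'
#' For every raw interaction, fills missing accessions, gene names and
#' taxonomy identifiers from an identifier-mapping table (UniProt
#' idmapping-style: one row per protein with `accession`, `gene_name`,
#' `taxonomy`). An interaction is valid only when, after completion, both
#' sides carry an accession, a gene name and a taxonomy. Failures are
#' classified with the first applicable reason in the order `NO_ACCESSION`,
#' `NO_GENE_NAME`, `NO_TAXONOMY`.
#'
#' @param interactions raw interaction data frame as from [parse_mitab()] (or
#'   a custom table with the same identifier columns).
#' @param idmap data frame with columns `accession`, `gene_name`, `taxonomy`.
#' @return The interaction table with filled fields plus `status`
#'   (`"valid"`/`"invalid"`) and `reason` (`"none"` or a failure code).
#' @export
resolve_identifiers <- function(interactions, idmap) {
  for (col in c("accession", "gene_name", "taxonomy")) {
    if (!col %in% names(idmap)) {
      config_error(sprintf("idmap lacks column '%s'", col))
    }
  }
  x <- interactions
  if (!nrow(x)) {
    x$status <- character(0)
    x$reason <- character(0)
    return(x)
  }
  by_acc <- setNames(seq_len(nrow(idmap)), toupper(idmap$accession))
  by_gene <- setNames(seq_len(nrow(idmap)), idmap$gene_name)

  fill_side <- function(acc, gene, tax, raw) {
    # try accession first, then gene name, then the verbatim raw identifier
    row <- by_acc[toupper(acc %||% NA_character_)]
    if (is.na(row) && !is.na(gene)) row <- by_gene[gene]
    if (is.na(row) && !is.na(raw)) {
      bare <- sub("^[a-z ]+:", "", raw)
      row <- by_acc[toupper(bare)]
      if (is.na(row)) row <- by_gene[bare]
    }
    if (!is.na(row)) {
      if (is.na(acc)) acc <- idmap$accession[row]
      if (is.na(gene)) gene <- idmap$gene_name[row]
      if (is.na(tax)) tax <- idmap$taxonomy[row]
    }
    list(acc = acc, gene = gene, tax = tax)
  }

  status <- character(nrow(x))
  reason <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    a <- fill_side(x$accession_a[i], x$gene_a[i], x$taxonomy_a[i],
                   if ("raw_id_a" %in% names(x)) x$raw_id_a[i] else NA_character_)
    b <- fill_side(x$accession_b[i], x$gene_b[i], x$taxonomy_b[i],
                   if ("raw_id_b" %in% names(x)) x$raw_id_b[i] else NA_character_)
    x$accession_a[i] <- a$acc; x$gene_a[i] <- a$gene; x$taxonomy_a[i] <- a$tax
    x$accession_b[i] <- b$acc; x$gene_b[i] <- b$gene; x$taxonomy_b[i] <- b$tax
    if (is.na(a$acc) || is.na(b$acc)) {
      status[i] <- "invalid"; reason[i] <- "NO_ACCESSION"
    } else if (is.na(a$gene) || is.na(b$gene)) {
      status[i] <- "invalid"; reason[i] <- "NO_GENE_NAME"
    } else if (is.na(a$tax) || is.na(b$tax)) {
      status[i] <- "invalid"; reason[i] <- "NO_TAXONOMY"
    } else {
      status[i] <- "valid"; reason[i] <- "none"
    }
  }
  x$status <- status
  x$reason <- reason
  x
}

#' Combine per-source interaction confidence scores
#'
#' Merges the confidence values attached to one interaction by different
#' databases into a single normalized score. The default noisy-OR rule,
#' `1 - prod(1 - s)`, treats each source score as an independent probability
#' that the interaction is real: the combined score is monotone nondecreasing
#' in every argument, never below the best single source, and 1 is absorbing.
#' `method = "max"` simply takes the best source.
#'
#' @param scores numeric vector of scores in [0, 1] (`NA`s are dropped).
#' @param method `"noisy_or"` (default) or `"max"`.
#' @return The combined score, or `NA` when no score is available.
#' @examples
#' combine_scores(c(0.6, 0.5))  # 0.8
#' @export
combine_scores <- function(scores, method = c("noisy_or", "max")) {
  method <- match.arg(method)
  scores <- scores[!is.na(scores)]
  if (!length(scores)) return(NA_real_)
  if (any(scores < 0 | scores > 1)) {
    config_error("scores must lie in [0, 1]")
  }
  switch(method,
         noisy_or = 1 - prod(1 - scores),
         max = max(scores))
}

#' Merge validated interactions into the nonredundant raw network
#'
#' Builds the undirected, source-annotated interaction network used as the
#' reference ("raw") network for all bait-centric analyses. Self-interactions
#' and pairs with differing taxonomy identifiers are dropped (reason codes
#' `SELF_INTERACTION` / `CROSS_TAXONOMY`); remaining interactions are keyed by
#' the lexicographically ordered accession pair, deduplicated within each
#' source, and merged across sources with the union of source names and a
#' combined confidence score (see [combine_scores()]). The merge report
#' accounts for every input interaction exactly once, per source.
#'
#' @param interactions a single validated interaction table (from
#'   [resolve_identifiers()], or any table with the interaction columns and no
#'   missing identifiers) or a list of such tables, one per source.
#' @param score_method passed to [combine_scores()].
#' @return An object of class `ppi_network`: list with `nodes` (accession,
#'   gene_name, taxonomy), `edges` (acc_a, acc_b, gene_a, gene_b, taxonomy,
#'   sources as `;`-joined names, score) and `report`.
#' @export
build_raw_network <- function(interactions, score_method = c("noisy_or", "max")) {
  score_method <- match.arg(score_method)
  if (is.data.frame(interactions)) interactions <- list(interactions)
  x <- do.call(rbind, lapply(interactions, function(df) {
    keep <- c("accession_a", "accession_b", "gene_a", "gene_b",
              "taxonomy_a", "taxonomy_b", "source", "score")
    missing_cols <- setdiff(keep, names(df))
    if (length(missing_cols)) {
      config_error(sprintf("interaction table lacks column(s): %s",
                           paste(missing_cols, collapse = ", ")))
    }
    df <- df[if ("status" %in% names(df)) df$status == "valid" else
      rep(TRUE, nrow(df)), keep, drop = FALSE]
    df
  }))
  report <- list(per_source = list(), dropped = list())
  if (is.null(x) || !nrow(x)) {
    return(new_ppi_network(
      nodes = data.frame(accession = character(), gene_name = character(),
                         taxonomy = integer(), stringsAsFactors = FALSE),
      edges = empty_edges(), report = report))
  }

  self_loop <- x$accession_a == x$accession_b
  cross_tax <- !self_loop & (x$taxonomy_a != x$taxonomy_b)
  report$dropped <- data.frame(
    accession_a = x$accession_a[self_loop | cross_tax],
    accession_b = x$accession_b[self_loop | cross_tax],
    source = x$source[self_loop | cross_tax],
    reason = ifelse(self_loop[self_loop | cross_tax],
                    "SELF_INTERACTION", "CROSS_TAXONOMY"),
    stringsAsFactors = FALSE)
  kept <- x[!self_loop & !cross_tax, , drop = FALSE]

  # canonical unordered pair
  flip <- kept$accession_a > kept$accession_b
  kept[flip, c("accession_a", "accession_b")] <- kept[flip, c("accession_b", "accession_a")]
  kept[flip, c("gene_a", "gene_b")] <- kept[flip, c("gene_b", "gene_a")]
  key <- paste(kept$accession_a, kept$accession_b, sep = "\r")

  # per-source deduplication first (max score within a source), then
  # cross-source combination
  per_source_key <- paste(key, kept$source, sep = "\r")
  first <- !duplicated(per_source_key)
  best <- tapply(kept$score, per_source_key, function(s) {
    s <- s[!is.na(s)]
    if (length(s)) max(s) else NA_real_
  })
  dedup <- kept[first, , drop = FALSE]
  dedup$score <- as.numeric(best[paste(paste(dedup$accession_a, dedup$accession_b,
                                             sep = "\r"), dedup$source, sep = "\r")])
  dkey <- paste(dedup$accession_a, dedup$accession_b, sep = "\r")
  groups <- split(seq_len(nrow(dedup)), dkey)
  edges <- do.call(rbind, lapply(groups, function(ix) {
    srcs <- sort(unique(dedup$source[ix]))
    data.frame(
      acc_a = dedup$accession_a[ix[1]],
      acc_b = dedup$accession_b[ix[1]],
      gene_a = dedup$gene_a[ix[1]],
      gene_b = dedup$gene_b[ix[1]],
      taxonomy = dedup$taxonomy_a[ix[1]],
      sources = paste(srcs, collapse = ";"),
      score = combine_scores(dedup$score[ix], method = score_method),
      stringsAsFactors = FALSE)
  }))
  edges <- edges[order(edges$acc_a, edges$acc_b), , drop = FALSE]
  rownames(edges) <- NULL

  node_df <- unique(rbind(
    data.frame(accession = kept$accession_a, gene_name = kept$gene_a,
               taxonomy = kept$taxonomy_a, stringsAsFactors = FALSE),
    data.frame(accession = kept$accession_b, gene_name = kept$gene_b,
               taxonomy = kept$taxonomy_b, stringsAsFactors = FALSE)))
  node_df <- node_df[!duplicated(node_df$accession), , drop = FALSE]
  node_df <- node_df[order(node_df$accession), , drop = FALSE]
  rownames(node_df) <- NULL

  # per-source accounting: valid-merged or dropped with one reason
  report$per_source <- lapply(split(seq_len(nrow(x)), x$source), function(ix) {
    list(total = length(ix),
         merged = sum(!self_loop[ix] & !cross_tax[ix]),
         self_interaction = sum(self_loop[ix]),
         cross_taxonomy = sum(cross_tax[ix]))
  })
  new_ppi_network(nodes = node_df, edges = edges, report = report)
}

empty_edges <- function() {
  data.frame(acc_a = character(), acc_b = character(), gene_a = character(),
             gene_b = character(), taxonomy = integer(), sources = character(),
             score = numeric(), stringsAsFactors = FALSE)
}

new_ppi_network <- function(nodes, edges, report = list()) {
  structure(list(nodes = nodes, edges = edges, report = report),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d node(s), %d nonredundant edge(s)\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Convert a network to an igraph object
#'
#' Exposes the package's network containers as undirected
#' \pkg{igraph} graphs with all node and edge attributes, for layouting,
#' GraphML export, and any downstream graph analysis.
#'
#' @param net a `ppi_network` or `annotated_network`.
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(net) {
  UseMethod("as_igraph")
}

#' @export
as_igraph.ppi_network <- function(net) {
  vertices <- data.frame(name = net$nodes$accession,
                         gene_name = net$nodes$gene_name,
                         taxonomy = net$nodes$taxonomy,
                         stringsAsFactors = FALSE)
  edges <- net$edges
  if (nrow(edges)) {
    d <- data.frame(from = edges$acc_a, to = edges$acc_b,
                    sources = edges$sources, score = edges$score,
                    stringsAsFactors = FALSE)
  } else {
    d <- data.frame(from = character(), to = character(),
                    sources = character(), score = numeric())
  }
  igraph::graph_from_data_frame(d, directed = FALSE, vertices = vertices)
}
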