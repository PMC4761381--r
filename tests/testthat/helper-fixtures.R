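# builders and independent brute-force oracles shared across tests

# quant_dataset from a values matrix (proteins x samples) for one experiment,
# or an array for several
toy_dataset <- function(values, accessions = NULL, genes = NULL,
                        experiments = NULL) {
  if (is.matrix(values)) values <- array(values, dim = c(nrow(values), 1L, ncol(values)))
  n <- dim(values)[1]
  accessions <- accessions %||% sprintf("ACC%03d", seq_len(n))
  genes <- genes %||% sprintf("G%03d", seq_len(n))
  proteins <- data.frame(accession = accessions, gene_name = genes,
                         taxonomy = rep(9606L, n),
                         description = rep(NA_character_, n),
                         stringsAsFactors = FALSE)
  quant_dataset(proteins, values, experiments)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-written BFS over an edge data frame (acc_a, acc_b); independent of the
# igraph code path used by focused_network()
bfs_distances <- function(edges, start, nodes) {
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  dist[start] <- 0
  frontier <- start
  d <- 0
  while (length(frontier)) {
    nb <- unique(c(edges$acc_b[edges$acc_a %in% frontier],
                   edges$acc_a[edges$acc_b %in% frontier]))
    nxt <- nb[dist[nb] == Inf]
    d <- d + 1
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

# brute-force nonredundant merge of an interaction table: canonical pairs,
# per-source max score, then noisy-OR across sources
dedup_oracle <- function(df) {
  a <- pmin(df$accession_a, df$accession_b)
  b <- pmax(df$accession_a, df$accession_b)
  keep <- a != b & df$taxonomy_a == df$taxonomy_b
  df <- data.frame(a = a[keep], b = b[keep], source = df$source[keep],
                   score = df$score[keep], stringsAsFactors = FALSE)
  out <- list()
  for (key in unique(paste(df$a, df$b))) {
    sub <- df[paste(df$a, df$b) == key, , drop = FALSE]
    per_source <- vapply(unique(sub$source), function(s) {
      sc <- sub$score[sub$source == s]
      sc <- sc[!is.na(sc)]
      if (length(sc)) max(sc) else NA_real_
    }, numeric(1))
    sc <- per_source[!is.na(per_source)]
    out[[key]] <- data.frame(
      acc_a = sub$a[1], acc_b = sub$b[1],
      sources = paste(sort(unique(sub$source)), collapse = ";"),
      score = if (length(sc)) 1 - prod(1 - sc) else NA_real_,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$acc_a, res$acc_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# direction-of-mean one-sided p via stats::t.test (independent oracle)
oracle_one_sided_p <- function(x) {
  x <- x[!is.na(x)]
  side <- if (mean(x) >= 0) "greater" else "less"
  stats::t.test(x, mu = 0, alternative = side)$p.value
}

# closed-form upper tail of |t| for df = 2
df2_tail <- function(t) 0.5 * (1 - abs(t) / sqrt(t^2 + 2))

make_interactions <- function(acc_a, acc_b, source, score = NA_real_,
                              tax_a = 9606L, tax_b = 9606L) {
  n <- length(acc_a)
  score <- rep(score, length.out = n)
  tax_a <- rep(tax_a, length.out = n)
  tax_b <- rep(tax_b, length.out = n)
  gene_of <- function(a) if (length(a)) paste0("g", a) else character(0)
  data.frame(accession_a = acc_a, accession_b = acc_b,
             gene_a = gene_of(acc_a), gene_b = gene_of(acc_b),
             taxonomy_a = tax_a, taxonomy_b = tax_b,
             source = source, score = score, stringsAsFactors = FALSE)
}

# small annotated network straight from edge/status tables
make_annotated <- function(edges, statuses, bait, depths = NULL) {
  nodes <- data.frame(accession = names(statuses),
                      gene_name = names(statuses), taxonomy = 9606L,
                      status = unname(statuses),
                      depth = if (is.null(depths)) NA_integer_ else
                        unname(depths[names(statuses)]),
                      stringsAsFactors = FALSE)
  if (!"provisional" %in% names(edges)) edges$provisional <- FALSE
  for (col in c("gene_a", "gene_b")) if (!col %in% names(edges)) edges[[col]] <- NA_character_
  if (!"taxonomy" %in% names(edges)) edges$taxonomy <- 9606L
  if (!"sources" %in% names(edges)) edges$sources <- "db"
  if (!"score" %in% names(edges)) edges$score <- NA_real_
  structure(list(nodes = nodes,
                 edges = edges[, c("acc_a", "acc_b", "gene_a", "gene_b",
                                   "taxonomy", "sources", "score", "provisional")],
                 bait = bait, report = NULL),
            class = "annotated_network")
}
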