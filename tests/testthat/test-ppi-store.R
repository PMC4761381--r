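test_that("MITAB lines parse identifiers, taxa and miscores", {
  path <- withr::local_tempfile(fileext = ".mitab")
  line <- paste("uniprotkb:P42224", "uniprotkb:P40763", "-", "-",
                "uniprotkb:STAT1(gene name)", "uniprotkb:STAT3(gene name)",
                "psi-mi:\"MI:0004\"(affinity chromatography technology)", "-",
                "pubmed:12345", "taxid:9606(human)", "taxid:9606(human)",
                "psi-mi:\"MI:0915\"(physical association)",
                "psi-mi:\"MI:0471\"(mentha)", "-",
                "author-score:low|intact-miscore:0.9", sep = "\t")
  writeLines(c("#ID(A)\tID(B)\t...", line), path)
  x <- parse_mitab(path)
  expect_equal(nrow(x), 1L)
  expect_equal(x$accession_a, "P42224")
  expect_equal(x$accession_b, "P40763")
  expect_equal(x$gene_a, "STAT1")
  expect_equal(x$gene_b, "STAT3")
  expect_equal(x$taxonomy_a, 9606L)
  expect_equal(x$taxonomy_b, 9606L)
  expect_equal(x$source, "mentha")
  expect_equal(x$score, 0.9)

  # missing confidence column value -> score absent
  line2 <- sub("author-score:low\\|intact-miscore:0.9$", "-", line)
  writeLines(line2, path)
  expect_true(is.na(parse_mitab(path)$score))

  # malformed (short) lines are skipped and counted
  writeLines(c(line, "uniprotkb:P1\tuniprotkb:P2"), path)
  x3 <- parse_mitab(path)
  expect_equal(nrow(x3), 1L)
  expect_equal(attr(x3, "mitab_report")$skipped, 1L)

  # empty file -> empty interaction list
  writeLines(character(0), path)
  expect_equal(nrow(parse_mitab(path)), 0L)
})

test_that("identifier resolution completes fields and orders failure reasons", {
  idmap <- data.frame(accession = c("P1", "P2"),
                      gene_name = c("G1", "G2"),
                      taxonomy = c(9606L, 9606L), stringsAsFactors = FALSE)
  # gene names only: both mappable -> valid with accessions filled
  raw <- make_interactions(NA_character_, NA_character_, "db")
  raw$gene_a <- "G1"; raw$gene_b <- "G2"
  raw$taxonomy_a <- NA_integer_; raw$taxonomy_b <- NA_integer_
  res <- resolve_identifiers(raw, idmap)
  expect_equal(res$status, "valid")
  expect_equal(res$accession_a, "P1")
  expect_equal(res$accession_b, "P2")
  expect_equal(res$taxonomy_a, 9606L)

  # unmappable interactor -> NO_ACCESSION (first applicable reason)
  raw2 <- raw
  raw2$gene_a <- "UNKNOWN"
  res2 <- resolve_identifiers(raw2, idmap)
  expect_equal(res2$status, "invalid")
  expect_equal(res2$reason, "NO_ACCESSION")

  # accession known but gene name not derivable -> NO_GENE_NAME
  raw3 <- make_interactions("P9", "P1", "db")
  raw3$gene_a <- NA_character_
  res3 <- resolve_identifiers(raw3, idmap)
  expect_equal(res3$reason, "NO_GENE_NAME")

  # complete interaction passes through unchanged
  ok <- make_interactions("P1", "P2", "db", 0.5)
  res4 <- resolve_identifiers(ok, idmap)
  expect_equal(res4$status, "valid")
  expect_equal(res4$reason, "none")
  expect_equal(res4[names(ok)], ok, ignore_attr = TRUE)
})

test_that("score combination is noisy-OR with max as an option", {
  expect_equal(combine_scores(c(0.6, 0.5)), 0.8)
  expect_equal(combine_scores(c(1, 0.3)), 1)
  expect_true(is.na(combine_scores(numeric(0))))
  expect_true(is.na(combine_scores(NA_real_)))
  expect_equal(combine_scores(c(0.6, 0.5), method = "max"), 0.6)
  expect_error(combine_scores(c(0.5, 1.2)), class = "apms_config_error")

  # monotone, and never below the best single source
  set.seed(2)
  for (i in 1:50) {
    s <- runif(sample(1:4, 1))
    comb <- combine_scores(s)
    expect_gte(comb, max(s))
    expect_lte(comb, 1)
    bumped <- pmin(s + 0.05, 1)
    expect_gte(combine_scores(bumped), comb)
  }
})

test_that("the raw-network merge drops, deduplicates and accounts per source", {
  inputs <- rbind(
    make_interactions("A", "B", "mentha", 0.6),
    make_interactions("B", "A", "intact", 0.5),
    make_interactions("A", "A", "biogrid"),
    make_interactions("A", "C", "dip", tax_a = 9606L, tax_b = 10090L))
  net <- build_raw_network(inputs)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$acc_a, "A")
  expect_equal(net$edges$acc_b, "B")
  expect_equal(net$edges$sources, "intact;mentha")
  expect_equal(net$edges$score, 0.8)  # 1 - 0.4 * 0.5
  expect_equal(sort(net$report$dropped$reason),
               c("CROSS_TAXONOMY", "SELF_INTERACTION"))
  # per-source accounting covers every input exactly once
  tot <- sum(vapply(net$report$per_source, `[[`, numeric(1), "total"))
  expect_equal(tot, nrow(inputs))

  # duplicate within one source counted once
  dup <- rbind(make_interactions("A", "B", "mentha", 0.6),
               make_interactions("A", "B", "mentha", 0.6))
  netd <- build_raw_network(dup)
  expect_equal(nrow(netd$edges), 1L)
  expect_equal(netd$edges$sources, "mentha")
  expect_equal(netd$edges$score, 0.6)

  # empty input -> empty network
  empty <- build_raw_network(make_interactions(character(0), character(0),
                                               character(0)))
  expect_equal(nrow(empty$edges), 0L)
  expect_equal(nrow(empty$nodes), 0L)
})

test_that("merging is order-independent and matches the brute-force oracle", {
  set.seed(9)
  n_edges <- 1000
  acc <- sprintf("P%03d", 1:40)
  df <- make_interactions(sample(acc, n_edges, TRUE), sample(acc, n_edges, TRUE),
                          sample(c("mentha", "intact", "mint"), n_edges, TRUE),
                          ifelse(runif(n_edges) < 0.2, NA_real_,
                                 round(runif(n_edges), 3)))
  df$taxonomy_b[runif(n_edges) < 0.05] <- 10090L

  net <- build_raw_network(df)
  oracle <- dedup_oracle(df)
  expect_equal(net$edges[, c("acc_a", "acc_b", "sources")],
               oracle[, c("acc_a", "acc_b", "sources")], ignore_attr = TRUE)
  expect_equal(net$edges$score, oracle$score, tolerance = 1e-12)

  # permuting the input changes nothing
  perm <- df[sample(nrow(df)), ]
  net2 <- build_raw_network(perm)
  expect_equal(net2$edges, net$edges)
  expect_equal(net2$nodes, net$nodes)

  # output size bounds
  expect_lte(nrow(net$edges), n_edges)
  expect_lte(nrow(net$nodes), 2 * nrow(net$edges))
})

test_that("score-free sources contribute provenance but no score", {
  mixed <- rbind(make_interactions("A", "B", "hprd"),
                 make_interactions("A", "B", "intact", 0.7))
  net <- build_raw_network(mixed)
  expect_equal(net$edges$sources, "hprd;intact")
  expect_equal(net$edges$score, 0.7)
  only_free <- build_raw_network(make_interactions("A", "B", "hprd"))
  expect_true(is.na(only_free$edges$score))
})
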