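test_that("technical replicates combine by the mean of observed values", {
  # all missingness patterns for a group of two technical replicates
  ds <- toy_dataset(matrix(c(2, 4,
                             2, NA,
                             NA, 2,
                             NA, NA), ncol = 2, byrow = TRUE))
  comb <- combine_technical_replicates(ds, c(1, 1))
  expect_equal(dim(comb), c(4L, 1L, 1L))
  expect_equal(as.vector(comb$values), c(3, 2, 2, NA))

  # grouping of the wrong length is a configuration error
  expect_error(combine_technical_replicates(ds, c(1, 1, 2)),
               class = "apms_config_error")

  # two groups stay separate
  ds2 <- toy_dataset(matrix(c(1, 3, 10, 20), nrow = 1))
  comb2 <- combine_technical_replicates(ds2, c("a", "a", "b", "b"))
  expect_equal(as.vector(comb2$values), c(2, 15))
})

test_that("sample means and protein medians use observed values only", {
  ds <- toy_dataset(matrix(c(1, NA, 3), ncol = 1))
  expect_equal(as.vector(sample_means(ds)), 2)
  ds1 <- toy_dataset(matrix(5, ncol = 1))
  expect_equal(as.vector(sample_means(ds1)), 5)

  med <- protein_medians(toy_dataset(matrix(c(1, 2, 10), nrow = 1)))
  expect_equal(as.vector(med), 2)
  expect_equal(as.vector(protein_medians(toy_dataset(matrix(c(1, 3), nrow = 1)))), 2)
  expect_equal(as.vector(protein_medians(toy_dataset(matrix(4, nrow = 1)))), 4)
  # no observed sample: statistic undefined
  expect_true(is.na(protein_medians(toy_dataset(matrix(NA_real_, nrow = 1)))[1]))
})

test_that("log2 transform applies the median/mean normalisation as documented", {
  # V = 2, med = 1, smean = 1: reduces to plain log2
  one <- toy_dataset(matrix(2, ncol = 1))
  st <- list(sample_means = matrix(1), protein_medians = matrix(1))
  expect_equal(as.vector(log2_transform(one, st, normalize = TRUE)$values), 1)
  # V = 4, med = 2, smean = 4: log2(4 * 2 / 4) = 1
  st2 <- list(sample_means = matrix(4), protein_medians = matrix(2))
  lg <- log2_transform(toy_dataset(matrix(4, ncol = 1)), st2, normalize = TRUE)
  expect_equal(as.vector(lg$values), 1)
  # divide option flips the median's role: log2(4 / 2 / 4) = -1
  lgd <- log2_transform(toy_dataset(matrix(4, ncol = 1)), st2, normalize = TRUE,
                        median_action = "divide")
  expect_equal(as.vector(lgd$values), -1)
  # normalize = FALSE is a plain log2
  expect_equal(as.vector(log2_transform(toy_dataset(matrix(8, ncol = 1)),
                                        normalize = FALSE)$values), 3)
  # nonpositive values flagged to missing with a warning
  expect_warning(
    lg0 <- log2_transform(toy_dataset(matrix(c(0, 4), nrow = 1)), normalize = FALSE),
    "nonpositive")
  expect_true(is.na(lg0$values[1, 1, 1]))
})

test_that("with unit medians and sample means normalisation is a no-op", {
  set.seed(41)
  vals <- matrix(2^rnorm(30), ncol = 3)
  ds <- toy_dataset(vals)
  st <- list(sample_means = matrix(1, 1, 3), protein_medians = matrix(1, 10, 1))
  expect_equal(log2_transform(ds, st, normalize = TRUE)$values,
               log2_transform(ds, normalize = FALSE)$values)
})

test_that("enrichment ratio is the mean of observed log2 values", {
  expect_equal(enrichment_ratio(c(1, 2, 3)), 2)
  expect_equal(enrichment_ratio(c(-1, 1)), 0)
  expect_equal(enrichment_ratio(c(3.40, 3.45, 3.50)), 3.45)
  expect_equal(enrichment_ratio(c(NA, 4, 6)), 5)
  expect_error(enrichment_ratio(c(NA, 4)), class = "apms_insufficiency")
  expect_error(enrichment_ratio(numeric(0)), class = "apms_insufficiency")
})

test_that("the one-sided paired t-test matches the df = 2 closed form", {
  # closed form for n = 3: P(T2 > t) = (1 - t / sqrt(t^2 + 2)) / 2
  x <- c(3.40, 3.45, 3.50)
  t_x <- mean(x) / (sd(x) / sqrt(3))
  expect_equal(one_sided_paired_t(x), df2_tail(t_x), tolerance = 1e-12)
  expect_equal(one_sided_paired_t(x), 3.5003e-5, tolerance = 1e-3)

  y <- c(1, 2, 3)
  expect_equal(one_sided_paired_t(y), df2_tail(mean(y) / (sd(y) / sqrt(3))),
               tolerance = 1e-12)
  expect_equal(one_sided_paired_t(y), 0.03709, tolerance = 1e-3)

  # degenerate spreads
  expect_warning(p0 <- one_sided_paired_t(c(0, 0, 0)))
  expect_equal(p0, 0.5)
  expect_warning(p1 <- one_sided_paired_t(c(2, 2, 2)))
  expect_gt(p1, 0)
  expect_lt(p1, 1e-100)
  expect_error(one_sided_paired_t(5), class = "apms_insufficiency")
})

test_that("p decreases strictly in |t| and is symmetric for depletion", {
  base <- c(-0.5, 0, 0.5)
  shifts <- c(0.2, 0.5, 1, 2, 5)
  ps <- vapply(shifts, function(m) one_sided_paired_t(base + m), numeric(1))
  expect_true(all(diff(ps) < 0))
  # negative means are their own side's evidence: p identical under sign flip
  expect_equal(one_sided_paired_t(-(base + 2)), one_sided_paired_t(base + 2))
})

test_that("ratio and test agree with an independent oracle on random triples", {
  set.seed(7)
  for (i in 1:1000) {
    x <- rnorm(3, mean = runif(1, -3, 3), sd = runif(1, 0.01, 2))
    expect_equal(enrichment_ratio(x), sum(x) / 3, tolerance = 1e-12)
    p <- one_sided_paired_t(x)
    expect_equal(p, oracle_one_sided_p(x), tolerance = 1e-12)
  }
})

test_that("directional false-positive rate on null proteins is controlled", {
  set.seed(11)
  n_null <- 5000
  x <- matrix(rnorm(n_null * 3, mean = 0, sd = 0.3), ncol = 3)
  calls <- vapply(seq_len(n_null), function(i) {
    mean(x[i, ]) > 0 && one_sided_paired_t(x[i, ]) < 0.05
  }, logical(1))
  expect_lte(mean(calls), 0.06)
})

test_that("compute_stats applies the full chain with the insufficiency rule", {
  # one protein quantified once: insufficient, no ratio or p
  ds <- toy_dataset(matrix(c(4, NA, NA), nrow = 1))
  st <- compute_stats(ds, normalize = FALSE)
  expect_equal(st$status, "insufficient")
  expect_equal(st$n_used, 1L)
  expect_true(is.na(st$log2_ratio) && is.na(st$p_value))

  # a bad row never aborts the rest
  ds2 <- toy_dataset(matrix(c(4, NA, NA,
                              2, 4, 8), ncol = 3, byrow = TRUE))
  st2 <- compute_stats(ds2, normalize = FALSE)
  expect_equal(st2$status, c("insufficient", "computed"))
  expect_equal(st2$log2_ratio[2], 2)
  expect_equal(st2$sd[2], 1)

  # empty dataset gives an empty table
  empty <- toy_dataset(matrix(numeric(0), nrow = 0, ncol = 2))
  expect_equal(nrow(compute_stats(empty)), 0L)
  expect_s3_class(compute_stats(empty), "stat_table")

  # one record per (protein, experiment)
  vals <- array(2^rnorm(12), dim = c(2, 3, 2))
  st3 <- compute_stats(toy_dataset(vals, experiments = c("a", "b", "c")),
                       normalize = FALSE)
  expect_equal(nrow(st3), 6L)
  expect_equal(sort(unique(st3$experiment)), c("a", "b", "c"))
})
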