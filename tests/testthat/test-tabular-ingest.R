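supp_template <- function() {
  load_template(list(
    name = "pd_3x6", header_rows = 1, field_delimiter = "\t",
    n_experiments = 3, n_samples_per_experiment = 6,
    experiment_names = c("pSTAT1_vs_GFP", "STAT1_vs_GFP", "pSTAT1_vs_STAT1"),
    fixed_values = list(taxonomy = 9606),
    mappings = c(
      list(list(source = "Accession", target = "accession"),
           list(source = "Description", target = "gene_name", pattern = "GN=(.*) P"),
           list(source = "Description", target = "description")),
      unlist(lapply(1:3, function(j) lapply(1:6, function(k) {
        list(source = sprintf("Ratio E%d S%d", j, k), target = "sample_value",
             experiment = j, sample = k)
      })), recursive = FALSE)
    )
  ))
}

test_that("a realistic search-engine template validates and round-trips", {
  tpl <- supp_template()
  expect_s3_class(tpl, "parse_template")
  expect_equal(tpl$n_experiments, 3L)
  expect_equal(tpl$n_samples_per_experiment, 6L)
  expect_equal(tpl$fixed_values$taxonomy, 9606)
  expect_equal(sum(tpl$column_map$target == "sample_value"), 18L)

  path <- withr::local_tempfile(fileext = ".yaml")
  save_template(tpl, path)
  expect_equal(load_template(path), tpl)
})

test_that("minimal template is legal and invalid configurations name the field", {
  tpl <- load_template(list(
    header_rows = 0, field_delimiter = ",", n_experiments = 1,
    n_samples_per_experiment = 1,
    mappings = list(list(source = 1, target = "accession"),
                    list(source = 2, target = "sample_value",
                         experiment = 1, sample = 1))))
  expect_s3_class(tpl, "parse_template")

  base <- list(header_rows = 0, field_delimiter = ",", n_experiments = 1,
               n_samples_per_experiment = 1,
               mappings = list(list(source = 1, target = "accession")))
  bad <- base
  bad$n_samples_per_experiment <- 0
  expect_error(load_template(bad), class = "apms_config_error")
  bad <- base
  bad$field_delimiter <- NULL
  err <- tryCatch(load_template(bad), error = identity)
  expect_s3_class(err, "apms_config_error")
  expect_equal(err$field, "field_delimiter")
  # a sample slot mapped twice is rejected
  bad <- base
  bad$mappings <- list(
    list(source = 2, target = "sample_value", experiment = 1, sample = 1),
    list(source = 3, target = "sample_value", experiment = 1, sample = 1))
  expect_error(load_template(bad), class = "apms_config_error")
  # two-group patterns are rejected
  bad <- base
  bad$mappings <- list(list(source = 1, target = "accession",
                            pattern = "(a)(b)"))
  expect_error(load_template(bad), class = "apms_config_error")
})

test_that("extract_field returns the capture group of the first match", {
  expect_identical(extract_field("P42224", "(.*)"), "P42224")
  desc <- "STAT1_HUMAN Signal transducer and activator of transcription 1 GN=STAT1 PE=1 SV=2"
  expect_identical(extract_field(desc, "GN=(.*) P"), "STAT1")
  # cross-check against an independent regex route (sub with backreference)
  expect_identical(sub(".*GN=(.*) P.*", "\\1", desc), "STAT1")
  expect_error(extract_field("no gene tag here", "GN=(.*) P"),
               class = "apms_extraction_error")
})

test_that("parse_table transcribes values, keeps row order and flags problems", {
  tpl <- load_template(list(
    header_rows = 1, field_delimiter = "\t", n_experiments = 1,
    n_samples_per_experiment = 2,
    mappings = list(list(source = "acc", target = "accession"),
                    list(source = "v1", target = "sample_value",
                         experiment = 1, sample = 1),
                    list(source = "v2", target = "sample_value",
                         experiment = 1, sample = 2))))
  txt <- c("acc\tv1\tv2", "P1\t1.0\t2.0", "P2\t3.0\t4.0")
  ds <- parse_table(txt, tpl)
  expect_equal(dim(ds), c(2L, 1L, 2L))
  expect_equal(ds$proteins$accession, c("P1", "P2"))
  expect_equal(as.vector(ds$values[, 1, ]), c(1, 3, 2, 4))

  # an unparseable numeric cell becomes missing, the record survives
  ds2 <- suppressWarnings(parse_table(c("acc\tv1\tv2", "P1\tNA\t2.0"), tpl))
  expect_equal(dim(ds2)[1], 1L)
  expect_true(is.na(ds2$values[1, 1, 1]))
  expect_equal(ds2$values[1, 1, 2], 2)
  expect_equal(parse_report(ds2)$cells_missing, 1L)

  # header-only file: empty dataset, not an error
  ds3 <- parse_table("acc\tv1\tv2", tpl)
  expect_equal(dim(ds3)[1], 0L)

  # short row flagged with a reason; duplicate accession keeps the first
  ds4 <- parse_table(c("acc\tv1\tv2", "P1\t1.0\t2.0", "P2\t5.0",
                       "P1\t7.0\t8.0"), tpl)
  rep4 <- parse_report(ds4)
  expect_equal(rep4$rows_read, 3L)
  expect_equal(ds4$proteins$accession, c("P1", "P2"))
  expect_equal(ds4$values[1, 1, 1], 1)  # first occurrence wins
  expect_true(any(grepl("fewer columns", rep4$rows_flagged$reason)))
  expect_true(any(grepl("duplicate accession", rep4$rows_flagged$reason)))
})

test_that("preview equals the prefix of the full parse for all n", {
  tpl <- load_template(list(
    header_rows = 1, field_delimiter = ",", n_experiments = 1,
    n_samples_per_experiment = 1,
    mappings = list(list(source = "acc", target = "accession"),
                    list(source = "v", target = "sample_value",
                         experiment = 1, sample = 1))))
  txt <- c("acc,v", paste0("P", 1:5, ",", 1:5))
  full <- parse_table(txt, tpl)
  for (n in 1:7) {
    prev <- preview_conversion(txt, tpl, n_rows = n)
    m <- min(n, 5L)
    expect_equal(prev$proteins, full$proteins[seq_len(m), , drop = FALSE])
    expect_equal(as.vector(prev$values), as.vector(full$values[seq_len(m), , ]))
  }
})

test_that("serialised datasets round-trip identifiers and values exactly", {
  vals <- array(c(1.5, NA, 2.25, 4, 0.5, 8, NA, 16, 3, 5, 7, 11),
                dim = c(2, 3, 2))
  ds <- toy_dataset(vals, experiments = c("e1", "e2", "e3"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_equal(back$proteins$accession, ds$proteins$accession)
  expect_equal(back$experiment_names, ds$experiment_names)
  expect_equal(back$values, ds$values, ignore_attr = TRUE)
})

test_that("a UTF-8 byte-order mark does not disturb header matching", {
  tpl <- load_template(list(
    header_rows = 1, field_delimiter = ",", n_experiments = 1,
    n_samples_per_experiment = 1,
    mappings = list(list(source = "acc", target = "accession"),
                    list(source = "v", target = "sample_value",
                         experiment = 1, sample = 1))))
  ds <- parse_table(c("\ufeffacc,v", "P1,2.0"), tpl)
  expect_equal(ds$proteins$accession, "P1")
  expect_equal(ds$values[1, 1, 1], 2)
})
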