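test_that("matrix loading keeps clean proteins and drops incomplete ones", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "m.csv")
  writeLines(c("protein,S1,S2,S3,S4",
               "P1,1,2,3,4",
               "P2,5,NA,7,8",
               "P3,9,10,11,12"), csv)
  suppressMessages(mat <- read_matrix(csv))
  expect_s3_class(mat, "expression_matrix")
  expect_equal(dim(mat), c(2L, 4L))
  expect_equal(mat$protein_ids, c("P1", "P3"))
  expect_equal(mat$scale_tag, "raw")
})

test_that("malformed cells and duplicate identifiers are rejected", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.csv")
  writeLines(c("protein,S1,S2,S3", "P1,1,x,3", "P2,4,5,6"), bad)
  expect_error(read_matrix(bad), "non-numeric")
  dup <- file.path(dir, "dup.csv")
  writeLines(c("protein,S1,S2,S3", "P1,1,2,3", "P1,4,5,6"), dup)
  expect_error(read_matrix(dup), "duplicate")
  expect_error(expression_matrix(matrix(1:6, 2, 3),
                                 protein_ids = c("A", "A"),
                                 sample_ids = c("S1", "S2", "S3")),
               "duplicate protein")
})

test_that("write/read round trip reproduces values to 1e-12", {
  set.seed(99)
  vals <- matrix(rnorm(30) * 10^sample(-3:3, 30, TRUE), 5, 6,
                 dimnames = list(paste0("P", 1:5), paste0("S", 1:6)))
  mat <- tiny_matrix(vals)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "rt.csv")
  write_matrix(mat, p)
  back <- read_matrix(p)
  expect_lt(max(abs(back$values - vals)), 1e-12)
  expect_identical(back$protein_ids, mat$protein_ids)
})

test_that("samples_as_rows orientation transposes on load", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "t.csv")
  writeLines(c("sample,P1,P2", "S1,1,4", "S2,2,5", "S3,3,6"), csv)
  mat <- read_matrix(csv, orientation = "samples_as_rows")
  expect_equal(dim(mat), c(2L, 3L))
  expect_equal(mat$values["P2", "S3"], 6)
})

test_that("configuration defaults reproduce the reference schedule and are validated", {
  cfg <- run_config()
  expect_equal(cfg$pretrain_epochs_early, 7L)
  expect_equal(cfg$pretrain_epochs_last, 20L)
  expect_equal(cfg$finetune_epochs, 20L)
  expect_equal(cfg$retrain_epochs, 200L)
  expect_equal(cfg$q_norm, 1)
  expect_equal(cfg$lambda_reg, 0)
  expect_equal(cfg$outlier_sigma, 2)
  expect_equal(cfg$amplitude_rescue_percentile, 75)
  expect_error(run_config(finetune_epochs = 0), "epoch")
  expect_error(run_config(q_norm = 0), "q_norm")
  expect_error(run_config(lambda_reg = -1), "lambda")
})

test_that("configuration round-trips through YAML and rejects unknown keys", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "cfg.yaml")
  writeLines(c("seed: 7", "q_norm: 2", "regularizer: tv"), p)
  cfg <- read_config(p)
  expect_equal(cfg$seed, 7L)
  expect_equal(cfg$q_norm, 2)
  expect_equal(cfg$regularizer, "tv")
  writeLines("not_a_key: 1", p)
  expect_error(read_config(p), "unknown configuration keys")
})

test_that("result tables convert phases to degrees and hours and flag outliers", {
  ds <- generate_synthetic(synthetic_spec(m = 12, n = 40, rhythmic_fraction = 0.5,
                                          noise_sd = 0.2, seed = 3))
  fit <- suppressMessages(run_pipeline(run_config(seed = 5, retrain_epochs = 5L),
                                       ds$matrix))
  st <- fit$sample_table
  ok <- !is.na(st$phase_radians)
  expect_equal(st$phase_degrees[ok], st$phase_radians[ok] * 180 / pi)
  expect_equal(st$phase_hours[ok], st$phase_radians[ok] * 12 / pi)
  # every input protein appears exactly once, outliers flagged without calls
  pt <- fit$protein_table
  expect_setequal(pt$protein_id, ds$matrix$protein_ids)
  expect_equal(anyDuplicated(pt$protein_id), 0L)
  out <- pt$protein_id[pt$outlier_flag]
  expect_true(all(is.na(pt$fdr[pt$outlier_flag])))
  expect_length(intersect(out, fit$rhythmic_ids), 0)
  dir <- withr::local_tempdir()
  paths <- write_results(fit, dir)
  expect_true(all(file.exists(paths)))
})

test_that("pipeline runs are reproducible and tiny inputs are rejected", {
  ds <- generate_synthetic(synthetic_spec(m = 10, n = 30, rhythmic_fraction = 0.5,
                                          noise_sd = 0.2, seed = 21))
  cfg <- run_config(seed = 9, retrain_epochs = 5L)
  f1 <- suppressMessages(run_pipeline(cfg, ds$matrix))
  f2 <- suppressMessages(run_pipeline(cfg, ds$matrix))
  expect_identical(f1$sample_table, f2$sample_table)
  expect_identical(f1$protein_table, f2$protein_table)
  dir <- withr::local_tempdir()
  write_results(f1, file.path(dir, "a"))
  write_results(f2, file.path(dir, "b"))
  for (f in c("sample_phases.csv", "protein_stats.csv"))
    expect_identical(readLines(file.path(dir, "a", f)),
                     readLines(file.path(dir, "b", f)))
  expect_error(expression_matrix(matrix(rnorm(4), 2, 2)), "3 samples")
})
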