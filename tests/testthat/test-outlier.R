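test_that("signed residual means match the definition, including cancellation", {
  obs <- matrix(c(1, -1), 1, 2)
  pred <- matrix(0, 1, 2)
  rs <- compute_residuals(obs, pred)
  expect_equal(unname(rs$protein_residuals), 0)   # +1 and -1 cancel
  obs2 <- pred2 <- matrix(rnorm(12), 3, 4)
  rs2 <- compute_residuals(obs2, pred2)
  expect_true(all(rs2$sample_residuals == 0) && all(rs2$protein_residuals == 0))
  set.seed(44)
  o <- matrix(rnorm(24), 4, 6); p <- matrix(rnorm(24), 4, 6)
  rs3 <- compute_residuals(o, p)
  Ei <- numeric(6); Dp <- numeric(4)
  for (i in 1:6) Ei[i] <- sum(o[, i] - p[, i]) / 4
  for (q in 1:4) Dp[q] <- sum(o[q, ] - p[q, ]) / 6
  expect_equal(unname(rs3$sample_residuals), Ei)
  expect_equal(unname(rs3$protein_residuals), Dp)
  # population SD
  expect_equal(rs3$sample_sd, sqrt(mean((Ei - mean(Ei))^2)))
})

fake_summary <- function(Ei, Dp) {
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  structure(list(sample_residuals = Ei, sample_mean = mean(Ei),
                 sample_sd = pop_sd(Ei), protein_residuals = Dp,
                 protein_mean = mean(Dp), protein_sd = pop_sd(Dp)),
            class = "residual_summary")
}

test_that("two-sigma flagging follows the hand-computed mean and SD", {
  # residuals (0 x9, 10): mean 1, population SD 3 -> only the 10 deviates > 2 SD
  Ei <- c(rep(0, 9), 10)
  rs <- fake_summary(Ei, rep(0, 4))
  rep_ <- flag_outliers(rs, rep(1, 4), run_config())
  expect_equal(rep_$outlier_samples, "S10")
  expect_length(rep_$candidate_proteins, 0)
  # all-equal residuals: sigma = 0 branch, nothing flagged
  rs0 <- fake_summary(rep(2, 6), rep(-1, 5))
  rep0 <- flag_outliers(rs0, rep(1, 5), run_config())
  expect_length(rep0$outlier_samples, 0)
  expect_length(rep0$candidate_proteins, 0)
})

test_that("high-amplitude candidates are rescued, low-amplitude ones confirmed", {
  Dp <- c(rep(0, 8), 5, -5)
  rs <- fake_summary(rep(0, 6), Dp)
  amps <- c(seq(0.1, 0.8, length.out = 8), 10, 0.01)  # P9 top amplitude, P10 tiny
  rep_ <- flag_outliers(rs, amps, run_config())
  expect_setequal(rep_$candidate_proteins, c("P9", "P10"))
  expect_equal(rep_$confirmed_outlier_proteins, "P10")
  # rescue rule: nothing in the top quartile of amplitude is ever confirmed
  q75 <- quantile(amps, 0.75, type = 7)
  confirmed_amps <- amps[match(rep_$confirmed_outlier_proteins,
                               paste0("P", 1:10))]
  expect_true(all(confirmed_amps < q75))
})

test_that("screening inside the pipeline is consistent and bookkept", {
  ds <- generate_synthetic(synthetic_spec(m = 12, n = 200, rhythmic_fraction = 0.5,
                                          noise_sd = 0.15,
                                          phase_sampling = "two_day_grid",
                                          outlier_protein_count = 5, seed = 101))
  fit <- suppressMessages(run_pipeline(run_config(seed = 31), ds$matrix))
  rep_ <- fit$report
  # confirmed set is a subset of candidates, all below the rescue cutoff
  expect_true(all(rep_$confirmed_outlier_proteins %in% rep_$candidate_proteins))
  det <- rep_$detail[rep_$detail$type == "protein", ]
  expect_true(all(det$amplitude[det$decision == "outlier"] <
                    rep_$amplitude_rescue_cutoff))
  # bookkeeping: every input protein in the table, removed ones flagged
  expect_equal(nrow(fit$protein_table), 205L)
  expect_equal(sum(fit$protein_table$outlier_flag),
               length(rep_$confirmed_outlier_proteins))
  expect_true(all(is.na(fit$protein_table$fdr[fit$protein_table$outlier_flag])))
})

test_that("clean data rarely flags samples and removal keeps the run valid", {
  flags <- 0L; m <- 10L
  for (s in 1:10) {
    ds <- generate_synthetic(synthetic_spec(m = m, n = 60, rhythmic_fraction = 0.5,
                                            noise_sd = 0.3, seed = 400 + s))
    z <- zscore_normalize(ds$matrix)
    stack <- pretrain_stack(z, plan_architecture(nrow(z$values)),
                            run_config(seed = s))
    phi0 <- initial_phase(stack$final_pair)
    ip <- circaphase:::init_params_from_fits(batch_fit(z, phi0), z$values)
    ft <- finetune(z, stack, ip, run_config(seed = s), epochs = 30)
    rs <- compute_residuals(z$values, ft$predicted)
    rep_ <- flag_outliers(rs, ft$params$amplitude, run_config(),
                          sample_ids = z$sample_ids, protein_ids = z$protein_ids)
    flags <- flags + length(rep_$outlier_samples)
  }
  expect_lte(flags / 10, ceiling(0.1 * m))
})

test_that("removal that would leave too few samples aborts with a report", {
  ds <- generate_synthetic(synthetic_spec(m = 4, n = 20, rhythmic_fraction = 0.5,
                                          noise_sd = 0.2, seed = 9))
  rep_ <- structure(list(outlier_samples = c("S01", "S02"),
                         candidate_proteins = character(0),
                         confirmed_outlier_proteins = character(0),
                         amplitude_rescue_cutoff = 1,
                         detail = data.frame()),
                    class = "outlier_report")
  expect_error(remove_and_retrain(ds$matrix, rep_, NULL, run_config()),
               "aborting")
})
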