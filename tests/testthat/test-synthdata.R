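test_that("generation is deterministic and labels are consistent", {
  sp <- synthetic_spec(m = 10, n = 50, rhythmic_fraction = 0.4,
                       ultradian_fraction = 0.2, noise_sd = 0.5,
                       outlier_protein_count = 3, seed = 5)
  a <- generate_synthetic(sp)
  b <- generate_synthetic(sp)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_equal(sum(a$truth_params$is_rhythmic), 20)
  expect_equal(sum(a$truth_params$is_ultradian), 4)
  expect_length(a$outlier_ids, 3)
  # corrupted proteins are never labeled rhythmic in truth
  expect_true(all(!a$truth_params$is_rhythmic[a$truth_params$protein_id %in%
                                                a$outlier_ids]))
  expect_error(synthetic_spec(m = 10, n = 50, rhythmic_fraction = 0,
                              ultradian_fraction = 0.5),
               "rhythmic")
})

test_that("noiseless planted parameters are recovered exactly by the cosinor", {
  ds <- generate_synthetic(synthetic_spec(m = 12, n = 30, rhythmic_fraction = 1,
                                          noise_sd = 0, seed = 8))
  phi <- hours_to_radians(ds$truth_phases)
  for (p in c(1, 7, 30)) {
    fit <- fit_cosinor(ds$matrix$values[p, ], phi, omega = 1)
    tp <- ds$truth_params[p, ]
    expect_equal(fit$mesor, tp$mesor, tolerance = 1e-6)
    expect_equal(fit$amplitude, tp$amplitude, tolerance = 1e-6)
    d <- abs(radians_to_hours(fit$peak_phase) - tp$peak_hour) %% 24
    expect_lt(min(d, 24 - d), 1e-6)
  }
})

test_that("a non-rhythmic matrix produces few false calls at truth phases", {
  false_rate <- numeric(20)
  for (s in 1:20) {
    ds <- generate_synthetic(synthetic_spec(m = 12, n = 80, rhythmic_fraction = 0,
                                            noise_sd = 1, seed = 900 + s))
    fits <- batch_fit(ds$matrix, hours_to_radians(ds$truth_phases))
    false_rate[s] <- length(call_rhythmic(fits)) / 80
  }
  expect_lte(mean(false_rate), 0.05)
})

test_that("heavy-tailed noise has the requested scale", {
  sp <- synthetic_spec(m = 24, n = 400, rhythmic_fraction = 0, noise_sd = 0.8,
                       noise_family = "student_t", seed = 77)
  ds <- generate_synthetic(sp)
  resid <- ds$matrix$values - ds$truth_params$mesor
  expect_equal(sd(as.vector(resid)), 0.8, tolerance = 0.15)
})

test_that("the benchmark suite spans the four regimes with a learnable two-day design", {
  suite <- benchmark_suite(1L)
  expect_length(suite, 4L)
  mns <- t(vapply(suite, function(d) dim(d$matrix$values), integer(2)))
  expect_setequal(paste(mns[, 2], mns[, 1]),
                  c("6 800", "12 1800", "16 2500", "24 1400"))
  for (d in suite) {
    m <- length(d$truth_phases)
    # two traversals of an evenly spaced day: each clock phase sampled twice
    expect_equal(length(unique(round(d$truth_phases, 9))), ceiling(m / 2))
    expect_equal(d$noise_sd,
                 0.5 * median(d$truth_params$amplitude[d$truth_params$is_rhythmic]))
  }
  # learnability: cosinor at truth phases detects most planted rhythms where
  # the F-test has power (m >= 12); at m = 6 the test has (2, 3) d.f. and
  # cannot reach FDR < 0.05, so learnability shows as high R2 instead.
  # Sensitivity is judged on gate-eligible rhythms (planted relative
  # amplitude >= 0.1): smaller ones are uncallable by design.
  sens <- c()
  for (d in suite) {
    m <- length(d$truth_phases)
    fits <- batch_fit(d$matrix, hours_to_radians(d$truth_phases))
    tp <- d$truth_params
    rhy <- tp$protein_id[tp$is_rhythmic & tp$amplitude / tp$mesor >= 0.1]
    if (m >= 12) {
      sens <- c(sens, mean(rhy %in% call_rhythmic(fits)))
    } else {
      expect_gt(median(fits$r_squared[fits$protein_id %in% rhy]), 0.5)
    }
  }
  expect_gte(mean(sens), 0.8)
})
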