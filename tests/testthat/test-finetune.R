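test_that("initial phase uses the full-quadrant arctangent", {
  fp <- rbind(c(0, 1), c(1, 0), c(-1, -1))
  phi <- initial_phase(fp)
  expect_equal(phi, c(0, pi / 2, 5 * pi / 4))
  expect_error(initial_phase(rbind(c(0, 0), c(1, 1))), "degenerate")
})

test_that("cosine prediction matches scalar recomputation", {
  expect_equal(cosine_predict(0, list(mesor = 0, amplitude = 1,
                                      phase_offset = 0, omega = 1))[1, 1], 1)
  expect_equal(cosine_predict(0, list(mesor = 2, amplitude = 3,
                                      phase_offset = pi, omega = 1))[1, 1], -1)
  set.seed(20)
  n <- 7; m <- 5
  par <- list(mesor = rnorm(n), amplitude = runif(n), phase_offset = runif(n, 0, 2 * pi),
              omega = runif(n, 0.9, 3))
  phi <- runif(m, 0, 2 * pi)
  pred <- cosine_predict(phi, par)
  loop <- matrix(0, n, m)
  for (p in 1:n) for (i in 1:m)
    loop[p, i] <- par$mesor[p] + par$amplitude[p] *
      cos(par$omega[p] * phi[i] + par$phase_offset[p])
  expect_lt(max(abs(pred - loop)), 1e-10)
})

test_that("the fitting loss reduces to the mean absolute error at the defaults", {
  expect_equal(fitting_loss(matrix(1), matrix(1)), 0)
  expect_equal(fitting_loss(matrix(1), matrix(0)), 1)
  expect_equal(fitting_loss(matrix(c(1, 0, 0, 1), 2), matrix(0, 2, 2)), 0.5)
})

test_that("total-variation penalty equals the sorted-difference loop", {
  expect_equal(tv_penalty(c(2, 2, 2)), 0)
  expect_equal(tv_penalty(c(0, 1, 3)), 3)
  set.seed(30)
  x <- runif(25, 0, 2 * pi)
  s <- sort(x)
  expect_identical(tv_penalty(x), sum(abs(s[-1] - s[-length(s)])))
})

make_small_ft_instance <- function(seed = 17, m = 8, n = 12) {
  ds <- generate_synthetic(synthetic_spec(m = m, n = n, rhythmic_fraction = 0.5,
                                          noise_sd = 0.3, seed = seed))
  z <- zscore_normalize(ds$matrix)
  plan <- plan_architecture(nrow(z$values))
  stack <- pretrain_stack(z, plan, run_config(seed = seed))
  phi0 <- initial_phase(stack$final_pair)
  ip <- circaphase:::init_params_from_fits(batch_fit(z, phi0), z$values)
  list(ds = ds, z = z, plan = plan, stack = stack, ip = ip)
}

test_that("analytic gradient matches central finite differences", {
  inst <- make_small_ft_instance()
  z <- inst$z
  X <- z$values; Xin <- t(X); n <- nrow(X)
  nl <- length(inst$plan)
  blocks <- circaphase:::ft_blocks(inst$stack, inst$ip, rep(1, n))
  for (cfg in list(c(q = 2, lambda = 0), c(q = 2, lambda = 0.05))) {
    reg <- if (cfg["lambda"] > 0) "l2" else "none"
    lg <- circaphase:::ft_loss_grad(blocks, X, Xin, nl, cfg["q"], cfg["lambda"], reg)
    set.seed(8)
    eps <- 1e-5
    for (rep in 1:30) {
      k <- sample(length(blocks), 1)
      j <- sample(length(blocks[[k]]), 1)
      bp <- blocks; bp[[k]][j] <- bp[[k]][j] + eps
      bm <- blocks; bm[[k]][j] <- bm[[k]][j] - eps
      fd <- (circaphase:::ft_loss_grad(bp, X, Xin, nl, cfg["q"], cfg["lambda"],
                                       reg, want_grad = FALSE)$loss -
             circaphase:::ft_loss_grad(bm, X, Xin, nl, cfg["q"], cfg["lambda"],
                                       reg, want_grad = FALSE)$loss) / (2 * eps)
      an <- lg$grad[[k]][j]
      denom <- max(abs(fd), abs(an), 1e-6)
      expect_lt(abs(fd - an) / denom, 1e-4)
    }
  }
})

test_that("lambda = 0 and regularizer = none coincide and runs are deterministic", {
  inst <- make_small_ft_instance()
  cfg0 <- run_config(seed = 3, lambda_reg = 0, regularizer = "tv")
  cfg_none <- run_config(seed = 3, lambda_reg = 0, regularizer = "none")
  fa <- finetune(inst$z, inst$stack, inst$ip, cfg0, epochs = 10)
  fb <- finetune(inst$z, inst$stack, inst$ip, cfg_none, epochs = 10)
  expect_identical(fa$phases$current, fb$phases$current)
  fc <- finetune(inst$z, inst$stack, inst$ip, cfg_none, epochs = 10)
  expect_identical(fb$phases$current, fc$phases$current)
})

test_that("the best-iterate loss never exceeds the initial loss", {
  inst <- make_small_ft_instance(seed = 23)
  for (optn in c("adam", "dadapt_sgd")) {
    ft <- finetune(inst$z, inst$stack, inst$ip, run_config(seed = 1),
                   epochs = 15, optimizer = optn)
    expect_lte(min(ft$loss_trace), ft$loss_trace[1] + 1e-12)
    final_loss <- fitting_loss(inst$z$values, ft$predicted)
    expect_lte(final_loss, ft$loss_trace[1] + 1e-9)
  }
})

test_that("phases and offsets are canonicalized into [0, 2pi) with non-negative amplitude", {
  inst <- make_small_ft_instance(seed = 29)
  ft <- finetune(inst$z, inst$stack, inst$ip, run_config(seed = 2), epochs = 30)
  expect_true(all(ft$phases$current >= 0 & ft$phases$current < 2 * pi))
  expect_true(all(ft$params$amplitude >= 0))
  expect_true(all(ft$params$phase_offset >= 0 & ft$params$phase_offset < 2 * pi))
  expect_true(all(ft$params$omega > 0.9 & ft$params$omega < 3.1))
})
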