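# Independent oracles used by the tests. These deliberately avoid the code
# paths they check: the cosinor oracle is a nested grid refinement over
# (mesor, amplitude, psi), the alignment oracle a finer brute-force grid.

# minimize SSE of x ~ M + A cos(omega*phi + psi) by iterative grid refinement
grid_cosinor_oracle <- function(x, phi, omega = 1, iters = 9L, pts = 21L) {
  sdx <- stats::sd(x)
  M0 <- mean(x); Mw <- 4 * sdx + 1e-6
  A0 <- sdx * 1.5; Aw <- 3 * sdx + 1e-6
  P0 <- pi; Pw <- pi
  best <- c(M0, A0, P0)
  for (it in seq_len(iters)) {
    Ms <- seq(best[1] - Mw, best[1] + Mw, length.out = pts)
    As <- seq(max(0, best[2] - Aw), best[2] + Aw, length.out = pts)
    Ps <- seq(best[3] - Pw, best[3] + Pw, length.out = pts)
    g <- expand.grid(M = Ms, A = As, P = Ps)
    pred <- outer(g$A, cos(omega * phi)) * cos(g$P) -
      outer(g$A, sin(omega * phi)) * sin(g$P) + g$M
    sse <- rowSums((pred - matrix(x, nrow(g), length(x), byrow = TRUE))^2)
    j <- which.min(sse)
    best <- c(g$M[j], g$A[j], g$P[j])
    shrink <- 2 / (pts - 1) * 2   # keep a few grid cells around the optimum
    Mw <- Mw * shrink; Aw <- Aw * shrink; Pw <- Pw * shrink
  }
  list(mesor = best[1], amplitude = best[2], psi = best[3] %% (2 * pi),
       sse = min(sse))
}

# brute-force circular alignment at a finer offset grid than the implementation
brute_align_oracle <- function(pred_h, truth_h, step = 0.01) {
  offsets <- seq(0, 24 - step, by = step)
  best <- Inf
  for (orient in c(1, -1)) {
    base <- (orient * pred_h) %% 24
    for (off in offsets) {
      e <- mean(circular_error((base + off) %% 24, truth_h))
      if (e < best) best <- e
    }
  }
  best
}

# circular correlation (Fisher-Lee) between two angle vectors
circ_cor <- function(a, b) {
  num <- sum(sin(a - mean_angle(a)) * sin(b - mean_angle(b)))
  den <- sqrt(sum(sin(a - mean_angle(a))^2) * sum(sin(b - mean_angle(b))^2))
  num / den
}
mean_angle <- function(a) atan2(mean(sin(a)), mean(cos(a)))

# tiny raw-scale matrix fixture with controllable values
tiny_matrix <- function(vals, ids = NULL, samples = NULL) {
  expression_matrix(vals, protein_ids = ids, sample_ids = samples,
                    scale_tag = "raw")
}
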