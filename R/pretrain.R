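#' Plan the encoder architecture for a given feature count
#'
#' Layer widths run from `2^floor(log2(f))` down to the two-neuron bottleneck
#' that encodes the angular phase, with intermediate widths geometrically
#' interpolated over six layers and truncated to integers. Repeated widths
#' (possible for very small `f`) are deduplicated so the plan stays strictly
#' decreasing.
#'
#' @param f Feature (protein) count, at least 4.
#' @return Integer vector of hidden-layer widths, ending in 2.
#' @export
#' @examples
#' plan_architecture(1000)  # 512 168 55 18 6 2
plan_architecture <- function(f) {
  if (!is.numeric(f) || length(f) != 1 || f < 4)
    stop("feature count must be a single number >= 4", call. = FALSE)
  s0 <- 2^floor(log2(f))
  sizes <- floor(s0 * (2 / s0)^((0:5) / 5))
  sizes[length(sizes)] <- 2L
  sizes <- as.integer(sizes)
  keep <- c(TRUE, diff(sizes) < 0)
  while (!all(keep)) {
    sizes <- sizes[keep]
    keep <- c(TRUE, diff(sizes) < 0)
  }
  sizes
}

# loss and gradient of one shallow autoencoder; parameters as a block list
# (W1, b1, W2, b2) so optimizer updates avoid flatten/unflatten copies
ae_loss_grad <- function(p, X, want_grad = TRUE) {
  m <- nrow(X); d <- ncol(X)
  A <- sweep(X %*% p[[1]], 2, p[[2]], "+")
  H <- tanh(A)
  Y <- sweep(H %*% p[[3]], 2, p[[4]], "+")
  R <- Y - X
  loss <- mean(R^2)
  if (!want_grad) return(list(loss = loss, H = H))
  dY <- (2 / (m * d)) * R
  gW2 <- crossprod(H, dY)
  gb2 <- colSums(dY)
  dH <- dY %*% t(p[[3]])
  dA <- dH * (1 - H^2)
  gW1 <- crossprod(X, dA)
  gb1 <- colSums(dA)
  list(loss = loss, H = H, grad = list(gW1, gb1, gW2, gb2))
}

xavier_limits <- function(fan_in, fan_out) sqrt(6 / (fan_in + fan_out))

#' Train one shallow autoencoder
#'
#' A single hidden layer with hyperbolic-tangent activation and a linear
#' decoder is trained by full-batch gradient descent on the mean squared
#' reconstruction error. Weights start from Xavier-uniform draws (biases at
#' zero) under the given seed; the best-loss iterate over the epochs
#' (including the initialization itself) is returned, so the final
#' reconstruction error never exceeds the initial one.
#'
#' @param inputs Numeric matrix, samples x d.
#' @param hidden_size Width of the hidden layer (at most d).
#' @param epochs Number of full-batch updates; `epochs = 0` returns the
#'   initialization untouched.
#' @param optimizer_name `"adam"`, `"sgd"` or `"dadapt_sgd"`.
#' @param seed Integer seed for the weight initialization.
#' @return List with encoder `W` (d x hidden) and `b`, the hidden
#'   representation `hidden` (samples x hidden) at the returned weights, and
#'   the per-epoch `loss_trace` (element 1 = loss at initialization).
#' @export
train_autoencoder <- function(inputs, hidden_size, epochs, optimizer_name = "adam",
                              seed = 1L) {
  X <- as.matrix(inputs)
  d <- ncol(X); h <- as.integer(hidden_size)
  if (h > d) stop("hidden_size (", h, ") exceeds input width (", d, ")", call. = FALSE)
  if (h < 1) stop("hidden_size must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  lw1 <- xavier_limits(d, h); lw2 <- xavier_limits(h, d)
  theta <- list(matrix(stats::runif(d * h, -lw1, lw1), d, h), numeric(h),
                matrix(stats::runif(h * d, -lw2, lw2), h, d), numeric(d))
  best_theta <- theta; best_loss <- Inf
  trace <- numeric(epochs + 1L)
  if (epochs > 0) {
    opt <- make_optimizer(optimizer_name, theta)
    for (e in seq_len(epochs)) {
      lg <- ae_loss_grad(theta, X)
      if (!is.finite(lg$loss))
        stop("non-finite autoencoder loss at epoch ", e, call. = FALSE)
      trace[e] <- lg$loss
      if (lg$loss < best_loss) { best_loss <- lg$loss; best_theta <- theta }
      theta <- opt$step(theta, lg$grad)
    }
  }
  l_fin <- ae_loss_grad(theta, X, want_grad = FALSE)$loss
  trace[epochs + 1L] <- l_fin
  if (l_fin < best_loss) { best_loss <- l_fin; best_theta <- theta }
  H <- tanh(sweep(X %*% best_theta[[1]], 2, best_theta[[2]], "+"))
  list(W = best_theta[[1]], b = best_theta[[2]], hidden = H,
       loss_trace = trace, best_loss = best_loss)
}

#' Greedy layer-wise pretraining of the encoder stack
#'
#' Trains one shallow autoencoder per planned layer, each consuming the
#' previous hidden representation; the decoders are discarded after each
#' stage. All but the last autoencoder train for
#' `config$pretrain_epochs_early` epochs with `config$optimizer_name`; the
#' last (bottleneck) autoencoder trains for `config$pretrain_epochs_last`
#' epochs with the learning-rate-free optimizer. The two bottleneck
#' activations per sample, `(s_i, c_i)`, seed the initial phase estimate.
#'
#' @param matrix A z-scored `expression_matrix`.
#' @param plan Integer widths from [plan_architecture()].
#' @param config A [run_config()].
#' @return An object of class `encoder_stack`: per-layer `weights`
#'   (`W`, `b`), `hidden_reps`, and `final_pair` (samples x 2).
#' @export
pretrain_stack <- function(matrix, plan, config = run_config()) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (matrix$scale_tag != "zscored")
    stop("pretrain_stack expects a z-scored matrix", call. = FALSE)
  L <- length(plan)
  X <- t(matrix$values)   # samples x features
  weights <- vector("list", L)
  hidden_reps <- vector("list", L)
  inp <- X
  for (l in seq_len(L)) {
    epochs <- if (l < L) config$pretrain_epochs_early else config$pretrain_epochs_last
    optimizer <- if (l < L) config$optimizer_name else "dadapt_sgd"
    seed_l <- (as.integer(config$seed) %% 1000000L) * 101L + l
    fit <- tryCatch(
      train_autoencoder(inp, plan[l], epochs, optimizer, seed = seed_l),
      error = function(e) stop("pretraining failed at layer ", l, ": ",
                               conditionMessage(e), call. = FALSE))
    weights[[l]] <- list(W = fit$W, b = fit$b)
    hidden_reps[[l]] <- fit$hidden
    inp <- fit$hidden
  }
  structure(list(weights = weights, hidden_reps = hidden_reps,
                 final_pair = hidden_reps[[L]], plan = plan,
                 sample_ids = matrix$sample_ids),
            class = "encoder_stack")
}

#' Recompute the stacked hidden representations from stored weights
#'
#' The stack is purely feed-forward; this reapplies each encoder layer to
#' fresh input (defaults to checking against the stored activations).
#'
#' @param stack An `encoder_stack`.
#' @param X Samples x features input matrix.
#' @return List of per-layer hidden representations.
#' @export
forward_stack <- function(stack, X) {
  out <- vector("list", length(stack$weights))
  inp <- X
  for (l in seq_along(stack$weights)) {
    w <- stack$weights[[l]]
    inp <- tanh(sweep(inp %*% w$W, 2, w$b, "+"))
    out[[l]] <- inp
  }
  out
}
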