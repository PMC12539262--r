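# Joint fine-tuning: the pretrained encoder maps each sample to a 2-vector
# (s_i, c_i) read out as a phase phi_i = atan2(s_i, c_i); per-protein cosine
# parameters (mesor L_p, amplitude A_p, acrophase offset psi_p, frequency
# omega_p) predict xhat_ip = L_p + A_p cos(omega_p phi_i + psi_p); encoder
# weights and cosine parameters are optimized together under the lq loss.
# omega_p is re-parameterized through a scaled logistic so the learned period
# stays in a physiological band (24h/3.1 .. 24h/0.9) without hard clipping.

OMEGA_LO <- 0.9
OMEGA_HI <- 3.1

omega_from_u <- function(u) OMEGA_LO + (OMEGA_HI - OMEGA_LO) * stats::plogis(u)
u_from_omega <- function(omega) stats::qlogis((omega - OMEGA_LO) / (OMEGA_HI - OMEGA_LO))
domega_du <- function(u) {
  s <- stats::plogis(u)
  (OMEGA_HI - OMEGA_LO) * s * (1 - s)
}

#' Initial per-sample phase from the bottleneck pair
#'
#' The two bottleneck activations `(s_i, c_i)` are read as sine-like and
#' cosine-like coordinates and converted to an angle with the full-quadrant
#' two-argument arctangent, reduced into `[0, 2pi)`.
#'
#' @param final_pair Samples x 2 matrix from [pretrain_stack()].
#' @return Radians vector in `[0, 2pi)`.
#' @export
initial_phase <- function(final_pair) {
  fp <- as.matrix(final_pair)
  if (ncol(fp) != 2) stop("final_pair must have two columns", call. = FALSE)
  degen <- fp[, 1] == 0 & fp[, 2] == 0
  if (any(degen))
    stop("degenerate bottleneck (0, 0) for sample(s) ",
         paste(which(degen), collapse = ", "), call. = FALSE)
  atan2(fp[, 1], fp[, 2]) %% (2 * pi)
}

#' Predicted expression from phases and cosine parameters
#'
#' @param phases Radians vector of length m.
#' @param params List with numeric vectors `mesor`, `amplitude`,
#'   `phase_offset`, `omega`, all of length n.
#' @return n x m matrix `L_p + A_p cos(omega_p phi_i + psi_p)`.
#' @export
cosine_predict <- function(phases, params) {
  theta <- outer(params$omega, phases) + params$phase_offset
  params$mesor + params$amplitude * cos(theta)
}

#' Fitting loss
#'
#' Mean over all matrix entries of `|x - xhat|^q` plus `lambda` times the
#' chosen regularizer (`l1`/`l2` over the cosine parameters and phases, or
#' the total-variation penalty on sorted phases). With the defaults
#' (`q = 1`, `lambda = 0`) this is the mean absolute error.
#'
#' @param observed,predicted n x m matrices.
#' @param q Positive exponent of the per-entry error.
#' @param lambda Non-negative regularization weight.
#' @param regularizer `"none"`, `"l1"`, `"l2"` or `"tv"`.
#' @param phases,params Current phases/parameters (used by the regularizers).
#' @return Non-negative scalar.
#' @export
fitting_loss <- function(observed, predicted, q = 1, lambda = 0,
                         regularizer = "none", phases = NULL, params = NULL) {
  base <- mean(abs(observed - predicted)^q)
  if (lambda > 0 && regularizer != "none") {
    theta <- c(params$mesor, params$amplitude, params$phase_offset, phases)
    reg <- switch(regularizer,
                  l1 = sum(abs(theta)),
                  l2 = sum(theta^2),
                  tv = tv_penalty(phases))
    base <- base + lambda * reg
  }
  base
}

#' Total-variation penalty on sample phases
#'
#' Sum of absolute differences between consecutive phases after sorting
#' ascending; penalizes abrupt shifts between neighbouring sample phases.
#'
#' @param phases Radians vector, length >= 2.
#' @return Non-negative scalar.
#' @export
tv_penalty <- function(phases) {
  if (length(phases) < 2) stop("tv_penalty needs at least 2 phases", call. = FALSE)
  sum(abs(diff(sort(phases))))
}

# forward + loss + full gradient for the fine-tuning objective.
# Parameters travel as a block list so the optimizer can update each weight
# matrix / parameter vector without flatten-unflatten copies:
#   blocks[[2l-1]] = W_l, blocks[[2l]] = b_l for l = 1..nl,
#   then L, A, psi, u (length-n vectors) at the tail.
ft_blocks <- function(stack, init_params, omega0) {
  blocks <- list()
  for (l in seq_along(stack$weights)) {
    blocks[[2 * l - 1]] <- stack$weights[[l]]$W
    blocks[[2 * l]] <- stack$weights[[l]]$b
  }
  nl <- length(stack$weights)
  blocks[[2 * nl + 1]] <- as.numeric(init_params$mesor)
  blocks[[2 * nl + 2]] <- as.numeric(init_params$amplitude)
  blocks[[2 * nl + 3]] <- as.numeric(init_params$phase_offset)
  blocks[[2 * nl + 4]] <- u_from_omega(omega0)
  blocks
}

ft_loss_grad <- function(blocks, X, Xin, nl, q, lambda, regularizer,
                         want_grad = TRUE) {
  n <- nrow(X); m <- ncol(X)
  Lp <- blocks[[2 * nl + 1]]; Ap <- blocks[[2 * nl + 2]]
  psip <- blocks[[2 * nl + 3]]; up <- blocks[[2 * nl + 4]]
  H <- vector("list", nl)
  inp <- Xin
  for (l in seq_len(nl)) {
    inp <- tanh(sweep(inp %*% blocks[[2 * l - 1]], 2, blocks[[2 * l]], "+"))
    H[[l]] <- inp
  }
  s <- H[[nl]][, 1]; cc <- H[[nl]][, 2]
  phi <- atan2(s, cc)
  omega <- omega_from_u(up)
  theta_mat <- outer(omega, phi) + psip
  ct <- cos(theta_mat)
  xhat <- Lp + Ap * ct
  r <- X - xhat
  loss <- mean(abs(r)^q)
  if (lambda > 0 && regularizer != "none") {
    th <- c(Lp, Ap, psip, phi)
    loss <- loss + lambda * switch(regularizer,
                                   l1 = sum(abs(th)),
                                   l2 = sum(th^2),
                                   tv = tv_penalty(phi))
  }
  if (!want_grad)
    return(list(loss = loss, phi = phi, xhat = xhat,
                params = list(L = Lp, A = Ap, psi = psip, u = up)))
  # dLoss/dxhat
  ar <- abs(r)
  pow <- if (q == 1) 1 else if (q >= 1) ar^(q - 1) else pmax(ar, 1e-12)^(q - 1)
  G <- -(q / (n * m)) * sign(r) * pow
  st <- sin(theta_mat)
  S <- G * (-Ap * st)
  gL <- rowSums(G)
  gA <- rowSums(G * ct)
  gpsi <- rowSums(S)
  gomega <- drop(S %*% phi)
  gu <- gomega * domega_du(up)
  gphi <- drop(crossprod(S, omega))
  if (lambda > 0 && regularizer != "none") {
    if (regularizer == "l1") {
      gL <- gL + lambda * sign(Lp)
      gA <- gA + lambda * sign(Ap)
      gpsi <- gpsi + lambda * sign(psip)
      gphi <- gphi + lambda * sign(phi)
    } else if (regularizer == "l2") {
      gL <- gL + 2 * lambda * Lp
      gA <- gA + 2 * lambda * Ap
      gpsi <- gpsi + 2 * lambda * psip
      gphi <- gphi + 2 * lambda * phi
    } else if (regularizer == "tv") {
      # sorted-difference sum telescopes to max - min
      gphi[which.max(phi)] <- gphi[which.max(phi)] + lambda
      gphi[which.min(phi)] <- gphi[which.min(phi)] - lambda
    }
  }
  den <- s^2 + cc^2
  grad <- vector("list", length(blocks))
  delta <- cbind(gphi * cc / den, gphi * (-s) / den)
  for (l in rev(seq_len(nl))) {
    dA <- delta * (1 - H[[l]]^2)
    prev <- if (l == 1) Xin else H[[l - 1]]
    grad[[2 * l - 1]] <- crossprod(prev, dA)
    grad[[2 * l]] <- colSums(dA)
    if (l > 1) delta <- dA %*% t(blocks[[2 * l - 1]])
  }
  grad[[2 * nl + 1]] <- gL
  grad[[2 * nl + 2]] <- gA
  grad[[2 * nl + 3]] <- gpsi
  grad[[2 * nl + 4]] <- gu
  list(loss = loss, grad = grad, phi = phi)
}

# canonical readout: non-negative amplitude, psi and phi folded into [0, 2pi)
canonicalize_params <- function(L, A, psi, omega) {
  neg <- A < 0
  A[neg] <- -A[neg]
  psi[neg] <- psi[neg] + pi
  list(mesor = L, amplitude = A, phase_offset = psi %% (2 * pi), omega = omega)
}

#' Joint fine-tuning of encoder weights and cosine parameters
#'
#' Builds the deep encoder from the transferred pretraining weights, maps each
#' sample to a phase, and optimizes the encoder together with the per-protein
#' cosine parameters by full-batch gradient descent on [fitting_loss()] for
#' `epochs` full-batch updates, tracking the best iterate so the returned
#' loss never exceeds the initial loss. Amplitude-sign folding and reduction
#' of angles into `[0, 2pi)` happen only at read-out, never mid-optimization.
#'
#' @param matrix A z-scored `expression_matrix`.
#' @param stack A pretrained `encoder_stack` on the same matrix.
#' @param init_params Per-protein initial values: list with `mesor`,
#'   `amplitude`, `phase_offset` (from the cosinor fit at the initial phases)
#'   and optionally `omega` (default 1, the 24-h period).
#' @param config A [run_config()]; `q_norm`, `lambda_reg`, `regularizer` and
#'   the optimizer family are taken from it.
#' @param epochs Number of updates; defaults to `config$finetune_epochs`.
#' @param optimizer `"adam"` (default; per-coordinate steps handle the very
#'   different gradient scales of encoder weights and cosine parameters) or
#'   the learning-rate-free `"dadapt_sgd"`.
#' @param lr Adam learning rate for fine-tuning; the default 0.01 suits the
#'   small number of full-batch updates. Ignored for `"dadapt_sgd"`.
#' @return List: `phases` (list with `initial`, `current`, both in
#'   `[0, 2pi)`), `params` (canonicalized `mesor`, `amplitude`,
#'   `phase_offset`, `omega`, plus `init_snapshot`), `loss_trace`
#'   (epochs + 1 values, element 1 at initialization), `predicted`
#'   (n x m matrix at the returned iterate).
#' @export
finetune <- function(matrix, stack, init_params, config = run_config(),
                     epochs = config$finetune_epochs, optimizer = "adam",
                     lr = 0.01) {
  stopifnot(inherits(matrix, "expression_matrix"), inherits(stack, "encoder_stack"))
  if (matrix$scale_tag != "zscored")
    stop("finetune expects a z-scored matrix", call. = FALSE)
  X <- matrix$values
  Xin <- t(X)
  n <- nrow(X)
  nl <- length(stack$plan)
  omega0 <- if (is.null(init_params$omega)) rep(1, n) else init_params$omega
  blocks <- ft_blocks(stack, init_params, omega0)
  q <- config$q_norm; lambda <- config$lambda_reg; reg <- config$regularizer
  # one loss+gradient evaluation per epoch: trace[e] is the loss at the
  # iterate entering epoch e, and a final evaluation closes the trace
  opt <- make_optimizer(optimizer, blocks,
                        lr = if (optimizer == "adam") lr else NULL)
  best_blocks <- blocks; best_loss <- Inf; phi0 <- NULL
  trace <- numeric(epochs + 1L)
  for (e in seq_len(epochs)) {
    lg <- ft_loss_grad(blocks, X, Xin, nl, q, lambda, reg)
    if (!is.finite(lg$loss))
      stop("non-finite fine-tuning loss at epoch ", e, call. = FALSE)
    if (e == 1L) phi0 <- lg$phi %% (2 * pi)
    trace[e] <- lg$loss
    if (lg$loss < best_loss) { best_loss <- lg$loss; best_blocks <- blocks }
    blocks <- opt$step(blocks, lg$grad)
  }
  l_fin <- ft_loss_grad(blocks, X, Xin, nl, q, lambda, reg, want_grad = FALSE)
  if (epochs == 0L) phi0 <- l_fin$phi %% (2 * pi)
  trace[epochs + 1L] <- l_fin$loss
  if (l_fin$loss < best_loss) { best_loss <- l_fin$loss; best_blocks <- blocks }
  fin <- ft_loss_grad(best_blocks, X, Xin, nl, q, lambda, reg, want_grad = FALSE)
  p <- fin$params
  cp <- canonicalize_params(p$L, p$A, p$psi, omega_from_u(p$u))
  cp$init_snapshot <- list(mesor = init_params$mesor,
                           amplitude = init_params$amplitude,
                           phase_offset = init_params$phase_offset)
  phases <- list(initial = phi0, current = fin$phi %% (2 * pi))
  pred <- cosine_predict(phases$current, cp)
  dimnames(pred) <- dimnames(X)
  enc_weights <- lapply(seq_len(nl),
                        function(l) list(W = best_blocks[[2 * l - 1]],
                                         b = best_blocks[[2 * l]]))
  list(phases = phases, params = cp, loss_trace = trace, predicted = pred,
       weights = enc_weights)
}
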