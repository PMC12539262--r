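#' Single-component cosinor fit
#'
#' Fits `x = M + A cos(omega * phi + psi)` by ordinary least squares through
#' the linearization `x = M + beta_c cos(omega phi) + beta_s sin(omega phi)`,
#' with `A = sqrt(beta_c^2 + beta_s^2)` and `psi` chosen so that
#' `A cos(omega phi + psi)` reproduces the linear combination (amplitude is
#' therefore always non-negative). Significance is the classical cosinor
#' F-test of the two cosine terms against the intercept-only model on
#' (2, m - 3) degrees of freedom.
#'
#' @param values Numeric vector of length m (m >= 4).
#' @param phases Sample phases in radians, same length.
#' @param omega Angular-frequency multiplier: 1 is a 24-h period, 2 a 12-h
#'   (ultradian) period.
#' @return List of class `cosine_fit`: `mesor`, `amplitude`,
#'   `phase_offset` (psi in `[0, 2pi)`), `peak_phase` (`(-psi/omega) mod 2pi`),
#'   `omega`, `p_value`, `r_squared`, `ramp` (amplitude / |mesor|, `NA` when
#'   the mesor is within 1e-8 of zero).
#' @export
fit_cosinor <- function(values, phases, omega = 1) {
  m <- length(values)
  if (m < 4) stop("cosinor fit needs at least 4 samples", call. = FALSE)
  if (length(phases) != m) stop("values and phases lengths differ", call. = FALSE)
  if (any(!is.finite(phases))) stop("phases must be finite", call. = FALSE)
  cc <- cos(omega * phases); ss <- sin(omega * phases)
  X <- cbind(1, cc, ss)
  qrX <- qr(X)
  if (qrX$rank < 3)
    stop("singular cosinor design: phases collinear modulo the period",
         call. = FALSE)
  beta <- qr.coef(qrX, values)
  fitted <- drop(X %*% beta)
  sse <- sum((values - fitted)^2)
  sst <- sum((values - mean(values))^2)
  amplitude <- sqrt(beta[2]^2 + beta[3]^2)
  psi <- atan2(-beta[3], beta[2]) %% (2 * pi)
  mesor <- beta[1]
  if (sst <= 0) {
    r2 <- 0; pval <- 1
  } else {
    r2 <- 1 - sse / sst
    fstat <- ((sst - sse) / 2) / (sse / (m - 3))
    pval <- if (sse <= .Machine$double.eps * sst) 0
            else stats::pf(fstat, 2, m - 3, lower.tail = FALSE)
  }
  ramp <- if (abs(mesor) < 1e-8) NA_real_ else amplitude / abs(mesor)
  structure(list(mesor = unname(mesor), amplitude = unname(amplitude),
                 phase_offset = unname(psi),
                 peak_phase = unname((-psi / omega) %% (2 * pi)),
                 omega = omega, p_value = unname(pval), r_squared = unname(r2),
                 ramp = unname(ramp)),
            class = "cosine_fit")
}

#' Cosinor fits for every protein with Benjamini-Hochberg correction
#'
#' Runs [fit_cosinor()] per protein at the given phases and adjusts the
#' p-values across all successfully fitted proteins by the Benjamini-Hochberg
#' step-up procedure. Proteins whose design is singular are reported with
#' `fit_ok = FALSE` and excluded from the FDR family.
#'
#' @param matrix An `expression_matrix` (original scale for rhythmicity
#'   statistics; z-scored for fine-tuning initialization).
#' @param phases Radians vector, one per sample.
#' @param omega Frequency multiplier shared across proteins.
#' @return A `data.frame`, one row per protein: `protein_id`, `mesor`,
#'   `amplitude`, `phase_offset`, `peak_phase`, `omega`, `p_value`, `fdr`,
#'   `r_squared`, `ramp`, `fit_ok`.
#' @export
batch_fit <- function(matrix, phases, omega = 1) {
  stopifnot(inherits(matrix, "expression_matrix"))
  vals <- matrix$values
  m <- ncol(vals)
  if (length(phases) != m)
    stop("phases must have one entry per sample", call. = FALSE)
  n <- nrow(vals)
  out <- data.frame(protein_id = matrix$protein_ids,
                    mesor = NA_real_, amplitude = NA_real_,
                    phase_offset = NA_real_, peak_phase = NA_real_,
                    omega = omega, p_value = NA_real_, fdr = NA_real_,
                    r_squared = NA_real_, ramp = NA_real_,
                    fit_ok = FALSE, stringsAsFactors = FALSE)
  for (p in seq_len(n)) {
    fit <- tryCatch(fit_cosinor(vals[p, ], phases, omega), error = function(e) NULL)
    if (is.null(fit)) next
    out$mesor[p] <- fit$mesor
    out$amplitude[p] <- fit$amplitude
    out$phase_offset[p] <- fit$phase_offset
    out$peak_phase[p] <- fit$peak_phase
    out$p_value[p] <- fit$p_value
    out$r_squared[p] <- fit$r_squared
    out$ramp[p] <- fit$ramp
    out$fit_ok[p] <- TRUE
  }
  ok <- out$fit_ok
  out$fdr[ok] <- stats::p.adjust(out$p_value[ok], method = "BH")
  out
}
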