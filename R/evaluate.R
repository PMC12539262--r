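#' Circular error between two clock times
#'
#' The shorter of the two arc distances on the 24-h circle, in hours
#' (vectorized; result in `[0, 12]`).
#'
#' @param a,b Clock times in hours.
#' @return Hours in `[0, 12]`.
#' @export
circular_error <- function(a, b) {
  d <- abs(a - b) %% 24
  pmin(d, 24 - d)
}

#' Convert radians to hours on the 24-h clock
#' @param rad Phases in radians.
#' @return Hours in `[0, 24)`.
#' @export
radians_to_hours <- function(rad) (rad * 12 / pi) %% 24

#' Convert hours to radians
#' @param hours Clock times in hours.
#' @return Radians in `[0, 2pi)`.
#' @export
hours_to_radians <- function(hours) (hours * pi / 12) %% (2 * pi)

#' Align unsupervised phase predictions to known times
#'
#' Unsupervised phases are identifiable only up to a global rotation and
#' reflection of the circle. This searches orientation in {+1, -1} and a
#' rotation offset over a 0.05-h grid on `[0, 24)` and returns the transform
#' minimizing the mean circular error against the truth.
#'
#' @param predicted Predicted phases in radians (or hours with
#'   `units = "hours"`).
#' @param truth Known collection times in hours.
#' @param units Units of `predicted`.
#' @return List: `aligned` (hours), `offset` (hours), `orientation`
#'   (+1 or -1), `mean_error` (hours).
#' @export
align_phases <- function(predicted, truth, units = c("radians", "hours")) {
  units <- match.arg(units)
  pred_h <- if (units == "radians") radians_to_hours(predicted) else predicted %% 24
  if (length(pred_h) != length(truth))
    stop("predicted and truth lengths differ", call. = FALSE)
  if (length(truth) < 3) stop("need at least 3 samples to align", call. = FALSE)
  offsets <- seq(0, 24 - 0.05, by = 0.05)
  best <- list(err = Inf)
  for (orient in c(1, -1)) {
    base <- (orient * pred_h) %% 24
    # mean circular error for every offset at once: samples x offsets
    cand <- outer(base, offsets, "+")
    errs <- colMeans(matrix(circular_error(cand, truth), nrow = length(truth)))
    j <- which.min(errs)
    if (errs[j] < best$err)
      best <- list(err = errs[j], offset = offsets[j], orientation = orient)
  }
  aligned <- (best$orientation * pred_h + best$offset) %% 24
  list(aligned = aligned, offset = best$offset, orientation = best$orientation,
       mean_error = best$err)
}

#' Error-threshold curve and normalized AUC
#'
#' For thresholds from 0 to 12 h in 0.1-h steps, the fraction of samples
#' whose circular error against the truth is at most the threshold; the
#' normalized AUC is the trapezoidal area under that curve divided by the
#' 12-h maximum, so a perfect predictor scores 1 and errors of 12 h
#' everywhere score ~0.
#'
#' @param aligned Aligned predictions in hours (see [align_phases()]).
#' @param truth Known collection times in hours.
#' @return List of class `roc_curve`: `thresholds`, `fraction_correct`,
#'   `nauc`.
#' @export
roc_and_nauc <- function(aligned, truth) {
  if (length(aligned) != length(truth))
    stop("aligned and truth lengths differ", call. = FALSE)
  err <- circular_error(aligned, truth)
  thresholds <- seq(0, 12, by = 0.1)
  frac <- vapply(thresholds, function(t) mean(err <= t + 1e-12), numeric(1))
  nauc <- pracma::trapz(thresholds, frac) / 12
  structure(list(thresholds = thresholds, fraction_correct = frac, nauc = nauc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: nAUC = %.4f over %d thresholds (0-12 h)\n",
              x$nauc, length(x$thresholds)))
  invisible(x)
}

#' Align predictions to truth and score them in one call
#'
#' @param predicted Predicted phases in radians.
#' @param truth Known collection times in hours.
#' @return List: `alignment` (from [align_phases()]) and `roc`
#'   (from [roc_and_nauc()]).
#' @export
evaluate_phases <- function(predicted, truth) {
  al <- align_phases(predicted, truth)
  list(alignment = al, roc = roc_and_nauc(al$aligned, truth))
}
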