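#' Call rhythmic proteins from cosinor fits
#'
#' A protein is called rhythmic when its Benjamini-Hochberg adjusted p-value
#' is below 0.05, its relative amplitude (amplitude / |mesor|) is at least
#' 0.1, and its coefficient of determination is at least 0.1. Proteins with
#' an undefined relative amplitude (mesor at zero) fail the gate.
#'
#' @param fits A [batch_fit()] table computed on original-scale data at
#'   `omega = 1`.
#' @param fdr_max,ramp_min,r2_min Gate thresholds.
#' @return Character vector of rhythmic protein ids.
#' @export
call_rhythmic <- function(fits, fdr_max = 0.05, ramp_min = 0.1, r2_min = 0.1) {
  ok <- fits$fit_ok & !is.na(fits$fdr)
  undef <- ok & is.na(fits$ramp)
  if (any(undef))
    log_msg("rhythmic", "%d protein(s) with undefined relative amplitude fail the gate",
            sum(undef))
  called <- ok & !is.na(fits$ramp) &
    fits$fdr < fdr_max & fits$ramp >= ramp_min & fits$r_squared >= r2_min
  fits$protein_id[called]
}

#' Call ultradian (12-h period) proteins
#'
#' Refits every protein at `omega = 2` (12-h period) using the final
#' predicted phases and applies the stringent ultradian gates: FDR < 5e-4,
#' relative amplitude >= 0.2 and R-squared >= 0.6. The FDR family is all
#' proteins of the 12-h refit, separate from the circadian family.
#'
#' @param matrix Original-scale `expression_matrix`.
#' @param phases Final sample phases in radians.
#' @param fdr_max,ramp_min,r2_min Gate thresholds.
#' @return List: `called` (protein ids) and `fits` (the 12-h fit table).
#' @export
call_ultradian <- function(matrix, phases, fdr_max = 5e-4, ramp_min = 0.2,
                           r2_min = 0.6) {
  fits <- batch_fit(matrix, phases, omega = 2)
  called <- call_rhythmic(fits, fdr_max = fdr_max, ramp_min = ramp_min,
                          r2_min = r2_min)
  list(called = called, fits = fits)
}

#' Anchor acrophases to a reference protein
#'
#' Rotates all peak phases so the reference protein peaks at zero; the
#' others are reported in `[0, 2pi)` relative to it. Pairwise circular
#' differences are preserved exactly and anchoring is idempotent.
#'
#' @param peak_phases Named radians vector of per-protein peak phases.
#' @param reference_id Name of the reference protein (must be present).
#' @return Shifted named radians vector with the reference at 0.
#' @export
anchor_to_reference <- function(peak_phases, reference_id) {
  if (is.null(names(peak_phases)))
    stop("peak_phases must be named by protein id", call. = FALSE)
  if (!reference_id %in% names(peak_phases))
    stop("reference protein '", reference_id, "' not found; available: ",
         paste(utils::head(names(peak_phases), 20), collapse = ", "),
         call. = FALSE)
  (peak_phases - peak_phases[[reference_id]]) %% (2 * pi)
}

#' Histogram of peak times around the circadian circle
#'
#' Counts peaks per circular bin over `[0, 2pi)`; the first bin starts at 0,
#' so angles just below `2pi` land in the last bin, circularly adjacent to
#' the first.
#'
#' @param peak_phases Radians vector.
#' @param bins Number of bins (>= 4).
#' @return Integer vector of counts, one per bin, summing to
#'   `length(peak_phases)`.
#' @export
peak_time_histogram <- function(peak_phases, bins = 24) {
  if (bins < 4) stop("need at least 4 bins", call. = FALSE)
  ph <- peak_phases %% (2 * pi)
  idx <- pmin(floor(ph / (2 * pi) * bins) + 1L, bins)
  tabulate(idx, nbins = bins)
}
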