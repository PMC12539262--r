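#' Signed mean fitting residuals per sample and per protein
#'
#' `E_i = (1/n) sum_p (x_ip - xhat_ip)` over proteins for each sample, and
#' `D_p = (1/m) sum_i (x_ip - xhat_ip)` over samples for each protein. The
#' averages are signed, exactly as defined (positive and negative residuals
#' can cancel); summary means/SDs use the population (1/N) standard
#' deviation.
#'
#' @param observed,predicted n x m matrices on the same scale.
#' @return List of class `residual_summary`: `sample_residuals` (`E_i`),
#'   `sample_mean`, `sample_sd`, `protein_residuals` (`D_p`), `protein_mean`,
#'   `protein_sd`.
#' @export
compute_residuals <- function(observed, predicted) {
  if (!all(dim(observed) == dim(predicted)))
    stop("observed and predicted shapes differ", call. = FALSE)
  r <- observed - predicted
  Ei <- colMeans(r)
  Dp <- rowMeans(r)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  structure(list(sample_residuals = Ei, sample_mean = mean(Ei),
                 sample_sd = pop_sd(Ei),
                 protein_residuals = Dp, protein_mean = mean(Dp),
                 protein_sd = pop_sd(Dp)),
            class = "residual_summary")
}

#' Flag outlier samples and proteins from residual summaries
#'
#' A sample is an outlier when its mean residual deviates from the mean of
#' all sample residuals by more than `outlier_sigma` standard deviations;
#' likewise a protein becomes an outlier *candidate*. Candidates whose
#' predicted amplitude reaches the `amplitude_rescue_percentile`-th percentile
#' of all predicted amplitudes are rescued (a strongly rhythmic protein is
#' never removed); the remaining candidates are confirmed outliers. When a
#' residual SD is zero (all residual means equal) nothing is flagged on that
#' axis.
#'
#' @param summary A `residual_summary`.
#' @param amplitudes Predicted per-protein amplitudes (same order/length as
#'   `summary$protein_residuals`).
#' @param config A [run_config()] supplying `outlier_sigma` and
#'   `amplitude_rescue_percentile`.
#' @param sample_ids,protein_ids Identifier vectors for reporting.
#' @return List of class `outlier_report`: `outlier_samples`,
#'   `candidate_proteins`, `confirmed_outlier_proteins`,
#'   `amplitude_rescue_cutoff`, and a `detail` data.frame (entity, type,
#'   residual, deviation, amplitude, decision).
#' @export
flag_outliers <- function(summary, amplitudes, config = run_config(),
                          sample_ids = NULL, protein_ids = NULL) {
  stopifnot(inherits(summary, "residual_summary"))
  m <- length(summary$sample_residuals)
  n <- length(summary$protein_residuals)
  if (length(amplitudes) != n)
    stop("need one predicted amplitude per protein", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(m))
  if (is.null(protein_ids)) protein_ids <- paste0("P", seq_len(n))
  k <- config$outlier_sigma
  dev_s <- abs(summary$sample_residuals - summary$sample_mean)
  out_s <- if (summary$sample_sd > 0) dev_s > k * summary$sample_sd else rep(FALSE, m)
  dev_p <- abs(summary$protein_residuals - summary$protein_mean)
  cand <- if (summary$protein_sd > 0) dev_p > k * summary$protein_sd else rep(FALSE, n)
  cutoff <- unname(stats::quantile(amplitudes,
                                   config$amplitude_rescue_percentile / 100,
                                   type = 7, na.rm = TRUE))
  confirmed <- cand & (is.na(amplitudes) | amplitudes < cutoff)
  decision_p <- ifelse(confirmed, "outlier",
                       ifelse(cand, "rescued", "kept"))
  detail <- rbind(
    data.frame(entity = sample_ids, type = "sample",
               residual = unname(summary$sample_residuals),
               deviation = unname(dev_s), amplitude = NA_real_,
               decision = ifelse(out_s, "outlier", "kept"),
               stringsAsFactors = FALSE),
    data.frame(entity = protein_ids, type = "protein",
               residual = unname(summary$protein_residuals),
               deviation = unname(dev_p), amplitude = unname(amplitudes),
               decision = decision_p, stringsAsFactors = FALSE))
  structure(list(outlier_samples = sample_ids[out_s],
                 candidate_proteins = protein_ids[cand],
                 confirmed_outlier_proteins = protein_ids[confirmed],
                 amplitude_rescue_cutoff = cutoff,
                 detail = detail),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("outlier_report: %d outlier sample(s); %d candidate protein(s), %d confirmed (rescue cutoff %.4g)\n",
              length(x$outlier_samples), length(x$candidate_proteins),
              length(x$confirmed_outlier_proteins), x$amplitude_rescue_cutoff))
  invisible(x)
}
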