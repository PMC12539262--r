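#' Specification for a synthetic proteomic time course
#'
#' Declares the study conditions a generated dataset emulates: sample and
#' protein counts, the rhythmic and ultradian (12-h) fractions, raw-scale
#' mesor and amplitude ranges, the noise model, the sampling design of the
#' true collection times, and the number of injected corrupted proteins.
#'
#' Defaults: mesors uniform on [5, 15] and amplitudes uniform on [0.5, 3] so
#' relative amplitudes straddle the 0.1 rhythmicity gate; Gaussian noise;
#' `noise_sd = NA` means "0.5 x the median planted amplitude", the moderate
#' noise level of the benchmark regimes. `student_t` noise (3 d.f., scaled to
#' the same SD) exercises the heavy-tailed setting the l1 fitting loss is
#' designed for.
#'
#' @param m Sample count (>= 3).
#' @param n Protein count before appending outliers (>= 2).
#' @param rhythmic_fraction Fraction of the n proteins carrying a planted
#'   24-h cosine.
#' @param ultradian_fraction Fraction *of the rhythmic proteins* planted at a
#'   12-h period instead.
#' @param amplitude_range,mesor_range Uniform draw ranges on the raw scale.
#' @param noise_sd Additive noise SD; `NA` = 0.5 x median planted amplitude.
#' @param noise_family `"gaussian"` or `"student_t"` (3 d.f.).
#' @param phase_sampling `"uniform"` (random clock times), `"even_grid"`
#'   (m equally spaced times over one day) or `"two_day_grid"` (two
#'   traversals of an evenly spaced day, emulating 2-day collection designs;
#'   clock phases then repeat between the two days).
#' @param outlier_protein_count Corrupted proteins appended after the n
#'   regular ones (sample-shuffled, variance inflated 5x).
#' @param seed Integer seed; generation is fully deterministic given the seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(m, n, rhythmic_fraction = 0.3,
                           ultradian_fraction = 0,
                           amplitude_range = c(0.5, 3),
                           mesor_range = c(5, 15),
                           noise_sd = NA_real_,
                           noise_family = c("gaussian", "student_t"),
                           phase_sampling = c("uniform", "even_grid", "two_day_grid"),
                           outlier_protein_count = 0L,
                           seed = 1L) {
  noise_family <- match.arg(noise_family)
  phase_sampling <- match.arg(phase_sampling)
  if (m < 3) stop("need m >= 3 samples", call. = FALSE)
  if (n < 2) stop("need n >= 2 proteins", call. = FALSE)
  if (rhythmic_fraction < 0 || rhythmic_fraction > 1 ||
      ultradian_fraction < 0 || ultradian_fraction > 1)
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (ultradian_fraction > 0 && round(rhythmic_fraction * n) < 1)
    stop("ultradian_fraction > 0 requires at least one rhythmic protein",
         call. = FALSE)
  if (!is.na(noise_sd) && noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(m = as.integer(m), n = as.integer(n),
                 rhythmic_fraction = rhythmic_fraction,
                 ultradian_fraction = ultradian_fraction,
                 amplitude_range = amplitude_range, mesor_range = mesor_range,
                 noise_sd = noise_sd, noise_family = noise_family,
                 phase_sampling = phase_sampling,
                 outlier_protein_count = as.integer(outlier_protein_count),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic proteomic time course with ground truth
#'
#' Rhythmic proteins follow `x = L + A cos(w (t - peak)) + noise` with
#' `w = 2 pi / 24` (or `2 pi / 12` for the ultradian subset); non-rhythmic
#' proteins are mesor plus noise. Corrupted outlier proteins are built like a
#' rhythmic protein, then their values are shuffled across samples and their
#' deviations from the mean scaled by `sqrt(5)` (variance inflated 5x), so
#' they carry no phase-coherent signal.
#'
#' @param spec A [synthetic_spec()].
#' @return List of class `synthetic_dataset`: `matrix` (raw-scale
#'   `expression_matrix` with `times_known` set to the truth), `truth_phases`
#'   (hours, length m), `truth_params` (per-protein data.frame with
#'   `protein_id`, `is_rhythmic`, `is_ultradian`, `mesor`, `amplitude`,
#'   `peak_hour`), `outlier_ids`, and the realized `noise_sd`.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  m <- spec$m; n <- spec$n
  t_h <- switch(spec$phase_sampling,
                uniform = stats::runif(m, 0, 24),
                even_grid = seq(0, 24, length.out = m + 1)[seq_len(m)],
                two_day_grid = ((seq_len(m) - 1) * (48 / m)) %% 24)
  t_h <- t_h %% 24
  n_rhy <- round(spec$rhythmic_fraction * n)
  n_ult <- round(spec$ultradian_fraction * n_rhy)
  k_out <- spec$outlier_protein_count
  n_tot <- n + k_out
  is_rhythmic <- c(rep(TRUE, n_rhy), rep(FALSE, n - n_rhy), rep(FALSE, k_out))
  is_ultradian <- c(rep(c(TRUE, FALSE), c(n_ult, n_rhy - n_ult)),
                    rep(FALSE, n - n_rhy + k_out))
  mesor <- stats::runif(n_tot, spec$mesor_range[1], spec$mesor_range[2])
  amplitude <- stats::runif(n_tot, spec$amplitude_range[1], spec$amplitude_range[2])
  peak_hour <- stats::runif(n_tot, 0, 24)
  amp_planted <- amplitude
  amp_planted[!is_rhythmic & seq_len(n_tot) <= n] <- 0
  noise_sd <- spec$noise_sd
  if (is.na(noise_sd)) {
    med_amp <- if (n_rhy > 0) stats::median(amplitude[seq_len(n_rhy)]) else
      stats::median(spec$amplitude_range)
    noise_sd <- 0.5 * med_amp
  }
  draw_noise <- function(k) {
    if (noise_sd == 0) return(numeric(k))
    switch(spec$noise_family,
           gaussian = stats::rnorm(k, 0, noise_sd),
           student_t = stats::rt(k, df = 3) * noise_sd / sqrt(3))
  }
  w24 <- 2 * pi / 24; w12 <- 2 * pi / 12
  vals <- matrix(0, n_tot, m)
  for (p in seq_len(n_tot)) {
    w <- if (is_ultradian[p]) w12 else w24
    signal <- if (p <= n && is_rhythmic[p])
      mesor[p] + amplitude[p] * cos(w * (t_h - peak_hour[p]))
    else if (p > n)  # outlier template: rhythmic shape before corruption
      mesor[p] + amplitude[p] * cos(w24 * (t_h - peak_hour[p]))
    else mesor[p]
    vals[p, ] <- signal + draw_noise(m)
  }
  if (k_out > 0) {
    for (p in n + seq_len(k_out)) {
      x <- vals[p, sample.int(m)]
      vals[p, ] <- mean(x) + sqrt(5) * (x - mean(x))
    }
  }
  protein_ids <- c(sprintf("P%04d", seq_len(n)),
                   if (k_out > 0) sprintf("OUT%02d", seq_len(k_out)))
  sample_ids <- sprintf("S%02d", seq_len(m))
  rownames(vals) <- protein_ids; colnames(vals) <- sample_ids
  truth <- data.frame(protein_id = protein_ids,
                      is_rhythmic = is_rhythmic,
                      is_ultradian = is_ultradian,
                      mesor = mesor,
                      amplitude = ifelse(is_rhythmic, amplitude, 0),
                      peak_hour = ifelse(is_rhythmic, peak_hour, NA_real_),
                      stringsAsFactors = FALSE)
  mat <- expression_matrix(vals, times_known = t_h, scale_tag = "raw")
  structure(list(matrix = mat, truth_phases = t_h, truth_params = truth,
                 outlier_ids = if (k_out > 0) protein_ids[n + seq_len(k_out)]
                               else character(0),
                 noise_sd = noise_sd, spec = spec),
            class = "synthetic_dataset")
}

#' Benchmark suite emulating the labeled-dataset regimes
#'
#' Produces one dataset per (regime, seed) pair over the four regimes
#' `(m, n)` in `{(6, 800), (12, 1800), (16, 2500), (24, 1400)}` with a 0.3
#' rhythmic fraction, two-day evenly spaced collection designs, and Gaussian
#' noise at 0.5 x the median planted amplitude.
#'
#' @param seed_list Non-empty integer vector; one full sweep of the four
#'   regimes per seed.
#' @return Named list of `synthetic_dataset` objects
#'   (`m<RS>_n<proteins>_seed<seed>`).
#' @export
benchmark_suite <- function(seed_list = 1L) {
  if (length(seed_list) < 1) stop("seed_list must be non-empty", call. = FALSE)
  regimes <- list(c(6L, 800L), c(12L, 1800L), c(16L, 2500L), c(24L, 1400L))
  out <- list()
  for (seed in seed_list) {
    for (j in seq_along(regimes)) {
      mn <- regimes[[j]]
      ds_seed <- (as.integer(seed) %% 100000L) * 10L + j
      sp <- synthetic_spec(m = mn[1], n = mn[2], rhythmic_fraction = 0.3,
                           phase_sampling = "two_day_grid",
                           noise_sd = NA_real_, noise_family = "gaussian",
                           seed = ds_seed)
      out[[sprintf("m%d_n%d_seed%d", mn[1], mn[2], seed)]] <- generate_synthetic(sp)
    }
  }
  out
}
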