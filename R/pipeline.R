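# End-to-end orchestration: normalize -> (reduce) -> pretrain -> initial
# phases -> cosinor init -> fine-tune -> outlier screen -> removal + retrain
# -> final phases, per-protein statistics and calls.

# initial cosine parameters from a cosinor sweep at the initial phases;
# singular fits fall back to a flat curve at the row mean
init_params_from_fits <- function(fits, zvals) {
  mesor <- ifelse(fits$fit_ok, fits$mesor, rowMeans(zvals))
  amplitude <- ifelse(fits$fit_ok, fits$amplitude, 0)
  psi <- ifelse(fits$fit_ok, fits$phase_offset, 0)
  list(mesor = mesor, amplitude = amplitude, phase_offset = psi)
}

#' Drop screened outliers and retrain the network
#'
#' Removes confirmed outlier proteins and outlier samples, re-normalizes,
#' re-plans the architecture if the feature count changed its
#' `floor(log2)` bracket, reruns the pretraining initialization transfer and
#' fine-tunes for `config$retrain_epochs`. With an empty report this equals a
#' plain fine-tune of the original data for `retrain_epochs` (the pretrained
#' stack is reused unchanged).
#'
#' @param matrix Raw-scale `expression_matrix` (the working protein set).
#' @param report An `outlier_report` from [flag_outliers()].
#' @param stack The pretrained `encoder_stack` of the first round (reused
#'   when nothing was removed).
#' @param config A [run_config()].
#' @return List: `phases`, `params`, `predicted`, `matrix_z`, `matrix_raw`
#'   (the retained raw submatrix), `loss_trace`.
#' @export
remove_and_retrain <- function(matrix, report, stack = NULL,
                               config = run_config()) {
  stopifnot(inherits(matrix, "expression_matrix"),
            inherits(report, "outlier_report"))
  keep_p <- setdiff(matrix$protein_ids, report$confirmed_outlier_proteins)
  keep_s <- setdiff(matrix$sample_ids, report$outlier_samples)
  if (length(keep_s) < 3 || length(keep_p) < 2)
    stop("outlier removal would leave ", length(keep_p), " proteins x ",
         length(keep_s), " samples; aborting (",
         length(report$confirmed_outlier_proteins), " proteins, ",
         length(report$outlier_samples), " samples flagged)", call. = FALSE)
  removed <- length(keep_p) < length(matrix$protein_ids) ||
    length(keep_s) < length(matrix$sample_ids)
  raw2 <- if (removed) subset_matrix(matrix, proteins = keep_p, samples = keep_s)
          else matrix
  z2 <- zscore_normalize(raw2)
  if (removed || is.null(stack)) {
    plan <- plan_architecture(nrow(z2$values))
    stack <- pretrain_stack(z2, plan, config)
  }
  phi0 <- initial_phase(stack$final_pair)
  fits0 <- batch_fit(z2, phi0, omega = 1)
  ip <- init_params_from_fits(fits0, z2$values)
  ft <- finetune(z2, stack, ip, config, epochs = config$retrain_epochs)
  list(phases = ft$phases, params = ft$params, predicted = ft$predicted,
       matrix_z = z2, matrix_raw = raw2, loss_trace = ft$loss_trace)
}

#' Run the full unsupervised phase-inference pipeline
#'
#' Executes normalization, optional feature reduction (matrices of at least
#' 5000 proteins are reduced to `config$feature_cap` by top variance on the
#' raw scale), greedy layer-wise pretraining, initial phase extraction,
#' cosinor initialization, joint fine-tuning, residual-based outlier
#' screening with amplitude rescue, and a retraining round on the screened
#' data. Per-protein rhythmicity statistics are refit on the original scale
#' at the 24-h period using the final phases. Fully reproducible given
#' `config$seed`.
#'
#' @param config A [run_config()].
#' @param matrix A raw-scale `expression_matrix` (optionally carrying
#'   `times_known` for evaluation).
#' @return Object of class `circaphase_fit`: `sample_table` (sample_id,
#'   phase_radians/degrees/hours, outlier_flag), `protein_table` (protein_id,
#'   mesor, amplitude, phase_offset, period_hours, p_value, fdr, rAMP, R2,
#'   outlier_flag, status), `phases` (final radians, named, NA for removed
#'   samples), `rhythmic_ids`, `report` (outlier report), `params` (learned
#'   cosine parameters incl. per-protein omega), `loss_trace`
#'   (fine-tune and retrain traces), `evaluation` (alignment + ROC when
#'   collection times are known), `config`.
#' @export
run_pipeline <- function(config, matrix) {
  stopifnot(inherits(config, "circaphase_config"),
            inherits(matrix, "expression_matrix"))
  validate_config(config)
  if (matrix$scale_tag != "raw")
    stop("run_pipeline expects a raw-scale matrix", call. = FALSE)
  if (ncol(matrix$values) < 3)
    stop("need at least 3 samples", call. = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  all_ids <- matrix$protein_ids
  z <- stage("normalize", zscore_normalize(matrix))
  status <- setNames(rep("ok", length(all_ids)), all_ids)
  status[setdiff(all_ids, z$protein_ids)] <- "dropped_zero_variance"
  n_feat <- nrow(z$values)
  if (!is.null(config$feature_cap) && n_feat >= 5000 && n_feat > config$feature_cap) {
    raw_var <- apply(matrix$values[z$protein_ids, , drop = FALSE], 1, stats::var)
    z <- stage("reduce", reduce_features(z, config$feature_cap,
                                         method = "variance_top_k",
                                         seed = config$seed, ranking = raw_var))
    status[setdiff(names(status)[status == "ok"], z$protein_ids)] <- "dropped_reduced"
  }
  raw_used <- subset_matrix(matrix, proteins = z$protein_ids)
  plan <- stage("plan", plan_architecture(nrow(z$values)))
  stack <- stage("pretrain", pretrain_stack(z, plan, config))
  phi0 <- stage("initial_phase", initial_phase(stack$final_pair))
  fits0 <- stage("cosinor_init", batch_fit(z, phi0, omega = 1))
  ip <- init_params_from_fits(fits0, z$values)
  ft <- stage("finetune", finetune(z, stack, ip, config,
                                   epochs = config$finetune_epochs))
  rs <- stage("residuals", compute_residuals(z$values, ft$predicted))
  report <- stage("outlier_screen",
                  flag_outliers(rs, ft$params$amplitude, config,
                                sample_ids = z$sample_ids,
                                protein_ids = z$protein_ids))
  status[report$confirmed_outlier_proteins] <- "outlier"
  rt <- stage("retrain", remove_and_retrain(raw_used, report, stack, config))
  final_raw <- rt$matrix_raw
  phases_named <- setNames(rep(NA_real_, length(matrix$sample_ids)),
                           matrix$sample_ids)
  phases_named[final_raw$sample_ids] <- rt$phases$current
  fits_final <- stage("rhythm_stats", batch_fit(final_raw, rt$phases$current,
                                                omega = 1))
  rhythmic_ids <- call_rhythmic(fits_final)
  # protein table covering every input protein exactly once
  pt <- data.frame(protein_id = all_ids,
                   mesor = NA_real_, amplitude = NA_real_,
                   phase_offset = NA_real_, period_hours = NA_real_,
                   p_value = NA_real_, fdr = NA_real_, rAMP = NA_real_,
                   R2 = NA_real_, outlier_flag = FALSE,
                   status = unname(status[all_ids]),
                   stringsAsFactors = FALSE)
  idx <- match(fits_final$protein_id, pt$protein_id)
  pt$mesor[idx] <- fits_final$mesor
  pt$amplitude[idx] <- fits_final$amplitude
  pt$phase_offset[idx] <- fits_final$phase_offset
  pt$period_hours[idx] <- config$period_hours / fits_final$omega
  pt$p_value[idx] <- fits_final$p_value
  pt$fdr[idx] <- fits_final$fdr
  pt$rAMP[idx] <- fits_final$ramp
  pt$R2[idx] <- fits_final$r_squared
  pt$outlier_flag <- pt$status == "outlier"
  st <- data.frame(sample_id = matrix$sample_ids,
                   phase_radians = unname(phases_named),
                   phase_degrees = unname(phases_named) * 180 / pi,
                   phase_hours = unname(phases_named) * config$period_hours / (2 * pi),
                   outlier_flag = matrix$sample_ids %in% report$outlier_samples,
                   stringsAsFactors = FALSE)
  evaluation <- NULL
  if (!is.null(final_raw$times_known))
    evaluation <- evaluate_phases(rt$phases$current, final_raw$times_known)
  structure(list(sample_table = st, protein_table = pt,
                 phases = phases_named, initial_phases = phi0,
                 rhythmic_ids = rhythmic_ids, report = report,
                 params = rt$params,
                 loss_trace = list(finetune = ft$loss_trace,
                                   retrain = rt$loss_trace),
                 evaluation = evaluation,
                 matrix_raw = final_raw, config = config),
            class = "circaphase_fit")
}

#' @export
print.circaphase_fit <- function(x, ...) {
  m <- nrow(x$sample_table); n <- nrow(x$protein_table)
  cat(sprintf("circaphase_fit: %d samples, %d proteins; %d rhythmic call(s); %d outlier protein(s), %d outlier sample(s)\n",
              m, n, length(x$rhythmic_ids),
              sum(x$protein_table$outlier_flag),
              sum(x$sample_table$outlier_flag)))
  if (!is.null(x$evaluation))
    cat(sprintf("  aligned mean circular error %.2f h, nAUC %.3f\n",
                x$evaluation$alignment$mean_error, x$evaluation$roc$nauc))
  invisible(x)
}

fmt_num_cols <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]))
      df[[j]] <- ifelse(is.na(df[[j]]), "NA", sprintf("%.10g", df[[j]]))
  }
  df
}

#' Write pipeline results to a directory
#'
#' Emits `sample_phases.csv`, `protein_stats.csv`, `outlier_report.csv` and
#' `loss_trace.csv` with fixed numeric formatting, so identical runs produce
#' byte-identical files.
#'
#' @param fit A `circaphase_fit`.
#' @param out_dir Output directory (created if missing).
#' @return Character vector of the written paths, invisibly.
#' @export
write_results <- function(fit, out_dir) {
  stopifnot(inherits(fit, "circaphase_fit"))
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory: ", out_dir, call. = FALSE)
  paths <- file.path(out_dir, c("sample_phases.csv", "protein_stats.csv",
                                "outlier_report.csv", "loss_trace.csv"))
  data.table::fwrite(fmt_num_cols(fit$sample_table), paths[1], quote = FALSE)
  data.table::fwrite(fmt_num_cols(fit$protein_table), paths[2], quote = FALSE)
  data.table::fwrite(fmt_num_cols(fit$report$detail), paths[3], quote = FALSE)
  lt <- data.frame(
    stage = c(rep("finetune", length(fit$loss_trace$finetune)),
              rep("retrain", length(fit$loss_trace$retrain))),
    epoch = c(seq_along(fit$loss_trace$finetune) - 1L,
              seq_along(fit$loss_trace$retrain) - 1L),
    loss = c(fit$loss_trace$finetune, fit$loss_trace$retrain))
  data.table::fwrite(fmt_num_cols(lt), paths[4], quote = FALSE)
  invisible(paths)
}
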