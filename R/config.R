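#' Run configuration for the phase-inference pipeline
#'
#' Collects every tunable of the pipeline in one validated list. The defaults
#' reproduce the reference training schedule: the first five autoencoders are
#' pretrained for 7 epochs each and the last for 20, the full network is
#' fine-tuned for 20 epochs, and after outlier removal the network is
#' retrained for 200 epochs. The fitting loss uses the l1 norm (`q_norm = 1`)
#' with no regularization (`lambda_reg = 0`).
#'
#' @param seed Integer seed controlling every stochastic step (weight
#'   initialization, k-means restarts). Runs with the same seed and inputs are
#'   bit-identical.
#' @param optimizer_name Optimizer for the pretraining autoencoders:
#'   `"dadapt_sgd"` (learning-rate free, the default — it makes real progress
#'   within the few full-batch updates of the pretraining schedule, which a
#'   small fixed learning rate cannot), `"adam"` (learning rate 0.001) or
#'   `"sgd"` (learning rate 0.1, momentum 0.85). The last autoencoder always
#'   uses `"dadapt_sgd"`; the fine-tuning stage uses per-coordinate Adam.
#' @param pretrain_epochs_early Epochs for all but the last autoencoder.
#' @param pretrain_epochs_last Epochs for the final (bottleneck) autoencoder.
#' @param finetune_epochs Epochs for the joint fine-tuning stage.
#' @param retrain_epochs Epochs for the post-screening retraining stage.
#' @param feature_cap Maximum feature count before dimensionality reduction is
#'   applied (only matrices with at least 5000 proteins are reduced); `NULL`
#'   disables reduction.
#' @param q_norm Exponent q of the per-entry fitting error |x - xhat|^q.
#' @param lambda_reg Non-negative regularization weight.
#' @param regularizer One of `"none"`, `"l1"`, `"l2"`, `"tv"`.
#' @param outlier_sigma Number of standard deviations a residual mean must
#'   deviate from its population mean to flag a sample/protein.
#' @param amplitude_rescue_percentile Percentile of predicted amplitudes below
#'   which an outlier-candidate protein is confirmed (candidates at or above
#'   it are rescued).
#' @param period_hours Length of the base cycle in hours; phases are mapped to
#'   clock time through it.
#' @return An object of class `circaphase_config` (a named list).
#' @export
run_config <- function(seed = 1L,
                       optimizer_name = c("dadapt_sgd", "adam", "sgd"),
                       pretrain_epochs_early = 7L,
                       pretrain_epochs_last = 20L,
                       finetune_epochs = 20L,
                       retrain_epochs = 200L,
                       feature_cap = 5000L,
                       q_norm = 1,
                       lambda_reg = 0,
                       regularizer = c("none", "l1", "l2", "tv"),
                       outlier_sigma = 2,
                       amplitude_rescue_percentile = 75,
                       period_hours = 24) {
  optimizer_name <- match.arg(optimizer_name)
  regularizer <- match.arg(regularizer)
  cfg <- list(
    seed = as.integer(seed),
    optimizer_name = optimizer_name,
    pretrain_epochs_early = as.integer(pretrain_epochs_early),
    pretrain_epochs_last = as.integer(pretrain_epochs_last),
    finetune_epochs = as.integer(finetune_epochs),
    retrain_epochs = as.integer(retrain_epochs),
    feature_cap = if (is.null(feature_cap)) NULL else as.integer(feature_cap),
    q_norm = as.numeric(q_norm),
    lambda_reg = as.numeric(lambda_reg),
    regularizer = regularizer,
    outlier_sigma = as.numeric(outlier_sigma),
    amplitude_rescue_percentile = as.numeric(amplitude_rescue_percentile),
    period_hours = as.numeric(period_hours)
  )
  class(cfg) <- "circaphase_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "circaphase_config"))
  epochs <- c(cfg$pretrain_epochs_early, cfg$pretrain_epochs_last,
              cfg$finetune_epochs, cfg$retrain_epochs)
  if (any(epochs < 1L)) stop("all epoch counts must be >= 1", call. = FALSE)
  if (cfg$q_norm <= 0) stop("q_norm must be > 0", call. = FALSE)
  if (cfg$lambda_reg < 0) stop("lambda_reg must be >= 0", call. = FALSE)
  if (cfg$outlier_sigma <= 0) stop("outlier_sigma must be > 0", call. = FALSE)
  if (cfg$amplitude_rescue_percentile < 0 || cfg$amplitude_rescue_percentile > 100)
    stop("amplitude_rescue_percentile must lie in [0, 100]", call. = FALSE)
  if (cfg$period_hours <= 0) stop("period_hours must be > 0", call. = FALSE)
  if (!is.null(cfg$feature_cap) && cfg$feature_cap < 2L)
    stop("feature_cap must be >= 2 or NULL", call. = FALSE)
  invisible(cfg)
}

#' Read a run configuration from a flat YAML file
#'
#' The file holds `key: value` pairs mirroring the [run_config()] arguments;
#' keys absent from the file keep their defaults. Unknown keys are an error so
#' that typos do not silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return A `circaphase_config` object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0)
    stop("unknown configuration keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(run_config, raw)
}

#' @export
print.circaphase_config <- function(x, ...) {
  cat("circaphase run configuration\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-28s %s\n", k, if (is.null(v)) "NULL" else as.character(v)))
  }
  invisible(x)
}

# timestamped, stage-tagged log line (message stream so it is sink-able)
log_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, sprintf(fmt, ...)))
}
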