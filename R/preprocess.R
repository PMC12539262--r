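#' Per-protein z-score normalization
#'
#' Standardizes each protein across samples by subtracting its mean and
#' dividing by its population (1/m) standard deviation, so every protein sits
#' on a comparable scale before network training. Zero-variance proteins are
#' dropped (the division is undefined) and the drop logged. Callers keep the
#' raw matrix: rhythmicity statistics are computed on the original scale.
#'
#' @param matrix An `expression_matrix` with `scale_tag = "raw"`.
#' @return An `expression_matrix` with `scale_tag = "zscored"`.
#' @export
zscore_normalize <- function(matrix) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (matrix$scale_tag != "raw")
    stop("zscore_normalize expects a raw-scale matrix", call. = FALSE)
  vals <- matrix$values
  mu <- rowMeans(vals)
  sdp <- sqrt(rowMeans((vals - mu)^2))
  keep <- sdp > 0
  if (any(!keep))
    log_msg("normalize", "dropped %d zero-variance protein(s)", sum(!keep))
  vals <- (vals[keep, , drop = FALSE] - mu[keep]) / sdp[keep]
  expression_matrix(vals, times_known = matrix$times_known, scale_tag = "zscored")
}

#' Reduce a very wide matrix to at most `cap` proteins
#'
#' For matrices with thousands of proteins, training cost and noise can be
#' cut by keeping only informative features. `variance_top_k` keeps the `cap`
#' proteins of highest variance. `kmeans_cluster` groups proteins into
#' `max(10, cap/50)` k-means clusters (on the z-scored profiles, seeded) and
#' keeps whole clusters in decreasing order of their mean within-protein
#' variance until at least `cap` proteins are retained.
#'
#' Normalization equalizes per-protein variance, so on a genuinely z-scored
#' matrix the variance ranking must come from the original scale: pass the
#' raw-scale row variances through `ranking` (the pipeline does). When
#' `ranking` is omitted the row variances of the supplied values are used,
#' which is only discriminative for matrices that are not exactly unit-scale.
#'
#' @param matrix A z-scored `expression_matrix`.
#' @param cap Target protein count; `cap >= n` is a warning no-op.
#' @param method `"variance_top_k"` (default) or `"kmeans_cluster"`.
#' @param seed Integer seed for the k-means restarts.
#' @param ranking Optional per-protein score (larger = keep first), typically
#'   the raw-scale row variances.
#' @return The reduced `expression_matrix`; retained values are unaltered.
#' @export
reduce_features <- function(matrix, cap,
                            method = c("variance_top_k", "kmeans_cluster"),
                            seed = 1L, ranking = NULL) {
  stopifnot(inherits(matrix, "expression_matrix"))
  method <- match.arg(method)
  if (matrix$scale_tag != "zscored")
    stop("reduce_features expects a z-scored matrix", call. = FALSE)
  n <- nrow(matrix$values)
  if (cap >= n) {
    warning("feature cap (", cap, ") >= protein count (", n, "); no reduction")
    return(matrix)
  }
  vals <- matrix$values
  rv <- if (is.null(ranking)) apply(vals, 1, stats::var) else as.numeric(ranking)
  if (length(rv) != n) stop("ranking must have one score per protein", call. = FALSE)
  if (method == "variance_top_k") {
    keep_idx <- order(rv, decreasing = TRUE)[seq_len(cap)]
    keep <- sort(keep_idx)
  } else {
    k <- max(10L, as.integer(ceiling(cap / 50)))
    set.seed(seed)
    km <- stats::kmeans(vals, centers = k, nstart = 5, iter.max = 50)
    cl_var <- tapply(rv, km$cluster, mean)
    ord <- as.integer(names(sort(cl_var, decreasing = TRUE)))
    keep <- integer(0)
    for (cl in ord) {
      keep <- c(keep, which(km$cluster == cl))
      if (length(keep) >= cap) break
    }
    keep <- sort(keep)
  }
  log_msg("reduce", "retained %d of %d proteins (%s)", length(keep), n, method)
  subset_matrix(matrix, proteins = matrix$protein_ids[keep])
}
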