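#' Expression-matrix container
#'
#' A light S3 wrapper around a numeric proteins-by-samples matrix with unique
#' row (protein) and column (sample) identifiers, an optional vector of known
#' collection clock times for evaluation, and a scale tag recording whether
#' the values are raw or z-scored.
#'
#' @param values Numeric matrix, proteins in rows, samples in columns.
#' @param protein_ids,sample_ids Unique identifier character vectors; default
#'   to the dimnames of `values`.
#' @param times_known Optional numeric vector of per-sample clock times in
#'   hours, reduced modulo 24 into [0, 24).
#' @param scale_tag `"raw"` or `"zscored"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, protein_ids = rownames(values),
                              sample_ids = colnames(values),
                              times_known = NULL,
                              scale_tag = c("raw", "zscored")) {
  scale_tag <- match.arg(scale_tag)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values); m <- ncol(values)
  if (is.null(protein_ids)) protein_ids <- paste0("P", seq_len(n))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(m))
  protein_ids <- as.character(protein_ids)
  sample_ids <- as.character(sample_ids)
  if (length(protein_ids) != n || length(sample_ids) != m)
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  if (anyDuplicated(protein_ids))
    stop("duplicate protein identifiers: ",
         paste(unique(protein_ids[duplicated(protein_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (n < 2 || m < 3)
    stop("need at least 2 proteins and 3 samples (got ", n, " x ", m, ")",
         call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression matrix contains missing or non-finite values after loading",
         call. = FALSE)
  if (!is.null(times_known)) {
    if (length(times_known) != m)
      stop("times_known must have one entry per sample", call. = FALSE)
    times_known <- as.numeric(times_known) %% 24
  }
  dimnames(values) <- list(protein_ids, sample_ids)
  structure(list(values = values, protein_ids = protein_ids,
                 sample_ids = sample_ids, times_known = times_known,
                 scale_tag = scale_tag),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d proteins x %d samples [%s]%s\n",
              nrow(x$values), ncol(x$values), x$scale_tag,
              if (is.null(x$times_known)) "" else ", collection times known"))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression matrix from delimited text
#'
#' Expects one header row and one leading identifier column; the body must be
#' numeric. Proteins (rows after orientation) containing any missing value are
#' dropped and the drop count logged, mirroring the no-imputation policy for
#' incomplete proteins.
#'
#' @param path CSV/TSV file path (delimiter sniffed by [data.table::fread()]).
#' @param orientation `"proteins_as_rows"` (default proteomics export
#'   convention) or `"samples_as_rows"` (the table is transposed after
#'   reading).
#' @param times_known Optional per-sample collection times in hours.
#' @return An `expression_matrix` with `scale_tag = "raw"`.
#' @export
read_matrix <- function(path, orientation = c("proteins_as_rows", "samples_as_rows"),
                        times_known = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2) stop("expected an identifier column plus numeric columns in ",
                         path, call. = FALSE)
  ids <- as.character(dt[[1]])
  body <- dt[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (is.character(col)) {
      suppressWarnings(num <- as.numeric(ifelse(col %in% c("", "NA", "NaN"), NA, col)))
      bad <- which(!is.na(col) & !(col %in% c("", "NA", "NaN")) & is.na(num))
      if (length(bad) > 0)
        stop(sprintf("non-numeric cell at row %d, column '%s' in %s",
                     bad[1] + 1L, names(body)[j], path), call. = FALSE)
      body[[j]] <- num
    }
  }
  mat <- as.matrix(body)
  rownames(mat) <- ids
  if (orientation == "samples_as_rows") mat <- t(mat)
  if (anyDuplicated(rownames(mat)))
    stop("duplicate protein identifiers in ", path, call. = FALSE)
  if (anyDuplicated(colnames(mat)))
    stop("duplicate sample identifiers in ", path, call. = FALSE)
  keep <- rowSums(!is.finite(mat)) == 0
  if (any(!keep))
    log_msg("load", "dropped %d of %d proteins with missing values",
            sum(!keep), length(keep))
  mat <- mat[keep, , drop = FALSE]
  expression_matrix(mat, times_known = times_known, scale_tag = "raw")
}

#' Write an expression matrix as delimited text
#'
#' Values are serialized with 17 significant digits so a write/read round trip
#' reproduces them exactly.
#'
#' @param matrix An `expression_matrix`.
#' @param path Output file (`.csv` or `.tsv` chooses the delimiter).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "expression_matrix"))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  vals <- matrix$values
  out <- data.frame(protein_id = matrix$protein_ids,
                    apply(vals, 2, function(col) sprintf("%.17g", col)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- c("protein_id", matrix$sample_ids)
  data.table::fwrite(out, path, sep = sep, quote = FALSE)
  invisible(path)
}

# subset helper keeping metadata consistent
subset_matrix <- function(matrix, proteins = NULL, samples = NULL) {
  stopifnot(inherits(matrix, "expression_matrix"))
  vals <- matrix$values
  pk <- if (is.null(proteins)) matrix$protein_ids else proteins
  sk <- if (is.null(samples)) matrix$sample_ids else samples
  vals <- vals[pk, sk, drop = FALSE]
  tk <- matrix$times_known
  if (!is.null(tk)) tk <- tk[match(sk, matrix$sample_ids)]
  expression_matrix(vals, times_known = tk, scale_tag = matrix$scale_tag)
}
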