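# CpG methylation beta-value pipeline: counts -> beta -> missing-aware
# quantile normalisation -> low-coverage filtering/imputation -> variable
# probe selection. beta = methylated / total lies in [0, 1] (0 fully
# unmethylated, 1 fully methylated); cells with fewer than 10 reads are
# unreliable and treated as missing.

#' Compute beta values from methylated / total read counts
#'
#' beta = methylated / total where total >= `min_reads`, missing otherwise.
#' Blacklisted CpGs (probes reported as poor-accuracy) are dropped entirely.
#'
#' @param methylated,total CpGs x samples integer matrices with identical
#'   dimnames; `methylated <= total` element-wise.
#' @param min_reads coverage floor (default 10).
#' @param blacklist character vector of CpG row names to drop.
#' @return CpGs x samples matrix of beta values with `NA` at low-coverage
#'   cells.
#' @export
compute_beta <- function(methylated, total, min_reads = 10,
                         blacklist = NULL) {
  methylated <- as.matrix(methylated); total <- as.matrix(total)
  stopifnot(identical(dim(methylated), dim(total)))
  if (any(methylated < 0 | total < 0)) stop("malformed counts: negative values")
  if (any(methylated > total)) stop("malformed counts: methylated > total")
  beta <- ifelse(total >= min_reads, methylated / total, NA_real_)
  dimnames(beta) <- dimnames(total)
  if (!is.null(blacklist) && length(blacklist)) {
    keep <- !(rownames(beta) %in% blacklist)
    beta <- beta[keep, , drop = FALSE]
  }
  beta
}

#' Quantile-normalise a beta matrix (missing-aware)
#'
#' Forces each sample's empirical distribution onto the mean-of-order-
#' statistics reference distribution. On a complete matrix this is exact:
#' sorted values become identical across columns, and within-sample rank
#' order is preserved (ties map to the average of the tied reference
#' values). Missing cells are ignored when building the reference (each
#' column's available values are interpolated onto a common quantile grid)
#' and stay missing in the output.
#'
#' @param b numeric matrix (features x samples), possibly with `NA`.
#' @return Matrix of the same shape.
#' @export
quantile_normalize <- function(b) {
  b <- as.matrix(b)
  if (ncol(b) < 2) {
    warning("single-sample matrix: quantile normalisation is a no-op")
    return(b)
  }
  n <- nrow(b)
  grid <- if (n == 1) 0.5 else seq(0, 1, length.out = n)
  contrib <- vapply(seq_len(ncol(b)), function(j) {
    v <- sort(b[, j])  # drops NA
    if (!length(v)) stop("sample with no observed values: ", colnames(b)[j])
    if (length(v) == 1) return(rep(v, n))
    stats::approx(seq(0, 1, length.out = length(v)), v, xout = grid)$y
  }, numeric(n))
  ref <- rowMeans(contrib)
  out <- b
  for (j in seq_len(ncol(b))) {
    ok <- !is.na(b[, j])
    nj <- sum(ok)
    r <- rank(b[ok, j], ties.method = "average")
    p <- if (nj == 1) 0.5 else (r - 1) / (nj - 1)
    out[ok, j] <- stats::approx(grid, ref, xout = p)$y
  }
  out
}

#' Remove or impute low-coverage CpG positions
#'
#' CpGs missing (low-coverage) in two or more samples are removed; a CpG
#' missing in exactly one sample has that cell replaced with the median beta
#' of the remaining samples at that position. The result has no missing
#' cells.
#'
#' @param b beta matrix with `NA` marking low-coverage cells.
#' @return Complete beta matrix; removed CpG ids in attribute `"removed"`.
#' @export
filter_and_impute <- function(b) {
  b <- as.matrix(b)
  n_low <- rowSums(is.na(b))
  removed <- rownames(b)[n_low >= 2]
  keep <- n_low < 2
  out <- b[keep, , drop = FALSE]
  one <- which(rowSums(is.na(out)) == 1)
  for (i in one) {
    j <- which(is.na(out[i, ]))
    out[i, j] <- median(out[i, -j])
  }
  attr(out, "removed") <- removed %||% character(0)
  out
}

#' Select the most variable features
#'
#' Rows ranked by variance (descending) computed across the designated
#' sample subset; ties broken by row name for determinism.
#'
#' @param b complete numeric matrix (features x samples).
#' @param k number of rows to keep (default 1000; all rows if `k >=` the row
#'   count).
#' @param samples optional column subset over which variability is computed
#'   (e.g. the clone samples); all columns are retained in the output.
#' @return The matrix restricted to the top `k` rows, in ranked order.
#' @export
select_top_variable <- function(b, k = 1000, samples = NULL) {
  if (k <= 0) stop("k must be positive")
  b <- as.matrix(b)
  sub <- if (is.null(samples)) b else b[, samples, drop = FALSE]
  v <- apply(sub, 1, var)
  ids <- rownames(b) %||% as.character(seq_len(nrow(b)))
  o <- order(-v, ids)
  b[o[seq_len(min(k, nrow(b)))], , drop = FALSE]
}
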