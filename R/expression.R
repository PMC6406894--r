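# Expression normalisation and fold-change flagging.
#
# Counts are scaled to counts-per-million using an effective library size:
# raw library size times a trimmed-mean-of-M-values (TMM) factor. TMM
# computes, for each sample against a reference sample, gene-wise log-ratios
# (M) and log-abundances (A), double-trims them (30% on M, 5% on A), and
# takes a precision-weighted mean of the surviving M values; factors are
# renormalised to geometric mean 1. Fold changes versus the normal cortex
# are log2((tumour + 1) / (cortex + 1)) on normalised values.

# TMM factor of one sample against the reference (both raw count vectors)
tmm_pair <- function(obs, ref, lib_obs = sum(obs), lib_ref = sum(ref),
                     logratio_trim = 0.3, sum_trim = 0.05, weighted = TRUE,
                     a_cutoff = -1e10) {
  obs <- as.numeric(obs); ref <- as.numeric(ref)
  logR <- log2((obs / lib_obs) / (ref / lib_ref))
  absE <- (log2(obs / lib_obs) + log2(ref / lib_ref)) / 2
  v <- (lib_obs - obs) / lib_obs / obs + (lib_ref - ref) / lib_ref / ref
  fin <- is.finite(logR) & is.finite(absE) & (absE > a_cutoff)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (!length(logR) || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1; hiS <- n + 1 - loS
  rL <- rank(logR); rS <- rank(absE)
  keep <- rL >= loL & rL <= hiL & rS >= loS & rS <= hiS
  f <- if (weighted) {
    sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  } else {
    mean(logR[keep], na.rm = TRUE)
  }
  if (is.na(f)) f <- 0
  2^f
}

#' TMM normalisation factors
#'
#' Trimmed mean of M-values with the reference sample chosen as the column
#' whose 75th count percentile (scaled by library size) is closest to the
#' mean across samples; trimming defaults 30% on M and 5% on A; factors are
#' renormalised so their geometric mean is 1.
#'
#' @param counts genes x samples non-negative count matrix (>= 2 samples).
#' @param lib_sizes library sizes (default column sums).
#' @param logratio_trim,sum_trim trim fractions on M and A.
#' @return Named numeric vector of factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, lib_sizes = colSums(counts),
                        logratio_trim = 0.3, sum_trim = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("TMM needs at least 2 samples")
  if (any(counts < 0)) stop("negative counts")
  if (any(lib_sizes == 0)) stop("all-zero sample in count matrix")
  f75 <- vapply(seq_len(ncol(counts)),
                function(j) quantile(counts[, j], 0.75) / lib_sizes[j],
                numeric(1))
  ref <- if (median(f75) < 1e-20) which.max(colSums(sqrt(counts))) else
    which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair(counts[, j], counts[, ref], lib_sizes[j], lib_sizes[ref],
             logratio_trim, sum_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' Normalise a count matrix to TMM-scaled counts per million
#'
#' @inheritParams tmm_factors
#' @return List with `cpm` (genes x samples), `tmm_factors`, `lib_sizes`.
#' @export
normalize_expression <- function(counts, lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  f <- tmm_factors(counts, lib_sizes)
  eff <- lib_sizes * f
  cpm <- sweep(counts, 2, eff / 1e6, "/")
  list(cpm = cpm, tmm_factors = f, lib_sizes = lib_sizes)
}

#' Log2 fold change versus the normal cortex column
#'
#' Per gene and tumour-derived sample: log2((tumour + 1) / (cortex + 1)) on
#' normalised expression, antisymmetric under swapping the two samples.
#'
#' @param normalised genes x samples matrix of normalised expression.
#' @param cortex name (or index) of the designated normal-cortex column.
#' @return Genes x (samples - cortex) matrix of log2 fold changes.
#' @export
log2_fold_change <- function(normalised, cortex) {
  normalised <- as.matrix(normalised)
  if (is.character(cortex)) {
    if (!cortex %in% colnames(normalised))
      stop("cortex column not found: ", cortex)
    cortex <- match(cortex, colnames(normalised))
  }
  ref <- normalised[, cortex]
  lfc <- log2(sweep(normalised[, -cortex, drop = FALSE] + 1, 1, ref + 1, "/"))
  lfc
}

#' Flag over-expressed genes per sample
#'
#' A gene is flagged in a sample when its fold change versus cortex is
#' strictly greater than `threshold_fold` (i.e. log2 value > log2(threshold);
#' exactly 2-fold is not flagged).
#'
#' @param lfc log2 fold-change matrix from [log2_fold_change()].
#' @param threshold_fold linear fold-change threshold (default 2).
#' @return Named list of flagged gene vectors, one per sample.
#' @export
flag_overexpressed <- function(lfc, threshold_fold = 2) {
  lfc <- as.matrix(lfc)
  lapply(stats::setNames(nm = colnames(lfc)), function(s) {
    rownames(lfc)[lfc[, s] > log2(threshold_fold)]
  })
}

#' Select genes driving the first two principal components
#'
#' PCA on gene-centred data; genes ranked by the larger of their absolute
#' loadings on PC1 and PC2, top `k` retained. Invariant to sample order.
#'
#' @param normalised genes x samples matrix (>= 3 samples); log-scale values
#'   are recommended.
#' @param k number of genes to keep (default 500).
#' @return Character vector of gene names, ranked.
#' @export
select_variable_genes <- function(normalised, k = 500) {
  x <- as.matrix(normalised)
  if (ncol(x) < 3) stop("PCA gene selection needs >= 3 samples")
  x <- x - rowMeans(x)
  if (all(abs(x) < 1e-12)) stop("constant matrix: no variance to decompose")
  # principal components of the samples; rotation rows = gene loadings
  pc <- prcomp(t(x), center = FALSE, scale. = FALSE)
  load <- abs(pc$rotation[, seq_len(min(2, ncol(pc$rotation))), drop = FALSE])
  score <- apply(load, 1, max)
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  o <- order(-score, ids)
  ids[o[seq_len(min(k, length(o)))]]
}

#' Gene-wise centred and scaled log2 values for heat-map export
#'
#' @param normalised genes x samples matrix of normalised expression.
#' @return Per-gene z-scores of log2(x + 1).
#' @export
center_scale_log2 <- function(normalised) {
  l <- log2(as.matrix(normalised) + 1)
  sdv <- apply(l, 1, stats::sd)
  sdv[sdv == 0] <- 1
  (l - rowMeans(l)) / sdv
}
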