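# SNP-array stage: pairwise genotype concordance across >400K polymorphic
# positions confirms all samples derive from one patient; the most variable
# LogR-ratio probes (cross-sample range > 0.3 and < 1.5, the upper bound
# excluding extreme-artifact probes) feed the sample-relationship dendrogram.

#' Pairwise genotype concordance
#'
#' For every sample pair, the fraction of probes with identical calls among
#' probes non-missing in both samples. Symmetric with unit diagonal.
#'
#' @param genotypes probes x samples matrix of calls (e.g. `"AA"`, `"AB"`,
#'   `"BB"`); `NA` marks missing calls.
#' @return Samples x samples numeric matrix; `NA` (with a warning) for pairs
#'   sharing no callable probe.
#' @export
genotype_concordance <- function(genotypes) {
  g <- as.matrix(genotypes)
  if (ncol(g) < 2) stop("concordance needs at least 2 samples")
  ns <- ncol(g)
  out <- matrix(NA_real_, ns, ns, dimnames = list(colnames(g), colnames(g)))
  diag(out) <- 1
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
    ok <- !is.na(g[, i]) & !is.na(g[, j])
    if (!any(ok)) {
      warning("no callable probes shared by ", colnames(g)[i], " and ",
              colnames(g)[j])
      next
    }
    out[i, j] <- out[j, i] <- mean(g[ok, i] == g[ok, j])
  }
  out
}

#' Select variable LogR probes
#'
#' A probe is retained when its cross-sample LogR range (max - min) is
#' strictly greater than `low` and strictly less than `high`. Probes with any
#' missing value are excluded from candidacy.
#'
#' @param logr probes x samples LogR-ratio matrix (>= 2 samples).
#' @param low,high strict range bounds (defaults 0.3 and 1.5).
#' @return Character vector of retained probe names (row indices as
#'   characters when unnamed).
#' @export
select_variable_probes <- function(logr, low = 0.3, high = 1.5) {
  x <- as.matrix(logr)
  if (ncol(x) < 2) stop("probe selection needs at least 2 samples")
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  complete <- rowSums(is.na(x)) == 0
  rng <- apply(x[complete, , drop = FALSE], 1, function(v) max(v) - min(v))
  ids[complete][rng > low & rng < high]
}
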