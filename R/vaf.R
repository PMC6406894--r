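# Cross-sample VAF matrix, trunk/shared/private classification, and
# sample-relationship clustering.
#
# Trunk variants are carried by every tumour-derived sample and are presumed
# to predate clonal divergence; private variants by exactly one sample;
# everything in between is shared. The matched normal is excluded from
# carrier determination.

#' Build a VAF matrix from pileup counts
#'
#' Takes pileup counts for the union of high-confidence variants over every
#' sample (including samples where a variant was never called) and computes
#' `vaf = alt / depth`, marking cells below a depth floor as missing.
#'
#' @param pileup data frame with columns `variant_id`, `sample`, `depth`,
#'   `alt_reads` (long format), or a TSV path.
#' @param min_depth depth floor below which a cell is missing (default 8).
#' @param variants optional variant ordering; defaults to first appearance.
#' @return A `vaf_matrix`: list with `vaf`, `depth`, `alt` (variants x
#'   samples; `vaf` is `NA` where depth < `min_depth`), `variants`, `samples`.
#' @export
build_vaf_matrix <- function(pileup, min_depth = 8, variants = NULL) {
  if (is.character(pileup)) pileup <- read_tsv(pileup)
  stopifnot(all(c("variant_id", "sample", "depth", "alt_reads") %in%
                  names(pileup)))
  if (any(pileup$alt_reads > pileup$depth))
    stop("malformed pileup: alt_reads exceeds depth")
  if (any(pileup$depth < 0)) stop("malformed pileup: negative depth")
  variants <- variants %||% unique(pileup$variant_id)
  samples <- unique(pileup$sample)
  shape <- list(variants, samples)
  depth <- alt <- matrix(NA_real_, length(variants), length(samples),
                         dimnames = shape)
  ij <- cbind(match(pileup$variant_id, variants), match(pileup$sample, samples))
  if (anyNA(ij[, 1])) {
    keep <- !is.na(ij[, 1])
    pileup <- pileup[keep, ]; ij <- ij[keep, , drop = FALSE]
  }
  depth[ij] <- pileup$depth
  alt[ij] <- pileup$alt_reads
  vaf <- ifelse(depth > 0, alt / depth, NA_real_)
  vaf[!is.na(depth) & depth < min_depth] <- NA_real_
  structure(list(vaf = vaf, depth = depth, alt = alt,
                 variants = variants, samples = samples,
                 min_depth = min_depth),
            class = "vaf_matrix")
}

#' Classify variants as trunk, shared or private
#'
#' A tumour-derived sample carries a variant when its VAF is at least
#' `presence_vaf` and it has at least `min_alt_reads` supporting reads
#' (missing cells are non-carriers). Trunk = carried by every tumour-derived
#' sample; private = carried by exactly one; shared = otherwise (carried by
#' more than one but not all). Variants carried by no sample are reported
#' separately as `absent` and excluded from the percentages.
#'
#' @param m a `vaf_matrix`, or a plain variants x samples matrix of VAFs (in
#'   which case the alt-read condition is skipped).
#' @param presence_vaf,min_alt_reads carrier thresholds (defaults 0.05 and 3).
#' @param normal name of the matched normal column to exclude (ignored when
#'   absent).
#' @param tumour_samples optionally, the exact tumour-derived sample set to
#'   classify over.
#' @return A `sharing_summary`: `assignment` (variant, category, n_carriers,
#'   carriers), `counts` and `percentages` over trunk/shared/private, and
#'   `n_samples`.
#' @export
classify_sharing <- function(m, presence_vaf = 0.05, min_alt_reads = 3,
                             normal = "Blood", tumour_samples = NULL) {
  if (inherits(m, "vaf_matrix")) {
    vaf <- m$vaf; alt <- m$alt
  } else {
    vaf <- as.matrix(m); alt <- NULL
  }
  tumour_samples <- tumour_samples %||% setdiff(colnames(vaf), normal)
  if (length(tumour_samples) < 2)
    stop("classification needs at least 2 tumour-derived samples")
  vaf <- vaf[, tumour_samples, drop = FALSE]
  carrier <- !is.na(vaf) & vaf >= presence_vaf
  if (!is.null(alt))
    carrier <- carrier & !is.na(alt[, tumour_samples, drop = FALSE]) &
      alt[, tumour_samples, drop = FALSE] >= min_alt_reads
  ncar <- rowSums(carrier)
  category <- ifelse(ncar == 0, "absent",
               ifelse(ncar == length(tumour_samples), "trunk",
                ifelse(ncar == 1, "private", "shared")))
  carriers <- apply(carrier, 1, function(x) tumour_samples[x],
                    simplify = FALSE)
  assignment <- data.frame(variant = rownames(vaf) %||%
                             as.character(seq_len(nrow(vaf))),
                           category = category, n_carriers = ncar,
                           stringsAsFactors = FALSE)
  assignment$carriers <- carriers
  present <- category != "absent"
  counts <- c(trunk = sum(category == "trunk"),
              shared = sum(category == "shared"),
              private = sum(category == "private"))
  total <- sum(present)
  percentages <- if (total > 0) 100 * counts / total else counts * NA_real_
  structure(list(assignment = assignment, counts = counts,
                 percentages = percentages, total = total,
                 n_absent = sum(!present),
                 n_samples = length(tumour_samples),
                 samples = tumour_samples),
            class = "sharing_summary")
}

#' @export
print.sharing_summary <- function(x, ...) {
  cat(sprintf("Sharing over %d samples, %d classified variants", x$n_samples,
              x$total))
  if (x$n_absent) cat(sprintf(" (%d absent in all)", x$n_absent))
  cat("\n")
  for (k in names(x$counts))
    cat(sprintf("  %-8s %6d  (%.2f%%)\n", k, x$counts[[k]],
                x$percentages[[k]]))
  invisible(x)
}

# union-find for transitive-closure clustering of SV records
uf_find <- function(parent, i) {
  while (parent[i] != i) { parent[i] <- parent[parent[i]]; i <- parent[i] }
  i
}

#' Classify structural-variant sharing across samples
#'
#' Two SV records match when they have the same type, the same chromosome
#' pair, and both breakend positions within `tolerance_bp`; matching is
#' clustered by transitive closure into SV events, which are then classified
#' trunk / shared / private by their carrier sample sets.
#'
#' @param sv data frame with columns `chrom1`, `pos1`, `chrom2`, `pos2`,
#'   `sv_type`, `sample` (or a TSV path).
#' @param tolerance_bp breakend matching tolerance (default 100).
#' @param samples full tumour-derived sample set (defaults to the samples
#'   observed in `sv`); trunk means carried by all of these.
#' @return A `sharing_summary` whose `assignment` has one row per SV event,
#'   plus `events` mapping each input record to its event.
#' @export
classify_sv_sharing <- function(sv, tolerance_bp = 100, samples = NULL) {
  if (is.character(sv)) sv <- read_tsv(sv)
  req <- c("chrom1", "pos1", "chrom2", "pos2", "sv_type", "sample")
  stopifnot(all(req %in% names(sv)))
  bad <- sv$chrom1 == sv$chrom2 & sv$pos1 > sv$pos2
  if (any(bad)) stop("malformed SV records: pos1 > pos2 on intrachromosomal events")
  if (any(sv$pos1 < 1 | sv$pos2 < 1)) stop("malformed SV records: positions < 1")
  samples <- samples %||% sort(unique(sv$sample))
  if (length(samples) < 2) stop("SV classification needs >= 2 samples")
  n <- nrow(sv)
  parent <- seq_len(n)
  key <- paste(sv$sv_type, sv$chrom1, sv$chrom2)
  for (g in split(seq_len(n), key)) {
    if (length(g) < 2) next
    for (a in seq_along(g)[-1]) for (b in seq_len(a - 1)) {
      i <- g[a]; j <- g[b]
      if (abs(sv$pos1[i] - sv$pos1[j]) <= tolerance_bp &&
          abs(sv$pos2[i] - sv$pos2[j]) <= tolerance_bp) {
        ri <- uf_find(parent, i); rj <- uf_find(parent, j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  root <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  event <- match(root, unique(root))
  carriers <- lapply(split(sv$sample, event), unique)
  ncar <- lengths(carriers)
  category <- ifelse(ncar == length(samples), "trunk",
               ifelse(ncar == 1, "private", "shared"))
  assignment <- data.frame(variant = sprintf("event%03d", seq_along(carriers)),
                           category = category, n_carriers = ncar,
                           stringsAsFactors = FALSE)
  assignment$carriers <- carriers
  counts <- c(trunk = sum(category == "trunk"),
              shared = sum(category == "shared"),
              private = sum(category == "private"))
  structure(list(assignment = assignment, counts = counts,
                 percentages = 100 * counts / length(carriers),
                 total = length(carriers), n_absent = 0L,
                 n_samples = length(samples), samples = samples,
                 events = data.frame(record = seq_len(n),
                                     event = assignment$variant[event])),
            class = "sharing_summary")
}

#' Hierarchically cluster samples
#'
#' Agglomerative complete-linkage clustering of samples on a features x
#' samples matrix, with Euclidean or Pearson-correlation (1 - r) distance.
#' Missing cells are imputed (default 0: absence of evidence at adequate
#' depth is treated as absence in near-pure clonal lines) before distances
#' are computed. Samples are ordered lexicographically internally so that
#' equal-distance merges resolve deterministically regardless of input column
#' order.
#'
#' @param x features x samples numeric matrix, or a `vaf_matrix`.
#' @param distance `"euclidean"` or `"pearson"` (1 minus Pearson correlation).
#' @param linkage only `"complete"` is supported.
#' @param impute value substituted for missing cells (default 0); use
#'   `NULL` to forbid missing data.
#' @return An [stats::hclust] object; export with [as_newick()].
#' @export
cluster_samples <- function(x, distance = c("euclidean", "pearson"),
                            linkage = "complete", impute = 0) {
  distance <- match.arg(distance)
  stopifnot(identical(linkage, "complete"))
  if (inherits(x, "vaf_matrix")) x <- x$vaf
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("clustering needs at least 2 samples")
  all_missing <- colSums(!is.na(x)) == 0
  if (any(all_missing))
    stop("sample(s) with no observed values: ",
         paste(colnames(x)[all_missing], collapse = ", "))
  if (anyNA(x)) {
    if (is.null(impute)) stop("missing cells present and impute = NULL")
    x[is.na(x)] <- impute
  }
  x <- x[, order(colnames(x)), drop = FALSE]
  d <- switch(distance,
    euclidean = dist(t(x), method = "euclidean"),
    pearson = stats::as.dist(1 - stats::cor(x))
  )
  hclust(d, method = "complete")
}

#' Export a dendrogram as a Newick string
#'
#' Ultrametric Newick via [ape::as.phylo()]: node heights are half the merge
#' heights, so the cophenetic (leaf-to-leaf) path length between two samples
#' equals the height at which they merge.
#'
#' @param hc an [stats::hclust] object.
#' @param file optional path to write to.
#' @return The Newick string, invisibly when written to file.
#' @export
as_newick <- function(hc, file = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(file)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = file)
  invisible(ape::write.tree(phy))
}
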