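# Copy-number state occupancy, whole-genome duplication (WGD) detection and
# correction, aberrant-genome fraction, copy-neutral LOH, and per-gene states.
#
# WGD leaves most of the genome at total copy number 3-4 (both alleles
# doubled, then scattered losses). Judging gene-level consequence on such a
# background is uninformative, so profiles are halved back to a near-diploid
# state (round-half-up, preserving heterozygosity) before aberrance is
# scored: a base is non-aberrant iff its state is diploid heterozygous
# (total 2, minor 1) after any correction.

#' Construct a per-sample copy-number profile
#'
#' @param sample sample name.
#' @param segments data frame with `chrom`, `start`, `end` (0-based
#'   half-open), `total_cn`, `minor_cn`; segments must be non-overlapping per
#'   chromosome with `minor_cn <= total_cn`.
#' @param genome_length total assayed bases (defaults to the sum of segment
#'   widths).
#' @param wgd_corrected internal flag; profiles are never corrected twice.
#' @return A `cn_profile` object.
#' @export
cn_profile <- function(sample, segments, genome_length = NULL,
                       wgd_corrected = FALSE) {
  if (is.character(segments)) segments <- read_tsv(segments)
  req <- c("chrom", "start", "end", "total_cn", "minor_cn")
  stopifnot(all(req %in% names(segments)))
  segments <- as.data.frame(segments)[req]
  if (any(segments$end <= segments$start)) stop("segments must have end > start")
  if (any(segments$total_cn < 0 | segments$minor_cn < 0))
    stop("negative copy numbers")
  if (any(segments$minor_cn > segments$total_cn))
    stop("minor_cn exceeds total_cn")
  for (sg in split(segments, segments$chrom)) {
    sg <- sg[order(sg$start), ]
    if (nrow(sg) > 1 && any(sg$start[-1] < sg$end[-nrow(sg)]))
      stop("overlapping segments on ", sg$chrom[1])
  }
  genome_length <- genome_length %||% sum(segments$end - segments$start)
  structure(list(sample = sample, segments = segments,
                 genome_length = genome_length,
                 wgd_corrected = isTRUE(wgd_corrected)),
            class = "cn_profile")
}

seg_width <- function(p) p$segments$end - p$segments$start

#' Genome fraction at each total copy number
#'
#' @param p a [cn_profile()].
#' @return Named numeric: fraction of `genome_length` at each observed
#'   integer total copy number.
#' @export
state_fractions <- function(p) {
  stopifnot(inherits(p, "cn_profile"))
  w <- tapply(seg_width(p), p$segments$total_cn, sum) / p$genome_length
  stats::setNames(as.numeric(w), names(w))
}

#' Detect whole-genome duplication
#'
#' A sample is called WGD when at least `threshold` of its genome sits at
#' total copy number 3 or 4 (the motivating cohort shows > 84% in WGD clones
#' versus <= 3% elsewhere, so 0.5 cleanly separates the regimes).
#'
#' @param x a [cn_profile()] or the output of [state_fractions()].
#' @param threshold decision threshold on the CN 3-4 fraction (`>=` passes).
#' @return Logical.
#' @export
detect_wgd <- function(x, threshold = 0.5) {
  fr <- if (inherits(x, "cn_profile")) state_fractions(x) else x
  f34 <- sum(fr[names(fr) %in% c("3", "4")])
  f34 >= threshold
}

#' Halve a WGD profile back to a near-diploid state
#'
#' Per segment, corrected total = round-half-up(total / 2) and corrected
#' minor = round-half-up(minor / 2), so odd states keep their heterozygosity
#' ((3,1) -> (2,1), never (2,0)). Refuses to run on a profile that does not
#' look WGD (unless `force`) and never corrects twice.
#'
#' @param p a [cn_profile()].
#' @param threshold passed to [detect_wgd()].
#' @param force correct even when [detect_wgd()] is FALSE.
#' @return The corrected `cn_profile` (flagged `wgd_corrected`).
#' @export
correct_wgd <- function(p, threshold = 0.5, force = FALSE) {
  stopifnot(inherits(p, "cn_profile"))
  if (p$wgd_corrected) stop("profile already WGD-corrected")
  if (!force && !detect_wgd(p, threshold))
    stop("profile does not look whole-genome duplicated; use force = TRUE")
  seg <- p$segments
  seg$total_cn <- round_half_up(seg$total_cn / 2)
  seg$minor_cn <- pmin(round_half_up(seg$minor_cn / 2), seg$total_cn)
  cn_profile(p$sample, seg, p$genome_length, wgd_corrected = TRUE)
}

#' Aberrant genome fraction
#'
#' Fraction of the assayed genome whose state is not diploid heterozygous
#' (total 2, minor 1); apply [correct_wgd()] first for WGD samples so that
#' polyploid-heterozygous genomes are not scored aberrant wholesale.
#'
#' @param p a [cn_profile()] (corrected first when WGD).
#' @return Fraction in [0, 1].
#' @export
aberrant_fraction <- function(p) {
  stopifnot(inherits(p, "cn_profile"))
  ab <- !(p$segments$total_cn == 2 & p$segments$minor_cn == 1)
  sum(seg_width(p)[ab]) / p$genome_length
}

#' Call copy-neutral LOH segments
#'
#' @param p a [cn_profile()] (post-correction for WGD samples).
#' @return The segments with total 2 and minor 0. A (1,0) segment is
#'   deletion-LOH, not cnLOH, and is not returned.
#' @export
call_cnloh <- function(p) {
  stopifnot(inherits(p, "cn_profile"))
  p$segments[p$segments$total_cn == 2 & p$segments$minor_cn == 0, ]
}

#' One-line copy-number summary of a sample
#'
#' @param p a [cn_profile()].
#' @param wgd_threshold passed to [detect_wgd()].
#' @return A `cn_summary` list: `state_fractions`, `wgd`,
#'   `aberrant_fraction` and `cnloh_fraction` (both computed after WGD
#'   correction when WGD is detected).
#' @export
summarize_cn <- function(p, wgd_threshold = 0.5) {
  fr <- state_fractions(p)
  wgd <- detect_wgd(fr, wgd_threshold)
  pc <- if (wgd && !p$wgd_corrected) correct_wgd(p, wgd_threshold) else p
  cnloh <- call_cnloh(pc)
  structure(list(
    sample = p$sample, state_fractions = fr, wgd = wgd,
    aberrant_fraction = aberrant_fraction(pc),
    cnloh_fraction = sum(cnloh$end - cnloh$start) / p$genome_length
  ), class = "cn_summary")
}

#' Per-gene copy-number state
#'
#' Each gene takes the state of the segment with the largest overlap
#' (majority rule): total 0 = homozygous loss; total below ploidy = loss;
#' minor 0 at or above ploidy = LOH; total >= `amp_threshold` =
#' amplification; total above ploidy = gain; otherwise neutral. Profiles
#' should be WGD-corrected first, so ploidy is 2.
#'
#' @param p a [cn_profile()].
#' @param genes data frame with `gene`, `chrom`, `start`, `end` (0-based
#'   half-open, same coordinate system as the profile).
#' @param ploidy reference ploidy after correction (default 2).
#' @param amp_threshold total copy number called amplification (default 6).
#' @return Data frame `gene`, `total_cn`, `minor_cn`, `state`; genes
#'   overlapping no segment are reported with state `"missing"`.
#' @export
gene_copy_state <- function(p, genes, ploidy = 2, amp_threshold = 6) {
  stopifnot(inherits(p, "cn_profile"),
            all(c("gene", "chrom", "start", "end") %in% names(genes)))
  seg <- p$segments
  gr_seg <- GenomicRanges::GRanges(seg$chrom,
                                   IRanges::IRanges(seg$start + 1, seg$end))
  gr_gene <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start + 1, genes$end))
  hits <- GenomicRanges::findOverlaps(gr_gene, gr_seg)
  ov <- IRanges::width(IRanges::pintersect(
    gr_gene[S4Vectors::queryHits(hits)], gr_seg[S4Vectors::subjectHits(hits)]))
  best <- rep(NA_integer_, nrow(genes))
  if (length(hits)) {
    o <- order(S4Vectors::queryHits(hits), -ov,
               S4Vectors::subjectHits(hits))  # ties -> first segment
    qh <- S4Vectors::queryHits(hits)[o]
    keep <- !duplicated(qh)
    best[qh[keep]] <- S4Vectors::subjectHits(hits)[o][keep]
  }
  total <- seg$total_cn[best]; minor <- seg$minor_cn[best]
  state <- ifelse(is.na(total), "missing",
           ifelse(total == 0, "homozygous_loss",
           ifelse(total < ploidy, "loss",
           ifelse(minor == 0, "LOH",
           ifelse(total >= amp_threshold, "amplification",
           ifelse(total > ploidy, "gain", "neutral"))))))
  data.frame(gene = genes$gene, total_cn = total, minor_cn = minor,
             state = state, stringsAsFactors = FALSE)
}

#' Write / read copy-number segments (BED-like TSV, 0-based half-open)
#'
#' @param p a [cn_profile()]; `path` a TSV path.
#' @return `write_segments` returns the path invisibly; `read_segments`
#'   returns a [cn_profile()].
#' @export
write_segments <- function(p, path) {
  write_tsv(p$segments, path)
}

#' @rdname write_segments
#' @param sample sample name for the profile read back.
#' @param genome_length see [cn_profile()].
#' @export
read_segments <- function(path, sample = basename(path), genome_length = NULL) {
  cn_profile(sample, read_tsv(path), genome_length)
}
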