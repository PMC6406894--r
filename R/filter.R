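# High-confidence somatic variant filter.
#
# Candidate calls (dual-caller SNVs and 1-50 bp indels) are kept only when the
# read-level evidence clears every rule: adequate control and tumour coverage,
# at least five supporting reads with distinct start positions, the variant
# not within the first or last five bases of its supporting reads, support on
# both strands, distance > 5 bp from a mononucleotide run of >= 7 bases, and
# < 3% variant evidence in the control. All rules are evaluated (no
# short-circuit) so every violated rule is reported.

filter_rule_names <- c("control_coverage", "tumour_coverage", "alt_support",
                       "distinct_starts", "read_end", "strand", "homopolymer",
                       "control_contamination")

#' Thresholds for the high-confidence somatic filter
#'
#' Defaults are the published rule set: control depth >= 8, tumour depth
#' >= 12, >= 5 variant-supporting reads with >= 5 distinct start positions,
#' variant more than 5 bases from either read end, support on both strands,
#' more than 5 bp from a mononucleotide run of >= 7 bases, and < 3% variant
#' evidence in the control sample.
#'
#' @param min_control_depth,min_tumour_depth minimum read depths (passing
#'   values are `>=` the threshold).
#' @param min_alt_reads,min_distinct_starts minimum variant-supporting reads
#'   and distinct alignment start positions (`>=`).
#' @param min_dist_read_end supporting-read end exclusion zone; the variant's
#'   minimum distance from either read end must be strictly greater.
#' @param min_dist_homopolymer distance to the nearest mononucleotide run of
#'   >= 7 bases must be strictly greater.
#' @param max_control_fraction control alt-read fraction must be strictly
#'   below this value (0.03 itself fails).
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(min_control_depth = 8, min_tumour_depth = 12,
                              min_alt_reads = 5, min_distinct_starts = 5,
                              min_dist_read_end = 5, min_dist_homopolymer = 5,
                              max_control_fraction = 0.03) {
  structure(list(
    min_control_depth = min_control_depth, min_tumour_depth = min_tumour_depth,
    min_alt_reads = min_alt_reads, min_distinct_starts = min_distinct_starts,
    min_dist_read_end = min_dist_read_end,
    min_dist_homopolymer = min_dist_homopolymer,
    max_control_fraction = max_control_fraction
  ), class = "filter_thresholds")
}

validate_evidence <- function(ev) {
  req <- c("control_depth", "tumour_depth", "alt_reads", "distinct_alt_starts",
           "min_dist_read_end", "fwd_alt", "rev_alt", "dist_to_homopolymer7",
           "control_alt_fraction")
  miss <- setdiff(req, names(ev))
  if (length(miss)) stop("evidence is missing columns: ", paste(miss, collapse = ", "))
  counts <- c("control_depth", "tumour_depth", "alt_reads",
              "distinct_alt_starts", "fwd_alt", "rev_alt")
  for (cc in counts) if (any(ev[[cc]] < 0, na.rm = TRUE))
    stop("malformed evidence: negative ", cc)
  if (any(ev$control_alt_fraction < 0 | ev$control_alt_fraction > 1, na.rm = TRUE))
    stop("malformed evidence: control_alt_fraction outside [0, 1]")
  invisible(ev)
}

#' Apply the high-confidence filter rules to variant evidence
#'
#' Evaluates every rule on each evidence row (vectorised; one row per
#' candidate variant per tumour sample) and records all violated rules.
#'
#' @param ev data frame of read-level evidence (see [simulate_reads()] for the
#'   schema) -- a single row is also accepted.
#' @param thresholds a [filter_thresholds()].
#' @return Data frame with `passed` (logical) and `failed_rules` (list column
#'   of character vectors; empty iff passed), row-parallel to `ev`.
#' @export
apply_filters <- function(ev, thresholds = filter_thresholds()) {
  ev <- as.data.frame(ev)
  validate_evidence(ev)
  th <- thresholds
  fails <- cbind(
    control_coverage = ev$control_depth < th$min_control_depth,
    tumour_coverage = ev$tumour_depth < th$min_tumour_depth,
    alt_support = ev$alt_reads < th$min_alt_reads,
    distinct_starts = ev$distinct_alt_starts < th$min_distinct_starts,
    read_end = ev$min_dist_read_end <= th$min_dist_read_end,
    strand = ev$fwd_alt < 1 | ev$rev_alt < 1,
    homopolymer = ev$dist_to_homopolymer7 <= th$min_dist_homopolymer,
    control_contamination = ev$control_alt_fraction >= th$max_control_fraction
  )
  failed_rules <- apply(fails, 1, function(f) filter_rule_names[f],
                        simplify = FALSE)
  res <- data.frame(passed = rowSums(fails) == 0)
  res$failed_rules <- failed_rules
  res
}

#' Filter a candidate cohort to the high-confidence set
#'
#' A variant enters the cohort's high-confidence set when it passes the full
#' rule set in at least one tumour sample. When the evidence carries a
#' `callers` column (comma-separated caller names), only variants reported by
#' at least two callers are eligible, reflecting a dual-calling strategy.
#'
#' @param vcf path to the candidate VCF (or `NULL` to derive records from the
#'   evidence table alone).
#' @param evidence evidence data frame or TSV path; every VCF record must have
#'   at least one matching evidence row (matched on chrom:pos:ref:alt).
#' @param thresholds a [filter_thresholds()].
#' @param out optional path for the filtered VCF; failed records receive a
#'   FILTER value naming the rules violated in every sample.
#' @return List with `high_confidence` (variant ids), `per_sample` (evidence
#'   rows + pass/fail), `report` (rejection counts per rule per sample), and
#'   `out` (path of the written VCF, if any).
#' @export
filter_cohort <- function(vcf = NULL, evidence, thresholds = filter_thresholds(),
                          out = NULL) {
  if (is.character(evidence)) evidence <- read_tsv(evidence)
  if (!nrow(evidence)) {
    if (!is.null(vcf) && !is.null(out)) {
      rec <- read_vcf(vcf)
      if (nrow(rec$records)) stop("VCF records without evidence rows: ",
                                  rec$records$ID[1])
      write_vcf(rec$records, out, header = rec$header)
    }
    return(list(high_confidence = character(0),
                per_sample = cbind(evidence, passed = logical(0)),
                report = data.frame(), out = out))
  }
  if (is.null(evidence$variant_id))
    evidence$variant_id <- paste(evidence$chrom, evidence$pos, evidence$ref,
                                 evidence$alt, sep = ":")
  res <- apply_filters(evidence, thresholds)
  evidence$passed <- res$passed
  eligible <- rep(TRUE, nrow(evidence))
  if (!is.null(evidence$callers)) {
    ncall <- vapply(strsplit(as.character(evidence$callers), ","),
                    function(x) length(unique(trimws(x))), integer(1))
    eligible <- ncall >= 2
  }
  pass_tab <- tapply(evidence$passed & eligible, evidence$variant_id, any)
  hc <- names(pass_tab)[pass_tab]

  # rejection report: per sample, per rule counts among failing rows
  long <- do.call(rbind, lapply(which(!res$passed), function(i) {
    data.frame(sample = evidence$sample[i], rule = res$failed_rules[[i]],
               stringsAsFactors = FALSE)
  }))
  report <- if (is.null(long)) data.frame() else
    as.data.frame(table(sample = long$sample, rule = long$rule),
                  responseName = "n")

  if (!is.null(vcf)) {
    rec <- read_vcf(vcf)
    missing_ev <- setdiff(rec$records$ID, evidence$variant_id)
    if (length(missing_ev))
      stop("VCF records without evidence rows: ",
           paste(utils::head(missing_ev, 5), collapse = ", "))
    if (!is.null(out)) {
      recs <- rec$records
      fr <- tapply(seq_len(nrow(evidence)), evidence$variant_id, function(ix) {
        rules <- sort(unique(unlist(res$failed_rules[ix])))
        if (!any(evidence$passed[ix])) paste(rules, collapse = ";") else "PASS"
      })
      recs$FILTER <- unname(fr[recs$ID])
      recs$FILTER[is.na(recs$FILTER) | recs$FILTER == ""] <- "PASS"
      write_vcf(recs, out, header = rec$header)
    }
  }
  # order high-confidence ids by first appearance in the evidence
  hc <- unique(evidence$variant_id)[unique(evidence$variant_id) %in% hc]
  list(high_confidence = hc, per_sample = evidence, report = report, out = out)
}
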