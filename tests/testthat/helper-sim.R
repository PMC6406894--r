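# Shared fixtures are generated in code at test time; these helpers keep the
# simulated cohorts desk-sized (feature counts scaled down; biological
# parameters such as depths, fractions and clade structure at their stated
# defaults).

small_config <- function(seed = 1L, ...) {
  args <- list(
    n_trunk = 120L, n_branch = 80L, n_private = 90L,
    n_cpgs = 1500L, n_genes = 800L, n_probes = 2500L,
    seed = seed
  )
  do.call(clone_sim_config, utils::modifyList(args, list(...)))
}

# A single evidence row that passes every filter rule with margin; boundary
# tests perturb one field at a time.
passing_evidence <- function(...) {
  base <- data.frame(
    chrom = "chr1", pos = 1000L, ref = "A", alt = "T", sample = "CloneA",
    control_depth = 30, tumour_depth = 60, alt_reads = 12,
    distinct_alt_starts = 12, min_dist_read_end = 10, fwd_alt = 6,
    rev_alt = 6, dist_to_homopolymer7 = 20, control_alt_fraction = 0,
    stringsAsFactors = FALSE
  )
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

# Independent brute-force re-application of the filter rules: scalar,
# condition-by-condition, deliberately not sharing code with apply_filters().
oracle_filter_row <- function(row, th = list(ctrl = 8, tum = 12, alt = 5,
                                             starts = 5, dend = 5, hp = 5,
                                             cfrac = 0.03)) {
  failed <- character(0)
  if (row$control_depth < th$ctrl) failed <- c(failed, "control_coverage")
  if (row$tumour_depth < th$tum) failed <- c(failed, "tumour_coverage")
  if (row$alt_reads < th$alt) failed <- c(failed, "alt_support")
  if (row$distinct_alt_starts < th$starts) failed <- c(failed, "distinct_starts")
  if (!(row$min_dist_read_end > th$dend)) failed <- c(failed, "read_end")
  if (!(row$fwd_alt >= 1 && row$rev_alt >= 1)) failed <- c(failed, "strand")
  if (!(row$dist_to_homopolymer7 > th$hp)) failed <- c(failed, "homopolymer")
  if (!(row$control_alt_fraction < th$cfrac))
    failed <- c(failed, "control_contamination")
  list(passed = length(failed) == 0, failed = failed)
}
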