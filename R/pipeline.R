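# End-to-end driver: simulate -> filter -> clonal / CN / methylation /
# expression / array stages from one JSON config, with per-stage logging and
# content-addressed stage caching (a stage re-runs only when its own
# parameters, or anything upstream of it, changed).

#' Write a simulated cohort to disk in standard formats
#'
#' Runs every simulator stage and writes: per-sample candidate VCFs plus a
#' merged cohort VCF, the evidence TSV, the pileup TSV, per-sample segment
#' TSVs (BED-like, 0-based half-open), an SV breakpoint TSV, CpG
#' methylated/total count TSVs with a probe blacklist, a gene count TSV, the
#' SNP-array LogR/BAF/genotype TSVs, and a ground-truth JSON + expected-VAF
#' TSV.
#'
#' @param config a [clone_sim_config()].
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects (`truth`, `reads`,
#'   `sv`, `methylation`, `expression`, `array`) and `files`.
#' @export
simulate_cohort <- function(config, outdir) {
  stopifnot(inherits(config, "clone_sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  truth <- simulate_phylogeny(config)
  reads <- simulate_reads(truth, config)
  sv <- simulate_sv(truth, config)
  meth <- simulate_methylation(config)
  expr <- simulate_expression(config)
  arr <- simulate_array(config)

  f <- list()
  f$evidence <- write_tsv(reads$evidence, file.path(outdir, "evidence.tsv"))
  f$pileup <- write_tsv(reads$pileup, file.path(outdir, "pileup.tsv"))
  f$vcfs <- write_candidate_vcfs(reads$evidence, config,
                                 file.path(outdir, "vcf"))
  segdir <- file.path(outdir, "segments")
  dir.create(segdir, showWarnings = FALSE)
  profiles <- simulate_cn(truth, config)
  f$segments <- vapply(names(profiles), function(s) {
    write_segments(profiles[[s]], file.path(segdir, paste0(s, ".segments.tsv")))
  }, character(1))
  f$sv <- write_tsv(sv$sv, file.path(outdir, "sv.tsv"))

  mwide <- function(m) data.frame(cpg_id = rownames(m), m, check.names = FALSE)
  f$methylated <- write_tsv(mwide(meth$methylated),
                            file.path(outdir, "methylated.tsv"))
  f$meth_total <- write_tsv(mwide(meth$total), file.path(outdir, "meth_total.tsv"))
  writeLines(meth$blacklist, file.path(outdir, "cpg_blacklist.txt"))
  f$blacklist <- file.path(outdir, "cpg_blacklist.txt")
  f$gene_counts <- write_tsv(
    data.frame(gene_id = rownames(expr$counts), expr$counts,
               check.names = FALSE),
    file.path(outdir, "gene_counts.tsv"))
  pwide <- function(m) data.frame(probe_id = rownames(m), m, check.names = FALSE)
  f$logr <- write_tsv(pwide(arr$logr), file.path(outdir, "array_logr.tsv"))
  f$baf <- write_tsv(pwide(arr$baf), file.path(outdir, "array_baf.tsv"))
  f$genotypes <- write_tsv(pwide(arr$genotypes),
                           file.path(outdir, "array_genotypes.tsv"))

  truth_json <- list(
    samples = truth$samples,
    categories = stats::setNames(truth$variants$category, truth$variants$id),
    wgd_status = as.list(truth$wgd_status),
    clades = as.list(truth$clades),
    sv_events = sv$events,
    artifacts = reads$artifacts,
    de_genes = expr$de_genes,
    seed = config$seed
  )
  f$truth <- file.path(outdir, "truth.json")
  jsonlite::write_json(truth_json, f$truth, auto_unbox = TRUE, digits = NA)
  f$expected_vaf <- write_tsv(
    data.frame(variant_id = rownames(truth$expected_vaf), truth$expected_vaf,
               check.names = FALSE),
    file.path(outdir, "truth_expected_vaf.tsv"))
  invisible(list(truth = truth, reads = reads, sv = sv, methylation = meth,
                 expression = expr, array = arr, files = f))
}

pipeline_log <- function(logfile, stage, msg) {
  line <- sprintf("[%s] %-10s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
}

stage_hash <- function(params) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

stage_cached <- function(outdir, stage, hash, outputs) {
  hfile <- file.path(outdir, ".hashes", paste0(stage, ".md5"))
  ok <- file.exists(hfile) && identical(readLines(hfile, warn = FALSE), hash) &&
    all(file.exists(outputs))
  ok
}

stage_done <- function(outdir, stage, hash) {
  dir.create(file.path(outdir, ".hashes"), showWarnings = FALSE, recursive = TRUE)
  writeLines(hash, file.path(outdir, ".hashes", paste0(stage, ".md5")))
}

#' Run the full simulate-then-analyse pipeline
#'
#' Executes the stages in dependency order -- simulate, somatic filter, VAF
#' matrix + SNV sharing + clustering, SV sharing, copy-number summaries,
#' methylation pipeline, expression pipeline, array stage -- and aggregates a
#' cohort report (sharing percentages, WGD flags, aberrant fractions,
#' concordance range, dendrogram files). Stage outputs are content-addressed
#' by a hash of the stage's parameters plus its upstream hash, so re-running
#' with a changed downstream parameter never re-runs upstream stages.
#'
#' @param config a config list, or the path of a JSON config file. Top-level
#'   fields: `outdir` (required), `seed`, `simulate` (arguments for
#'   [clone_sim_config()]), and optional per-stage blocks `filter`
#'   (thresholds), `vaf` (`min_depth`, `presence_vaf`, `min_alt_reads`), `sv`
#'   (`tolerance_bp`), `cn` (`wgd_threshold`), `methyl` (`min_reads`, `top`),
#'   `expr` (`fold`, `top`), `array` (`low`, `high`).
#' @return The cohort report (also written to `<outdir>/report.json`),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config$outdir)) stop("config$outdir is required")
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outdir, "run.log")
  seed <- config$seed %||% 1L

  sim_args <- as.list(config$simulate %||% list())
  sim_args$seed <- seed
  scfg <- do.call(clone_sim_config, sim_args)

  h_sim <- stage_hash(list(stage = "simulate", args = sim_args))
  sim_outputs <- file.path(outdir, c("evidence.tsv", "pileup.tsv", "sv.tsv",
                                     "truth.json", "gene_counts.tsv"))
  if (!stage_cached(outdir, "simulate", h_sim, sim_outputs)) {
    pipeline_log(logfile, "simulate", "generating synthetic cohort")
    simulate_cohort(scfg, outdir)
    stage_done(outdir, "simulate", h_sim)
  } else pipeline_log(logfile, "simulate", "cached; skipping")

  # --- somatic filter ---
  fargs <- as.list(config$filter %||% list())
  th <- do.call(filter_thresholds, fargs)
  h_filt <- stage_hash(list(stage = "filter", up = h_sim, args = fargs))
  filt_vcf <- file.path(outdir, "high_confidence.vcf")
  hc_file <- file.path(outdir, "high_confidence_ids.txt")
  if (!stage_cached(outdir, "filter", h_filt, c(filt_vcf, hc_file))) {
    pipeline_log(logfile, "filter", "applying high-confidence filters")
    fres <- filter_cohort(file.path(outdir, "vcf", "candidates.vcf"),
                          file.path(outdir, "evidence.tsv"), th, out = filt_vcf)
    writeLines(fres$high_confidence, hc_file)
    write_tsv(fres$report, file.path(outdir, "rejection_report.tsv"))
    stage_done(outdir, "filter", h_filt)
  } else pipeline_log(logfile, "filter", "cached; skipping")
  hc <- readLines(hc_file, warn = FALSE)

  # --- VAF matrix, SNV sharing, clustering ---
  vargs <- as.list(config$vaf %||% list())
  h_vaf <- stage_hash(list(stage = "vaf", up = h_filt, args = vargs))
  pileup <- read_tsv(file.path(outdir, "pileup.tsv"))
  pileup <- pileup[pileup$variant_id %in% hc, ]
  vm <- build_vaf_matrix(pileup, min_depth = vargs$min_depth %||% 8)
  sharing <- classify_sharing(vm, presence_vaf = vargs$presence_vaf %||% 0.05,
                              min_alt_reads = vargs$min_alt_reads %||% 3)
  vaf_tree <- file.path(outdir, "vaf_dendrogram.nwk")
  tum <- setdiff(vm$samples, "Blood")
  as_newick(cluster_samples(vm$vaf[, tum, drop = FALSE]), file = vaf_tree)
  write_tsv(data.frame(variant_id = vm$variants, vm$vaf, check.names = FALSE),
            file.path(outdir, "vaf_matrix.tsv"))
  stage_done(outdir, "vaf", h_vaf)
  pipeline_log(logfile, "vaf",
               sprintf("%d high-confidence variants; trunk %.2f%%",
                       sharing$total, sharing$percentages[["trunk"]]))

  # --- SV sharing ---
  svargs <- as.list(config$sv %||% list())
  svt <- read_tsv(file.path(outdir, "sv.tsv"))
  sv_sharing <- classify_sv_sharing(svt,
                                    tolerance_bp = svargs$tolerance_bp %||% 100,
                                    samples = sim_tumour_samples(scfg))
  pipeline_log(logfile, "sv", sprintf("%d SV events; trunk %.2f%%",
                                      sv_sharing$total,
                                      sv_sharing$percentages[["trunk"]]))

  # --- copy number ---
  cnargs <- as.list(config$cn %||% list())
  wgd_thr <- cnargs$wgd_threshold %||% 0.5
  segfiles <- list.files(file.path(outdir, "segments"), full.names = TRUE)
  cn_sum <- lapply(segfiles, function(p) {
    s <- sub("\\.segments\\.tsv$", "", basename(p))
    summarize_cn(read_segments(p, sample = s,
                               genome_length = genome_length(scfg)), wgd_thr)
  })
  names(cn_sum) <- vapply(cn_sum, `[[`, character(1), "sample")
  pipeline_log(logfile, "cn", sprintf("WGD in %d/%d samples",
                                      sum(vapply(cn_sum, `[[`, logical(1), "wgd")),
                                      length(cn_sum)))

  # --- methylation ---
  margs <- as.list(config$methyl %||% list())
  mm <- read_tsv(file.path(outdir, "methylated.tsv"))
  tt <- read_tsv(file.path(outdir, "meth_total.tsv"))
  meth_m <- as.matrix(mm[, -1]); rownames(meth_m) <- mm$cpg_id
  tot_m <- as.matrix(tt[, -1]); rownames(tot_m) <- tt$cpg_id
  bl <- readLines(file.path(outdir, "cpg_blacklist.txt"), warn = FALSE)
  beta <- compute_beta(meth_m, tot_m, min_reads = margs$min_reads %||% 10,
                       blacklist = bl)
  beta <- filter_and_impute(quantile_normalize(beta))
  beta_top <- select_top_variable(beta, k = margs$top %||% 1000,
                                  samples = scfg$clones)
  meth_tree <- file.path(outdir, "methylation_dendrogram.nwk")
  as_newick(cluster_samples(beta_top), file = meth_tree)
  pipeline_log(logfile, "methyl", sprintf("%d CpGs after filtering", nrow(beta)))

  # --- expression ---
  eargs <- as.list(config$expr %||% list())
  gc <- read_tsv(file.path(outdir, "gene_counts.tsv"))
  counts <- as.matrix(gc[, -1]); rownames(counts) <- gc$gene_id
  norm <- normalize_expression(counts)
  lfc <- log2_fold_change(norm$cpm, "Cortex")
  flagged <- flag_overexpressed(lfc, threshold_fold = eargs$fold %||% 2)
  vg <- select_variable_genes(log2(norm$cpm + 1), k = eargs$top %||% 500)
  expr_tree <- file.path(outdir, "expression_dendrogram.nwk")
  as_newick(cluster_samples(center_scale_log2(norm$cpm[vg, ]),
                            distance = "pearson"), file = expr_tree)
  pipeline_log(logfile, "expr", sprintf("%d variable genes selected", length(vg)))

  # --- array ---
  aargs <- as.list(config$array %||% list())
  lg <- read_tsv(file.path(outdir, "array_logr.tsv"))
  logr <- as.matrix(lg[, -1]); rownames(logr) <- lg$probe_id
  gt <- read_tsv(file.path(outdir, "array_genotypes.tsv"))
  gmat <- as.matrix(gt[, -1]); rownames(gmat) <- gt$probe_id
  conc <- genotype_concordance(gmat)
  probes <- select_variable_probes(logr, low = aargs$low %||% 0.3,
                                   high = aargs$high %||% 1.5)
  array_tree <- file.path(outdir, "array_dendrogram.nwk")
  as_newick(cluster_samples(logr[probes, , drop = FALSE]), file = array_tree)
  off <- conc[upper.tri(conc)]
  pipeline_log(logfile, "array", sprintf("concordance %.3f-%.3f",
                                         min(off, na.rm = TRUE),
                                         max(off, na.rm = TRUE)))

  report <- list(
    seed = seed,
    snv = list(total = sharing$total, counts = as.list(sharing$counts),
               percentages = as.list(round(sharing$percentages, 2))),
    sv = list(total = sv_sharing$total, counts = as.list(sv_sharing$counts),
              percentages = as.list(round(sv_sharing$percentages, 2))),
    copy_number = lapply(cn_sum, function(s)
      list(wgd = s$wgd, aberrant_fraction = s$aberrant_fraction,
           cnloh_fraction = s$cnloh_fraction)),
    concordance = list(min = min(off, na.rm = TRUE),
                       max = max(off, na.rm = TRUE)),
    n_variable_probes = length(probes),
    dendrograms = list(vaf = vaf_tree, methylation = meth_tree,
                       expression = expr_tree, array = array_tree)
  )
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log(logfile, "report", "written report.json")
  invisible(report)
}
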