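test_that("config validation rejects inconsistent cohorts", {
  expect_error(clone_sim_config(n_clones = 1), "n_clones")
  expect_error(clone_sim_config(n_trunk = -1), "counts")
  expect_error(clone_sim_config(artifact_rate = 1.2), "artifact_rate")
  expect_error(clone_sim_config(wgd_clones = "CloneZ"), "unknown clones")
  expect_error(clone_sim_config(branch_topology = list(c("CloneA", "CloneX"))),
               "unknown clones")
  expect_error(clone_sim_config(bulk_weights = c(1, 1, 1, 1, 1, 1)),
               "sum to 1")
  expect_error(clone_sim_config(cnloh_fraction = 1.1), "cnloh_fraction")
})

test_that("phylogeny assigns categories and expected VAFs per m/C", {
  cfg <- small_config()
  tr <- simulate_phylogeny(cfg)
  v <- tr$variants

  # categories partition the variant set with the configured counts
  expect_equal(unname(table(v$category)[c("trunk", "shared", "private")]),
               c(cfg$n_trunk, cfg$n_branch, cfg$n_private),
               ignore_attr = TRUE)

  # every trunk variant is carried by all clones and has VAF > 0 in every
  # tumour-derived sample; private variants sit in exactly one clone
  trunk <- v$category == "trunk"
  expect_true(all(lengths(v$carriers[trunk]) == cfg$n_clones))
  tum <- c("Tumour", cfg$clones)
  expect_true(all(tr$expected_vaf[trunk, tum] > 0))
  expect_true(all(lengths(v$carriers[v$category == "private"]) == 1))

  # matched normal: expected VAF exactly 0 for all somatic variants
  expect_true(all(tr$expected_vaf[, "Blood"] == 0))

  # m/C arithmetic: diploid het 1/2; pre-WGD variant on doubled (4,2) has
  # multiplicity 2 -> 1/2; on doubled (3,1) -> 2/3; post-WGD private variant
  # keeps multiplicity 1 -> 1/4 or 1/3
  nonwgd <- setdiff(cfg$clones, cfg$wgd_clones)[1]
  wgd <- cfg$wgd_clones[1]
  ev_non <- tr$expected_vaf[trunk, nonwgd]
  expect_true(all(ev_non %in% c(0.5, 1 / 3)))  # (2,1) or the small (3,1) gain
  ev_wgd <- tr$expected_vaf[trunk, wgd]
  expect_true(all(ev_wgd %in% c(0.5, 2 / 3)))
  priv_w <- v$category == "private" &
    vapply(v$carriers, function(x) identical(x, wgd), logical(1))
  expect_true(all(tr$expected_vaf[priv_w, wgd] %in% c(0.25, 1 / 3)))

  # bulk VAF is the mixture-weighted mean of clone VAFs
  expect_equal(tr$expected_vaf[, "Tumour"],
               as.numeric(tr$expected_vaf[, cfg$clones] %*% cfg$bulk_weights),
               ignore_attr = TRUE)
})

test_that("seeded simulation is deterministic and sub-streams are isolated", {
  cfg <- small_config(seed = 42)
  a <- simulate_phylogeny(cfg); b <- simulate_phylogeny(cfg)
  expect_identical(a$variants, b$variants)
  expect_identical(simulate_reads(a, cfg)$evidence,
                   simulate_reads(b, cfg)$evidence)
  expect_identical(simulate_methylation(cfg)$methylated,
                   simulate_methylation(cfg)$methylated)
  expect_identical(simulate_expression(cfg)$counts,
                   simulate_expression(cfg)$counts)

  # changing a late-stage knob leaves earlier streams untouched
  cfg2 <- small_config(seed = 42, n_genes = 900L)
  expect_identical(simulate_phylogeny(cfg2)$variants, a$variants)
  expect_identical(simulate_methylation(cfg2)$methylated,
                   simulate_methylation(cfg)$methylated)
})

test_that("read simulation matches binomial expectations at deep coverage", {
  cfg <- small_config(seed = 5, n_trunk = 150L, n_branch = 0L, n_private = 0L,
                      mean_depth_tumour = 1000, artifact_rate = 0)
  tr <- simulate_phylogeny(cfg)
  rd <- simulate_reads(tr, cfg)
  cl <- setdiff(cfg$clones, cfg$wgd_clones)[1]  # diploid clone: VAF 0.5
  ev <- rd$evidence[rd$evidence$sample == cl, ]
  ev <- ev[tr$expected_vaf[ev$variant_id, cl] == 0.5, ]
  vaf <- ev$alt_reads / ev$tumour_depth
  se <- sqrt(0.25 / mean(ev$tumour_depth)) / sqrt(nrow(ev))
  expect_lt(abs(mean(vaf) - 0.5), 3 * se)
})

test_that("artifacts violate exactly their labelled rule", {
  cfg <- small_config(seed = 9, artifact_rate = 0.3)
  tr <- simulate_phylogeny(cfg)
  rd <- simulate_reads(tr, cfg)
  expect_equal(nrow(rd$artifacts),
               round(0.3 / 0.7 * nrow(tr$variants)))
  ev <- merge(rd$evidence, rd$artifacts, by = "variant_id")
  res <- apply_filters(ev)
  expect_true(all(!res$passed))
  expect_true(all(lengths(res$failed_rules) == 1))
  expect_equal(unlist(res$failed_rules), ev$rule, ignore_attr = TRUE)
  # construction detail: homopolymer artifacts sit within 5 bp of the run
  expect_true(all(ev$dist_to_homopolymer7[ev$rule == "homopolymer"] <= 5))
})

test_that("copy-number truth matches the WGD / cnLOH construction", {
  cfg <- small_config(seed = 2)
  tr <- simulate_phylogeny(cfg)
  profs <- simulate_cn(tr, cfg)
  for (s in names(profs)) {
    fr <- state_fractions(profs[[s]])
    f34 <- sum(fr[names(fr) %in% c("3", "4")])
    if (s %in% cfg$wgd_clones) {
      expect_gt(f34, 0.8)
      seg <- profs[[s]]$segments
      expect_true(all(seg$minor_cn[seg$total_cn %in% 3:4 &
                                     seg$minor_cn > 0] >= 1))
    } else {
      expect_lte(f34, 0.05)
    }
    # fractions are a proper distribution over the assayed genome
    expect_equal(sum(fr), 1, tolerance = 1e-9)
  }
  # cnloh_fraction of the genome at (2,0) in non-WGD tumour samples
  loh <- call_cnloh(profs$Tumour)
  expect_equal(sum(loh$end - loh$start) / profs$Tumour$genome_length,
               cfg$cnloh_fraction, tolerance = 1e-6)
})

test_that("segment files round-trip unchanged and cohort files are readable", {
  cfg <- small_config(seed = 11, n_cpgs = 300L, n_genes = 200L,
                      n_probes = 400L)
  out <- withr::local_tempdir()
  res <- simulate_cohort(cfg, out)
  p <- res$files$segments[["CloneB"]]
  back <- read_segments(p, sample = "CloneB",
                        genome_length = genome_length(cfg))
  expect_equal(back$segments,
               res$truth$segments$CloneB[names(back$segments)],
               ignore_attr = TRUE)

  # pipeline closure: every written file is accepted by its reader
  expect_s3_class(build_vaf_matrix(res$files$pileup), "vaf_matrix")
  fr <- filter_cohort(file.path(out, "vcf", "candidates.vcf"),
                      res$files$evidence)
  expect_gt(length(fr$high_confidence), 0)
  expect_silent(classify_sv_sharing(res$files$sv,
                                    samples = c("Tumour", cfg$clones)))
  mm <- read.delim(res$files$methylated, check.names = FALSE)
  tt <- read.delim(res$files$meth_total, check.names = FALSE)
  expect_silent(compute_beta(as.matrix(mm[, -1]), as.matrix(tt[, -1])))
  expect_identical(nrow(mm), cfg$n_cpgs)
})

test_that("methylation counts follow the Beta-binomial construction", {
  cfg <- small_config(seed = 21, n_cpgs = 2000L)
  me <- simulate_methylation(cfg)
  # degenerate binomial: wherever true beta is ~1, methylated == total
  hi <- me$beta_truth[, "CloneA"] > 1 - 1e-12
  if (any(hi))
    expect_equal(me$methylated[hi, "CloneA"], me$total[hi, "CloneA"])
  # empirical beta of high-coverage CpGs tracks the truth
  ok <- me$total[, "CloneA"] >= 30
  emp <- me$methylated[ok, "CloneA"] / me$total[ok, "CloneA"]
  expect_gt(cor(emp, me$beta_truth[ok, "CloneA"]), 0.95)
  # forced low-coverage fraction materialises
  expect_gt(mean(me$total < 10), 0.03)
})

test_that("expression counts recover planted fold changes and library sizes", {
  cfg <- small_config(seed = 31, n_genes = 3000L, expr_dispersion = 0.05)
  ex <- simulate_expression(cfg)
  norm <- normalize_expression(ex$counts)
  lfc <- log2_fold_change(norm$cpm, ex$cortex)
  tum_genes <- ex$de_genes$gene[ex$de_genes$group == "tumour"]
  deep <- tum_genes[rowMeans(ex$counts[tum_genes, ]) > 200]
  est <- rowMeans(lfc[deep, , drop = FALSE])
  expect_lt(abs(median(est) - 2), 0.5)  # true fold 4 -> log2 = 2
})
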