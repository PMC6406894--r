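make_pileup <- function(vaf, depth = 60) {
  # vaf: variants x samples matrix -> long pileup at constant depth
  long <- expand.grid(vi = seq_len(nrow(vaf)), sample = colnames(vaf),
                      stringsAsFactors = FALSE)
  data.frame(variant_id = rownames(vaf)[long$vi], chrom = "chr1",
             pos = long$vi, sample = long$sample, depth = depth,
             alt_reads = round(vaf[cbind(long$vi, match(long$sample,
                                                        colnames(vaf)))] * depth),
             stringsAsFactors = FALSE)
}

test_that("build_vaf_matrix computes alt/depth with a missingness floor", {
  pu <- data.frame(variant_id = c("v1", "v1", "v2", "v2"),
                   sample = c("s1", "s2", "s1", "s2"),
                   depth = c(60, 50, 7, 0), alt_reads = c(30, 0, 3, 0))
  vm <- build_vaf_matrix(pu)
  expect_equal(vm$vaf["v1", "s1"], 0.5)
  expect_equal(vm$vaf["v1", "s2"], 0.0)
  expect_true(is.na(vm$vaf["v2", "s1"]))  # depth 7 < floor 8
  expect_true(is.na(vm$vaf["v2", "s2"]))
  expect_error(build_vaf_matrix(data.frame(variant_id = "v", sample = "s",
                                           depth = 10, alt_reads = 11)),
               "alt_reads exceeds depth")
})

test_that("VAF matrix on a simulated cohort equals element-wise alt/depth", {
  cfg <- small_config(seed = 3)
  tr <- simulate_phylogeny(cfg)
  rd <- simulate_reads(tr, cfg)
  vm <- build_vaf_matrix(rd$pileup, min_depth = 1)
  # brute-force recomputation, row by row
  for (i in sample.int(nrow(rd$pileup), 500)) {
    r <- rd$pileup[i, ]
    expected <- if (r$depth == 0) NA_real_ else r$alt_reads / r$depth
    expect_identical(vm$vaf[r$variant_id, r$sample], expected)
  }
})

test_that("classify_sharing handles canonical cases and column order", {
  vaf <- rbind(
    all05 = c(Tumour = 0.5, CloneA = 0.5, CloneB = 0.5),
    oneclone = c(Tumour = 0, CloneA = 0.4, CloneB = 0),
    two = c(Tumour = 0.3, CloneA = 0.3, CloneB = 0)
  )
  sh <- classify_sharing(vaf)
  expect_equal(sh$assignment$category, c("trunk", "private", "shared"))
  expect_equal(sum(sh$percentages), 100, tolerance = 0.01)

  # invariant to sample column order
  sh2 <- classify_sharing(vaf[, c(3, 1, 2)])
  expect_equal(sh2$assignment$category, sh$assignment$category)

  expect_error(classify_sharing(vaf[, 1, drop = FALSE]), "at least 2")
})

test_that("sharing recovery on clone samples matches simulator truth", {
  cfg <- small_config(seed = 19, mean_depth_tumour = 120)
  tr <- simulate_phylogeny(cfg)
  rd <- simulate_reads(tr, cfg)
  vm <- build_vaf_matrix(rd$pileup)
  sh <- classify_sharing(vm, tumour_samples = cfg$clones)
  truth <- tr$variants$category[match(sh$assignment$variant, tr$variants$id)]
  agree <- mean(sh$assignment$category == truth)
  expect_gt(agree, 0.97)  # binomial sampling misses a few low-evidence cells
})

test_that("SV sharing clusters jittered breakpoints into events", {
  # identical breakpoint in every sample -> one trunk event
  sv <- data.frame(chrom1 = "chr1", pos1 = 100 + c(0, 5, -5),
                   chrom2 = "chr1", pos2 = 5000 + c(0, -3, 8),
                   sv_type = "deletion", sample = c("s1", "s2", "s3"))
  sh <- classify_sv_sharing(sv, samples = c("s1", "s2", "s3"))
  expect_equal(sh$total, 1)
  expect_equal(unname(sh$counts["trunk"]), 1L)

  # same position, different type -> distinct events
  sv2 <- sv; sv2$sv_type <- c("deletion", "duplication", "deletion")
  sh2 <- classify_sv_sharing(sv2, samples = c("s1", "s2", "s3"))
  expect_equal(sh2$total, 2)

  # transitive closure: A~B and B~C chained even when A-C exceeds tolerance
  sv3 <- data.frame(chrom1 = "chr1", pos1 = c(100, 190, 280),
                    chrom2 = "chr1", pos2 = c(900, 910, 920),
                    sv_type = "inversion", sample = c("s1", "s2", "s3"))
  expect_equal(classify_sv_sharing(sv3, samples = c("s1", "s2", "s3"))$total, 1)

  expect_error(classify_sv_sharing(
    data.frame(chrom1 = "chr1", pos1 = 10, chrom2 = "chr1", pos2 = 5,
               sv_type = "deletion", sample = "s1"), samples = c("a", "b")),
    "pos1 > pos2")
})

test_that("simulated SV cohorts recover the true event count and categories", {
  cfg <- small_config(seed = 29)
  tr <- simulate_phylogeny(cfg)
  sv <- simulate_sv(tr, cfg)
  sh <- classify_sv_sharing(sv$sv, samples = c("Tumour", cfg$clones))
  expect_equal(sh$total, nrow(sv$events))
  expect_equal(unname(sh$counts["trunk"]),
               sum(sv$events$category == "trunk"))
  expect_equal(unname(sh$counts["private"]),
               sum(sv$events$category == "private"))
})

test_that("clustering reproduces a hand-traced complete-linkage agglomeration", {
  # samples as points: s1=(0,0), s2=(3,4), s3=(6,9)
  x <- cbind(s1 = c(0, 0), s2 = c(3, 4), s3 = c(6, 9))
  hc <- cluster_samples(x)
  # d(s1,s2)=5, d(s2,s3)=sqrt(34)~5.831, d(s1,s3)=sqrt(117)~10.817
  # complete linkage: merge {s1,s2} at 5, then {s1,s2}+{s3} at max = sqrt(117)
  expect_equal(hc$height, c(5, sqrt(117)))
  first <- hc$labels[-hc$merge[1, ]]
  expect_setequal(first, c("s1", "s2"))

  # duplicated column merges first at height 0
  x2 <- cbind(x, s2bis = c(3, 4))
  hc2 <- cluster_samples(x2)
  expect_equal(hc2$height[1], 0)
  expect_setequal(hc2$labels[-hc2$merge[1, ]], c("s2", "s2bis"))

  # deterministic under column permutation (lexicographic tie-break)
  hc3 <- cluster_samples(x[, c(2, 3, 1)])
  expect_identical(as_newick(hc3), as_newick(hc))

  expect_error(cluster_samples(x[, 1, drop = FALSE]), "at least 2")
  xna <- x; xna[, 2] <- NA
  expect_error(cluster_samples(xna), "no observed values")
})

test_that("two-clade cohorts are recovered by VAF clustering", {
  cfg <- small_config(seed = 37, n_branch = 200L, mean_depth_tumour = 60)
  tr <- simulate_phylogeny(cfg)
  rd <- simulate_reads(tr, cfg)
  vm <- build_vaf_matrix(rd$pileup)
  hc <- cluster_samples(vm$vaf[, cfg$clones])
  ari <- adjusted_rand_index(cutree(hc, 2), tr$clades[cfg$clones])
  expect_equal(ari, 1)
})

test_that("Newick export round-trips through ape with merge-height ultrametry", {
  x <- cbind(a = c(0, 0), b = c(1, 0), c = c(5, 0))
  hc <- cluster_samples(x)
  phy <- ape::read.tree(text = as_newick(hc))
  expect_setequal(phy$tip.label, c("a", "b", "c"))
  # cophenetic distance between the two deepest leaves = final merge height
  coph <- ape::cophenetic.phylo(phy)
  expect_equal(max(coph), max(hc$height), tolerance = 1e-9)
  expect_equal(coph["a", "b"], hc$height[1], tolerance = 1e-9)
})
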