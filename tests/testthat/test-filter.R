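test_that("single-rule violations are isolated and labelled", {
  # one field below threshold from an otherwise passing profile
  cases <- list(
    list(mod = list(control_depth = 7), rule = "control_coverage"),
    list(mod = list(tumour_depth = 11), rule = "tumour_coverage"),
    list(mod = list(alt_reads = 4, fwd_alt = 2, rev_alt = 2),
         rule = c("alt_support", "distinct_starts")),  # starts capped by alt
    list(mod = list(distinct_alt_starts = 4), rule = "distinct_starts"),
    list(mod = list(min_dist_read_end = 5), rule = "read_end"),
    list(mod = list(fwd_alt = 12, rev_alt = 0), rule = "strand"),
    list(mod = list(dist_to_homopolymer7 = 5), rule = "homopolymer"),
    list(mod = list(control_alt_fraction = 0.03), rule = "control_contamination")
  )
  for (cs in cases) {
    ev <- do.call(passing_evidence, cs$mod)
    if ("alt_reads" %in% names(cs$mod))
      ev$distinct_alt_starts <- ev$alt_reads  # keep evidence coherent
    res <- apply_filters(ev)
    expect_false(res$passed[1])
    expect_setequal(res$failed_rules[[1]], cs$rule)
  }
  ok <- apply_filters(passing_evidence())
  expect_true(ok$passed[1])
  expect_length(ok$failed_rules[[1]], 0)
})

test_that("boundary values follow the stated inequality directions", {
  at <- function(...) apply_filters(passing_evidence(...))$passed[1]
  expect_true(at(control_depth = 8));        expect_false(at(control_depth = 7))
  expect_true(at(tumour_depth = 12));        expect_false(at(tumour_depth = 11))
  expect_true(at(alt_reads = 5, distinct_alt_starts = 5, fwd_alt = 3,
                 rev_alt = 2))
  expect_false(at(alt_reads = 4, distinct_alt_starts = 5, fwd_alt = 2,
                  rev_alt = 2))
  expect_true(at(distinct_alt_starts = 5)); expect_false(at(distinct_alt_starts = 4))
  expect_true(at(min_dist_read_end = 6));    expect_false(at(min_dist_read_end = 5))
  expect_true(at(dist_to_homopolymer7 = 6)); expect_false(at(dist_to_homopolymer7 = 5))
  expect_true(at(control_alt_fraction = 0.029))
  expect_false(at(control_alt_fraction = 0.03))  # "<3%": 0.03 itself fails
  expect_true(at(fwd_alt = 1, rev_alt = 11));  expect_false(at(fwd_alt = 0, rev_alt = 12))
})

test_that("filter is monotone in evidence quality", {
  set.seed(71)
  good_up <- c("control_depth", "tumour_depth", "alt_reads",
               "distinct_alt_starts", "min_dist_read_end",
               "dist_to_homopolymer7")
  for (rep in 1:200) {
    ev <- passing_evidence(
      control_depth = sample(0:20, 1), tumour_depth = sample(0:30, 1),
      alt_reads = sample(0:10, 1), distinct_alt_starts = sample(0:10, 1),
      min_dist_read_end = sample(0:10, 1), fwd_alt = sample(0:3, 1),
      rev_alt = sample(0:3, 1), dist_to_homopolymer7 = sample(0:10, 1),
      control_alt_fraction = runif(1, 0, 0.06)
    )
    before <- apply_filters(ev)$passed[1]
    up <- ev
    f <- sample(good_up, 1)
    up[[f]] <- up[[f]] + sample(1:5, 1)
    expect_true(!before || apply_filters(up)$passed[1])
    worse <- ev
    worse$control_alt_fraction <- worse$control_alt_fraction + 0.05
    expect_true(before || !apply_filters(worse)$passed[1])
  }
})

test_that("apply_filters agrees with the brute-force oracle on simulated candidates", {
  cfg <- small_config(seed = 13, artifact_rate = 0.2)
  tr <- simulate_phylogeny(cfg)
  rd <- simulate_reads(tr, cfg)
  ev <- rd$evidence[sample.int(nrow(rd$evidence), 1000), ]
  res <- apply_filters(ev)
  for (i in seq_len(nrow(ev))) {
    o <- oracle_filter_row(ev[i, ])
    expect_identical(res$passed[i], o$passed)
    expect_setequal(res$failed_rules[[i]], o$failed)
  }
})

test_that("malformed evidence is rejected", {
  expect_error(apply_filters(passing_evidence(alt_reads = -1)), "negative")
  expect_error(apply_filters(passing_evidence(control_alt_fraction = 1.5)),
               "\\[0, 1\\]")
  expect_error(apply_filters(data.frame(chrom = "chr1")), "missing columns")
})

test_that("filter_cohort keeps variants passing in >= 1 sample and reports rejections", {
  cfg <- small_config(seed = 17, artifact_rate = 0.2)
  out <- withr::local_tempdir()
  res <- simulate_cohort(cfg, out)
  fc <- filter_cohort(file.path(out, "vcf", "candidates.vcf"),
                      res$files$evidence,
                      out = file.path(out, "filtered.vcf"))

  # oracle: brute-force per-row evaluation, then any() per variant
  ev <- res$reads$evidence
  pass <- vapply(seq_len(nrow(ev)), function(i) oracle_filter_row(ev[i, ])$passed,
                 logical(1))
  oracle_hc <- unique(ev$variant_id[pass])
  expect_setequal(fc$high_confidence, oracle_hc)

  # artifacts never survive; their labels appear in the rejection report
  expect_length(intersect(fc$high_confidence, res$reads$artifacts$variant_id), 0)
  expect_true(all(res$reads$artifacts$rule %in% unique(fc$report$rule)))

  # filtered VCF carries PASS / rule names in FILTER
  vv <- read_vcf(file.path(out, "filtered.vcf"))
  expect_setequal(vv$records$ID[vv$records$FILTER == "PASS"], oracle_hc)
})

test_that("filter_cohort edge cases: empty input, all-pass, missing evidence", {
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      sample = character(0), control_depth = numeric(0),
                      tumour_depth = numeric(0), alt_reads = numeric(0),
                      distinct_alt_starts = numeric(0),
                      min_dist_read_end = numeric(0), fwd_alt = numeric(0),
                      rev_alt = numeric(0), dist_to_homopolymer7 = numeric(0),
                      control_alt_fraction = numeric(0))
  res <- filter_cohort(NULL, empty)
  expect_length(res$high_confidence, 0)
  expect_equal(nrow(res$report), 0)

  ev <- do.call(rbind, lapply(1:5, function(i)
    passing_evidence(pos = 1000L + i, sample = "CloneA")))
  ev$variant_id <- paste0("v", 1:5)
  all_pass <- filter_cohort(NULL, ev)
  expect_length(all_pass$high_confidence, 5)

  tmp <- withr::local_tempfile(fileext = ".vcf")
  rec <- data.frame(CHROM = "chr1", POS = 99L, ID = "chr1:99:A:T", REF = "A",
                    ALT = "T")
  write_vcf(rec, tmp)
  expect_error(filter_cohort(tmp, ev), "chr1:99:A:T")
})

test_that("dual-caller eligibility requires two callers when present", {
  ev <- rbind(passing_evidence(pos = 1L), passing_evidence(pos = 2L))
  ev$variant_id <- c("v1", "v2")
  ev$callers <- c("qsnp", "qsnp,gatk")
  res <- filter_cohort(NULL, ev)
  expect_identical(res$high_confidence, "v2")
})

test_that("written VCFs are valid per the reference parser", {
  skip_if_not_installed("VariantAnnotation")
  cfg <- small_config(seed = 23, n_trunk = 20L, n_branch = 10L,
                      n_private = 10L)
  out <- withr::local_tempdir()
  res <- simulate_cohort(cfg, out)
  vcf <- suppressWarnings(
    VariantAnnotation::readVcf(file.path(out, "vcf", "CloneA.candidates.vcf")))
  own <- read_vcf(file.path(out, "vcf", "CloneA.candidates.vcf"))
  expect_equal(nrow(vcf), nrow(own$records))
  expect_equal(as.character(VariantAnnotation::ref(vcf)), own$records$REF)
  expect_setequal(colnames(vcf), own$samples)
})
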