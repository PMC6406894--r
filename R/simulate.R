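# Synthetic multi-clone cohort generator.
#
# The stated world: one patient-derived tumour deconstructed into K single-cell
# clones plus the bulk tumour and a matched normal. Somatic SNVs partition into
# trunk (all tumour cells), shared (a clade of clones) and private (one clone)
# categories; a subset of clones has undergone whole-genome duplication (WGD);
# part of the genome is copy-neutral LOH in every tumour sample. Reads are
# binomially sampled at the expected VAF, methylation is Beta/binomial, and
# expression is negative-binomial. All randomness flows from one root seed via
# per-stage sub-streams.

#' Configuration for the synthetic clonal cohort
#'
#' Defaults mirror the motivating cohort: six clones, 8696 somatic SNVs of
#' which 3490 are trunk and 3492 private, WGD in every clone but the first,
#' ~10% of the genome copy-neutral LOH, clone/control depth ~68x, and a
#' miniature genome of 22 autosomes x 10 Mb.
#'
#' @param n_clones number of single-cell clones (>= 2); clones are named
#'   `CloneA`, `CloneB`, ... The cohort adds a bulk `Tumour` and a matched
#'   normal `Blood` sample.
#' @param n_trunk,n_branch,n_private SNV counts per clonal category.
#' @param branch_topology list of clone-name subsets (clades) to which shared
#'   variants are assigned; default splits the clones into two clades. Subsets
#'   must reference known clones.
#' @param bulk_weights clone mixture weights of the bulk tumour, summing to 1;
#'   default uniform.
#' @param mean_depth_tumour,mean_depth_control expected sequencing depths
#'   (Poisson means) for tumour-derived and control reads.
#' @param wgd_clones character vector of clones that underwent WGD; default all
#'   but the first clone.
#' @param cnloh_fraction fraction of the genome affected by a trunk
#'   copy-neutral LOH event: (total 2, minor 0) in non-WGD tumour samples and
#'   (4, 0) in WGD clones (the doubling affects both alleles), which the WGD
#'   correction restores to (2, 0).
#' @param wgd_cn4_fraction within a WGD clone, the fraction of the doubled
#'   genome still at total copy number 4; the remainder has lost one copy
#'   (total 3). The whole genome outside the cnLOH region is doubled, so the
#'   CN 3-4 fraction is `1 - cnloh_fraction` (> 0.8, as in the motivating
#'   cohort).
#' @param gain_fraction fraction of genome at a (3,1) gain in non-WGD tumour
#'   samples (keeps them <= 5% at CN 3-4).
#' @param artifact_rate fraction of candidate variants that are injected
#'   artifacts, each violating exactly one labelled filter rule.
#' @param n_sv_trunk,n_sv_shared,n_sv_private structural-variant event counts
#'   per category (defaults 10/8/65, i.e. 83 events).
#' @param n_cpgs,n_genes,n_probes feature counts for the methylation,
#'   expression and SNP-array simulators.
#' @param methyl_mean_depth,methyl_lowcov_fraction,methyl_diff_fraction CpG
#'   read depth (Poisson mean), fraction of cells forced below 10 reads, and
#'   fraction of CpGs with clade-specific methylation.
#' @param expr_de_fraction,expr_fold,expr_dispersion,expr_libsize_range
#'   expression simulator knobs: fraction of genes differentially expressed
#'   versus cortex, their true fold change, NB dispersion, and the range of
#'   relative library sizes.
#' @param array_noise_sd,array_shift,array_diff_probes,genotype_error,genotype_missing
#'   SNP-array knobs: LogR noise, clade-specific LogR shift, number of shifted
#'   probes per clade, genotype miscall and missing rates.
#' @param n_chromosomes,chrom_length miniature genome model.
#' @param seed root integer seed; per-stage sub-streams are derived from it.
#' @return A validated `clone_sim_config` list.
#' @export
clone_sim_config <- function(n_clones = 6L,
                             n_trunk = 3490L, n_branch = 1714L, n_private = 3492L,
                             branch_topology = NULL,
                             bulk_weights = NULL,
                             mean_depth_tumour = 68, mean_depth_control = 68,
                             wgd_clones = NULL,
                             cnloh_fraction = 0.10,
                             wgd_cn4_fraction = 0.70,
                             gain_fraction = 0.02,
                             artifact_rate = 0.10,
                             n_sv_trunk = 10L, n_sv_shared = 8L, n_sv_private = 65L,
                             n_cpgs = 20000L, n_genes = 5000L, n_probes = 20000L,
                             methyl_mean_depth = 50, methyl_lowcov_fraction = 0.05,
                             methyl_diff_fraction = 0.10,
                             expr_de_fraction = 0.10, expr_fold = 4,
                             expr_dispersion = 0.1, expr_libsize_range = c(0.5, 2),
                             array_noise_sd = 0.15, array_shift = 0.5,
                             array_diff_probes = 2000L,
                             genotype_error = 0.005, genotype_missing = 0.01,
                             n_chromosomes = 22L, chrom_length = 1e7,
                             seed = 1L) {
  n_clones <- as.integer(n_clones)
  if (is.na(n_clones) || n_clones < 2) stop("n_clones must be >= 2")
  counts <- c(n_trunk = n_trunk, n_branch = n_branch, n_private = n_private,
              n_sv_trunk = n_sv_trunk, n_sv_shared = n_sv_shared,
              n_sv_private = n_sv_private)
  if (any(counts < 0)) stop("variant/SV counts must be >= 0")
  if (artifact_rate < 0 || artifact_rate >= 1) stop("artifact_rate must be in [0, 1)")
  clones <- paste0("Clone", LETTERS[seq_len(n_clones)])
  if (is.null(wgd_clones)) wgd_clones <- clones[-1]
  if (!all(wgd_clones %in% clones)) stop("wgd_clones references unknown clones")
  if (is.null(branch_topology)) {
    half <- max(1L, n_clones %/% 2L)
    branch_topology <- list(clones[seq_len(half)], clones[-seq_len(half)])
    branch_topology <- Filter(length, branch_topology)
  }
  bad <- vapply(branch_topology, function(s) !all(s %in% clones), logical(1))
  if (any(bad)) stop("branch_topology references unknown clones")
  if (is.null(bulk_weights)) bulk_weights <- rep(1 / n_clones, n_clones)
  if (length(bulk_weights) != n_clones || abs(sum(bulk_weights) - 1) > 1e-9)
    stop("bulk_weights must have one weight per clone and sum to 1")
  if (cnloh_fraction < 0 || cnloh_fraction >= 1)
    stop("cnloh_fraction must be in [0, 1): the cnLOH plus WGD-affected ",
         "regions cannot exceed the genome")
  if (wgd_cn4_fraction < 0 || wgd_cn4_fraction > 1)
    stop("wgd_cn4_fraction must be in [0, 1]")
  if (cnloh_fraction + gain_fraction > 1) stop("gain_fraction too large")
  cfg <- list(
    n_clones = n_clones, clones = clones,
    n_trunk = as.integer(n_trunk), n_branch = as.integer(n_branch),
    n_private = as.integer(n_private),
    branch_topology = branch_topology,
    bulk_weights = stats::setNames(bulk_weights, clones),
    mean_depth_tumour = mean_depth_tumour, mean_depth_control = mean_depth_control,
    wgd_clones = wgd_clones, cnloh_fraction = cnloh_fraction,
    wgd_cn4_fraction = wgd_cn4_fraction, gain_fraction = gain_fraction,
    artifact_rate = artifact_rate,
    n_sv_trunk = as.integer(n_sv_trunk), n_sv_shared = as.integer(n_sv_shared),
    n_sv_private = as.integer(n_sv_private),
    n_cpgs = as.integer(n_cpgs), n_genes = as.integer(n_genes),
    n_probes = as.integer(n_probes),
    methyl_mean_depth = methyl_mean_depth,
    methyl_lowcov_fraction = methyl_lowcov_fraction,
    methyl_diff_fraction = methyl_diff_fraction,
    expr_de_fraction = expr_de_fraction, expr_fold = expr_fold,
    expr_dispersion = expr_dispersion, expr_libsize_range = expr_libsize_range,
    array_noise_sd = array_noise_sd, array_shift = array_shift,
    array_diff_probes = as.integer(array_diff_probes),
    genotype_error = genotype_error, genotype_missing = genotype_missing,
    n_chromosomes = as.integer(n_chromosomes), chrom_length = chrom_length,
    seed = as.integer(seed)
  )
  structure(cfg, class = "clone_sim_config")
}

# sample-name helpers -------------------------------------------------------
sim_samples <- function(config) c("Blood", "Tumour", config$clones)
sim_tumour_samples <- function(config) c("Tumour", config$clones)
genome_length <- function(config) config$n_chromosomes * config$chrom_length

# clade (two-group) assignment of clones used by the methylation, expression
# and array simulators; the first topology subset is clade "A"
sim_clades <- function(config) {
  cladeA <- config$branch_topology[[1]]
  stats::setNames(ifelse(config$clones %in% cladeA, "A", "B"), config$clones)
}

linear_to_genome <- function(x, config) {
  # x: 0-based linear coordinate on the concatenated miniature genome
  idx <- x %/% config$chrom_length
  list(chrom = paste0("chr", idx + 1L),
       pos = as.integer(x %% config$chrom_length + 1))  # 1-based
}

# Per-sample copy-number state as a function of linear position.
# Layout (linear): [0, loh) cnLOH | [loh, loh+...) WGD / gain block | rest (2,1).
sample_segment_table <- function(sample, config) {
  G <- genome_length(config)
  loh <- round(config$cnloh_fraction * G)
  role <- if (sample == "Blood") "normal"
          else if (sample %in% config$wgd_clones) "wgd" else "tumour"
  if (role == "normal") {
    brk <- c(0, G); states <- cbind(total = 2, minor = 1, doubled = 0)
  } else if (role == "wgd") {
    w4 <- round(config$wgd_cn4_fraction * (G - loh))
    brk <- c(0, loh, loh + w4, G)
    states <- cbind(total = c(4, 4, 3), minor = c(0, 2, 1),
                    doubled = c(1, 1, 1))
  } else {
    g <- round(config$gain_fraction * G)
    brk <- c(0, loh, loh + g, G)
    states <- cbind(total = c(2, 3, 2), minor = c(0, 1, 1), doubled = c(0, 0, 0))
  }
  # split region boundaries at chromosome bounds so every segment sits on one
  # chromosome; carry the state of the enclosing region
  chrom_bounds <- seq(0, G, by = config$chrom_length)
  cuts <- sort(unique(c(brk, chrom_bounds)))
  cuts <- cuts[cuts >= 0 & cuts <= G]
  start <- cuts[-length(cuts)]; end <- cuts[-1]
  region <- findInterval(start, brk, rightmost.closed = TRUE)
  loc <- linear_to_genome(start, config)
  data.frame(
    chrom = loc$chrom,
    start = as.integer(start %% config$chrom_length),      # 0-based
    end = as.integer((end - 1) %% config$chrom_length + 1),  # half-open
    total_cn = states[region, "total"],
    minor_cn = states[region, "minor"],
    doubled = as.logical(states[region, "doubled"]),
    stringsAsFactors = FALSE
  )
}

# state at linear positions x for one sample: list(total, doubled)
state_at <- function(x, sample, config) {
  G <- genome_length(config)
  loh <- round(config$cnloh_fraction * G)
  if (sample == "Blood") return(list(total = rep(2, length(x)), doubled = rep(FALSE, length(x))))
  if (sample %in% config$wgd_clones) {
    w4 <- round(config$wgd_cn4_fraction * (G - loh))
    total <- ifelse(x < loh + w4, 4, 3)
    doubled <- rep(TRUE, length(x))
  } else {
    g <- round(config$gain_fraction * G)
    total <- ifelse(x < loh, 2, ifelse(x < loh + g, 3, 2))
    doubled <- rep(FALSE, length(x))
  }
  list(total = total, doubled = doubled)
}

#' Simulate the clonal phylogeny and its ground truth
#'
#' Assigns every somatic SNV to a clonal category (trunk: all clones and the
#' bulk; shared: one clade; private: exactly one clone), places variants on the
#' miniature genome outside the cnLOH region, derives per-sample copy-number
#' segments, and computes the expected VAF of each variant in each sample as
#' `m / C` -- mutation multiplicity over total copy number. Trunk and shared
#' variants predate WGD, so their multiplicity is doubled on doubled segments
#' (expected VAF stays 0.5 on a (4,2) segment); private variants arise after
#' WGD (multiplicity 1, VAF 0.25 on total 4). Bulk VAFs are mixture-weighted
#' means of the clone VAFs; the matched normal has expected VAF 0 everywhere.
#'
#' @param config a [clone_sim_config()].
#' @return A `clone_truth` list: `variants` (id, chrom, pos, ref, alt,
#'   category, carriers), `expected_vaf` (variants x samples), `wgd_status`,
#'   `segments` (per-sample data frames, 0-based half-open, with true
#'   total/minor copy number), `clades`, `samples`, `genome_length`.
#' @export
simulate_phylogeny <- function(config) {
  stopifnot(inherits(config, "clone_sim_config"))
  set.seed(substream_seed(config$seed, "phylogeny"))
  G <- genome_length(config)
  loh <- round(config$cnloh_fraction * G)
  n_total <- config$n_trunk + config$n_branch + config$n_private
  if (n_total < 1) stop("at least one variant is required")

  # positions outside the cnLOH block so every carried variant has VAF > 0
  lin <- loh + sample.int(G - loh, n_total) - 1
  loc <- linear_to_genome(lin, config)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_total, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))

  category <- rep(c("trunk", "shared", "private"),
                  times = c(config$n_trunk, config$n_branch, config$n_private))
  topo <- config$branch_topology
  carriers <- vector("list", n_total)
  ci_shared <- rep(seq_along(topo), length.out = config$n_branch)
  ci_private <- rep(seq_len(config$n_clones), length.out = config$n_private)
  k <- s <- p <- 0L
  for (i in seq_len(n_total)) {
    carriers[[i]] <- switch(category[i],
      trunk = config$clones,
      shared = { s <- s + 1L; topo[[ci_shared[s]]] },
      private = { p <- p + 1L; config$clones[ci_private[p]] })
  }
  variants <- data.frame(
    id = paste(loc$chrom, loc$pos, ref, alt, sep = ":"),
    chrom = loc$chrom, pos = loc$pos, ref = ref, alt = alt,
    category = category, stringsAsFactors = FALSE
  )
  variants$carriers <- I(carriers)

  samples <- sim_samples(config)
  evaf <- matrix(0, n_total, length(samples), dimnames = list(variants$id, samples))
  pre_wgd <- category %in% c("trunk", "shared")
  for (cl in config$clones) {
    st <- state_at(lin, cl, config)
    m <- ifelse(pre_wgd & st$doubled, 2, 1)
    carried <- vapply(carriers, function(cc) cl %in% cc, logical(1))
    evaf[, cl] <- ifelse(carried, m / st$total, 0)
  }
  evaf[, "Tumour"] <- as.numeric(evaf[, config$clones, drop = FALSE] %*%
                                   config$bulk_weights)
  segs <- lapply(stats::setNames(nm = samples), sample_segment_table,
                 config = config)
  wgd <- stats::setNames(samples %in% config$wgd_clones, samples)
  # aberrant fraction each sample would show absent the WGD event: the trunk
  # cnLOH region, plus the small gain carried by non-WGD tumour samples
  pre_ab <- stats::setNames(ifelse(
    samples == "Blood", 0,
    ifelse(wgd, config$cnloh_fraction,
           config$cnloh_fraction + config$gain_fraction)), samples)
  structure(list(
    config = config, samples = samples, variants = variants,
    expected_vaf = evaf, wgd_status = wgd, segments = segs,
    pre_wgd_aberrant = pre_ab,
    clades = sim_clades(config), genome_length = G
  ), class = "clone_truth")
}

# Filter rules that an artifact can violate in isolation. alt_support cannot
# be violated alone (distinct_alt_starts <= alt_reads drags distinct_starts
# down with it), so it is exercised by boundary tests instead.
artifact_rules <- c("control_coverage", "tumour_coverage", "distinct_starts",
                    "read_end", "strand", "homopolymer", "control_contamination")

#' Simulate read evidence for candidate variants
#'
#' Draws per-(variant, sample) depths from a Poisson at the configured means
#' and alt counts binomially at the expected VAF, derives the read-level
#' evidence features consumed by the high-confidence filter, and injects
#' labelled artifact candidates that each violate exactly one filter rule
#' while passing all others by construction.
#'
#' @param truth a `clone_truth` from [simulate_phylogeny()].
#' @param config the same [clone_sim_config()].
#' @return List with `evidence` (one row per candidate variant per tumour
#'   sample; schema: chrom, pos, ref, alt, sample, control_depth,
#'   tumour_depth, alt_reads, distinct_alt_starts, min_dist_read_end, fwd_alt,
#'   rev_alt, dist_to_homopolymer7, control_alt_fraction, plus variant_id),
#'   `pileup` (variant_id, chrom, pos, sample, depth, alt_reads over all
#'   samples including the normal), and `artifacts` (variant_id, rule).
#' @export
simulate_reads <- function(truth, config) {
  stopifnot(inherits(truth, "clone_truth"))
  set.seed(substream_seed(config$seed, "reads"))
  tsamples <- sim_tumour_samples(config)
  v <- truth$variants
  n <- nrow(v)

  grid <- expand.grid(vi = seq_len(n), sample = tsamples,
                      stringsAsFactors = FALSE)
  depth <- rpois(nrow(grid), config$mean_depth_tumour)
  evaf <- truth$expected_vaf[cbind(grid$vi, match(grid$sample, truth$samples))]
  altc <- rbinom(nrow(grid), depth, evaf)
  fwd <- rbinom(nrow(grid), altc, 0.5)
  evidence <- data.frame(
    chrom = v$chrom[grid$vi], pos = v$pos[grid$vi],
    ref = v$ref[grid$vi], alt = v$alt[grid$vi],
    sample = grid$sample,
    control_depth = rpois(nrow(grid), config$mean_depth_control),
    tumour_depth = depth, alt_reads = altc,
    distinct_alt_starts = altc,
    min_dist_read_end = ifelse(altc > 0, sample(6:70, nrow(grid), TRUE), 0L),
    fwd_alt = fwd, rev_alt = altc - fwd,
    dist_to_homopolymer7 = sample(6:500, nrow(grid), TRUE),
    control_alt_fraction = 0,
    variant_id = v$id[grid$vi],
    stringsAsFactors = FALSE
  )

  # artifacts: artifact_rate of *candidates* are artifacts
  n_art <- round(config$artifact_rate / (1 - config$artifact_rate) * n)
  artifacts <- data.frame(variant_id = character(0), rule = character(0))
  if (n_art > 0) {
    G <- genome_length(config)
    lohG <- round(config$cnloh_fraction * G)
    lin <- lohG + sample.int(G - lohG, n_art) - 1
    loc <- linear_to_genome(lin, config)
    bases <- c("A", "C", "G", "T")
    aref <- sample(bases, n_art, replace = TRUE)
    aalt <- vapply(aref, function(r) sample(setdiff(bases, r), 1), character(1))
    rule <- rep(artifact_rules, length.out = n_art)
    aid <- paste(loc$chrom, loc$pos, aref, aalt, sep = ":")
    artifacts <- data.frame(variant_id = aid, rule = rule,
                            stringsAsFactors = FALSE)
    agrid <- expand.grid(ai = seq_len(n_art), sample = tsamples,
                         stringsAsFactors = FALSE)
    m <- nrow(agrid)
    # start from evidence guaranteed to pass every rule ...
    td <- pmax(rpois(m, config$mean_depth_tumour), 12L)
    ac <- pmin(pmax(rbinom(m, td, 0.4), 5L), td)
    ev <- data.frame(
      chrom = loc$chrom[agrid$ai], pos = loc$pos[agrid$ai],
      ref = aref[agrid$ai], alt = aalt[agrid$ai], sample = agrid$sample,
      control_depth = pmax(rpois(m, config$mean_depth_control), 8L),
      tumour_depth = td, alt_reads = ac, distinct_alt_starts = ac,
      min_dist_read_end = sample(6:70, m, TRUE),
      fwd_alt = pmin(ceiling(ac / 2), ac - 1L), rev_alt = 0L,
      dist_to_homopolymer7 = sample(6:500, m, TRUE),
      control_alt_fraction = 0,
      variant_id = aid[agrid$ai], stringsAsFactors = FALSE
    )
    ev$rev_alt <- ev$alt_reads - ev$fwd_alt
    # ... then break exactly the labelled rule
    r <- rule[agrid$ai]
    i <- r == "control_coverage"; ev$control_depth[i] <- sample(0:7, sum(i), TRUE)
    i <- r == "tumour_coverage"
    ev$tumour_depth[i] <- 11L; ev$alt_reads[i] <- 5L
    ev$distinct_alt_starts[i] <- 5L; ev$fwd_alt[i] <- 3L; ev$rev_alt[i] <- 2L
    i <- r == "distinct_starts"; ev$distinct_alt_starts[i] <- sample(0:4, sum(i), TRUE)
    i <- r == "read_end"; ev$min_dist_read_end[i] <- sample(0:5, sum(i), TRUE)
    i <- r == "strand"; ev$fwd_alt[i] <- ev$alt_reads[i]; ev$rev_alt[i] <- 0L
    i <- r == "homopolymer"; ev$dist_to_homopolymer7[i] <- sample(0:5, sum(i), TRUE)
    i <- r == "control_contamination"
    ev$control_alt_fraction[i] <- runif(sum(i), 0.031, 0.25)
    evidence <- rbind(evidence, ev)
  }

  # pileup over ALL samples (incl. matched normal) for the true variants
  pgrid <- expand.grid(vi = seq_len(n), sample = truth$samples,
                       stringsAsFactors = FALSE)
  pmean <- ifelse(pgrid$sample == "Blood", config$mean_depth_control,
                  config$mean_depth_tumour)
  pdepth <- rpois(nrow(pgrid), pmean)
  pvaf <- truth$expected_vaf[cbind(pgrid$vi, match(pgrid$sample, truth$samples))]
  pileup <- data.frame(
    variant_id = v$id[pgrid$vi], chrom = v$chrom[pgrid$vi],
    pos = v$pos[pgrid$vi], sample = pgrid$sample,
    depth = pdepth, alt_reads = rbinom(nrow(pgrid), pdepth, pvaf),
    stringsAsFactors = FALSE
  )
  list(evidence = evidence, pileup = pileup, artifacts = artifacts)
}

#' Simulate per-sample copy-number profiles
#'
#' Materialises the truth segment tables as [cn_profile] objects: WGD clones
#' carry > 80% of the genome at total copy number 3-4 with minor >= 1, non-WGD
#' samples stay <= 5% at CN 3-4, and `cnloh_fraction` of every tumour sample's
#' genome sits at (total 2, minor 0).
#'
#' @inheritParams simulate_reads
#' @return Named list of [cn_profile] objects, one per sample.
#' @export
simulate_cn <- function(truth, config) {
  stopifnot(inherits(truth, "clone_truth"))
  lapply(stats::setNames(nm = truth$samples), function(s) {
    seg <- truth$segments[[s]]
    cn_profile(s, seg[c("chrom", "start", "end", "total_cn", "minor_cn")],
               genome_length = truth$genome_length)
  })
}

#' Simulate structural-variant breakpoint tables
#'
#' Generates SV events (trunk / clade-shared / private) and emits one record
#' per carrier sample with breakend positions jittered by less than the
#' default matching tolerance.
#'
#' @inheritParams simulate_reads
#' @param jitter_bp maximum per-sample breakend jitter (default 20).
#' @return List with `sv` (chrom1, pos1, chrom2, pos2, sv_type, sample,
#'   event_id) and `events` (event_id, category).
#' @export
simulate_sv <- function(truth, config, jitter_bp = 20) {
  set.seed(substream_seed(config$seed, "cn"))
  n_ev <- config$n_sv_trunk + config$n_sv_shared + config$n_sv_private
  if (n_ev == 0) {
    return(list(sv = data.frame(), events = data.frame()))
  }
  types <- c("deletion", "duplication", "inversion", "translocation")
  category <- rep(c("trunk", "shared", "private"),
                  times = c(config$n_sv_trunk, config$n_sv_shared,
                            config$n_sv_private))
  sv_type <- sample(types, n_ev, replace = TRUE)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  chrom1 <- sample(chroms, n_ev, replace = TRUE)
  chrom2 <- ifelse(sv_type == "translocation",
                   sample(chroms, n_ev, replace = TRUE), chrom1)
  pos1 <- sample.int(config$chrom_length - 2e4, n_ev) + 1e4
  pos2 <- ifelse(sv_type == "translocation",
                 sample.int(config$chrom_length - 2e4, n_ev) + 1e4,
                 pos1 + sample(5e3:5e5, n_ev, TRUE))
  topo <- config$branch_topology
  carriers <- vector("list", n_ev)
  si <- rep(seq_along(topo), length.out = config$n_sv_shared)
  pi_ <- rep(seq_len(config$n_clones), length.out = config$n_sv_private)
  s <- p <- 0L
  for (i in seq_len(n_ev)) {
    carriers[[i]] <- switch(category[i],
      trunk = sim_tumour_samples(config),
      shared = { s <- s + 1L; topo[[si[s]]] },
      private = { p <- p + 1L; config$clones[pi_[p]] })
  }
  events <- data.frame(event_id = sprintf("sv%03d", seq_len(n_ev)),
                       category = category, stringsAsFactors = FALSE)
  recs <- lapply(seq_len(n_ev), function(i) {
    cs <- carriers[[i]]
    j1 <- sample(-jitter_bp:jitter_bp, length(cs), TRUE)
    j2 <- sample(-jitter_bp:jitter_bp, length(cs), TRUE)
    data.frame(chrom1 = chrom1[i], pos1 = pos1[i] + j1,
               chrom2 = chrom2[i], pos2 = pos2[i] + j2,
               sv_type = sv_type[i], sample = cs,
               event_id = events$event_id[i], stringsAsFactors = FALSE)
  })
  sv <- do.call(rbind, recs)
  intra <- sv$chrom1 == sv$chrom2 & sv$pos1 > sv$pos2
  sv[intra, c("pos1", "pos2")] <- sv[intra, c("pos2", "pos1")]
  list(sv = sv, events = events)
}

#' Simulate a CpG methylated/unmethylated count matrix
#'
#' Per-CpG true beta drawn from a bimodal Beta mixture (hypo/hyper peaks);
#' a configurable CpG fraction carries clade-specific methylation; totals are
#' Poisson with a configurable fraction of cells forced below 10 reads to
#' exercise the coverage filter; methylated counts are binomial at the true
#' beta.
#'
#' @param config a [clone_sim_config()].
#' @return List with `methylated` and `total` (CpGs x samples integer
#'   matrices over `Tumour` + clones), `cpgs` (cpg_id, chrom, pos),
#'   `beta_truth` (CpGs x samples), `blacklist` (CpG ids flagged
#'   poor-accuracy), and `clades`.
#' @export
simulate_methylation <- function(config) {
  stopifnot(inherits(config, "clone_sim_config"))
  if (config$n_cpgs <= 0) stop("n_cpgs must be > 0")
  set.seed(substream_seed(config$seed, "methylation"))
  nc <- config$n_cpgs
  samples <- c("Tumour", config$clones)
  clade <- c(Tumour = "A", sim_clades(config))[samples]

  rbimodal <- function(n) {
    lo <- rbeta(n, 0.6, 6); hi <- rbeta(n, 6, 0.6)
    ifelse(runif(n) < 0.5, lo, hi)
  }
  base <- rbimodal(nc)
  beta <- matrix(base, nc, length(samples), dimnames = list(NULL, samples))
  n_diff <- round(config$methyl_diff_fraction * nc)
  if (n_diff > 0) {
    altb <- rbimodal(n_diff)
    beta[seq_len(n_diff), clade == "B"] <- altb
  }
  total <- matrix(rpois(nc * length(samples), config$methyl_mean_depth),
                  nc, length(samples), dimnames = list(NULL, samples))
  n_low <- round(config$methyl_lowcov_fraction * length(total))
  if (n_low > 0) {
    low_cells <- sample.int(length(total), n_low)
    total[low_cells] <- sample(0:9, n_low, TRUE)
  }
  meth <- matrix(rbinom(length(total), total, beta), nc, length(samples),
                 dimnames = list(NULL, samples))
  ids <- sprintf("cpg%06d", seq_len(nc))
  rownames(meth) <- rownames(total) <- rownames(beta) <- ids
  lin <- sort(sample.int(genome_length(config), nc))
  loc <- linear_to_genome(lin - 1, config)
  blacklist <- sample(ids, max(1, round(0.01 * nc)))
  list(methylated = meth, total = total,
       cpgs = data.frame(cpg_id = ids, chrom = loc$chrom, pos = loc$pos,
                         stringsAsFactors = FALSE),
       beta_truth = beta, blacklist = blacklist,
       clades = clade[samples != "Tumour"])
}

#' Simulate a gene-expression count matrix with a normal-cortex column
#'
#' Negative-binomial counts over `Cortex` + `Tumour` + clones. A configurable
#' gene fraction is differentially expressed versus cortex at a true fold
#' change > 2 (half cohort-wide, the rest clade-specific to give the cohort a
#' two-group structure); library sizes vary across samples to exercise
#' normalisation.
#'
#' @param config a [clone_sim_config()].
#' @return List with `counts` (genes x samples), `cortex` (the designated
#'   normal column name), `de_genes` (gene, group, fold), `lib_factors`,
#'   `clades`.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "clone_sim_config"))
  if (config$n_genes <= 0) stop("n_genes must be > 0")
  set.seed(substream_seed(config$seed, "expression"))
  ng <- config$n_genes
  samples <- c("Cortex", "Tumour", config$clones)
  clade <- c(Cortex = "-", Tumour = "A", sim_clades(config))[samples]
  mu <- exp(rnorm(ng, log(100), 1.2))
  n_de <- round(config$expr_de_fraction * ng)
  grp <- rep("none", ng)
  if (n_de > 0) {
    n_all <- ceiling(n_de / 2); n_cl <- n_de - n_all
    grp[seq_len(n_all)] <- "tumour"
    if (n_cl > 0)
      grp[n_all + seq_len(n_cl)] <- rep(c("cladeA", "cladeB"), length.out = n_cl)
  }
  lib <- runif(length(samples), config$expr_libsize_range[1],
               config$expr_libsize_range[2])
  names(lib) <- samples
  fold <- matrix(1, ng, length(samples), dimnames = list(NULL, samples))
  tum <- samples != "Cortex"
  fold[grp == "tumour", tum] <- config$expr_fold
  fold[grp == "cladeA", clade == "A"] <- config$expr_fold
  fold[grp == "cladeB", clade == "B"] <- config$expr_fold
  counts <- matrix(0L, ng, length(samples), dimnames = list(
    sprintf("gene%05d", seq_len(ng)), samples))
  for (j in seq_along(samples)) {
    counts[, j] <- rnbinom(ng, mu = mu * fold[, j] * lib[j],
                           size = 1 / config$expr_dispersion)
  }
  de <- data.frame(gene = rownames(counts)[grp != "none"],
                   group = grp[grp != "none"], fold = config$expr_fold,
                   stringsAsFactors = FALSE)
  list(counts = counts, cortex = "Cortex", de_genes = de, lib_factors = lib,
       clades = clade[!(samples %in% c("Cortex", "Tumour"))])
}

#' Simulate SNP-array LogR / BAF / genotype matrices
#'
#' Germline genotypes are shared across all samples of the patient (with small
#' miscall and missing rates, keeping pairwise concordance high); LogR ratios
#' are Gaussian noise plus clade-specific shifts on a probe subset, giving the
#' clones a recoverable two-group copy-number structure.
#'
#' @param config a [clone_sim_config()].
#' @return List with `probes` (probe_id, chrom, pos), `logr`, `baf`,
#'   `genotypes` (probes x samples over Blood + Tumour + clones), `clades`.
#' @export
simulate_array <- function(config) {
  stopifnot(inherits(config, "clone_sim_config"))
  set.seed(substream_seed(config$seed, "array"))
  np <- config$n_probes
  samples <- c("Blood", "Tumour", config$clones)
  clade <- c(Blood = "-", Tumour = "-", sim_clades(config))[samples]
  gt_true <- sample(c("AA", "AB", "BB"), np, TRUE, prob = c(0.3, 0.4, 0.3))
  gt <- matrix(gt_true, np, length(samples), dimnames = list(NULL, samples))
  err <- matrix(runif(length(gt)) < config$genotype_error, np, length(samples))
  if (any(err)) {
    gt[err] <- vapply(gt[err], function(g) sample(setdiff(c("AA", "AB", "BB"), g), 1),
                      character(1))
  }
  gt[matrix(runif(length(gt)) < config$genotype_missing, np, length(samples))] <- NA
  logr <- matrix(rnorm(np * length(samples), 0, config$array_noise_sd),
                 np, length(samples), dimnames = list(NULL, samples))
  nd <- min(config$array_diff_probes, floor(np / 2))
  if (nd > 0) {
    ia <- seq_len(nd); ib <- nd + seq_len(nd)
    logr[ia, clade == "A"] <- logr[ia, clade == "A"] + config$array_shift
    logr[ib, clade == "B"] <- logr[ib, clade == "B"] - config$array_shift
  }
  baf_mean <- c(AA = 0.02, AB = 0.5, BB = 0.98)[gt_true]
  baf <- matrix(pmin(pmax(rnorm(np * length(samples), baf_mean, 0.03), 0), 1),
                np, length(samples), dimnames = list(NULL, samples))
  ids <- sprintf("probe%06d", seq_len(np))
  rownames(gt) <- rownames(logr) <- rownames(baf) <- ids
  lin <- sort(sample.int(genome_length(config), np))
  loc <- linear_to_genome(lin - 1, config)
  list(probes = data.frame(probe_id = ids, chrom = loc$chrom, pos = loc$pos,
                           stringsAsFactors = FALSE),
       logr = logr, baf = baf, genotypes = gt,
       clades = clade[!(samples %in% c("Blood", "Tumour"))])
}
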