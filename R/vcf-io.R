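# Minimal VCF v4.2 writer/reader for the somatic candidate files this package
# emits and re-consumes (fixed columns + DP:AD sample columns). A test
# round-trips a written file through VariantAnnotation::readVcf to validate
# the format against the reference parser.

vcf_filter_header <- function() {
  c('##FILTER=<ID=PASS,Description="All filters passed">',
    sprintf('##FILTER=<ID=%s,Description="Failed the %s rule">',
            filter_rule_names, filter_rule_names))
}

#' Write a simple somatic VCF v4.2
#'
#' @param records data frame with columns CHROM, POS, ID, REF, ALT and
#'   optionally QUAL, FILTER, INFO, plus any genotype columns listed in
#'   `sample_cols` (values already formatted, FORMAT DP:AD).
#' @param path output path.
#' @param sample_cols names of genotype columns in `records`.
#' @param contigs named vector of contig lengths for the header.
#' @param header optionally, a full header (character vector of `##` lines)
#'   to reuse verbatim.
#' @return The path, invisibly.
#' @export
write_vcf <- function(records, path, sample_cols = character(0),
                      contigs = NULL, header = NULL) {
  if (is.null(header)) {
    header <- c("##fileformat=VCFv4.2", "##source=clonehet",
                vcf_filter_header(),
                '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
                '##FORMAT=<ID=AD,Number=1,Type=Integer,Description="Alt-supporting reads">')
    if (!is.null(contigs))
      header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                  names(contigs), as.integer(contigs)))
  }
  if (!length(sample_cols))
    sample_cols <- setdiff(names(records),
                           c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                             "FILTER", "INFO", "FORMAT"))
  n <- nrow(records)
  qual <- records$QUAL %||% rep(".", n)
  filt <- records$FILTER %||% rep(".", n)
  info <- records$INFO %||% rep(".", n)
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  body <- data.frame(records$CHROM, records$POS, records$ID, records$REF,
                     records$ALT, qual, filt, info, stringsAsFactors = FALSE)
  if (length(sample_cols) && n > 0) {
    body$FORMAT <- records$FORMAT %||% rep("DP:AD", n)
    for (s in sample_cols) body[[s]] <- records[[s]]
    cols <- c(cols, "FORMAT", sample_cols)
  } else if (length(sample_cols)) {
    cols <- c(cols, "FORMAT", sample_cols)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(cols, collapse = "\t"), con)
  if (n > 0) {
    lines <- do.call(paste, c(unname(as.list(body)), sep = "\t"))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a VCF written by this package
#'
#' @param path VCF path.
#' @return List with `header` (the `##` lines), `samples` (genotype column
#'   names) and `records` (data frame of the body; POS integer).
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "##")]
  cline <- lines[startsWith(lines, "#CHROM")]
  if (!length(cline)) stop("not a VCF: no #CHROM header in ", path)
  cols <- strsplit(cline[1], "\t", fixed = TRUE)[[1]]
  cols[1] <- "CHROM"
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) {
    records <- as.data.frame(stats::setNames(
      replicate(length(cols), character(0), simplify = FALSE), cols))
    records$POS <- integer(0)
  } else {
    parts <- strsplit(body, "\t", fixed = TRUE)
    records <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
    names(records) <- cols
    records$POS <- as.integer(records$POS)
  }
  fixed <- c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
             "FORMAT")
  list(header = hdr, samples = setdiff(cols, fixed), records = records)
}

# Per-sample candidate VCFs (matched-normal + tumour genotype columns) and a
# merged cohort VCF, from a simulate_reads() evidence table.
write_candidate_vcfs <- function(evidence, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  contigs <- stats::setNames(rep(config$chrom_length, config$n_chromosomes),
                             paste0("chr", seq_len(config$n_chromosomes)))
  paths <- character(0)
  for (s in sim_tumour_samples(config)) {
    ev <- evidence[evidence$sample == s & (evidence$alt_reads > 0), ]
    ev <- ev[order(ev$chrom, ev$pos), ]
    rec <- data.frame(
      CHROM = ev$chrom, POS = ev$pos, ID = ev$variant_id, REF = ev$ref,
      ALT = ev$alt, QUAL = ".", FILTER = ".", INFO = ".", FORMAT = "DP:AD",
      stringsAsFactors = FALSE
    )
    rec$NORMAL <- sprintf("%d:%d", ev$control_depth,
                          round(ev$control_depth * ev$control_alt_fraction))
    rec[[s]] <- sprintf("%d:%d", ev$tumour_depth, ev$alt_reads)
    p <- file.path(dir, paste0(s, ".candidates.vcf"))
    write_vcf(rec, p, sample_cols = c("NORMAL", s), contigs = contigs)
    paths <- c(paths, p)
  }
  # merged cohort VCF: one record per candidate variant
  first <- evidence[!duplicated(evidence$variant_id), ]
  first <- first[order(first$chrom, first$pos), ]
  rec <- data.frame(CHROM = first$chrom, POS = first$pos, ID = first$variant_id,
                    REF = first$ref, ALT = first$alt, stringsAsFactors = FALSE)
  merged <- file.path(dir, "candidates.vcf")
  write_vcf(rec, merged, contigs = contigs)
  c(paths, merged)
}
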