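#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same objects,
#' used to score recovered sample groupings against simulated truth.
#'
#' @param x,y vectors of cluster labels of equal length (any comparable type).
#' @return Numeric scalar; 1 for identical partitions, ~0 for independent ones.
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  tab <- table(x, y)
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  idx <- sum(choose(tab, 2))
  expected <- a * b / n2
  max_idx <- (a + b) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (idx - expected) / (max_idx - expected)
}

# Derive a reproducible sub-stream seed for a named simulation stage so that
# adding one stage never perturbs the draws of another. Kept below 2^31.
substream_seed <- function(seed, stage) {
  stages <- c(
    phylogeny = 101L, reads = 211L, cn = 307L, methylation = 401L,
    expression = 503L, array = 601L, pipeline = 701L
  )
  off <- stages[[stage]]
  as.integer((as.numeric(seed) * 2654435.0 + off * 97561.0) %% 2147483629)
}

# round-half-up, used by the WGD ploidy correction (base round() is banker's)
round_half_up <- function(x) floor(x + 0.5)

read_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
}

write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
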