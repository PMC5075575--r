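#' Founder-of-origin matrices at marker positions
#'
#' Looks up, for every line and marker, which founder each homolog descends
#' from in the true simulated mosaic.
#'
#' @param mosaics List of mosaic genomes from [simulate_mosaics()].
#' @param map A [genetic_map()]; its chromosomes must match the mosaics.
#' @return List with integer matrices `h1`, `h2` (lines x markers).
#' @export
mosaic_founders <- function(mosaics, map) {
  chroms <- map_chroms(map)
  if (!all(chroms %in% names(mosaics[[1]]))) {
    stop("mosaic/map mismatch: mosaics lack chromosome(s) ",
         paste(setdiff(chroms, names(mosaics[[1]])), collapse = ", "))
  }
  n <- length(mosaics); m <- nrow(map)
  h1 <- matrix(0L, n, m, dimnames = list(names(mosaics), map$marker))
  h2 <- h1
  for (ch in chroms) {
    j <- which(map$chrom == ch)
    pos <- map$cM[j]
    for (i in seq_len(n)) {
      h1[i, j] <- founder_at(mosaics[[i]][[ch]]$h1, pos)
      h2[i, j] <- founder_at(mosaics[[i]][[ch]]$h2, pos)
    }
  }
  list(h1 = h1, h2 = h2)
}

#' Emit observed genotypes from true mosaics
#'
#' Translates founder mosaics into observed biallelic genotypes through the
#' founder haplotypes, with independent per-allele genotyping errors and
#' missing-at-random masking (default missing rate 2.19%, matching the
#' missingness level the pipeline is designed to tolerate).
#'
#' @param mosaics List of mosaic genomes.
#' @param founders A [founder_set()].
#' @param error_rate Per-allele flip probability (default 0).
#' @param missing_rate Per-genotype masking probability (default 0.0219).
#' @param seed Optional integer seed.
#' @return Integer matrix (lines x markers) coded 0/1/2 counts of the
#'   alternate allele, `NA` for missing, with the map as attribute `map`.
#' @export
emit_genotypes <- function(mosaics, founders, error_rate = 0,
                           missing_rate = 0.0219, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(error_rate >= 0, error_rate < 1,
            missing_rate >= 0, missing_rate < 1)
  map <- attr(founders, "map")
  fo <- mosaic_founders(mosaics, map)
  n <- nrow(fo$h1); m <- ncol(fo$h1)
  # allele of each homolog: founder haplotype value at (marker, founder)
  idx1 <- cbind(rep(seq_len(m), each = n), as.vector(fo$h1))
  idx2 <- cbind(rep(seq_len(m), each = n), as.vector(fo$h2))
  a1 <- matrix(unclass(founders)[idx1], n, m)
  a2 <- matrix(unclass(founders)[idx2], n, m)
  if (error_rate > 0) {
    a1 <- abs(a1 - (matrix(runif(n * m), n, m) < error_rate))
    a2 <- abs(a2 - (matrix(runif(n * m), n, m) < error_rate))
  }
  g <- a1 + a2
  if (missing_rate > 0) {
    g[matrix(runif(n * m), n, m) < missing_rate] <- NA_integer_
  }
  dimnames(g) <- list(names(mosaics), map$marker)
  structure(g, map = map)
}
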