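#' Construct a genetic map
#'
#' A genetic map is an ordered table of markers with chromosome labels and
#' centimorgan (cM) positions. Positions are chromosome-local and
#' non-decreasing within each chromosome; all downstream coordinates in the
#' package are cM (no physical positions are used).
#'
#' @param marker Character vector of unique marker identifiers.
#' @param chrom Character vector of chromosome labels, same length.
#' @param cM Numeric vector of map positions in centimorgans.
#' @return A `data.frame` of class `genetic_map` with columns
#'   `marker`, `chrom`, `cM`, ordered by chromosome (first appearance) then
#'   position.
#' @examples
#' genetic_map(c("m1", "m2", "m3"), c("1A", "1A", "2B"), c(0, 10, 0))
#' @export
genetic_map <- function(marker, chrom, cM) {
  if (length(marker) != length(chrom) || length(marker) != length(cM)) {
    stop("marker, chrom and cM must have the same length")
  }
  if (anyDuplicated(marker)) {
    stop("duplicated marker ids: ",
         paste(unique(marker[duplicated(marker)]), collapse = ", "))
  }
  chrom <- as.character(chrom)
  ord <- order(match(chrom, unique(chrom)), cM)
  map <- data.frame(marker = as.character(marker)[ord],
                    chrom = chrom[ord], cM = as.numeric(cM)[ord],
                    stringsAsFactors = FALSE)
  counts <- table(map$chrom)
  if (any(counts < 2)) {
    stop("each chromosome needs at least 2 markers; offending: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  if (any(map$cM < 0)) stop("cM positions must be non-negative")
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Build a regular synthetic map
#'
#' Convenience constructor for simulation studies: `n_mark` markers per
#' chromosome, evenly spaced from 0 to `length_cM`.
#'
#' @param chroms Character vector of chromosome names.
#' @param n_mark Markers per chromosome.
#' @param length_cM Chromosome length in cM.
#' @return A [genetic_map()].
#' @export
regular_map <- function(chroms = c("4D", "5A", "5B"), n_mark = 100,
                        length_cM = 100) {
  pos <- seq(0, length_cM, length.out = n_mark)
  genetic_map(
    marker = as.vector(vapply(chroms, function(ch)
      sprintf("%s_m%03d", ch, seq_len(n_mark)), character(n_mark))),
    chrom = rep(chroms, each = n_mark),
    cM = rep(pos, times = length(chroms))
  )
}

#' Chromosomes of a map, in map order
#' @param map A [genetic_map()].
#' @return Character vector.
#' @export
map_chroms <- function(map) unique(map$chrom)

#' Chromosome lengths of a map
#'
#' @param map A [genetic_map()].
#' @return Named numeric vector: the last marker position per chromosome.
#' @export
chrom_lengths <- function(map) {
  vapply(split(map$cM, factor(map$chrom, levels = map_chroms(map))), max,
         numeric(1))
}

#' The eight NIAB elite MAGIC founder varieties
#'
#' Founder order used throughout the package and in reported effect tables.
#' @return Character vector of length 8.
#' @export
magic_founder_names <- function() {
  c("Alchemy", "Brompton", "Claire", "Hereward",
    "Rialto", "Robigus", "Soissons", "Xi-19")
}

#' Construct a founder haplotype set
#'
#' @param haplotypes Numeric 0/1 matrix, markers in rows (rownames = marker
#'   ids), founders in columns (colnames = founder names).
#' @param map The [genetic_map()] the rows are aligned to.
#' @return Object of class `founder_set`: the haplotype matrix with the map
#'   attached as an attribute.
#' @export
founder_set <- function(haplotypes, map) {
  haplotypes <- as.matrix(haplotypes)
  if (ncol(haplotypes) < 2) stop("need at least 2 founders")
  if (nrow(haplotypes) != nrow(map)) {
    stop("haplotype rows (", nrow(haplotypes), ") do not match map markers (",
         nrow(map), ")")
  }
  if (!all(haplotypes %in% c(0, 1))) stop("haplotypes must be biallelic 0/1")
  if (is.null(colnames(haplotypes))) {
    colnames(haplotypes) <- paste0("F", seq_len(ncol(haplotypes)))
  }
  rownames(haplotypes) <- map$marker
  structure(haplotypes, map = map, class = "founder_set")
}

#' @export
print.founder_set <- function(x, ...) {
  cat("<founder_set> ", ncol(x), " founders x ", nrow(x), " markers\n",
      sep = "")
  cat("founders:", paste(colnames(x), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate founder haplotypes
#'
#' Draws biallelic founder haplotypes marker by marker so that the expected
#' proportion of markers distinguishing a random founder pair equals
#' `divergence`. For `divergence <= 0.5` each marker's alternate allele is
#' assigned to founders as independent Bernoulli(q) draws with q solving
#' 2q(1-q) = divergence; i.i.d. draws cap the pairwise difference at 0.5,
#' so larger values switch to allocating the alternate allele to a random
#' half of the founders (pairwise difference S/(2(S-1)): complementary
#' haplotypes for two founders, 4/7 for eight). Monomorphic draws are
#' redrawn, so every marker is polymorphic among the founders (mirroring an
#' array design that retains only scorable polymorphic SNPs).
#'
#' @param map A [genetic_map()].
#' @param n_founders Number of founders (default 8).
#' @param divergence Probability that a marker distinguishes a random founder
#'   pair; must be in (0, 1].
#' @param seed Integer RNG seed.
#' @param names Founder names; defaults to [magic_founder_names()] when
#'   `n_founders == 8`.
#' @return A [founder_set()].
#' @export
simulate_founders <- function(map, n_founders = 8, divergence = 0.5,
                              seed = 1, names = NULL) {
  if (divergence <= 0) stop("divergence must be > 0: no informative markers possible")
  if (divergence > 1) stop("divergence must be <= 1")
  if (is.null(names)) {
    names <- if (n_founders == 8) magic_founder_names()
             else paste0("F", seq_len(n_founders))
  }
  stopifnot(length(names) == n_founders)
  set.seed(seed)
  m <- nrow(map)
  S <- n_founders
  if (divergence > 0.5) {
    # iid Bernoulli alleles cannot exceed pairwise difference 0.5; allocate
    # the alternate allele to a random half-split of the founders instead
    # (pairwise difference S/(2(S-1)): 1 for S=2, 4/7 for S=8)
    k <- round(S / 2)
    h <- matrix(0L, nrow = m, ncol = S)
    for (i in seq_len(m)) h[i, sample.int(S, k)] <- 1L
  } else {
    # allele frequency q with expected pairwise difference 2q(1-q) = divergence
    q <- (1 - sqrt(max(0, 1 - 2 * divergence))) / 2
    h <- matrix(rbinom(m * S, 1L, q), nrow = m, ncol = S)
    mono <- rowSums(h) %in% c(0L, S)
    while (any(mono)) {
      k <- sum(mono)
      h[mono, ] <- matrix(rbinom(k * S, 1L, q), nrow = k, ncol = S)
      mono <- rowSums(h) %in% c(0L, S)
    }
  }
  colnames(h) <- names
  founder_set(h, map)
}
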