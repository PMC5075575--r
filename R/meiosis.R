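# Mosaic tracks: a homolog on one chromosome is list(pos, founder) where
# pos are increasing segment end positions in cM (last = chromosome length)
# and founder are integer founder indices; segment j covers (pos[j-1], pos[j]]
# with an implicit 0 origin. A mosaic genome is, per chromosome, a pair of
# such tracks (h1, h2).

new_track <- function(founder, len) list(pos = len, founder = as.integer(founder))

track_valid <- function(tr, len, n_founders) {
  is.list(tr) && length(tr$pos) == length(tr$founder) &&
    !is.unsorted(tr$pos, strictly = TRUE) &&
    isTRUE(all.equal(tr$pos[length(tr$pos)], len)) &&
    all(tr$founder >= 1L & tr$founder <= n_founders)
}

# sub-track of tr covering (a, b]; assumes 0 <= a < b <= max(tr$pos)
sub_track <- function(tr, a, b) {
  i1 <- findInterval(a, tr$pos, left.open = TRUE) + 1L
  i2 <- findInterval(b, tr$pos, left.open = TRUE) + 1L
  if (i2 > length(tr$pos)) i2 <- length(tr$pos)
  pos <- tr$pos[i1:i2]
  pos[length(pos)] <- b
  list(pos = pos, founder = tr$founder[i1:i2])
}

merge_track <- function(pos, founder) {
  n <- length(founder)
  if (n > 1L) {
    keep <- c(founder[-n] != founder[-1L], TRUE)
    pos <- pos[keep]; founder <- founder[keep]
  }
  list(pos = pos, founder = founder)
}

#' Simulate one meiosis on one chromosome
#'
#' Forms a gamete from a parental homolog pair by drawing crossover counts
#' from a Poisson process at 1 crossover per 100 cM (Haldane model, no
#' interference), with crossover positions uniform along the chromosome and
#' the starting homolog chosen uniformly.
#'
#' @param h1,h2 Parental homolog tracks (`list(pos, founder)`).
#' @param len Chromosome length in cM.
#' @return A gamete track.
#' @export
meiosis_track <- function(h1, h2, len) {
  if (identical(h1, h2)) return(h1)           # fully homozygous: gamete fixed
  k <- if (len > 0) rpois(1L, len / 100) else 0L
  first <- sample.int(2L, 1L)
  if (k == 0L) return(if (first == 1L) h1 else h2)
  cuts <- c(sort(runif(k, 0, len)), len)
  a <- 0
  pos <- numeric(0); founder <- integer(0)
  src <- list(h1, h2)
  which_src <- first
  for (b in cuts) {
    if (b > a) {
      piece <- sub_track(src[[which_src]], a, b)
      pos <- c(pos, piece$pos); founder <- c(founder, piece$founder)
      a <- b
    }
    which_src <- 3L - which_src
  }
  merge_track(pos, founder)
}

#' Simulate a gamete across the genome
#'
#' Applies [meiosis_track()] independently to every chromosome of a parental
#' diplotype.
#'
#' @param diplotype Per-chromosome list of `list(h1, h2)` tracks.
#' @param lengths Named chromosome lengths (cM).
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return Per-chromosome list of gamete tracks.
#' @export
meiosis <- function(diplotype, lengths, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_along(diplotype), function(i) {
    meiosis_track(diplotype[[i]]$h1, diplotype[[i]]$h2, lengths[[i]])
  })
}

cross <- function(parent1, parent2, lengths) {
  g1 <- lapply(seq_along(parent1), function(i)
    meiosis_track(parent1[[i]]$h1, parent1[[i]]$h2, lengths[[i]]))
  g2 <- lapply(seq_along(parent2), function(i)
    meiosis_track(parent2[[i]]$h1, parent2[[i]]$h2, lengths[[i]]))
  lapply(seq_along(g1), function(i) list(h1 = g1[[i]], h2 = g2[[i]]))
}

founder_diplotype <- function(f, lengths) {
  lapply(lengths, function(len) {
    tr <- new_track(f, len)
    list(h1 = tr, h2 = tr)
  })
}

#' Simulate one MAGIC funnel
#'
#' Runs the eight-way funnel crossing scheme: four two-way crosses, two
#' four-way crosses, one eight-way cross (three cycles of recombination),
#' followed by `n_self` generations of self-fertilisation by single-seed
#' descent, yielding one near-inbred recombinant line.
#'
#' @param funnel_order Integer permutation of the 8 founder indices giving
#'   the funnel leaf order.
#' @param lengths Named chromosome lengths in cM.
#' @param n_self Number of selfing generations (default 5).
#' @param seed Optional integer seed.
#' @return A mosaic genome: per-chromosome list of `list(h1, h2)` tracks,
#'   with attribute `funnel_order`.
#' @export
simulate_funnel <- function(funnel_order, lengths, n_self = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(funnel_order) != 8 || anyDuplicated(funnel_order)) {
    stop("funnel_order must be a permutation of 8 distinct founders")
  }
  if (n_self < 0) stop("n_self must be >= 0")
  f <- as.integer(funnel_order)
  g0 <- lapply(f, founder_diplotype, lengths = lengths)
  two_way <- lapply(c(1, 3, 5, 7), function(i)
    cross(g0[[i]], g0[[i + 1]], lengths))
  four_way <- list(cross(two_way[[1]], two_way[[2]], lengths),
                   cross(two_way[[3]], two_way[[4]], lengths))
  ind <- cross(four_way[[1]], four_way[[2]], lengths)
  for (s in seq_len(n_self)) ind <- cross(ind, ind, lengths)
  names(ind) <- names(lengths)
  attr(ind, "funnel_order") <- f
  ind
}

#' Founder of origin at given positions
#'
#' @param track A homolog track.
#' @param pos Positions in cM (0 maps to the first segment).
#' @return Integer founder indices.
#' @export
founder_at <- function(track, pos) {
  idx <- findInterval(pos, track$pos, left.open = TRUE) + 1L
  idx[idx > length(track$founder)] <- length(track$founder)
  track$founder[idx]
}

#' Simulate a MAGIC RIL population
#'
#' Generates `n_lines` recombinant inbred lines, each from one independently
#' randomised eight-way funnel (one line per funnel), on the chromosomes of
#' `map`.
#'
#' @param map A [genetic_map()].
#' @param n_lines Number of RILs (default 208, the NIAB core-set size).
#' @param n_self Selfing generations (default 5).
#' @param seed Optional integer seed.
#' @param line_prefix Prefix for line identifiers.
#' @return List of mosaic genomes with names `<line_prefix>NNN`, with the
#'   chromosome lengths attached as attribute `lengths`.
#' @export
simulate_mosaics <- function(map, n_lines = 208, n_self = 5, seed = NULL,
                             line_prefix = "MEL") {
  if (!is.null(seed)) set.seed(seed)
  lengths <- chrom_lengths(map)
  mosaics <- lapply(seq_len(n_lines), function(i)
    simulate_funnel(sample.int(8L), lengths, n_self = n_self))
  names(mosaics) <- sprintf("%s%03d", line_prefix, seq_len(n_lines))
  attr(mosaics, "lengths") <- lengths
  mosaics
}
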