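#' HMM parameters for founder-descent inference
#'
#' @param generations Effective number of meioses g scaling the transition
#'   rate (default 8: three funnel crosses plus five selfing rounds).
#' @param error_rate Allele-flip emission probability (default 0.01).
#' @param inbred_mode If `TRUE` (default) the hidden state is the single
#'   founder of descent (S states, appropriate for near-inbred RILs);
#'   otherwise an ordered founder-pair diplotype chain (S^2 states).
#' @return An `hmm_params` list.
#' @export
hmm_params <- function(generations = 8, error_rate = 0.01,
                       inbred_mode = TRUE) {
  stopifnot(generations > 0, error_rate >= 0, error_rate < 0.5)
  structure(list(generations = generations, error_rate = error_rate,
                 inbred_mode = inbred_mode), class = "hmm_params")
}

#' Founder-state transition matrix over a map interval
#'
#' Exponential-decay parameterisation: over d cM and g effective meioses the
#' chain stays on the same founder with probability
#' `exp(-g d / 100) + (1 - exp(-g d / 100)) / S` and switches to any
#' particular other founder with probability `(1 - exp(-g d / 100)) / S`.
#' At d = 0 this is the identity; as d grows it approaches the uniform
#' stationary distribution.
#'
#' @param d Interval length in cM (>= 0).
#' @param params An [hmm_params()].
#' @param S Number of founders.
#' @return S x S stochastic matrix.
#' @export
transition_matrix <- function(d, params, S) {
  stopifnot(d >= 0)
  r <- exp(-params$generations * d / 100)
  M <- matrix((1 - r) / S, S, S)
  diag(M) <- r + (1 - r) / S
  M
}

#' Haploid emission probability
#'
#' Probability of an observed 0/1/2 genotype given descent from a founder
#' carrying allele 0 or 1 at the marker. Matching homozygotes score
#' `1 - error_rate`, mismatching homozygotes `error_rate`, heterozygous
#' observations 0.5 (uninformative under residual heterozygosity), and
#' missing observations 1.
#'
#' @param observed Genotype code 0, 1, 2 or `NA` (vectorised).
#' @param founder_allele 0 or 1 (vectorised, recycled).
#' @param error_rate Allele-flip probability.
#' @return Numeric emission probabilities.
#' @export
emission_prob <- function(observed, founder_allele, error_rate) {
  bad <- !is.na(observed) & !observed %in% c(0, 1, 2)
  if (any(bad)) {
    stop("invalid genotype code(s): ",
         paste(unique(observed[bad]), collapse = ", "))
  }
  out <- rep(1, length(observed))
  het <- !is.na(observed) & observed == 1
  hom <- !is.na(observed) & observed != 1
  out[het] <- 0.5
  match_ <- (observed == 0 & founder_allele == 0) |
    (observed == 2 & founder_allele == 1)
  out[hom] <- ifelse(match_[hom], 1 - error_rate, error_rate)
  out
}

# n x S emission matrices for one chromosome block of markers, all lines
emission_block <- function(G, hap, error_rate) {
  n <- nrow(G); m <- ncol(G); S <- ncol(hap)
  E <- array(1, c(n, m, S))
  eps <- error_rate
  for (s in seq_len(S)) {
    A <- matrix(hap[, s], n, m, byrow = TRUE)
    Es <- matrix(1, n, m)
    het <- !is.na(G) & G == 1
    hom <- !is.na(G) & G != 1
    Es[het] <- 0.5
    mt <- (G == 0 & A == 0) | (G == 2 & A == 1)
    Es[hom] <- ifelse(mt[hom], 1 - eps, eps)
    E[, , s] <- Es
  }
  E
}

#' Founder-descent posterior probabilities for all lines
#'
#' Runs the scaled forward-backward algorithm independently per chromosome,
#' vectorised across lines, under the haploid founder-state model. Per-locus
#' rescaling keeps the recursion in linear space without underflow.
#'
#' @param genotypes Lines x markers 0/1/2/NA matrix aligned to `map`.
#' @param founders A [founder_set()].
#' @param map A [genetic_map()].
#' @param params An [hmm_params()].
#' @return Object of class `founder_probs`: array lines x markers x founders
#'   of posterior descent probabilities (each locus vector sums to 1), with
#'   attributes `map`, `founder_names`, and per-line log-likelihood
#'   `loglik`.
#' @export
infer_founder_probs <- function(genotypes, founders, map = attr(founders, "map"),
                                params = hmm_params()) {
  G <- as.matrix(genotypes)
  if (ncol(G) != nrow(map)) {
    stop("genotype columns (", ncol(G), ") do not match map markers (",
         nrow(map), ")")
  }
  n <- nrow(G); S <- ncol(founders)
  hap <- unclass(founders)
  FP <- array(0, c(n, nrow(map), S),
              dimnames = list(rownames(G), map$marker, colnames(founders)))
  loglik <- numeric(n)
  for (ch in map_chroms(map)) {
    j <- which(map$chrom == ch)
    m <- length(j)
    if (any(apply(is.na(G[, j, drop = FALSE]), 1, all))) {
      warning("chromosome ", ch, ": line(s) with no observed genotypes; ",
              "posteriors are the uniform prior there")
    }
    E <- emission_block(G[, j, drop = FALSE], hap[j, , drop = FALSE],
                        params$error_rate)
    d <- diff(map$cM[j])
    Tm <- lapply(d, transition_matrix, params = params, S = S)
    alpha <- array(0, c(n, m, S))
    a <- matrix(1 / S, n, S) * matrix(E[, 1, ], n, S)
    sc <- rowSums(a)
    a <- a / sc
    loglik <- loglik + log(sc)
    alpha[, 1, ] <- a
    for (l in seq_len(m - 1)) {
      a <- (a %*% Tm[[l]]) * matrix(E[, l + 1, ], n, S)
      sc <- rowSums(a)
      a <- a / sc
      loglik <- loglik + log(sc)
      alpha[, l + 1, ] <- a
    }
    b <- matrix(1, n, S)
    FP[, j[m], ] <- alpha[, m, ]
    for (l in rev(seq_len(m - 1))) {
      b <- (b * matrix(E[, l + 1, ], n, S)) %*% t(Tm[[l]])
      b <- b / rowSums(b)
      post <- matrix(alpha[, l, ], n, S) * b
      FP[, j[l], ] <- post / rowSums(post)
    }
  }
  structure(FP, map = map, founder_names = colnames(founders),
            loglik = loglik, params = params, class = "founder_probs")
}

#' Forward-backward posteriors for a single line
#'
#' Convenience wrapper around [infer_founder_probs()] for one genotype
#' vector; returns the markers x founders posterior matrix and the
#' log-likelihood of the genotype vector under the HMM.
#'
#' @param genotype Numeric vector of 0/1/2/NA codes aligned to `map`.
#' @inheritParams infer_founder_probs
#' @return List with `probs` (markers x founders) and `loglik`.
#' @export
forward_backward <- function(genotype, founders, map = attr(founders, "map"),
                             params = hmm_params()) {
  FP <- infer_founder_probs(matrix(genotype, nrow = 1), founders, map, params)
  list(probs = matrix(FP[1, , ], nrow(map), ncol(founders),
                      dimnames = list(map$marker, colnames(founders))),
       loglik = attr(FP, "loglik")[1])
}

#' Log-probability of a given founder path
#'
#' Joint log-probability of a founder-state path and the observed genotypes
#' under the haploid HMM; the Viterbi path maximises this quantity.
#'
#' @param path Integer founder indices, one per marker of `map`.
#' @param genotype 0/1/2/NA vector aligned to `map`.
#' @inheritParams infer_founder_probs
#' @return Scalar log-probability.
#' @export
path_logprob <- function(path, genotype, founders,
                         map = attr(founders, "map"), params = hmm_params()) {
  S <- ncol(founders)
  hap <- unclass(founders)
  lp <- 0
  for (ch in map_chroms(map)) {
    j <- which(map$chrom == ch)
    lp <- lp - log(S)
    e <- emission_prob(genotype[j],
                       hap[cbind(j, path[j])], params$error_rate)
    lp <- lp + sum(log(e))
    if (length(j) > 1) {
      for (l in seq_len(length(j) - 1)) {
        Tm <- transition_matrix(map$cM[j[l + 1]] - map$cM[j[l]], params, S)
        lp <- lp + log(Tm[path[j[l]], path[j[l + 1]]])
      }
    }
  }
  lp
}

#' Most probable founder mosaic (Viterbi decoding)
#'
#' Computes the single most probable founder path per line under the haploid
#' HMM and converts it to mosaic tracks, with segment boundaries at
#' midpoints between markers where the decoded founder changes. Ties are
#' broken toward the lower founder index. Lines with no observed genotypes
#' on a chromosome decode to a single founder-1 segment and are flagged.
#'
#' @inheritParams infer_founder_probs
#' @return List per line of per-chromosome tracks (`h1` = `h2`, haploid
#'   decoding), each with the decoded path in attribute `path`; lines whose
#'   chromosomes were fully missing are named in attribute `low_confidence`.
#' @export
viterbi_mosaic <- function(genotypes, founders, map = attr(founders, "map"),
                           params = hmm_params()) {
  G <- as.matrix(genotypes)
  n <- nrow(G); S <- ncol(founders)
  hap <- unclass(founders)
  paths <- matrix(0L, n, nrow(map))
  low_conf <- logical(n)
  for (ch in map_chroms(map)) {
    j <- which(map$chrom == ch)
    m <- length(j)
    low_conf <- low_conf | apply(is.na(G[, j, drop = FALSE]), 1, all)
    E <- emission_block(G[, j, drop = FALSE], hap[j, , drop = FALSE],
                        params$error_rate)
    lE <- log(E)
    d <- diff(map$cM[j])
    ld <- log(matrix(1 / S, n, S)) + matrix(lE[, 1, ], n, S)
    ptr <- array(0L, c(n, m, S))
    for (l in seq_len(m - 1)) {
      lT <- log(transition_matrix(d[l], params, S))
      new_ld <- matrix(0, n, S)
      for (s in seq_len(S)) {
        cand <- sweep(ld, 2, lT[, s], "+")
        p <- max.col(cand, ties.method = "first")
        ptr[, l + 1, s] <- p
        new_ld[, s] <- cand[cbind(seq_len(n), p)] + lE[, l + 1, s]
      }
      ld <- new_ld
    }
    last <- max.col(ld, ties.method = "first")
    paths[, j[m]] <- last
    if (m > 1) {
      for (l in rev(seq_len(m - 1))) {
        last <- ptr[cbind(seq_len(n), l + 1, last)]
        paths[, j[l]] <- last
      }
    }
  }
  lengths <- chrom_lengths(map)
  mosaics <- lapply(seq_len(n), function(i) {
    trks <- lapply(map_chroms(map), function(ch) {
      j <- which(map$chrom == ch)
      p <- paths[i, j]
      changes <- which(p[-1] != p[-length(p)])
      pos <- if (length(changes)) {
        (map$cM[j[changes]] + map$cM[j[changes + 1]]) / 2
      } else numeric(0)
      tr <- list(pos = c(pos, lengths[[ch]]),
                 founder = p[c(changes, length(p))])
      structure(list(h1 = tr, h2 = tr), path = p)
    })
    names(trks) <- map_chroms(map)
    trks
  })
  names(mosaics) <- rownames(G)
  attr(mosaics, "lengths") <- lengths
  attr(mosaics, "low_confidence") <- rownames(G)[low_conf]
  mosaics
}
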