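#' Diplotype (founder-pair) posterior probabilities
#'
#' Forward-backward over the ordered founder-pair state space (S^2 states),
#' for use with the full interaction model. The two homolog chains move
#' independently (product transition kernel) and the emission models two
#' independently error-prone allele observations, so heterozygous genotype
#' calls are informative here. The posterior F[i, L, s, t] is symmetric in
#' (s, t) by exchangeability of homologs.
#'
#' Memory grows as lines x markers x S^2; restrict `markers` for large maps.
#'
#' @inheritParams infer_founder_probs
#' @param markers Optional marker ids to report (all by default; the chain
#'   always runs over every marker of each involved chromosome).
#' @return Array lines x reported markers x S x S of posterior diplotype
#'   probabilities, with attributes `map` and `founder_names`.
#' @export
infer_diplotype_probs <- function(genotypes, founders,
                                  map = attr(founders, "map"),
                                  params = hmm_params(),
                                  markers = NULL) {
  G <- as.matrix(genotypes)
  n <- nrow(G); S <- ncol(founders)
  hap <- unclass(founders)
  if (is.null(markers)) markers <- map$marker
  if (!all(markers %in% map$marker)) {
    stop("unknown marker(s): ",
         paste(setdiff(markers, map$marker), collapse = ", "))
  }
  eps <- params$error_rate
  out <- array(0, c(n, length(markers), S, S),
               dimnames = list(rownames(G), markers,
                               colnames(founders), colnames(founders)))
  p_obs0 <- function(a) ifelse(a == 0, 1 - eps, eps)   # observe ref allele
  chroms_needed <- unique(map$chrom[match(markers, map$marker)])
  for (ch in chroms_needed) {
    j <- which(map$chrom == ch)
    m <- length(j)
    # per-locus 3 x S^2 emission tables: P(obs g | alleles a_s, a_t)
    etab <- lapply(seq_len(m), function(l) {
      a_s <- rep(hap[j[l], ], times = S)     # state order: s varies fastest
      a_t <- rep(hap[j[l], ], each = S)
      p0s <- p_obs0(a_s); p0t <- p_obs0(a_t)
      rbind(`0` = p0s * p0t,
            `1` = p0s * (1 - p0t) + (1 - p0s) * p0t,
            `2` = (1 - p0s) * (1 - p0t))
    })
    # per-line emissions by genotype-row lookup into the tables
    E_all <- lapply(seq_len(m), function(l) {
      g <- G[, j[l]]
      E <- matrix(1, n, S * S)
      obs <- which(!is.na(g))
      if (length(obs)) E[obs, ] <- etab[[l]][g[obs] + 1L, , drop = FALSE]
      E
    })
    d <- diff(map$cM[j])
    TT <- lapply(d, function(dd) {
      Tm <- transition_matrix(dd, params, S)
      kronecker(Tm, Tm)   # state order (s fastest) matches a_s construction
    })
    alpha <- vector("list", m)
    a <- matrix(1 / S^2, n, S * S) * E_all[[1]]
    a <- a / rowSums(a)
    alpha[[1]] <- a
    for (l in seq_len(m - 1)) {
      a <- (a %*% TT[[l]]) * E_all[[l + 1]]
      a <- a / rowSums(a)
      alpha[[l + 1]] <- a
    }
    post <- vector("list", m)
    b <- matrix(1, n, S * S)
    post[[m]] <- alpha[[m]]
    for (l in rev(seq_len(m - 1))) {
      b <- (b * E_all[[l + 1]]) %*% t(TT[[l]])
      b <- b / rowSums(b)
      p <- alpha[[l]] * b
      post[[l]] <- p / rowSums(p)
    }
    for (mk in intersect(markers, map$marker[j])) {
      l <- match(mk, map$marker[j])
      k <- match(mk, markers)
      out[, k, , ] <- array(post[[l]], c(n, S, S))
    }
  }
  structure(out, map = map, founder_names = colnames(founders),
            params = params)
}
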