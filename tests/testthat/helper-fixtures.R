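# Shared fixtures and independent oracles, built in code at test time.

tiny_map <- function(n_mark = 3, chroms = "1A", spacing = 10) {
  genetic_map(
    marker = as.vector(vapply(chroms, function(ch)
      paste0(ch, "_", seq_len(n_mark)), character(n_mark))),
    chrom = rep(chroms, each = n_mark),
    cM = rep(seq(0, by = spacing, length.out = n_mark), length(chroms)))
}

tiny_founders <- function(map, hap) {
  founder_set(hap, map)
}

# Exhaustive-path forward-backward oracle: enumerates every founder path on
# one chromosome and computes exact posteriors and likelihood. Independent
# of the package's recursion (direct sum over S^m paths).
enumerate_posterior <- function(genotype, founders, map, params) {
  S <- ncol(founders)
  m <- nrow(map)
  stopifnot(length(unique(map$chrom)) == 1)
  hap <- unclass(founders)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), m)))
  probs <- apply(paths, 1, function(p) {
    lp <- log(1 / S)
    for (l in seq_len(m)) {
      e <- emission_prob(genotype[l], hap[l, p[l]], params$error_rate)
      lp <- lp + log(e)
      if (l < m) {
        Tm <- transition_matrix(map$cM[l + 1] - map$cM[l], params, S)
        lp <- lp + log(Tm[p[l], p[l + 1]])
      }
    }
    exp(lp)
  })
  post <- matrix(0, m, S)
  for (l in seq_len(m)) {
    for (s in seq_len(S)) {
      post[l, s] <- sum(probs[paths[, l] == s])
    }
  }
  list(probs = post / rowSums(post), loglik = log(sum(probs)))
}

# Direct independent Storey step-up implementation (loop form, no cummin)
qvalues_direct <- function(pvals, pi0) {
  m <- length(pvals)
  o <- order(pvals)
  ps <- pvals[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(pi0 * m * ps[i:m] / seq(i, m))
  }
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# two-subpopulation structured genotype control: same map, two disjoint
# founder pools with opposite allele frequencies (q = 0.3 vs 0.7), half the
# lines descending from each pool
structured_population <- function(map, n_lines = 104, seed = 1) {
  set.seed(seed)
  draw_pool <- function(q, sd) {
    set.seed(sd)
    h <- matrix(rbinom(nrow(map) * 8, 1, q), nrow(map), 8)
    mono <- rowSums(h) %in% c(0, 8)
    while (any(mono)) {
      h[mono, ] <- matrix(rbinom(sum(mono) * 8, 1, q), sum(mono), 8)
      mono <- rowSums(h) %in% c(0, 8)
    }
    founder_set(h, map)
  }
  fA <- draw_pool(0.3, seed + 1)
  fB <- draw_pool(0.7, seed + 2)
  mA <- simulate_mosaics(map, n_lines, seed = seed + 3, line_prefix = "A")
  mB <- simulate_mosaics(map, n_lines, seed = seed + 4, line_prefix = "B")
  rbind(emit_genotypes(mA, fA, 0, 0), emit_genotypes(mB, fB, 0, 0))
}
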