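test_that("transition matrix has the exponential-decay form", {
  p <- hmm_params(generations = 8)
  expect_equal(transition_matrix(0, p, 8), diag(8))
  far <- transition_matrix(1e6, p, 8)
  expect_equal(far, matrix(1 / 8, 8, 8), tolerance = 1e-12)
  M <- transition_matrix(10, p, 8)
  expect_equal(diag(M)[1], exp(-0.8) + (1 - exp(-0.8)) / 8, tolerance = 1e-12)
  expect_equal(rowSums(M), rep(1, 8))
  expect_equal(M[1, 2], (1 - exp(-0.8)) / 8, tolerance = 1e-12)
})

test_that("emission probabilities follow the error model", {
  expect_equal(emission_prob(NA, 0, 0.01), 1)
  expect_equal(emission_prob(2, 1, 0), 1)
  expect_equal(emission_prob(0, 1, 0.01), 0.01)
  expect_equal(emission_prob(2, 0, 0.01), 0.01)
  expect_equal(emission_prob(1, 0, 0.01), 0.5)
  expect_equal(emission_prob(c(0, 2, NA), c(0, 1, 0), 0.02),
               c(0.98, 0.98, 1))
  expect_error(emission_prob(3, 0, 0.01), "invalid genotype")
})

test_that("forward-backward equals exhaustive path enumeration", {
  # S = 2, 3 loci and S = 3, 4 loci instances with arbitrary distances,
  # error rates and missing data
  cases <- list(
    list(S = 2, m = 3, eps = 0.05, spacing = c(0, 12, 40)),
    list(S = 3, m = 4, eps = 0.01, spacing = c(0, 5, 25, 60)),
    list(S = 3, m = 4, eps = 0.2, spacing = c(0, 1, 2, 90))
  )
  for (cs in cases) {
    for (seed in 1:4) {
      set.seed(seed)
      map <- genetic_map(paste0("m", seq_len(cs$m)), rep("c1", cs$m),
                         cs$spacing)
      hap <- matrix(rbinom(cs$m * cs$S, 1, 0.5), cs$m, cs$S)
      while (any(rowSums(hap) %in% c(0, cs$S))) {
        hap <- matrix(rbinom(cs$m * cs$S, 1, 0.5), cs$m, cs$S)
      }
      founders <- founder_set(hap, map)
      geno <- sample(c(0, 1, 2, NA), cs$m, replace = TRUE)
      params <- hmm_params(generations = 6, error_rate = cs$eps)
      got <- forward_backward(geno, founders, map, params)
      want <- enumerate_posterior(geno, founders, map, params)
      expect_equal(unname(got$probs), want$probs, tolerance = 1e-9)
      expect_equal(got$loglik, want$loglik, tolerance = 1e-9)
    }
  }
})

test_that("posteriors are proper distributions and respect degenerate inputs", {
  map <- tiny_map(4)
  hap <- matrix(c(0, 1, 0, 1,  1, 0, 0, 1,  0, 0, 1, 0), 4, 3)
  founders <- founder_set(hap, map)
  expect_warning(fb <- forward_backward(rep(NA, 4), founders, map),
                 "no observed genotypes")
  expect_equal(unname(fb$probs), matrix(1 / 3, 4, 3))
  # single informative marker, zero error: all mass on the only founder
  # carrying the observed allele
  map1 <- tiny_map(2)
  hap1 <- matrix(c(0, 0, 0, 0, 1, 0), 2, 3)  # founder 3 alone carries alt at m1
  f1 <- founder_set(hap1, map1)
  fb1 <- forward_backward(c(2, NA), f1, map1,
                          hmm_params(error_rate = 0))
  expect_equal(unname(fb1$probs[1, ]), c(0, 0, 1))
})

test_that("posterior vectors sum to one across a simulated population", {
  map <- regular_map(n_mark = 30)
  set.seed(3)
  founders <- simulate_founders(map, 8, 0.5, seed = 5)
  mosaics <- simulate_mosaics(map, 40)
  g <- emit_genotypes(mosaics, founders, 0.01, 0.05)
  FP <- infer_founder_probs(g, founders)
  sums <- apply(FP, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-9)
  expect_true(all(FP >= 0 & FP <= 1))
})

test_that("posteriors are equivariant under founder relabeling", {
  map <- tiny_map(5)
  set.seed(11)
  hap <- matrix(rbinom(20, 1, 0.5), 5, 4)
  hap[rowSums(hap) %in% c(0, 4), 1] <- 1 - hap[rowSums(hap) %in% c(0, 4), 1]
  founders <- founder_set(hap, map)
  geno <- c(0, 2, 1, NA, 2)
  perm <- c(3, 1, 4, 2)
  f_perm <- founder_set(hap[, perm], map)
  a <- forward_backward(geno, founders, map)$probs
  b <- forward_backward(geno, f_perm, map)$probs
  expect_equal(unname(a[, perm]), unname(b), tolerance = 1e-12)
})

test_that("posterior confidence grows with marker density and falls with error", {
  set.seed(13)
  conf <- function(n_mark, eps_emit) {
    map <- regular_map(chroms = "1A", n_mark = n_mark)
    founders <- simulate_founders(map, 8, 0.5, seed = 14)
    mosaics <- simulate_mosaics(map, 30)
    g <- emit_genotypes(mosaics, founders, eps_emit, 0)
    FP <- infer_founder_probs(g, founders,
                              params = hmm_params(error_rate = max(eps_emit, 0.01)))
    fo <- mosaic_founders(mosaics, map)
    mean(FP[cbind(rep(1:30, nrow(map)),
                  rep(seq_len(nrow(map)), each = 30),
                  as.vector(fo$h1))])
  }
  set.seed(13); sparse <- conf(25, 0.001)
  set.seed(13); dense <- conf(100, 0.001)
  set.seed(13); noisy <- conf(100, 0.1)
  expect_gt(dense, sparse)
  expect_gt(dense, noisy)
})

test_that("viterbi decoding recovers dense noiseless mosaics and is optimal", {
  # decoding accuracy is density-limited by allele-sharing around true
  # junctions, so the >99% check runs at 4 markers/cM on well-separated
  # founders and near-complete inbreeding (unambiguous haploid target)
  map <- regular_map(chroms = "1A", n_mark = 400)
  set.seed(17)
  founders <- simulate_founders(map, 8, 4 / 7, seed = 18)
  mosaics <- simulate_mosaics(map, 20, n_self = 12)
  g <- emit_genotypes(mosaics, founders, 0, 0)
  vm <- viterbi_mosaic(g, founders, params = hmm_params(error_rate = 0.001))
  fo <- mosaic_founders(mosaics, map)
  acc <- mean(vapply(1:20, function(i) {
    path <- unlist(lapply(map_chroms(map), function(ch)
      attr(vm[[i]][[ch]], "path")))
    mean(path == fo$h1[i, ])
  }, numeric(1)))
  expect_gt(acc, 0.99)
  # optimality: viterbi path log-probability >= true path log-probability
  params <- hmm_params(error_rate = 0.001)
  for (i in 1:5) {
    vpath <- unlist(lapply(map_chroms(map), function(ch)
      attr(vm[[i]][[ch]], "path")))
    lp_v <- path_logprob(vpath, g[i, ], founders, map, params)
    lp_t <- path_logprob(fo$h1[i, ], g[i, ], founders, map, params)
    expect_gte(lp_v, lp_t - 1e-9)
  }
  # all-missing line decodes to the tie-break founder and is flagged
  g_na <- g
  g_na[1, ] <- NA
  vm_na <- viterbi_mosaic(g_na, founders, params = params)
  expect_true(rownames(g)[1] %in% attr(vm_na, "low_confidence"))
  expect_equal(unique(attr(vm_na[[1]][["1A"]], "path")), 1L)
})
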