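make_fp <- function(P, map = NULL, founder_names = NULL) {
  # founder_probs object from an n x m x S array built by hand
  n <- dim(P)[1]; m <- dim(P)[2]; S <- dim(P)[3]
  if (is.null(map)) map <- tiny_map(m)
  if (is.null(founder_names)) founder_names <- paste0("F", seq_len(S))
  structure(P, map = map, founder_names = founder_names,
            class = "founder_probs")
}

test_that("additive design rows conserve probability mass", {
  P <- array(1 / 8, c(5, 3, 8))
  FP <- make_fp(P)
  X <- additive_design(FP, 2)
  expect_equal(unname(X), matrix(1 / 8, 5, 8))
  expect_equal(rowSums(X), rep(1, 5))
  P2 <- array(0, c(4, 3, 8)); P2[, , 3] <- 1
  X2 <- additive_design(make_fp(P2), 1)
  expect_equal(unname(X2[1, ]), c(0, 0, 1, 0, 0, 0, 0, 0))
  # property over an inferred population: every row sums to 1 at every locus
  map <- regular_map(n_mark = 25)
  set.seed(31)
  founders <- simulate_founders(map, 8, 0.5, seed = 32)
  mosaics <- simulate_mosaics(map, 30)
  FPi <- infer_founder_probs(emit_genotypes(mosaics, founders, 0.01, 0.02),
                             founders)
  for (l in c(1, 40, 75)) {
    expect_equal(rowSums(additive_design(FPi, l)), rep(1, 30),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("full design has S(S-1)/2 + S columns and indicator structure", {
  FST8 <- array(0, c(3, 8, 8)); FST8[, 2, 2] <- 1
  X8 <- full_design(FST8)
  expect_equal(ncol(X8), 8 * 7 / 2 + 8)   # 36
  expect_equal(unname(X8[1, "F2:F2"]), 1)
  expect_equal(sum(X8[1, ]), 1)
  FST2 <- array(0, c(2, 2, 2))
  FST2[, 1, 2] <- 0.5; FST2[, 2, 1] <- 0.5
  X2 <- full_design(FST2)
  expect_equal(ncol(X2), 3)
  expect_equal(unname(X2[1, ]), c(0, 1, 0))  # all mass on the het pair
  P <- make_fp(array(1 / 2, c(2, 3, 2)))
  expect_error(full_design(P), "diplotype")
})

test_that("diplotype inference matches haploid marginals on inbred lines", {
  map <- regular_map(chroms = "1A", n_mark = 40)
  set.seed(33)
  founders <- simulate_founders(map, 8, 0.5, seed = 34)
  mosaics <- simulate_mosaics(map, 12, n_self = 12)   # essentially fully inbred
  g <- emit_genotypes(mosaics, founders, 0, 0)
  FST <- infer_diplotype_probs(g, founders, markers = map$marker[c(10, 20)])
  for (k in 1:2) {
    slice <- FST[, k, , ]
    # symmetric in (s, t)
    for (i in 1:12) {
      expect_equal(slice[i, , ], t(slice[i, , ]), tolerance = 1e-9)
    }
  }
  FP <- infer_founder_probs(g, founders)
  # haploid posterior ~ diplotype marginal at high inbreeding
  marg <- apply(FST[, 1, , ], c(1, 2), sum)
  expect_gt(cor(as.vector(marg), as.vector(FP[, 10, ])), 0.99)
})

test_that("fit_locus matches the two-sample t-test oracle and handles edge cases", {
  set.seed(41)
  n <- 20
  grp <- rep(c(1L, 2L), each = n / 2)
  X <- cbind(as.numeric(grp == 1), as.numeric(grp == 2))
  y <- rnorm(n, mean = c(3, 5)[grp])
  fit <- fit_locus(y, X)
  tt <- t.test(y[grp == 1], y[grp == 2], var.equal = TRUE)
  expect_equal(fit$f_stat, unname(tt$statistic^2), tolerance = 1e-10)
  expect_equal(fit$neg_log10_p, -log10(tt$p.value), tolerance = 1e-8)
  expect_equal(unname(fit$effects),
               c(mean(y[grp == 1]), mean(y[grp == 2])), tolerance = 1e-10)
  # constant phenotype: no variance to explain
  f0 <- fit_locus(rep(2, n), X)
  expect_equal(f0$f_stat, 0)
  expect_equal(f0$neg_log10_p, 0)
  expect_equal(f0$var_explained, 0)
  # missing phenotypes are dropped casewise
  y_na <- y; y_na[c(1, 11)] <- NA
  expect_equal(fit_locus(y_na, X)$n_used, 18)
})

test_that("locus p-values are calibrated under the null", {
  set.seed(43)
  n <- 200
  X <- t(rmultinom(n, 1, rep(1 / 8, 8)))   # hard founder assignments
  FP <- make_fp(aperm(array(X, c(n, 8, 2)), c(1, 3, 2)), tiny_map(2))
  eng <- magicqtl:::scan_engine(FP)
  Y <- matrix(rnorm(n * 1000), n, 1000)
  st <- magicqtl:::engine_scan(eng, Y)
  pv <- 10^(-st$neg_log10_p[1, ])
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.02)
  expect_gt(suppressWarnings(ks.test(pv, "punif")$p.value), 0.001)
})

test_that("genome scan localises a planted QTL and reports founder means", {
  map <- regular_map()
  qtls <- default_qtl_specs(map)[3]   # SH at mid-4D
  hits <- 0
  for (s in 1:8) {
    set.seed(100 + s)
    founders <- simulate_founders(map, 8, 0.5, seed = 200 + s)
    mosaics <- simulate_mosaics(map, 208)
    g <- emit_genotypes(mosaics, founders, 0.001, 0.0219)
    ph <- simulate_phenotypes(mosaics, founders, qtls, missing_rate = 0.0219)
    FP <- infer_founder_probs(g, founders)
    sc <- genome_scan(average_replicates(ph)$SH, FP)
    top <- which.max(sc$neg_log10_p)
    planted <- match(qtls[[1]]$marker, map$marker)
    if (sc$chrom[top] == map$chrom[planted] &&
        abs(sc$cM[top] - map$cM[planted]) <= 5) hits <- hits + 1
  }
  expect_gte(hits, 7)   # >= 90% expected; allow one miss in 8
})

test_that("scan statistics are equivariant under founder relabeling", {
  map <- regular_map(n_mark = 20)
  set.seed(51)
  founders <- simulate_founders(map, 8, 0.5, seed = 52)
  mosaics <- simulate_mosaics(map, 60)
  g <- emit_genotypes(mosaics, founders, 0.001, 0)
  ph <- simulate_phenotypes(mosaics, founders, default_qtl_specs(map),
                            missing_rate = 0)
  y <- average_replicates(ph)$SH
  FP <- infer_founder_probs(g, founders)
  perm <- c(5, 3, 8, 1, 7, 2, 6, 4)
  FPp <- structure(FP[, , perm], map = map,
                   founder_names = attr(FP, "founder_names")[perm],
                   class = "founder_probs")
  a <- genome_scan(y, FP)
  b <- genome_scan(y, FPp)
  expect_equal(a$neg_log10_p, b$neg_log10_p, tolerance = 1e-8)
  expect_equal(unname(as.matrix(a[, attr(FP, "founder_names")[perm]])),
               unname(as.matrix(b[, attr(FP, "founder_names")[perm]])),
               tolerance = 1e-6)
})

test_that("full model never explains less than the additive model", {
  map <- regular_map(chroms = "1A", n_mark = 30)
  set.seed(61)
  founders <- simulate_founders(map, 8, 0.5, seed = 62)
  mosaics <- simulate_mosaics(map, 100)
  g <- emit_genotypes(mosaics, founders, 0, 0)
  ph <- simulate_phenotypes(mosaics, founders,
                            list(qtl_spec("SH", map$marker[15],
                                          c(50, 52, 50, 50, 50, 64, 61, 47),
                                          0.4)),
                            missing_rate = 0)
  y <- average_replicates(ph)$SH
  FP <- infer_founder_probs(g, founders)
  FST <- infer_diplotype_probs(g, founders, markers = map$marker[c(5, 15, 25)])
  for (k in 1:3) {
    Xa <- additive_design(FP, match(dimnames(FST)[[2]][k], map$marker))
    Xf <- full_design(FST[, k, , ])
    fa <- fit_locus(y, Xa)
    suppressWarnings(ff <- fit_locus(y, Xf))
    expect_gte(ff$var_explained, fa$var_explained - 1e-8)
  }
})

test_that("scan peaks report one top marker per chromosome with flanks", {
  map <- regular_map(n_mark = 10)
  set.seed(71)
  founders <- simulate_founders(map, 8, 0.5, seed = 72)
  mosaics <- simulate_mosaics(map, 40)
  FP <- infer_founder_probs(emit_genotypes(mosaics, founders, 0, 0), founders)
  sc <- genome_scan(rnorm(40), FP)
  pk <- scan_peaks(sc)
  expect_equal(nrow(pk), 3)
  expect_equal(pk$chrom, map_chroms(map))
})
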