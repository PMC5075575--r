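test_that("genetic map validates structure and orders markers", {
  m <- genetic_map(c("b", "a", "c", "d"), c("1A", "1A", "2B", "2B"),
                   c(5, 0, 0, 3))
  expect_equal(m$marker, c("a", "b", "c", "d"))
  expect_error(genetic_map(c("a", "a"), c("1", "1"), c(0, 1)), "duplicated")
  expect_error(genetic_map(c("a", "b", "c"), c("1", "1", "2"), c(0, 1, 0)),
               "at least 2 markers")
})

test_that("founder simulation honours divergence and determinism", {
  map <- tiny_map(1000, spacing = 0.1)
  expect_error(simulate_founders(map, 8, divergence = 0), "divergence")
  f2 <- simulate_founders(map, 2, divergence = 1, seed = 1)
  expect_true(all(f2[, 1] != f2[, 2]))          # complementary everywhere
  f8 <- simulate_founders(map, 8, divergence = 0.5, seed = 3)
  pairs <- combn(8, 2)
  diffs <- apply(pairs, 2, function(p) mean(f8[, p[1]] != f8[, p[2]]))
  # mean pairwise difference 0.5 within ~4 binomial SEs at 1000 markers
  expect_lt(abs(mean(diffs) - 0.5), 4 * sqrt(0.25 / 1000))
  expect_true(all(rowSums(unclass(f8)) %in% 1:7))   # every marker polymorphic
  expect_identical(unclass(simulate_founders(map, 8, 0.5, seed = 9)),
                   unclass(simulate_founders(map, 8, 0.5, seed = 9)))
})

test_that("meiosis recombines at the Haldane rate", {
  h1 <- list(pos = 100, founder = 1L)
  h2 <- list(pos = 100, founder = 2L)
  # zero-length chromosome: gamete is one parental homolog unchanged
  set.seed(1)
  g0 <- meiosis_track(list(pos = 0, founder = 1L),
                      list(pos = 0, founder = 2L), 0)
  expect_true(identical(g0$founder, 1L) || identical(g0$founder, 2L))
  # recombinant fraction between markers 50 cM apart: (1 - exp(-1)) / 2
  set.seed(42)
  rec <- vapply(1:3000, function(i) {
    g <- meiosis_track(h1, h2, 100)
    founder_at(g, 25) != founder_at(g, 75)
  }, logical(1))
  expect_lt(abs(mean(rec) - (1 - exp(-1)) / 2), 0.03)
})

test_that("funnels tile chromosomes, keep residual heterozygosity at 2^-g and balance founders", {
  map <- regular_map(chroms = "5A", n_mark = 60)
  lengths <- chrom_lengths(map)
  expect_error(simulate_funnel(c(1, 1, 2:7), lengths), "permutation")
  set.seed(5)
  n <- 400
  het <- numeric(n)
  share <- matrix(0, n, 8)
  pos <- map$cM
  for (i in seq_len(n)) {
    mg <- simulate_funnel(sample.int(8), lengths, n_self = 5)
    tr1 <- mg[["5A"]]$h1; tr2 <- mg[["5A"]]$h2
    expect_true(magicqtl:::track_valid(tr1, lengths[["5A"]], 8))
    expect_true(magicqtl:::track_valid(tr2, lengths[["5A"]], 8))
    f1 <- founder_at(tr1, pos); f2 <- founder_at(tr2, pos)
    het[i] <- mean(f1 != f2)
    share[i, ] <- tabulate(c(f1, f2), 8) / (2 * length(pos))
  }
  # residual heterozygosity ~ (1/2)^5 of the (fully heterozygous) F1 state
  expect_lt(abs(mean(het) - 2^-5), 0.008)
  # genome-wide founder shares ~ 1/8 each
  expect_true(all(abs(colMeans(share) - 1 / 8) < 0.02))
})

test_that("funnel simulation is reproducible under a fixed seed", {
  lengths <- c(`1A` = 80)
  a <- simulate_funnel(1:8, lengths, seed = 77)
  b <- simulate_funnel(1:8, lengths, seed = 77)
  expect_identical(a, b)
  sim1 <- simulate_magic(regular_map(n_mark = 20), n_lines = 10, seed = 4)
  sim2 <- simulate_magic(regular_map(n_mark = 20), n_lines = 10, seed = 4)
  expect_identical(sim1$genotypes, sim2$genotypes)
  expect_identical(sim1$phenotypes, sim2$phenotypes)
})

test_that("genotype emission is exact at zero noise and masks at the target rate", {
  map <- regular_map(n_mark = 40)
  set.seed(8)
  founders <- simulate_founders(map, 8, 0.5, seed = 9)
  mosaics <- simulate_mosaics(map, 30)
  g <- emit_genotypes(mosaics, founders, error_rate = 0, missing_rate = 0)
  fo <- mosaic_founders(mosaics, map)
  hap <- unclass(founders)
  recon <- matrix(0L, 30, nrow(map))
  for (i in 1:30) {
    recon[i, ] <- hap[cbind(seq_len(nrow(map)), fo$h1[i, ])] +
      hap[cbind(seq_len(nrow(map)), fo$h2[i, ])]
  }
  expect_equal(unname(unclass(g)[, ]), recon, ignore_attr = TRUE)

  map2 <- regular_map(n_mark = 150)
  founders2 <- simulate_founders(map2, 8, 0.5, seed = 10)
  mosaics2 <- simulate_mosaics(map2, 208, seed = 11)
  gm <- emit_genotypes(mosaics2, founders2, 0, 0.0219, seed = 12)
  nm <- length(gm)
  expect_lt(abs(mean(is.na(gm)) - 0.0219),
            4 * sqrt(0.0219 * (1 - 0.0219) / nm))
  # mosaic/map mismatch (different chromosomes) is caught
  map_other <- regular_map(chroms = c("1A", "2B"), n_mark = 10)
  founders_other <- simulate_founders(map_other, 8, 0.5, seed = 13)
  expect_error(emit_genotypes(mosaics, founders_other), "mismatch")
})

test_that("phenotype simulation plants founder means, h2 and trait correlations", {
  map <- regular_map()
  qtls <- default_qtl_specs(map)
  set.seed(21)
  founders <- simulate_founders(map, 8, 0.5, seed = 22)
  mosaics <- simulate_mosaics(map, 208)
  expect_error(
    simulate_phenotypes(mosaics, founders,
                        list(qtl_spec("SH", "nope", rep(1, 8), 0.5))),
    "nope")
  # near-zero-noise limit: line value equals its founder mean (additively
  # averaged over the two homologs)
  q99 <- qtl_spec("SH", qtls[[3]]$marker, qtls[[3]]$founder_means, 0.999)
  tm <- default_trait_model()
  ph <- simulate_phenotypes(mosaics, founders, list(q99), tm,
                            missing_rate = 0, seed = 23)
  truth <- attr(ph, "truth")
  lmn <- average_replicates(ph)
  expected <- truth$genetic_values[, "SH"] + truth$base["SH"]
  expect_lt(max(abs(lmn$SH - expected)), 1.0)
  expect_gt(cor(lmn$SH, expected), 0.999)

  # planted h2 and correlation structure at study scale
  ph2 <- simulate_phenotypes(mosaics, founders, qtls, tm,
                             missing_rate = 0, seed = 24)
  lm2 <- average_replicates(ph2)
  g <- attr(ph2, "truth")$genetic_values
  h2_sh <- var(g[, "SH"]) / var(lm2$SH)
  expect_lt(abs(h2_sh - 0.38), 0.06)
  expect_lt(abs(cor(lm2$FLS, lm2$GS39) - 0.79), 0.08)  # Fisher-z 95% band
  expect_identical(
    simulate_phenotypes(mosaics, founders, qtls, tm, seed = 31),
    simulate_phenotypes(mosaics, founders, qtls, tm, seed = 31))
})

test_that("stress score is a right-skewed 0-4 ordinal", {
  map <- regular_map(n_mark = 20)
  set.seed(2)
  founders <- simulate_founders(map, 8, 0.5, seed = 3)
  mosaics <- simulate_mosaics(map, 150)
  ph <- simulate_phenotypes(mosaics, founders, default_qtl_specs(map),
                            missing_rate = 0, seed = 4)
  expect_true(all(ph$SM %in% 0:4))
  tab <- table(factor(ph$SM, levels = 0:4))
  expect_gt(tab["0"] + tab["1"] + tab["2"], 0.8 * sum(tab))
  expect_true(which.max(tab) <= 2)
})
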