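test_that("derived intervals are exact differences with NA propagation", {
  tb <- data.frame(line_id = c("a", "b", "c"), rep = 1,
                   GS39 = c(120, NA, 125), GS55 = c(136, 130, 125),
                   GS65 = c(140, 137, 131), FLS = c(170, 160, 120))
  d <- derive_intervals(tb)
  expect_equal(d$d3, c(34, 30, -5))
  expect_true(is.na(d$d1[2]))
  expect_equal(d$d1[3], 0)
  expect_match(attr(d, "qc_log"), "d3 negative", all = FALSE)
  expect_equal(derive_intervals(d)$d1, d$d1)  # idempotent
  expect_error(derive_intervals(tb[, -4]), "GS55")
})

test_that("chained-equation imputation preserves observed cells and beats mean fill", {
  set.seed(171)
  n <- 600
  z <- matrix(rnorm(n * 4), n, 4) %*% chol(matrix(c(1, .8, .6, .4,
                                                    .8, 1, .7, .3,
                                                    .6, .7, 1, .2,
                                                    .4, .3, .2, 1), 4))
  colnames(z) <- c("GS39", "GS55", "GS65", "FLS")
  full <- data.frame(line_id = sprintf("L%03d", 1:n), rep = 1L, z * 5 + 130)
  expect_identical(mice_impute(full, seed = 1)[, 3:6], full[, 3:6])
  masked <- full
  mask <- matrix(runif(n * 4) < 0.0219, n, 4)
  for (j in 1:4) masked[mask[, j], j + 2] <- NA
  imp <- mice_impute(masked, m = 5, seed = 2)
  obs <- !mask
  expect_equal(as.matrix(imp[, 3:6])[obs], as.matrix(full[, 3:6])[obs])
  rmse_mice <- sqrt(mean((as.matrix(imp[, 3:6])[mask] -
                            as.matrix(full[, 3:6])[mask])^2))
  mean_fill <- as.matrix(masked[, 3:6])
  for (j in 1:4) mean_fill[mask[, j], j] <- mean(mean_fill[, j], na.rm = TRUE)
  rmse_mean <- sqrt(mean((mean_fill[mask] - as.matrix(full[, 3:6])[mask])^2))
  expect_lt(rmse_mice, rmse_mean)
  expect_identical(mice_impute(masked, m = 5, seed = 9),
                   mice_impute(masked, m = 5, seed = 9))
  all_na <- masked; all_na$GS39 <- NA_real_
  expect_error(mice_impute(all_na, seed = 1), "entirely missing")
  heavy <- masked; heavy$GS39[1:400] <- NA
  expect_warning(mice_impute(heavy, seed = 1), "50%")
})

test_that("correlation matrix is symmetric with unit diagonal and sign-correct", {
  set.seed(181)
  x <- rnorm(100)
  tb <- data.frame(a = x, b = -x + rnorm(100, sd = 0.1), c = rnorm(100),
                   k = rep(1, 100))
  R <- correlation_matrix(tb)
  expect_equal(diag(R), setNames(rep(1, 4), colnames(R)))
  expect_equal(R, t(R))
  expect_lt(R["a", "b"], -0.9)
  expect_true(is.na(R["a", "k"]))   # constant column undefined
})

test_that("trait PCA fractions behave on rank-1 and general tables", {
  set.seed(191)
  x <- rnorm(50)
  p <- trait_pca(data.frame(a = x, b = 2 * x + 3))
  expect_equal(p$var_frac[1], 1, tolerance = 1e-12)
  tb <- as.data.frame(matrix(rnorm(50 * 6), 50))
  p2 <- trait_pca(tb)
  expect_equal(sum(p2$var_frac), 1, tolerance = 1e-12)
  # invariance to row order and to affine rescaling of columns
  p3 <- trait_pca(tb[sample(50), ])
  expect_equal(p2$var_frac, p3$var_frac, tolerance = 1e-9)
  p4 <- trait_pca(as.data.frame(scale(tb) * 7 + 2))
  expect_equal(p2$var_frac, p4$var_frac, tolerance = 1e-9)
  expect_error(trait_pca(data.frame(a = x)), "at least 2")
  expect_error(trait_pca(data.frame(a = x, b = c(NA, x[-1]))), "complete")
})

test_that("kinship PCA separates structured from unstructured populations", {
  map <- regular_map(chroms = paste0("chr", 1:7), n_mark = 150)
  set.seed(201)
  founders <- simulate_founders(map, 8, 0.5, seed = 202)
  mosaics <- simulate_mosaics(map, 208)
  g <- emit_genotypes(mosaics, founders, 0.001, 0.0219)
  kp <- kinship_pca(g)
  expect_equal(kp$A, t(kp$A), tolerance = 1e-9)
  expect_true(all(diag(kp$A) >= 0))
  expect_lt(kp$pc1_frac, 0.04)
  g2 <- structured_population(regular_map(n_mark = 60), n_lines = 60,
                              seed = 203)
  expect_gt(kinship_pca(g2)$pc1_frac, 0.1)   # strong positive control
  mono <- matrix(2L, 10, 5, dimnames = list(NULL, paste0("m", 1:5)))
  expect_error(kinship_pca(mono), "polymorphic")
})

test_that("MLRM flags planted predictors with the right sign", {
  set.seed(211)
  n <- 208
  FFLL <- rnorm(n, 20, 3)
  SH <- rnorm(n, 52, 5)
  FLS <- 190 - 1.2 * FFLL + rnorm(n, sd = 3)   # longer flag leaf, earlier FLS
  tb <- data.frame(FLS = FLS, FFLL = FFLL, SH = SH, TN = rnorm(n, 22, 4))
  r <- mlrm_fls(tb)
  expect_true("FFLL" %in% r$significant)
  expect_lt(r$coefficients$estimate[r$coefficients$predictor == "FFLL"], 0)
  # null predictors are flagged at roughly the nominal rate
  expect_lt(mean(c("SH", "TN") %in% r$significant), 1)
  # circularity warning for d3 and the stricter model without it
  tb$GS55 <- rnorm(n, 135, 5)
  tb$d3 <- tb$FLS - tb$GS55
  # d3 + GS55 reconstruct FLS exactly, so the fit is (near-)perfect and
  # summary warns; the circularity is the point being tested
  r2 <- suppressWarnings(mlrm_fls(tb))
  expect_match(r2$qc_log, "d3", all = FALSE)
  r3 <- mlrm_fls(tb, exclude_derived = TRUE)
  expect_false("d3" %in% r3$coefficients$predictor)
  # unidentifiable: more predictors than lines
  wide <- as.data.frame(matrix(rnorm(5 * 8), 5))
  wide$FLS <- rnorm(5)
  expect_error(mlrm_fls(wide), "too small")
})

test_that("replicate averaging and outlier flagging work on replicated tables", {
  tb <- data.frame(line_id = c("a", "a", "b", "b"), rep = c(1, 2, 1, 2),
                   SH = c(50, 54, NA, 60), TN = c(20, NA, 30, 34))
  av <- average_replicates(tb)
  expect_equal(av$SH, c(52, 60))
  expect_equal(av$TN, c(20, 32))
  out <- flag_outliers(data.frame(x = c(rnorm(50), 100)), k = 4)
  expect_equal(out$row, 51)
})
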