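#' Additive haplotype-dosage design matrix at a locus
#'
#' Under haploid coding the expected founder dosage of line i for founder s
#' is the posterior descent probability itself, so each row sums to 1 and
#' regression coefficients read directly as founder trait means.
#'
#' @param FP A `founder_probs` array from [infer_founder_probs()].
#' @param marker Marker id or index.
#' @return Lines x founders numeric matrix.
#' @export
additive_design <- function(FP, marker) {
  l <- if (is.character(marker)) match(marker, attr(FP, "map")$marker)
       else marker
  if (is.na(l)) stop("marker not in map: ", marker)
  X <- matrix(FP[, l, ], dim(FP)[1], dim(FP)[3])
  colnames(X) <- attr(FP, "founder_names")
  rownames(X) <- dimnames(FP)[[1]]
  X
}

#' Full diplotype-pair design matrix at a locus
#'
#' One column per unordered founder pair (s, t) including s = t, giving
#' S(S-1)/2 + S columns; entries are posterior diplotype probabilities (the
#' off-diagonal pair (s, t) column pools F[s,t] + F[t,s]).
#'
#' @param FST Lines x S x S diplotype probability array at one locus (from
#'   [infer_diplotype_probs()]), or a `founder_probs` object, in which case
#'   an informative error directs the user to diplotype mode.
#' @param founder_names Optional founder names for column labels.
#' @return Lines x S(S+1)/2 numeric matrix with columns named `s:t`.
#' @export
full_design <- function(FST, founder_names = NULL) {
  if (inherits(FST, "founder_probs")) {
    stop("haploid founder probabilities cannot supply diplotype pairs; ",
         "run infer_diplotype_probs() (inbred_mode = FALSE) first")
  }
  stopifnot(length(dim(FST)) == 3, dim(FST)[2] == dim(FST)[3])
  n <- dim(FST)[1]; S <- dim(FST)[2]
  if (is.null(founder_names)) founder_names <- paste0("F", seq_len(S))
  pairs <- which(upper.tri(diag(S), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  X <- matrix(0, n, nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    s <- pairs[k, 1]; t <- pairs[k, 2]
    X[, k] <- if (s == t) FST[, s, s] else FST[, s, t] + FST[, t, s]
  }
  colnames(X) <- paste(founder_names[pairs[, 1]], founder_names[pairs[, 2]],
                       sep = ":")
  rownames(X) <- dimnames(FST)[[1]]
  X
}

# Moore-Penrose pseudo-inverse solve for rank-deficient least squares
pinv_coef <- function(X, y, tol = 1e-10) {
  sv <- svd(X)
  pos <- sv$d > tol * sv$d[1]
  drop(sv$v[, pos, drop = FALSE] %*%
         ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos]))
}

#' Fit the locus association model
#'
#' Least-squares regression of the phenotype on the founder-dosage design,
#' with an F-test of the locus term against the covariate-only null model.
#' Rows with missing phenotype are dropped casewise. Effects are reported on
#' the founder-mean scale: the no-intercept fit of y on the dosage block
#' (with covariates centred so the dosage coefficients remain founder-mean
#' predictions at the covariate average).
#'
#' @param y Phenotype vector (may contain `NA`).
#' @param X Design matrix from [additive_design()] or [full_design()].
#' @param covariates Optional numeric matrix of extra model columns present
#'   in both null and full models.
#' @return `locus_fit` list: `effects`, `f_stat`, `df` (c(df1, df2)),
#'   `neg_log10_p`, `var_explained`, `n_used`.
#' @export
fit_locus <- function(y, X, covariates = NULL) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("y length does not match design rows")
  keep <- !is.na(y)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  C <- if (!is.null(covariates)) as.matrix(covariates)[keep, , drop = FALSE]
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  Z0 <- cbind(`(Intercept)` = rep(1, n), C)
  q0 <- qr(Z0)
  rss0 <- sum(qr.resid(q0, y)^2)
  q1 <- qr(cbind(Z0, X))
  rss1 <- sum(qr.resid(q1, y)^2)
  df1 <- q1$rank - q0$rank
  df2 <- n - q1$rank
  if (tss <= 0 || df1 < 1 || df2 < 1 || rss1 <= 0) {
    f <- 0; nlp <- 0; ve <- 0
    if (df1 < 1) df1 <- 0
  } else {
    f <- ((rss0 - rss1) / df1) / (rss1 / df2)
    f <- max(f, 0)
    nlp <- -pf(f, df1, df2, lower.tail = FALSE, log.p = TRUE) / log(10)
    ve <- max(0, min(1, (rss0 - rss1) / tss))
  }
  # founder-mean-scale effects: y ~ 0 + X + centred covariates
  Zc <- if (is.null(C)) X else cbind(X, scale(C, scale = FALSE))
  qe <- qr(Zc)
  if (qe$rank < ncol(Zc)) {
    warning("rank-deficient design; effects computed by pseudo-inverse")
    eff <- pinv_coef(Zc, y)[seq_len(ncol(X))]
  } else {
    eff <- qr.coef(qe, y)[seq_len(ncol(X))]
  }
  names(eff) <- colnames(X)
  structure(list(effects = eff, f_stat = f, df = c(df1, df2),
                 neg_log10_p = nlp, var_explained = ve, n_used = n),
            class = "locus_fit")
}

# Precomputed per-locus projection engine shared by genome_scan,
# permutation_null and forward selection. Null space = intercept +
# covariates; each locus contributes an orthonormal basis of its dosage
# columns residualised against the null space.
scan_engine <- function(FP, covariates = NULL, keep = NULL, tol = 1e-9) {
  n_all <- dim(FP)[1]
  if (is.null(keep)) keep <- rep(TRUE, n_all)
  m <- dim(FP)[2]; S <- dim(FP)[3]
  n <- sum(keep)
  C <- if (!is.null(covariates)) as.matrix(covariates)[keep, , drop = FALSE]
  Z0 <- cbind(rep(1, n), C)
  q0 <- qr(Z0)
  rank0 <- q0$rank
  Q0 <- qr.Q(q0)[, seq_len(rank0), drop = FALSE]
  Qs <- vector("list", m)
  df1 <- integer(m)
  for (l in seq_len(m)) {
    X <- matrix(FP[keep, l, ], n, S)
    Xr <- X - Q0 %*% crossprod(Q0, X)
    qx <- qr(Xr, tol = tol)
    r <- qx$rank
    Qs[[l]] <- qr.Q(qx)[, seq_len(r), drop = FALSE]
    df1[l] <- r
  }
  list(n = n, keep = keep, rank0 = rank0, Q0 = Q0,
       Qall = do.call(cbind, Qs), df1 = df1,
       block = rep(seq_len(m), df1), m = m, S = S)
}

# F statistics and -log10 p for every locus (rows) against each phenotype
# column of Y (already subset to engine$keep lines)
engine_scan <- function(eng, Y) {
  Y <- as.matrix(Y)
  Y0 <- Y - eng$Q0 %*% crossprod(eng$Q0, Y)
  rss0 <- colSums(Y0^2)
  B <- crossprod(eng$Qall, Y0)
  ssx <- matrix(0, eng$m, ncol(Y))              # m x k explained SS
  if (length(eng$block)) {
    tmp <- rowsum(B^2, eng$block)
    ssx[sort(unique(eng$block)), ] <- tmp
  }
  rss1 <- sweep(-ssx, 2, rss0, "+")
  rss1[rss1 < 0] <- 0
  df1 <- eng$df1
  df2 <- eng$n - eng$rank0 - df1
  Fm <- (ssx / pmax(df1, 1)) / (rss1 / pmax(df2, 1))
  Fm[!is.finite(Fm)] <- 0
  nlp <- matrix(-pf(Fm, pmax(df1, 1), pmax(df2, 1),
                    lower.tail = FALSE, log.p = TRUE) / log(10),
                eng$m, ncol(Y))
  nlp[!is.finite(nlp)] <- 0
  nlp[df1 < 1 | df2 < 1] <- 0
  ve <- sweep(ssx, 2, pmax(colSums(scale(Y, scale = FALSE)^2), 1e-300), "/")
  list(f = Fm, neg_log10_p = nlp, var_explained = ve,
       df1 = df1, df2 = df2)
}

#' Genome scan by haplotype regression
#'
#' Applies [fit_locus()] at every mapped marker (through a shared
#' precomputed projection engine) and returns the per-marker association
#' table in map order, including founder effect estimates at each locus.
#'
#' @param y Phenotype vector aligned to the lines of `FP` (replicates must
#'   already be averaged); `NA` rows are dropped casewise.
#' @param FP A `founder_probs` array.
#' @param model `"additive"` (haploid dosages) is currently the scanning
#'   model; the full diplotype model is available per locus via
#'   [full_design()] + [fit_locus()].
#' @param covariates Optional covariate matrix (e.g. dosage blocks of
#'   selected markers) included in both null and full models.
#' @param effects If `FALSE`, skip per-locus effect estimation (faster).
#' @return `data.frame` of class `scan_result`: marker, chrom, cM,
#'   f_stat, neg_log10_p, var_explained, and one effect column per founder.
#' @export
genome_scan <- function(y, FP, model = c("additive", "full"),
                        covariates = NULL, effects = TRUE) {
  model <- match.arg(model)
  if (model == "full") {
    stop("genome-wide scanning uses the additive model; fit full-model ",
         "loci individually with full_design() + fit_locus()")
  }
  map <- attr(FP, "map")
  if (length(y) != dim(FP)[1]) stop("y length does not match lines in FP")
  keep <- !is.na(y)
  eng <- scan_engine(FP, covariates = covariates, keep = keep)
  st <- engine_scan(eng, y[keep])
  res <- data.frame(marker = map$marker, chrom = map$chrom, cM = map$cM,
                    f_stat = st$f[, 1], df1 = st$df1, df2 = st$df2,
                    neg_log10_p = st$neg_log10_p[, 1],
                    var_explained = st$var_explained[, 1],
                    stringsAsFactors = FALSE)
  fn <- attr(FP, "founder_names")
  if (effects) {
    eff <- matrix(NA_real_, nrow(map), length(fn),
                  dimnames = list(NULL, fn))
    C <- if (!is.null(covariates)) as.matrix(covariates)[keep, , drop = FALSE]
    Cc <- if (!is.null(C)) scale(C, scale = FALSE)
    yk <- y[keep]
    for (l in seq_len(nrow(map))) {
      X <- matrix(FP[keep, l, ], sum(keep), length(fn))
      Z <- if (is.null(Cc)) X else cbind(X, Cc)
      qe <- qr(Z)
      eff[l, ] <- if (qe$rank < ncol(Z)) pinv_coef(Z, yk)[seq_along(fn)]
                  else qr.coef(qe, yk)[seq_along(fn)]
    }
    res <- cbind(res, eff)
  }
  rownames(res) <- NULL
  structure(res, class = c("scan_result", "data.frame"),
            founder_names = fn, n_used = sum(keep))
}

#' Top-scoring marker per chromosome
#'
#' @param scan A `scan_result`.
#' @return One row per chromosome, ordered by chromosome, with the flanking
#'   marker interval of each peak in `flank_left`/`flank_right`.
#' @export
scan_peaks <- function(scan) {
  out <- do.call(rbind, lapply(split(seq_len(nrow(scan)), scan$chrom), function(j) {
    top <- j[which.max(scan$neg_log10_p[j])]
    row <- scan[top, , drop = FALSE]
    row$flank_left <- scan$marker[max(top - 1, min(j))]
    row$flank_right <- scan$marker[min(top + 1, max(j))]
    row
  }))
  out[order(match(out$chrom, unique(scan$chrom))), ]
}
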