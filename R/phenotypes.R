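#' Specify a planted QTL
#'
#' @param trait Trait code the QTL acts on.
#' @param marker Marker id of the causal locus (must exist in the map).
#' @param founder_means Length-S numeric vector of founder trait means, in
#'   trait units, named or in founder order.
#' @param h2 Fraction of the trait's phenotypic variance attributable to the
#'   locus (0 < h2 < 1), on the replicate-averaged line scale.
#' @return A `qtl_spec` list.
#' @export
qtl_spec <- function(trait, marker, founder_means, h2) {
  stopifnot(h2 > 0, h2 < 1, length(trait) == 1, length(marker) == 1)
  structure(list(trait = trait, marker = marker,
                 founder_means = as.numeric(founder_means), h2 = h2),
            class = "qtl_spec")
}

#' Default planted QTL set
#'
#' Five QTL on three chromosomes emulating the published wheat phenology
#' architecture: a strong 5A locus acting on heading-date traits GS39 and
#' GS55 (the Xi-19 founder early by ~15 days), and a 4D dwarfing-type locus
#' acting on stem height SH and top internode length TIL (Robigus and
#' Soissons tall), plus a 5B ear-length locus for SEL. Founder means are in
#' trait units (days after sowing, cm); h2 is the locus-level variance
#' fraction.
#'
#' @param map A [genetic_map()]; markers are taken mid-chromosome on 5A, 4D
#'   and 5B (falling back to the first three chromosomes if those names are
#'   absent).
#' @return List of [qtl_spec()] objects.
#' @export
default_qtl_specs <- function(map = regular_map()) {
  chroms <- map_chroms(map)
  prefs <- c("5A", "4D", "5B")
  used <- character(0)
  pick <- function(pref) {
    ch <- if (pref %in% chroms) pref else setdiff(chroms, c(used, prefs))[1]
    if (is.na(ch)) ch <- setdiff(chroms, used)[1]
    used <<- c(used, ch)
    j <- which(map$chrom == ch)
    map$marker[j[ceiling(length(j) / 2)]]
  }
  m5A <- pick("5A"); m4D <- pick("4D"); m5B <- pick("5B")
  list(
    qtl_spec("GS39", m5A,
             c(127.34, 127.15, 125.21, 128.42, 128.01, 125.13, 127.07, 111.46),
             h2 = 0.35),
    qtl_spec("GS55", m5A,
             c(136.79, 135.89, 134.09, 138.57, 136.96, 134.49, 136.99, 119.18),
             h2 = 0.33),
    qtl_spec("SH", m4D,
             c(49.88, 51.63, 49.92, 50.13, 49.98, 63.89, 60.82, 47.34),
             h2 = 0.38),
    qtl_spec("TIL", m4D,
             c(27.78, 28.20, 27.80, 27.59, 27.64, 32.11, 32.40, 26.25),
             h2 = 0.31),
    qtl_spec("SEL", m5B,
             c(11.12, 11.19, 11.19, 11.13, 11.17, 11.33, 10.36, 10.00),
             h2 = 0.22)
  )
}

#' Default trait suite model
#'
#' Means, line-level standard deviations and the target phenotypic
#' correlation structure for the 17-trait wheat phenology suite (growth
#' stages in days after sowing, morphology in cm/g, SM an ordinal stress
#' score, HI a ratio). Correlation targets reproduce the reported headline
#' pattern: FLS strongly correlated with GS39 (0.79), GS55 (0.73) and GS65
#' (0.69); ear lengths mutually > 0.86; TIL-SH 0.76; PW-OEW and TEW-PW 0.87;
#' FFLL and SM negatively related to FLS. Remaining pairs are weakly
#' positive within their biplot group and zero across. The matrix is
#' projected to the nearest positive semi-definite correlation matrix.
#'
#' @return List with `traits`, `means`, `sds`, `corr` (T x T), and
#'   `ordinal` (traits rendered as ordinal scores).
#' @export
default_trait_model <- function() {
  tr <- c("GS39", "GS55", "GS65", "FLS", "PW", "TN", "SH", "TIL", "FEL",
          "SEL", "TEL", "FEW", "OEW", "TEW", "FFLL", "SM", "HI")
  means <- c(GS39 = 125, GS55 = 135, GS65 = 142, FLS = 170, PW = 72,
             TN = 22, SH = 52, TIL = 28, FEL = 11.5, SEL = 11, TEL = 10.5,
             FEW = 4, OEW = 37, TEW = 41, FFLL = 20, SM = 0, HI = 0.55)
  # FLS spread (sd 14 d) is set so the derived interval d3 = FLS - GS55
  # correlates with FLS at ~0.7 given the planted FLS-GS55 correlation
  sds <- c(GS39 = 5, GS55 = 5, GS65 = 5, FLS = 14, PW = 10, TN = 4,
           SH = 5.5, TIL = 2.5, FEL = 1, SEL = 1, TEL = 1, FEW = 1,
           OEW = 6, TEW = 6.5, FFLL = 3, SM = 1, HI = 0.05)
  C <- diag(length(tr)); dimnames(C) <- list(tr, tr)
  set_r <- function(a, b, r) {
    C[a, b] <<- r; C[b, a] <<- r
  }
  set_r("FLS", "GS39", 0.79); set_r("FLS", "GS55", 0.73)
  set_r("FLS", "GS65", 0.69)
  set_r("GS39", "GS55", 0.85); set_r("GS39", "GS65", 0.78)
  set_r("GS55", "GS65", 0.85)
  set_r("FEL", "SEL", 0.87); set_r("FEL", "TEL", 0.86)
  set_r("SEL", "TEL", 0.87)
  set_r("TIL", "SH", 0.76)
  set_r("PW", "OEW", 0.87); set_r("TEW", "PW", 0.87)
  set_r("TEW", "OEW", 0.90); set_r("TEW", "FEW", 0.55)
  set_r("FEW", "OEW", 0.45)
  set_r("PW", "SH", 0.45); set_r("PW", "TIL", 0.35)
  set_r("FFLL", "SH", 0.30); set_r("FFLL", "PW", 0.30)
  set_r("FFLL", "FLS", -0.35)
  set_r("SM", "FLS", -0.40); set_r("SM", "GS39", -0.30)
  set_r("SM", "GS55", -0.30)
  set_r("HI", "FLS", -0.20); set_r("HI", "SM", 0.15)
  set_r("TN", "GS39", 0.25); set_r("TN", "FLS", 0.25)
  list(traits = tr, means = means, sds = sds, corr = make_psd(C),
       ordinal = "SM")
}

#' Project a symmetric matrix to the nearest PSD correlation matrix
#'
#' Eigenvalue clipping at a small floor followed by rescaling to unit
#' diagonal.
#'
#' @param C Symmetric matrix with unit diagonal.
#' @param floor Smallest retained eigenvalue.
#' @return PSD correlation matrix.
#' @export
make_psd <- function(C, floor = 1e-6) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  d <- pmax(e$values, floor)
  M <- e$vectors %*% (d * t(e$vectors))
  s <- sqrt(diag(M))
  M <- M / tcrossprod(s)
  dimnames(M) <- dimnames(C)
  (M + t(M)) / 2
}

# factor A with A %*% t(A) ~= R (eigen clip; tolerates semi-definite R).
# After clipping negative eigenvalues the rows are rescaled so the diagonal
# of A A' matches diag(R) exactly: planted variances (hence locus h2) take
# priority over off-diagonal fidelity, which the clip perturbs only slightly.
chol_psd <- function(R, floor = 0) {
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  d <- pmax(e$values, floor)
  A <- e$vectors %*% diag(sqrt(d), length(d))
  v <- rowSums(A^2)
  target <- pmax(diag(R), 0)
  s <- ifelse(v > 0, sqrt(target / v), 0)
  A * s
}

#' Simulate the phenotype table
#'
#' Builds line-level trait values from the planted QTL (each line receives
#' the mean of its two founders' trait means at the causal marker, so
#' heterozygote effects are additive), adds a multivariate Gaussian residual
#' whose covariance is chosen so that (i) each planted locus explains its
#' specified `h2` of the trait's line-level variance in expectation and (ii)
#' the full trait suite attains the target phenotypic correlation matrix,
#' then adds independent replicate-level noise and missing-at-random
#' masking. Ordinal traits (SM) are thresholded to a right-skewed 0-4 score.
#'
#' @param mosaics List of mosaic genomes.
#' @param founders A [founder_set()] (supplies the map and founder count).
#' @param qtls List of [qtl_spec()]; traits may carry several QTL, whose
#'   variance fractions then add.
#' @param trait_model As [default_trait_model()].
#' @param n_reps Replicates per line (default 2).
#' @param missing_rate Per-cell missing probability (default 0.0219).
#' @param rep_noise_frac Fraction of the non-QTL variance attributed to
#'   replicate-level noise (after averaging `n_reps` replicates).
#' @param seed Optional integer seed.
#' @return `data.frame` with columns `line_id`, `rep`, then one column per
#'   trait; attribute `truth` holds the planted genetic values and specs.
#' @export
simulate_phenotypes <- function(mosaics, founders, qtls = NULL,
                                trait_model = default_trait_model(),
                                n_reps = 2, missing_rate = 0.0219,
                                rep_noise_frac = 0.25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  map <- attr(founders, "map")
  S <- ncol(founders)
  n <- length(mosaics)
  tr <- trait_model$traits
  Tn <- length(tr)
  if (is.null(qtls)) qtls <- default_qtl_specs(map)

  for (q in qtls) {
    if (!q$marker %in% map$marker) {
      stop("QTL marker not in map: ", q$marker)
    }
    if (length(q$founder_means) != S) {
      stop("founder_means for ", q$trait, " must have length ", S)
    }
    if (!q$trait %in% tr) stop("QTL trait not in trait suite: ", q$trait)
  }

  # founder of origin per homolog at each QTL marker
  qmark <- unique(vapply(qtls, `[[`, "", "marker"))
  qrow <- match(qmark, map$marker)
  assign1 <- assign2 <- matrix(0L, n, length(qmark),
                               dimnames = list(names(mosaics), qmark))
  for (k in seq_along(qmark)) {
    ch <- map$chrom[qrow[k]]; pos <- map$cM[qrow[k]]
    for (i in seq_len(n)) {
      assign1[i, k] <- founder_at(mosaics[[i]][[ch]]$h1, pos)
      assign2[i, k] <- founder_at(mosaics[[i]][[ch]]$h2, pos)
    }
  }

  # genetic values and line-level target variances
  G <- matrix(0, n, Tn, dimnames = list(names(mosaics), tr))
  base <- ifelse(tr %in% vapply(qtls, `[[`, "", "trait"), 0,
                 trait_model$means[tr])
  names(base) <- tr
  V <- trait_model$sds[tr]^2
  by_trait <- split(qtls, vapply(qtls, `[[`, "", "trait"))
  for (trait in names(by_trait)) {
    specs <- by_trait[[trait]]
    var_mu <- vapply(specs, function(q)
      mean((q$founder_means - mean(q$founder_means))^2), numeric(1))
    h2 <- vapply(specs, `[[`, numeric(1), "h2")
    if (sum(h2) >= 1) stop("total h2 for trait ", trait, " must be < 1")
    Vt <- sum(var_mu) / sum(h2)   # implied total line-level variance
    V[trait] <- Vt
    g <- numeric(n); lev <- 0
    for (j in seq_along(specs)) {
      q <- specs[[j]]
      k <- match(q$marker, qmark)
      raw <- (q$founder_means[assign1[, k]] +
                q$founder_means[assign2[, k]]) / 2
      cj <- sqrt(h2[j] * Vt / var_mu[j])
      g <- g + (raw - mean(q$founder_means)) * cj
      lev <- lev + mean(q$founder_means)
    }
    G[, trait] <- g
    base[trait] <- lev
  }

  # Line-level (replicate-averaged scale) values. QTL traits: genetic value
  # plus a residual whose covariance tops the realized genetic covariance up
  # to the target total covariance (so each locus explains its h2 and the
  # QTL-trait block attains its target correlations). Companion traits:
  # conditional Gaussian copula on the standardized realized QTL traits, so
  # companion-QTL correlations (e.g. FLS-GS39) hit their targets directly.
  C <- trait_model$corr[tr, tr]
  qtl_traits <- intersect(tr, names(by_trait))
  cmp <- setdiff(tr, qtl_traits)
  U <- matrix(0, n, Tn, dimnames = list(names(mosaics), tr))
  if (length(qtl_traits)) {
    iq <- match(qtl_traits, tr)
    Dq <- diag(sqrt(V[qtl_traits]), length(iq))
    Ct_qq <- Dq %*% C[iq, iq, drop = FALSE] %*% Dq
    Gq <- G[, qtl_traits, drop = FALSE]
    Sg <- crossprod(scale(Gq, scale = FALSE)) / (n - 1)
    # residual covariance: off-diagonals top the realized genetic covariance
    # up to the target totals; diagonals are the fixed non-QTL variance
    # V (1 - sum h2), so the noise-free limit is exact as h2 -> 1
    Rq <- Ct_qq - Sg
    h2_tot <- vapply(qtl_traits, function(trn)
      sum(vapply(by_trait[[trn]], `[[`, numeric(1), "h2")), numeric(1))
    diag(Rq) <- V[qtl_traits] * (1 - h2_tot)
    Aq <- chol_psd(Rq)
    Eq <- matrix(rnorm(n * length(iq)), n) %*% t(Aq)
    U[, qtl_traits] <- sweep(Gq + Eq, 2, base[qtl_traits], "+")
  }
  if (length(cmp)) {
    ic <- match(cmp, tr)
    if (length(qtl_traits)) {
      iq <- match(qtl_traits, tr)
      Zq <- scale(U[, qtl_traits, drop = FALSE])
      B <- C[ic, iq, drop = FALSE] %*% solve(C[iq, iq, drop = FALSE])
      Sig <- C[ic, ic, drop = FALSE] -
        B %*% C[iq, ic, drop = FALSE]
      Zc <- Zq %*% t(B) +
        matrix(rnorm(n * length(ic)), n) %*% t(chol_psd(Sig))
    } else {
      Zc <- matrix(rnorm(n * length(ic)), n) %*%
        t(chol_psd(C[ic, ic, drop = FALSE]))
    }
    Zc <- scale(Zc)
    U[, cmp] <- sweep(sweep(Zc, 2, sqrt(V[cmp]), "*"), 2, base[cmp], "+")
  }

  # replicates around the line value: noise contrasts are centred per line
  # so the replicate mean reproduces U exactly and the replicate-averaged
  # scale carries the planted variances, correlations and h2
  rep_sd <- sqrt(rep_noise_frac * V * n_reps)
  eta <- array(rnorm(n * Tn * n_reps), c(n, Tn, n_reps))
  eta <- sweep(eta, c(1, 2), apply(eta, c(1, 2), mean))
  out <- do.call(rbind, lapply(seq_len(n_reps), function(r) {
    Y <- U + sweep(matrix(eta[, , r], n, Tn), 2, rep_sd, "*")
    data.frame(line_id = names(mosaics), rep = r, Y,
               check.names = FALSE, stringsAsFactors = FALSE)
  }))
  colnames(out) <- c("line_id", "rep", tr)
  L <- U

  # ordinal stress score: threshold the latent to a right-skewed 0-4 scale
  for (o in intersect(trait_model$ordinal, tr)) {
    z <- (out[[o]] - trait_model$means[o]) / trait_model$sds[o]
    cuts <- qnorm(c(0.45, 0.75, 0.90, 0.97))
    out[[o]] <- findInterval(z, cuts)
  }

  if (missing_rate > 0) {
    cells <- as.matrix(out[, tr])
    cells[matrix(runif(length(cells)), nrow(cells)) < missing_rate] <- NA
    out[, tr] <- cells
  }
  out <- out[order(out$line_id, out$rep), ]
  rownames(out) <- NULL
  structure(out, truth = list(qtls = qtls, genetic_values = G,
                              line_values = L, base = base, var_line = V))
}
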