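#' Permutation null distribution of the genome-wide maximum scan statistic
#'
#' Permutes the phenotype between lines (breaking the line-genotype link
#' only; covariates, if any, travel with the phenotype as a unit), repeats
#' the whole-genome scan, and records the maximum -log10 p per permutation.
#' The upper 95% quantile of `max_scores` is the genome-wide 5% significance
#' threshold.
#'
#' @param y Phenotype vector aligned to the lines of `FP`.
#' @param FP A `founder_probs` array.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Optional integer seed governing the permutation order.
#' @param covariates Optional covariate matrix permuted jointly with `y`.
#' @return Object of class `permutation_null`: list with `max_scores`
#'   (length `n_perm`), `n_perm`, `seed`, and `threshold_95`.
#' @export
permutation_null <- function(y, FP, n_perm = 1000, seed = NULL,
                             covariates = NULL) {
  stopifnot(n_perm >= 1)
  if (!is.null(seed)) set.seed(seed)
  keep <- !is.na(y)
  yk <- y[keep]
  n <- sum(keep)
  if (is.null(covariates)) {
    eng <- scan_engine(FP, keep = keep)
    P <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
    Y <- matrix(yk[P], n, n_perm)
    st <- engine_scan(eng, Y)
    max_scores <- apply(st$neg_log10_p, 2, max)
  } else {
    C <- as.matrix(covariates)[keep, , drop = FALSE]
    max_scores <- vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      sc <- genome_scan(yk[p], subset_lines(FP, keep),
                        covariates = C[p, , drop = FALSE], effects = FALSE)
      max(sc$neg_log10_p)
    }, numeric(1))
  }
  structure(list(max_scores = max_scores, n_perm = n_perm, seed = seed,
                 threshold_95 = unname(quantile(max_scores, 0.95,
                                                type = 7))),
            class = "permutation_null")
}

# restrict a founder_probs array to a subset of lines
subset_lines <- function(FP, keep) {
  out <- FP[keep, , , drop = FALSE]
  attributes(out) <- c(attributes(out)[c("dim", "dimnames")],
                       attributes(FP)[c("map", "founder_names", "params")])
  class(out) <- "founder_probs"
  out
}

#' Empirical genome-wide p-value
#'
#' Add-one estimator `p = (r + 1) / (n_perm + 1)` where r counts null maxima
#' at or above the observed maximum; never returns 0.
#'
#' @param observed_max Observed genome-wide maximum -log10 p.
#' @param null A [permutation_null()].
#' @return Empirical p-value in (0, 1].
#' @export
empirical_pvalue <- function(observed_max, null) {
  stopifnot(length(null$max_scores) >= 1)
  r <- sum(null$max_scores >= observed_max)
  (r + 1) / (null$n_perm + 1)
}

#' Storey q-values with smoother pi0 estimate
#'
#' Estimates the null proportion pi0 by the smoother method (natural cubic
#' smoothing spline of pi0(lambda) over lambda = 0.05, ..., 0.95, evaluated
#' at the largest lambda, capped to (0, 1]), then applies the step-up
#' construction `q_(i) = min_{j >= i} pi0 m p_(j) / j`. On short p-vectors
#' (< 100) or if the smoother fails, pi0 falls back conservatively to 1
#' (Benjamini-Hochberg-equivalent), with a message.
#'
#' @param pvals Vector of p-values in `[0, 1]`.
#' @return Object of class `fdr_result`: list with `qvalues` (input order),
#'   `pi0`, and `p_at_q05`, the p-value corresponding to q = 0.05 by linear
#'   interpolation on the sorted (p, q) pairs (`NA` when no q-value is below
#'   0.05).
#' @export
qvalues <- function(pvals) {
  if (length(pvals) == 0) stop("empty p-value vector")
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must be in [0, 1] and non-missing")
  }
  m <- length(pvals)
  lambda <- seq(0.05, 0.95, by = 0.05)
  pi0 <- 1
  if (m >= 100) {
    pi0_l <- vapply(lambda, function(l) mean(pvals > l) / (1 - l), numeric(1))
    fit <- try(smooth.spline(lambda, pi0_l, df = 3), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      pi0 <- predict(fit, x = max(lambda))$y
      pi0 <- min(max(pi0, 1e-8), 1)
    } else {
      message("pi0 smoother failed; using conservative pi0 = 1")
    }
  }
  o <- order(pvals)
  p_sorted <- pvals[o]
  q_sorted <- pi0 * m * p_sorted / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  p_at_q05 <- NA_real_
  if (min(q_sorted) <= 0.05) {
    below <- q_sorted <= 0.05
    i <- max(which(below))
    if (i == m || q_sorted[i] == 0.05) {
      p_at_q05 <- p_sorted[i]
    } else {
      # interpolate between the last q <= 0.05 and the first above
      q1 <- q_sorted[i]; q2 <- q_sorted[i + 1]
      p1 <- p_sorted[i]; p2 <- p_sorted[i + 1]
      p_at_q05 <- if (q2 > q1) p1 + (0.05 - q1) * (p2 - p1) / (q2 - q1)
                  else p1
    }
  }
  structure(list(qvalues = q, pi0 = pi0, p_at_q05 = p_at_q05),
            class = "fdr_result")
}

#' Call QTL regions from a scan
#'
#' Reports markers exceeding the -log10 p threshold (default 4) and, when an
#' FDR result is supplied, with q <= `q_threshold`. Contiguous
#' super-threshold markers on one chromosome are grouped into a single QTL
#' region (runs may bridge one sub-threshold gap marker, so a few close
#' peaks read as one QTL), and each region reports its peak marker.
#'
#' @param scan A `scan_result`.
#' @param threshold_logp Entry threshold on -log10 p (default 4).
#' @param fdr Optional [qvalues()] result aligned to the scan rows.
#' @param q_threshold q-value cut-off (default 0.05).
#' @return `data.frame` with one row per QTL region: chrom, peak marker and
#'   position, peak -log10 p, var_explained, region bounds in cM and marker
#'   count; zero rows when nothing passes.
#' @export
call_qtls <- function(scan, threshold_logp = 4, fdr = NULL,
                      q_threshold = 0.05) {
  hit <- scan$neg_log10_p >= threshold_logp
  if (!is.null(fdr)) {
    if (length(fdr$qvalues) != nrow(scan)) {
      stop("fdr result not aligned to scan rows")
    }
    hit <- hit & fdr$qvalues <= q_threshold
  }
  empty <- data.frame(chrom = character(0), marker = character(0),
                      cM = numeric(0), neg_log10_p = numeric(0),
                      var_explained = numeric(0), start_cM = numeric(0),
                      end_cM = numeric(0), n_markers = integer(0),
                      stringsAsFactors = FALSE)
  if (!any(hit)) return(empty)
  out <- list()
  for (ch in unique(scan$chrom[hit])) {
    j <- which(scan$chrom == ch)
    h <- hit[j]
    idx <- which(h)
    # group contiguous hits, bridging a single sub-threshold gap marker
    grp <- cumsum(c(1, diff(idx) > 2))
    for (g in unique(grp)) {
      members <- j[idx[grp == g]]
      peak <- members[which.max(scan$neg_log10_p[members])]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, marker = scan$marker[peak], cM = scan$cM[peak],
        neg_log10_p = scan$neg_log10_p[peak],
        var_explained = scan$var_explained[peak],
        start_cM = min(scan$cM[members]), end_cM = max(scan$cM[members]),
        n_markers = length(members), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$chrom, unique(scan$chrom)), res$cM), ]
  rownames(res) <- NULL
  res
}
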