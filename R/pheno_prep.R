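#' Derive phenology interval traits
#'
#' Appends the developmental interval traits to a phenotype table:
#' d1 = GS55 - GS39 (flag leaf to ear emergence), d2 = GS65 - GS55 (ear
#' emergence to anthesis), d3 = FLS - GS55 (ear emergence to onset of flag
#' leaf senescence), all in days. Missing operands propagate. Negative
#' intervals (possible scoring errors) are kept but recorded in the
#' attribute `qc_log`.
#'
#' @param table Phenotype `data.frame` containing GS39, GS55, GS65, FLS.
#' @return The table with columns d1, d2, d3 appended and a `qc_log`
#'   character attribute.
#' @export
derive_intervals <- function(table) {
  need <- c("GS39", "GS55", "GS65", "FLS")
  miss <- setdiff(need, colnames(table))
  if (length(miss)) stop("missing growth-stage column(s): ",
                         paste(miss, collapse = ", "))
  table$d1 <- table$GS55 - table$GS39
  table$d2 <- table$GS65 - table$GS55
  table$d3 <- table$FLS - table$GS55
  qc <- character(0)
  for (d in c("d1", "d2", "d3")) {
    neg <- which(!is.na(table[[d]]) & table[[d]] < 0)
    if (length(neg)) {
      qc <- c(qc, paste0(d, " negative in ", length(neg), " row(s): ",
                         paste(head(neg, 10), collapse = ", ")))
    }
  }
  attr(table, "qc_log") <- qc
  table
}

#' Chained-equation multiple imputation
#'
#' Imputes missing numeric cells by chained equations: each incomplete
#' column is regressed on all other columns of the current completed table
#' and its missing entries replaced by the prediction plus a Gaussian draw
#' at the residual standard deviation; sweeps iterate to stabilisation.
#' The procedure runs `m` times with independent draws and the completed
#' tables are combined by per-cell averaging. Observed cells are never
#' altered. Assumes missing-at-random missingness.
#'
#' @param table `data.frame`; non-numeric columns (e.g. `line_id`, `rep`)
#'   are carried through untouched.
#' @param m Number of imputations (default 5).
#' @param n_iter Chained-equation sweeps per imputation (default 10).
#' @param seed Optional integer seed.
#' @return The completed table, with attribute `imputation` (list: `m`,
#'   `n_missing`, `missing_rate`, `columns` imputed).
#' @export
mice_impute <- function(table, m = 5, n_iter = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  num <- vapply(table, is.numeric, logical(1))
  num[names(num) == "rep"] <- FALSE
  X <- as.matrix(table[, num, drop = FALSE])
  na_mask <- is.na(X)
  if (!any(na_mask)) {
    attr(table, "imputation") <- list(m = m, n_missing = 0L,
                                      missing_rate = 0, columns = character(0))
    return(table)
  }
  all_missing <- colnames(X)[colSums(!na_mask) == 0]
  if (length(all_missing)) {
    stop("column(s) entirely missing, cannot impute: ",
         paste(all_missing, collapse = ", "))
  }
  heavy <- colnames(X)[colMeans(na_mask) > 0.5]
  if (length(heavy)) {
    warning("column(s) more than 50% missing: ",
            paste(heavy, collapse = ", "))
  }
  incomplete <- which(colSums(na_mask) > 0)
  acc <- matrix(0, nrow(X), ncol(X))
  for (imp in seq_len(m)) {
    Z <- X
    for (j in seq_len(ncol(Z))) {       # initialise at column means
      Z[na_mask[, j], j] <- mean(X[, j], na.rm = TRUE)
    }
    for (it in seq_len(n_iter)) {
      for (j in incomplete) {
        obs <- !na_mask[, j]
        D <- cbind(1, Z[, -j, drop = FALSE])
        fit <- qr(D[obs, , drop = FALSE])
        beta <- qr.coef(fit, X[obs, j])
        beta[is.na(beta)] <- 0          # aliased predictors drop out
        res <- X[obs, j] - D[obs, , drop = FALSE] %*% beta
        sdr <- sqrt(sum(res^2) / max(1, sum(obs) - fit$rank))
        pred <- D[!obs, , drop = FALSE] %*% beta
        Z[!obs, j] <- pred + rnorm(sum(!obs), 0, sdr)
      }
    }
    acc <- acc + Z
  }
  filled <- acc / m
  filled[!na_mask] <- X[!na_mask]
  out <- table
  out[, num] <- as.data.frame(filled)
  attr(out, "imputation") <- list(
    m = m, n_missing = sum(na_mask), missing_rate = mean(na_mask),
    columns = colnames(X)[incomplete])
  out
}

#' Average replicates to line-level phenotypes
#'
#' @param table Phenotype table with `line_id` and `rep` columns.
#' @return One row per line; trait cells are means over non-missing
#'   replicates.
#' @export
average_replicates <- function(table) {
  stopifnot("line_id" %in% colnames(table))
  traits <- setdiff(colnames(table), c("line_id", "rep"))
  agg <- aggregate(table[traits], by = list(line_id = table$line_id),
                   FUN = function(v) if (all(is.na(v))) NA_real_
                                     else mean(v, na.rm = TRUE))
  agg[order(agg$line_id), , drop = FALSE]
}

#' Pairwise-complete trait correlation matrix
#'
#' @param table Line-level phenotype table (trait columns only are used).
#' @param min_pairs Minimum complete pairs required per trait pair.
#' @return Symmetric Pearson correlation matrix with unit diagonal;
#'   pairs with fewer than `min_pairs` complete observations, or involving
#'   a constant column, are `NA`.
#' @export
correlation_matrix <- function(table, min_pairs = 3) {
  num <- vapply(table, is.numeric, logical(1))
  num[names(num) == "rep"] <- FALSE
  X <- as.matrix(table[, num, drop = FALSE])
  suppressWarnings(R <- cor(X, use = "pairwise.complete.obs"))
  cnt <- crossprod(!is.na(X))
  R[cnt < min_pairs] <- NA
  diag(R) <- 1
  R
}

#' Trait PCA on unit-variance-scaled data
#'
#' @param table Complete (post-imputation) line-level phenotype table.
#' @return List with `scores` (lines x PCs), `loadings` (traits x PCs) and
#'   `var_frac` per component (summing to 1).
#' @export
trait_pca <- function(table) {
  num <- vapply(table, is.numeric, logical(1))
  num[names(num) == "rep"] <- FALSE
  X <- as.matrix(table[, num, drop = FALSE])
  if (ncol(X) < 2) stop("need at least 2 traits for PCA")
  if (any(is.na(X))) stop("trait PCA requires a complete table; impute first")
  sdv <- apply(X, 2, sd)
  X <- X[, sdv > 0, drop = FALSE]
  p <- prcomp(X, center = TRUE, scale. = TRUE)
  vf <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x, loadings = p$rotation, var_frac = vf)
}

#' Marker-based kinship matrix and structure PCA
#'
#' VanRaden genomic relationship matrix from 0/1/2 genotypes: columns are
#' centred at twice the allele frequency and the cross-product scaled by
#' `2 * sum(p (1 - p))`. The leading eigenvalue fraction of the spectrum is
#' the population-structure statistic: an unstructured MAGIC population
#' shows no dominant component (PC1 well under a few percent of the
#' spectrum).
#'
#' @param genotypes Lines x markers 0/1/2 matrix (`NA` tolerated: mean
#'   imputed per marker for the purpose of the kinship estimate).
#' @return Object of class `kinship_pca`: list with `A` (n x n), `values`,
#'   `vectors`, `var_frac`, `pc1_frac`.
#' @export
kinship_pca <- function(genotypes) {
  X <- as.matrix(genotypes)
  p_hat <- colMeans(X, na.rm = TRUE) / 2
  poly <- p_hat > 0 & p_hat < 1 & !is.na(p_hat)
  if (!any(poly)) stop("no polymorphic markers: kinship undefined")
  X <- X[, poly, drop = FALSE]
  p_hat <- p_hat[poly]
  M <- sweep(X, 2, 2 * p_hat)
  if (anyNA(M)) M[is.na(M)] <- 0   # centred mean-imputation of missing calls
  A <- tcrossprod(M) / (2 * sum(p_hat * (1 - p_hat)))
  e <- eigen(A, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vf <- vals / sum(vals)
  structure(list(A = A, values = e$values, vectors = e$vectors,
                 var_frac = vf, pc1_frac = vf[1]),
            class = "kinship_pca")
}

#' Multiple linear regression screen for FLS predictors
#'
#' Ordinary least squares of the senescence-onset trait on the other traits
#' of the (complete, line-level) table, with per-coefficient t-tests.
#' Note that the derived interval d3 = FLS - GS55 contains the response
#' arithmetically; the default keeps it in the predictor set (flagging the
#' circularity in the QC log) and `exclude_derived = TRUE` gives the
#' stricter model without d1/d2/d3. Perfectly collinear predictors are
#' dropped with a warning.
#'
#' @param table Complete line-level phenotype table.
#' @param response Response trait (default `"FLS"`).
#' @param exclude_derived Drop d1/d2/d3 from the predictors.
#' @param alpha Significance level for flagging predictors (default 0.05).
#' @return Object of class `mlrm_result`: `coefficients` data.frame
#'   (estimate, std_error, t_value, p_value per predictor), `significant`
#'   predictor names, `qc_log`.
#' @export
mlrm_fls <- function(table, response = "FLS", exclude_derived = FALSE,
                     alpha = 0.05) {
  num <- vapply(table, is.numeric, logical(1))
  num[names(num) == "rep"] <- FALSE
  X <- as.data.frame(table[, num, drop = FALSE])
  if (!response %in% colnames(X)) stop("response not in table: ", response)
  preds <- setdiff(colnames(X), response)
  qc <- character(0)
  if (exclude_derived) {
    preds <- setdiff(preds, c("d1", "d2", "d3"))
  } else if ("d3" %in% preds) {
    qc <- c(qc, paste0("d3 is an arithmetic function of ", response,
                       " (circular predictor kept by request)"))
  }
  if (any(is.na(X[, c(response, preds)]))) {
    stop("MLRM requires complete data; impute first")
  }
  if (nrow(X) <= length(preds) + 1) {
    stop("n (", nrow(X), ") too small for ", length(preds),
         " predictors; reduce the predictor set or regularise")
  }
  fml <- reformulate(sprintf("`%s`", preds), response = sprintf("`%s`", response))
  fit <- lm(fml, data = X)
  ali <- is.na(coef(fit))
  if (any(ali)) {
    warning("collinear predictor(s) dropped: ",
            paste(names(coef(fit))[ali], collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  cf <- data.frame(predictor = rownames(sm), estimate = sm[, 1],
                   std_error = sm[, 2], t_value = sm[, 3],
                   p_value = sm[, 4], row.names = NULL,
                   stringsAsFactors = FALSE)
  cf$predictor <- gsub("`", "", cf$predictor)
  sig <- cf$predictor[cf$p_value < alpha & cf$predictor != "(Intercept)"]
  structure(list(coefficients = cf, significant = sig, qc_log = qc,
                 r_squared = summary(fit)$r.squared),
            class = "mlrm_result")
}

#' Flag outlying trait values
#'
#' Values more than `k` standard deviations from their trait mean are
#' reported, never altered (manual curation is not reproducible in code).
#'
#' @param table Phenotype table.
#' @param k SD multiple (default 4).
#' @return `data.frame` of flagged cells: row, trait, value, z.
#' @export
flag_outliers <- function(table, k = 4) {
  num <- vapply(table, is.numeric, logical(1))
  num[names(num) == "rep"] <- FALSE
  out <- list()
  for (tr in colnames(table)[num]) {
    v <- table[[tr]]
    mu <- mean(v, na.rm = TRUE); sdv <- sd(v, na.rm = TRUE)
    if (is.na(sdv) || sdv == 0) next
    z <- (v - mu) / sdv
    bad <- which(!is.na(z) & abs(z) > k)
    if (length(bad)) {
      out[[length(out) + 1]] <- data.frame(row = bad, trait = tr,
                                           value = v[bad], z = z[bad])
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(row = integer(0), trait = character(0),
                  value = numeric(0), z = numeric(0))
}
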