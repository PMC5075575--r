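#' Conditional (composite) genome scan
#'
#' Re-scans the genome with the additive founder-dosage blocks of selected
#' covariate markers absorbed into both the null and the locus model, so
#' that association signal explained by the covariates is removed. Loci
#' within `exclusion_cM` of a covariate marker are flagged in the result
#' (column `near_covariate`) since their conditional signal is dominated by
#' the covariate itself.
#'
#' @param y Phenotype vector aligned to the lines of `FP`.
#' @param FP A `founder_probs` array.
#' @param covariate_markers Character vector of marker ids to condition on.
#' @param exclusion_cM Window around covariates flagged as self-conditioned
#'   (default 10 cM).
#' @param effects Passed to [genome_scan()].
#' @return A `scan_result` with the extra logical column `near_covariate`.
#' @export
conditional_scan <- function(y, FP, covariate_markers, exclusion_cM = 10,
                             effects = FALSE) {
  map <- attr(FP, "map")
  miss <- setdiff(covariate_markers, map$marker)
  if (length(miss)) stop("covariate marker(s) not mapped: ",
                         paste(miss, collapse = ", "))
  C <- covariate_block(FP, covariate_markers)
  sc <- genome_scan(y, FP, covariates = C, effects = effects)
  near <- rep(FALSE, nrow(map))
  for (mk in covariate_markers) {
    i <- match(mk, map$marker)
    near <- near | (map$chrom == map$chrom[i] &
                      abs(map$cM - map$cM[i]) <= exclusion_cM)
  }
  sc$near_covariate <- near
  sc
}

# stacked additive dosage blocks of the given markers (first founder column
# of each block dropped: it is implied by the intercept + remaining columns)
covariate_block <- function(FP, markers) {
  if (!length(markers)) return(NULL)
  do.call(cbind, lapply(markers, function(mk) {
    X <- additive_design(FP, mk)
    colnames(X) <- paste0(mk, ".", colnames(X))
    X[, -1, drop = FALSE]
  }))
}

#' Forward selection of marker covariates
#'
#' Multiple-QTL modelling by iterative conditional scanning: at each step
#' the genome is scanned conditional on the current covariate set and the
#' top-scoring marker joins the set if its conditional -log10 p reaches the
#' entry threshold (default 4, the same threshold used for single-locus QTL
#' calling). Selection stops at `max_covariates` or when no marker
#' qualifies. A candidate whose dosage block adds no rank to the model
#' (collinear with what is already selected) is skipped with a warning and
#' the next-best marker is considered.
#'
#' @param y Phenotype vector aligned to the lines of `FP`.
#' @param FP A `founder_probs` array.
#' @param max_covariates Maximum number of selected markers (default 10).
#' @param entry_threshold_logp Conditional -log10 p required for entry
#'   (default 4).
#' @return Object of class `covariate_model`: list with `selected`
#'   (data.frame: marker, chrom, cM, entry_logp, entry_f, step, rss),
#'   `scan` (the final conditional scan), and `trace` of per-step scans'
#'   maxima.
#' @export
forward_select <- function(y, FP, max_covariates = 10,
                           entry_threshold_logp = 4) {
  stopifnot(max_covariates >= 0)
  map <- attr(FP, "map")
  keep <- !is.na(y)
  selected <- character(0)
  rows <- list()
  trace <- list()
  step <- 0L
  while (length(selected) < max_covariates) {
    C <- covariate_block(FP, selected)
    sc <- genome_scan(y, FP, covariates = C, effects = FALSE)
    step <- step + 1L
    trace[[step]] <- data.frame(step = step,
                                top_marker = sc$marker[which.max(sc$neg_log10_p)],
                                top_logp = max(sc$neg_log10_p))
    ord <- order(sc$neg_log10_p, decreasing = TRUE)
    entered <- FALSE
    for (cand in ord) {
      if (sc$neg_log10_p[cand] < entry_threshold_logp) break
      mk <- sc$marker[cand]
      if (mk %in% selected) next
      Xc <- covariate_block(FP, c(selected, mk))[keep, , drop = FALSE]
      r_new <- qr(cbind(1, Xc))$rank
      r_old <- qr(cbind(1, if (is.null(C)) NULL
                        else C[keep, , drop = FALSE]))$rank
      if (r_new <= r_old) {
        warning("marker ", mk, " collinear with selected covariates; skipped")
        next
      }
      selected <- c(selected, mk)
      i <- match(mk, map$marker)
      rss <- sum(qr.resid(qr(cbind(1, Xc)), y[keep])^2)
      rows[[length(rows) + 1]] <- data.frame(
        marker = mk, chrom = map$chrom[i], cM = map$cM[i],
        entry_logp = sc$neg_log10_p[cand], entry_f = sc$f_stat[cand],
        step = step, rss = rss, stringsAsFactors = FALSE)
      entered <- TRUE
      break
    }
    if (!entered) break
  }
  final <- if (length(selected)) {
    conditional_scan(y, FP, selected)
  } else {
    genome_scan(y, FP, effects = FALSE)
  }
  structure(list(
    selected = if (length(rows)) do.call(rbind, rows)
               else data.frame(marker = character(0), chrom = character(0),
                               cM = numeric(0), entry_logp = numeric(0),
                               entry_f = numeric(0), step = integer(0),
                               rss = numeric(0)),
    scan = final, trace = do.call(rbind, trace)),
    class = "covariate_model")
}
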