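#' Planted-QTL parameter recovery experiment
#'
#' Repeatedly simulates a MAGIC population with the given planted QTL,
#' reconstructs founder probabilities, scans each planted trait, and
#' records the founder effect estimates and locus variance explained at the
#' genome-wide top marker of each replicate, together with the map distance
#' between the top marker and the planted locus. This is the protocol used
#' to verify that the haplotype-regression scan recovers planted founder
#' means and locus heritabilities.
#'
#' @param qtls List of [qtl_spec()] to plant (their traits are scanned).
#' @param n_sim Number of replicate simulated populations (default 100).
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param map Genetic map (default [regular_map()]: 3 x 100 markers).
#' @param n_lines RILs per population (default 208).
#' @param trait_model Trait suite model.
#' @param geno_error,geno_missing,pheno_missing Generator noise rates.
#' @return `data.frame` with one row per replicate x trait: `sim`, `trait`,
#'   `top_marker`, `dist_cM` (top to planted locus), `neg_log10_p`,
#'   `var_explained`, and one effect column per founder.
#' @export
qtl_recovery_experiment <- function(qtls, n_sim = 100, seed = 1,
                                    map = regular_map(), n_lines = 208,
                                    trait_model = default_trait_model(),
                                    geno_error = 0.001,
                                    geno_missing = 0.0219,
                                    pheno_missing = 0.0219) {
  traits <- vapply(qtls, `[[`, "", "trait")
  planted <- match(vapply(qtls, `[[`, "", "marker"), map$marker)
  rows <- vector("list", n_sim * length(qtls))
  k <- 0L
  for (r in seq_len(n_sim)) {
    set.seed(seed + r)
    founders <- simulate_founders(map, 8, 0.5,
                                  seed = sample.int(2^30, 1))
    mosaics <- simulate_mosaics(map, n_lines)
    genotypes <- emit_genotypes(mosaics, founders, geno_error, geno_missing)
    phenos <- simulate_phenotypes(mosaics, founders, qtls, trait_model,
                                  n_reps = 2, missing_rate = pheno_missing)
    line_means <- average_replicates(phenos)
    FP <- infer_founder_probs(genotypes, founders)
    for (qi in seq_along(qtls)) {
      sc <- genome_scan(line_means[[traits[qi]]], FP)
      top <- which.max(sc$neg_log10_p)
      same_chr <- sc$chrom[top] == map$chrom[planted[qi]]
      k <- k + 1L
      rows[[k]] <- data.frame(
        sim = r, trait = traits[qi], top_marker = sc$marker[top],
        dist_cM = if (same_chr) abs(sc$cM[top] - map$cM[planted[qi]])
                  else Inf,
        neg_log10_p = sc$neg_log10_p[top],
        var_explained = sc$var_explained[top],
        sc[top, attr(FP, "founder_names"), drop = FALSE],
        stringsAsFactors = FALSE, check.names = FALSE, row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

#' Summarise a recovery experiment against planted values
#'
#' @param rec Output of [qtl_recovery_experiment()].
#' @param qtls The planted [qtl_spec()] list.
#' @param founder_names Founder order of the effect columns.
#' @return `data.frame` per trait x founder: planted mean, mean recovered
#'   effect, Monte-Carlo standard error of the mean, plus the planted and
#'   mean recovered `h2` rows (`founder = "(h2)"`).
#' @export
summarise_recovery <- function(rec, qtls,
                               founder_names = magic_founder_names()) {
  out <- list()
  for (q in qtls) {
    d <- rec[rec$trait == q$trait, , drop = FALSE]
    for (s in seq_along(founder_names)) {
      est <- d[[founder_names[s]]]
      out[[length(out) + 1]] <- data.frame(
        trait = q$trait, founder = founder_names[s],
        planted = q$founder_means[s], mean_recovered = mean(est),
        mc_se = sd(est) / sqrt(length(est)), stringsAsFactors = FALSE)
    }
    out[[length(out) + 1]] <- data.frame(
      trait = q$trait, founder = "(h2)", planted = q$h2,
      mean_recovered = mean(d$var_explained),
      mc_se = sd(d$var_explained) / sqrt(nrow(d)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Permutation threshold type-I error calibration
#'
#' Draws `n_datasets` null phenotypes on one simulated population, computes
#' each dataset's genome-wide 95% permutation threshold from its own
#' `n_perm` permutations, and reports the fraction of datasets whose
#' observed genome-wide maximum exceeds their threshold — the realised
#' family-wise type-I error of the permutation procedure (nominally 5%).
#'
#' @param FP A `founder_probs` array (one population's reconstruction).
#' @param n_datasets Number of independent null phenotype draws.
#' @param n_perm Permutations per dataset.
#' @param seed Integer seed.
#' @return List with `rejection_rate`, `n_datasets`, `n_perm`.
#' @export
permutation_calibration <- function(FP, n_datasets = 400, n_perm = 200,
                                    seed = 1) {
  set.seed(seed)
  n <- dim(FP)[1]
  eng <- scan_engine(FP)
  exceed <- logical(n_datasets)
  for (d in seq_len(n_datasets)) {
    y <- rnorm(n)
    P <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
    Y <- cbind(y, matrix(y[P], n, n_perm))
    st <- engine_scan(eng, Y)
    maxes <- apply(st$neg_log10_p, 2, max)
    thr <- quantile(maxes[-1], 0.95, type = 7)
    exceed[d] <- maxes[1] > thr
  }
  list(rejection_rate = mean(exceed), n_datasets = n_datasets,
       n_perm = n_perm)
}
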