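#' Simulate a complete MAGIC dataset
#'
#' One call producing map, founders, true mosaics, observed genotypes and
#' the replicated phenotype table, with planted-QTL ground truth attached.
#' Defaults are the desk-scale stand-in for the NIAB design: 208 RILs from
#' independent 8-way funnels, 3 chromosomes x 100 markers, two replicates,
#' 2.19% missingness.
#'
#' @param map A [genetic_map()] (default [regular_map()]).
#' @param n_lines Number of RILs.
#' @param n_self Selfing generations.
#' @param divergence Founder marker divergence (see [simulate_founders()]).
#' @param qtls Planted QTL list (default [default_qtl_specs()]).
#' @param trait_model Trait suite model (default [default_trait_model()]).
#' @param n_reps Phenotype replicates per line.
#' @param geno_error Genotyping error rate.
#' @param geno_missing Genotype missing rate.
#' @param pheno_missing Phenotype missing rate.
#' @param seed Integer seed (single source of randomness for the dataset).
#' @return List with `map`, `founders`, `mosaics`, `genotypes`,
#'   `phenotypes`, `qtls`.
#' @export
simulate_magic <- function(map = regular_map(), n_lines = 208, n_self = 5,
                           divergence = 0.5, qtls = default_qtl_specs(map),
                           trait_model = default_trait_model(), n_reps = 2,
                           geno_error = 0.001, geno_missing = 0.0219,
                           pheno_missing = 0.0219, seed = 1) {
  set.seed(seed)
  founders <- simulate_founders(map, 8, divergence,
                                seed = sample.int(.Machine$integer.max, 1))
  mosaics <- simulate_mosaics(map, n_lines, n_self)
  genotypes <- emit_genotypes(mosaics, founders, geno_error, geno_missing)
  phenotypes <- simulate_phenotypes(mosaics, founders, qtls, trait_model,
                                    n_reps, pheno_missing)
  list(map = map, founders = founders, mosaics = mosaics,
       genotypes = genotypes, phenotypes = phenotypes, qtls = qtls)
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run with its default: the
#' population size and map, HMM parameters, scan model, permutation count,
#' the -log10 p = 4 and q = 0.05 calling thresholds, and the imputation
#' count m = 5. Every stochastic stage draws from the single `seed`.
#'
#' @param seed Master seed.
#' @param n_lines,n_chrom,n_mark,chrom_length_cM Population and map size.
#' @param n_self Selfing generations.
#' @param divergence Founder divergence.
#' @param n_reps Phenotype replicates.
#' @param geno_error,geno_missing,pheno_missing Noise rates.
#' @param hmm_generations,hmm_error HMM transition/emission parameters.
#' @param traits Traits to scan.
#' @param n_perm Permutations per trait (0 = threshold-only calls).
#' @param threshold_logp,q_threshold QTL calling thresholds.
#' @param impute_m Imputations.
#' @param cim_max_covariates Forward-selection cap.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_lines = 208, n_chrom = 3,
                            n_mark = 100, chrom_length_cM = 100,
                            n_self = 5, divergence = 0.5, n_reps = 2,
                            geno_error = 0.001, geno_missing = 0.0219,
                            pheno_missing = 0.0219, hmm_generations = 8,
                            hmm_error = 0.01,
                            traits = c("GS39", "GS55", "SH"),
                            n_perm = 200, threshold_logp = 4,
                            q_threshold = 0.05, impute_m = 5,
                            cim_max_covariates = 10) {
  cfg <- as.list(environment())
  stopifnot(cfg$threshold_logp > 0, cfg$q_threshold > 0,
            cfg$n_perm >= 0, cfg$impute_m >= 1, length(cfg$seed) == 1)
  class(cfg) <- "pipeline_config"
  cfg
}

config_fingerprint <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(x)
    paste(format(x, digits = 15), collapse = ","), ""), sep = "=",
    collapse = ";")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(s, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' simulate -> prepare phenotypes -> infer founder probabilities -> scan ->
#' permutation significance + q-values -> QTL calls -> forward-selection
#' conditional scan -> report. Deterministic given the config: rerunning
#' with the same config writes byte-identical outputs. Artifacts are
#' written under `out_dir` with a machine-readable `manifest.json` (MD5
#' fingerprint per file).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the QTL report `data.frame`, per-trait
#'   scan results, permutation nulls, and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed [config ",
           config_fingerprint(config), "]: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  log_lines <- c(sprintf("config_fingerprint: %s", config_fingerprint(config)),
                 sprintf("%s: %s", names(config),
                         vapply(config, function(x)
                           paste(format(x), collapse = ","), "")))

  map <- regular_map(chroms = paste0("chr", seq_len(config$n_chrom)),
                     n_mark = config$n_mark,
                     length_cM = config$chrom_length_cM)
  sim <- stage("simulate", simulate_magic(
    map, n_lines = config$n_lines, n_self = config$n_self,
    divergence = config$divergence, n_reps = config$n_reps,
    geno_error = config$geno_error, geno_missing = config$geno_missing,
    pheno_missing = config$pheno_missing, seed = config$seed))
  write_map(sim$map, file.path(out_dir, "map.csv"))
  write_founders(sim$founders, file.path(out_dir, "founders.csv"))
  write_genotypes(sim$genotypes, file.path(out_dir, "genotypes.csv"))
  write_phenotypes(sim$phenotypes, file.path(out_dir, "phenotypes_raw.csv"))
  write_mosaics(sim$mosaics, file.path(out_dir, "mosaics_truth.tsv"))
  qtl_truth <- do.call(rbind, lapply(sim$qtls, function(q)
    data.frame(trait = q$trait, marker = q$marker, h2 = q$h2,
               t(q$founder_means))))
  colnames(qtl_truth)[-(1:3)] <- colnames(sim$founders)
  utils::write.table(qtl_truth, file.path(out_dir, "qtl_truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  prep <- stage("prep", {
    ph <- derive_intervals(sim$phenotypes)
    ph <- mice_impute(ph, m = config$impute_m,
                      seed = config$seed + 1000L)
    average_replicates(ph)
  })
  write_phenotypes(cbind(prep[1], rep = 1, prep[-1]),
                   file.path(out_dir, "phenotypes_prepared.csv"))
  utils::write.table(
    round(correlation_matrix(prep), 6), file.path(out_dir, "trait_corr.tsv"),
    sep = "\t", quote = FALSE)
  kp <- stage("structure", kinship_pca(sim$genotypes))
  log_lines <- c(log_lines, sprintf("kinship_pc1_frac: %.6f", kp$pc1_frac))

  FP <- stage("infer", infer_founder_probs(
    sim$genotypes, sim$founders,
    params = hmm_params(config$hmm_generations, config$hmm_error)))

  report <- list()
  scans <- list()
  nulls <- list()
  for (trait in config$traits) {
    if (!trait %in% colnames(prep)) {
      stop("pipeline stage 'scan' failed: trait absent from phenotypes: ",
           trait)
    }
    y <- prep[[trait]]
    sc <- stage("scan", genome_scan(y, FP))
    scans[[trait]] <- sc
    write_scan(sc, trait, file.path(out_dir, paste0("scan_", trait, ".tsv")))
    fdr <- qvalues(10^(-sc$neg_log10_p))
    if (config$n_perm > 0) {
      nl <- stage("perm", permutation_null(y, FP, config$n_perm,
                                           seed = config$seed + 2000L +
                                             match(trait, config$traits)))
      nulls[[trait]] <- nl
      utils::write.table(
        data.frame(perm = seq_along(nl$max_scores),
                   max_neg_log10_p = round(nl$max_scores, 6)),
        file.path(out_dir, paste0("null_", trait, ".tsv")),
        sep = "\t", row.names = FALSE, quote = FALSE)
      emp_p <- empirical_pvalue(max(sc$neg_log10_p), nl)
    } else {
      emp_p <- NA_real_
      log_lines <- c(log_lines,
                     sprintf("%s: no permutation null (n_perm = 0)", trait))
    }
    calls <- call_qtls(sc, config$threshold_logp, fdr, config$q_threshold)
    if (nrow(calls)) {
      idx <- match(calls$marker, sc$marker)
      fn <- attr(FP, "founder_names")
      rep_rows <- data.frame(Phenotype = trait, Marker = calls$marker,
                             Chr = calls$chrom, cM = calls$cM,
                             neg_logP = round(calls$neg_log10_p, 2),
                             h2 = round(calls$var_explained, 2),
                             GW_P = if (is.na(emp_p)) NA else round(emp_p, 4),
                             round(sc[idx, fn, drop = FALSE], 2),
                             check.names = FALSE)
      report[[trait]] <- rep_rows
    }
  }

  cim <- stage("cim", forward_select(prep[[config$traits[1]]], FP,
                                     max_covariates = config$cim_max_covariates,
                                     entry_threshold_logp = config$threshold_logp))
  utils::write.table(cim$selected, file.path(out_dir, "cim_selected.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  qtl_report <- if (length(report)) do.call(rbind, report)
                else data.frame()
  report_path <- file.path(out_dir, "qtl_report.tsv")
  con <- file(report_path, "w")
  writeLines(c(sprintf("# magicqtl %s",
                       as.character(utils::packageVersion("magicqtl"))),
               sprintf("# config %s", config_fingerprint(config)),
               sprintf("# seed %d", config$seed)), con)
  if (nrow(qtl_report)) {
    utils::write.table(qtl_report, con, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  close(con)
  writeLines(log_lines, file.path(out_dir, "pipeline_log.txt"))

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("magicqtl")),
    config = unclass(config),
    artifacts = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$artifacts) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(report = qtl_report, scans = scans, nulls = nulls,
                 cim = cim, kinship = kp, manifest = manifest))
}
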