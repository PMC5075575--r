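# File formats: comma-separated data files, tab-separated result files,
# UTF-8, header row required, "NA" missing sentinel, cM the only coordinate
# system. Every reader validates structure and names the offending file in
# its errors; read(write(x)) round-trips exactly for each type.

#' @rdname magic_io
#' @param map A [genetic_map()].
#' @param path File path.
#' @export
write_map <- function(map, path) {
  utils::write.csv(data.frame(marker_id = map$marker, chrom = map$chrom,
                              cM = map$cM),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write pipeline file formats
#'
#' CSV readers/writers for the genetic map (`marker_id,chrom,cM`), founder
#' haplotypes (markers x founders), RIL genotypes (lines x markers, 0/1/2,
#' `NA` sentinel) and phenotypes (`line_id,rep,<trait columns>`), plus the
#' BED-like mosaic TSV (`chrom,start_cM,end_cM,founder,homolog,line_id`).
#'
#' @name magic_io
#' @return Readers return the corresponding typed object; writers return
#'   the path invisibly.
NULL

#' @rdname magic_io
#' @export
read_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("marker_id", "chrom", "cM")
  if (!all(need %in% colnames(df))) {
    stop(path, ": malformed map header (need ", paste(need, collapse = ","), ")")
  }
  if (anyDuplicated(df$marker_id)) {
    stop(path, ": duplicated marker_id ",
         df$marker_id[duplicated(df$marker_id)][1])
  }
  genetic_map(df$marker_id, df$chrom, df$cM)
}

#' @rdname magic_io
#' @param founders A [founder_set()].
#' @export
write_founders <- function(founders, path) {
  df <- data.frame(marker_id = rownames(founders),
                   unclass(founders), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname magic_io
#' @export
read_founders <- function(path, map) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (colnames(df)[1] != "marker_id") {
    stop(path, ": malformed founder header (first column must be marker_id)")
  }
  if (!identical(df$marker_id, map$marker)) {
    bad <- setdiff(df$marker_id, map$marker)
    stop(path, ": founder markers do not match map",
         if (length(bad)) paste0(" (e.g. ", bad[1], ")"))
  }
  h <- as.matrix(df[, -1, drop = FALSE])
  founder_set(h, map)
}

#' @rdname magic_io
#' @param genotypes Lines x markers matrix as from [emit_genotypes()].
#' @export
write_genotypes <- function(genotypes, path) {
  df <- data.frame(line_id = rownames(genotypes),
                   as.data.frame(unclass(genotypes)), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname magic_io
#' @export
read_genotypes <- function(path, map) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (colnames(df)[1] != "line_id") {
    stop(path, ": malformed genotype header (first column must be line_id)")
  }
  if (anyDuplicated(df$line_id)) {
    stop(path, ": duplicated line_id ", df$line_id[duplicated(df$line_id)][1])
  }
  mk <- colnames(df)[-1]
  unknown <- setdiff(mk, map$marker)
  if (length(unknown)) {
    stop(path, ": marker absent from map: ", unknown[1])
  }
  if (length(mk) != nrow(map)) {
    stop(path, ": genotype/map dimension mismatch (", length(mk), " vs ",
         nrow(map), " markers)")
  }
  g <- as.matrix(df[, map$marker, drop = FALSE])
  rownames(g) <- df$line_id
  storage.mode(g) <- "integer"
  structure(g, map = map)
}

#' @rdname magic_io
#' @param phenotypes Phenotype table with `line_id`, `rep` columns.
#' @param traits Known trait vocabulary for validation of read files.
#' @export
write_phenotypes <- function(phenotypes, path) {
  df <- as.data.frame(phenotypes)
  attr(df, "truth") <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname magic_io
#' @export
read_phenotypes <- function(path, traits = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("line_id", "rep") %in% colnames(df))) {
    stop(path, ": malformed phenotype header (need line_id and rep)")
  }
  if (!is.null(traits)) {
    unknown <- setdiff(colnames(df), c("line_id", "rep", traits))
    if (length(unknown)) {
      warning(path, ": unknown trait column(s) carried through: ",
              paste(unknown, collapse = ", "))
    }
  }
  df
}

#' @rdname magic_io
#' @param mosaics List of mosaic genomes (with `lengths` attribute).
#' @export
write_mosaics <- function(mosaics, path) {
  rows <- list()
  for (id in names(mosaics)) {
    mg <- mosaics[[id]]
    for (ch in names(mg)) {
      for (hom in c("h1", "h2")) {
        tr <- mg[[ch]][[hom]]
        start <- c(0, tr$pos[-length(tr$pos)])
        rows[[length(rows) + 1]] <- data.frame(
          chrom = ch, start_cM = start, end_cM = tr$pos,
          founder = tr$founder, homolog = hom, line_id = id,
          stringsAsFactors = FALSE)
      }
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname magic_io
#' @export
read_mosaics <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start_cM", "end_cM", "founder", "homolog", "line_id")
  if (!all(need %in% colnames(df))) {
    stop(path, ": malformed mosaic header")
  }
  lengths <- tapply(df$end_cM, df$chrom, max)
  chroms <- unique(df$chrom)
  out <- lapply(split(df, df$line_id), function(dl) {
    trks <- lapply(chroms, function(ch) {
      dc <- dl[dl$chrom == ch, ]
      mk <- function(hom) {
        dh <- dc[dc$homolog == hom, ]
        dh <- dh[order(dh$start_cM), ]
        list(pos = dh$end_cM, founder = as.integer(dh$founder))
      }
      list(h1 = mk("h1"), h2 = mk("h2"))
    })
    names(trks) <- chroms
    trks
  })
  # restore original line order
  out <- out[unique(df$line_id)]
  attr(out, "lengths") <- lengths[chroms]
  out
}

#' Write a scan result table
#'
#' Tab-separated, with the effect-table column layout: Phenotype, Marker,
#' Chr, cM, the -log10 p statistic, the locus variance fraction, then one
#' column per founder effect.
#'
#' @param scan A `scan_result`.
#' @param trait Trait code for the Phenotype column.
#' @param path File path.
#' @export
write_scan <- function(scan, trait, path) {
  fn <- attr(scan, "founder_names")
  df <- data.frame(Phenotype = trait, Marker = scan$marker,
                   Chr = scan$chrom, cM = scan$cM,
                   neg_logP = scan$neg_log10_p, h2 = scan$var_explained,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(fn) && all(fn %in% colnames(scan))) {
    df <- cbind(df, scan[, fn, drop = FALSE])
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pipeline YAML configuration
#'
#' @param path YAML file path.
#' @return Named list merged over [pipeline_config()] defaults.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}
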