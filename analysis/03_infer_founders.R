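#!/usr/bin/env Rscript
# Stage 3: founder-descent reconstruction.
# Runs the forward-backward HMM (8 effective meioses, 1% emission error)
# to obtain per-line, per-locus posterior founder probabilities, and the
# Viterbi decoding to genome mosaics. The inferred mosaics are compared
# with the simulation truth to report decoding accuracy.
library(magicqtl)

out <- "results/analysis"
map <- read_map(file.path(out, "map.csv"))
founders <- read_founders(file.path(out, "founders.csv"), map)
genotypes <- read_genotypes(file.path(out, "genotypes.csv"), map)

FP <- infer_founder_probs(genotypes, founders, params = hmm_params())

# flat TSV export of the 3-axis array (line x locus x founder)
flat <- data.frame(
  line_id = rep(rownames(genotypes), times = nrow(map)),
  marker = rep(map$marker, each = nrow(genotypes)),
  matrix(FP, nrow(genotypes) * nrow(map), dim(FP)[3],
         dimnames = list(NULL, attr(FP, "founder_names"))),
  check.names = FALSE)
write.table(cbind(flat[1:2], round(flat[-(1:2)], 5)),
            file.path(out, "founder_probs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

vm <- viterbi_mosaic(genotypes, founders)
write_mosaics(vm, file.path(out, "mosaics_inferred.tsv"))

truth <- read_mosaics(file.path(out, "mosaics_truth.tsv"))
acc <- mean(vapply(names(vm), function(id) {
  mean(unlist(lapply(map_chroms(map), function(ch) {
    pos <- map$cM[map$chrom == ch]
    founder_at(vm[[id]][[ch]]$h1, pos) ==
      founder_at(truth[[id]][[ch]]$h1, pos)
  })))
}, numeric(1)))
cat(sprintf("Viterbi mosaic accuracy vs truth: %.1f%% of markers\n",
            100 * acc))
cat(sprintf("Mean posterior on decoded founder: %.3f\n",
            mean(apply(FP, c(1, 2), max))))
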