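#!/usr/bin/env Rscript
# Stage 1: simulate the study population.
# A desk-scale stand-in for the NIAB eight-founder MAGIC core set: 208 RILs
# from independent funnels (3 recombination cycles + 5 selfings), 3
# chromosomes x 100 markers, planted QTL for heading date (5A), stem
# height / internode length (4D) and ear length (5B), two phenotype
# replicates, 2.19% missingness in genotypes and phenotypes.
library(magicqtl)

out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

map <- regular_map()                       # 4D, 5A, 5B x 100 markers
sim <- simulate_magic(map, n_lines = 208, seed = 2024)

write_map(sim$map, file.path(out, "map.csv"))
write_founders(sim$founders, file.path(out, "founders.csv"))
write_genotypes(sim$genotypes, file.path(out, "genotypes.csv"))
write_phenotypes(sim$phenotypes, file.path(out, "phenotypes_raw.csv"))
write_mosaics(sim$mosaics, file.path(out, "mosaics_truth.tsv"))

cat("Simulated", length(sim$mosaics), "RILs x", nrow(map), "markers\n")
cat("Genotype missingness:",
    sprintf("%.2f%%", 100 * mean(is.na(sim$genotypes))), "\n")
cat("Planted QTL:\n")
for (q in sim$qtls) {
  cat(sprintf("  %-5s %-8s h2 = %.2f\n", q$trait, q$marker, q$h2))
}
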