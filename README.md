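# magicqtl

Haplotype-based QTL mapping for multi-parent (MAGIC) wheat populations,
with a fully simulated test bed.

## What this is for

Eight-founder MAGIC populations decompose each recombinant inbred line
(RIL) into a mosaic of founder haplotypes. Mapping quantitative trait loci
in such populations needs a haplotype-based analysis: single-marker tests
miss QTL whose causal alleles are spread across founders differently from
any one biallelic SNP. The analysis here is two-stage:

1. **Founder-descent reconstruction.** A hidden Markov model computes, for
   every line *i* and locus *L*, the posterior probability
   *F<sub>iLs</sub>* that the line descends from founder *s*, conditional
   on all its genotype data (scaled forward–backward; Viterbi decoding
   yields the mosaics themselves).
2. **Haplotype regression.** The phenotype is regressed on the expected
   founder dosages, E(y) = X<sub>L</sub> T, where the additive design is
   X<sub>Lis</sub> = F<sub>iLs</sub> (rows sum to 1, so the fitted T<sub>s</sub>
   read directly as founder trait means; the full interaction model has
   S(S−1)/2 + S parameters). An ANOVA F-test per locus gives the scan
   statistic −log₁₀ p; genome-wide significance comes from phenotype
   permutations (95th percentile of the per-permutation maximum) and FDR
   from Storey q-values, with QTL called at −log₁₀ p ≥ 4 and q ≤ 0.05.

Because the motivating study's phenotypes and 80K-array genotypes are not
publicly deposited, the package ships a first-class population simulator —
funnel crossing (three recombination cycles, five selfings), Haldane
meioses, founder SNP emission with error and 2.19% missingness, and a
17-trait phenotype suite with planted founder-effect QTL and the reported
trait-correlation structure — so every inference stage is validated against
known ground truth. Phenotype preparation (derived phenology intervals
d1/d2/d3, chained-equation imputation with m = 5, replicate averaging,
trait PCA, kinship-matrix structure checks, the senescence-predictor
regression screen) and forward-selection composite scanning complete the
pipeline.

Intended users: quantitative geneticists working with multi-parent
populations, and anyone needing a controlled simulation harness for
haplotype-reconstruction + dosage-regression methods.

## Worked example

```r
library(magicqtl)

map <- regular_map()                          # chromosomes 4D, 5A, 5B x 100 markers
sim <- simulate_magic(map, n_lines = 208, seed = 42)

pheno <- derive_intervals(sim$phenotypes)     # d1, d2, d3
pheno <- mice_impute(pheno, m = 5, seed = 43) # chained-equation imputation
line_means <- average_replicates(pheno)

FP   <- infer_founder_probs(sim$genotypes, sim$founders)
scan <- genome_scan(line_means$GS39, FP)
null <- permutation_null(line_means$GS39, FP, n_perm = 200, seed = 44)
fdr  <- qvalues(10^(-scan$neg_log10_p))
call_qtls(scan, threshold_logp = 4, fdr = fdr)
#>   chrom  marker       cM neg_log10_p var_explained start_cM   end_cM n_markers
#> 1    5A 5A_m049 48.48485    8.526397     0.2321786 33.33333 59.59596        27
```

One QTL region is called, on 5A around the planted heading-date locus
(5A_m050 at 49.5 cM): 27 contiguous markers exceed −log₁₀ p = 4, the peak
scores 8.5 and explains 23% of the line-level variance. The genome-wide
permutation threshold for this trait is 3.01 and the empirical genome-wide
p-value of the peak is 0.005 (the add-one floor at 200 permutations). The
founder effects at the peak marker recover the planted means — Xi-19 is
the early outlier:

```r
scan[match("5A_m049", scan$marker), magic_founder_names()]
#> Alchemy Brompton Claire Hereward Rialto Robigus Soissons  Xi-19
#>  126.53   127.68 125.69   129.66  128.1  123.62    127.5 114.95
```

## Analysis workflow

`analysis/` contains the numbered end-to-end workflow, each script a thin
driver over the package that prints what it found and writes tables under
`results/analysis/`:

| script | does |
|---|---|
| `01_simulate.R` | simulate the 208-RIL population with planted QTL |
| `02_prepare_phenotypes.R` | intervals, imputation, correlations, trait PCA, FLS regression screen |
| `03_infer_founders.R` | founder posteriors, Viterbi mosaics, accuracy vs truth |
| `04_scan_traits.R` | scans, permutation thresholds, q-values, QTL calls |
| `05_conditional_scan.R` | forward-selection composite scan |
| `06_structure_check.R` | kinship PCA structure statistic + positive control |

Run them in order from the repository root:
`Rscript analysis/01_simulate.R`, etc.

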