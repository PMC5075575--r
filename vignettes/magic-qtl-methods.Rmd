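---
title: "Haplotype-based QTL mapping in simulated MAGIC wheat: models and design choices"
author: "magicqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-based QTL mapping in simulated MAGIC wheat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magicqtl)
```

## The problem

Multi-parent advanced generation inter-cross (MAGIC) populations combine
many founders through structured crossing "funnels" and inbreeding, so each
recombinant inbred line (RIL) carries a fine-grained mosaic of founder
haplotypes. In an eight-founder wheat population, single-marker association
can miss a QTL whenever the causal alleles are distributed across founders
differently from any one biallelic marker. The haplotype-based approach
instead (i) reconstructs, at every locus, the probability that each line
descends from each founder, and (ii) regresses phenotypes on those
probabilities, testing whether the founder effects differ.

`magicqtl` implements that two-stage analysis together with everything
needed to exercise it end to end without external data: a funnel-crossing
population simulator with known ground truth, the phenotype-preparation
stages used in phenology studies (derived interval traits, chained-equation
imputation, trait correlation/PCA, kinship-structure checks, a
multiple-regression screen for senescence predictors), permutation-based
genome-wide significance with Storey q-values, and forward-selection
composite scanning.

## Population simulator

The simulator is first-class, tested code: it defines the study conditions
under which every inference stage is validated.

**Crossing design.** Each RIL derives from one eight-way funnel: four
two-way crosses, two four-way crosses, one eight-way cross (three cycles of
recombination), then five generations of selfing by single-seed descent.
Funnel leaf orders are randomised independently per line (one line per
funnel; the real core set represents 208 of 210 funnels and the per-funnel
replicate structure is not recorded, so one line per funnel is the neutral
default).

**Meiosis.** Crossovers follow a Poisson process at 1 crossover / 100 cM
with positions uniform on the chromosome and no interference (Haldane
model), the simplest standard choice; the starting homolog is uniform.
Consequences used as oracles in the test suite: the recombinant fraction
between markers d cM apart is $(1 - e^{-2d/100})/2$, residual
heterozygosity after $g$ selfing generations is $2^{-g}$ (3.125% at
$g = 5$), and genome-wide founder shares are $1/8$ each.

**Founder haplotypes and genotyping.** Founder SNP haplotypes are drawn
i.i.d. per marker with allele frequency chosen so a random founder pair
differs at a target fraction of markers (`divergence`, default 0.5);
monomorphic draws are redrawn, mirroring an array panel that retains only
polymorphic scorable SNPs. Observed RIL genotypes are the founder alleles
at the line's true mosaic, coded 0/1/2, with independent per-allele flip
errors (default 0.001) and missing-at-random masking at 2.19%, the
missingness level the preparation stage is designed to absorb.

**Phenotypes.** The 17-trait suite (growth stages GS39/GS55/GS65 and FLS in
days after sowing; biomass, height, ear and leaf morphology; an ordinal
stress score SM; harvest index) is generated at the line level and then
expanded to two replicates. For a trait with planted QTL, each line's
genetic value is the mean of its two founders' trait means at the causal
marker (heterozygote effects additive); the implied total variance is
$V = \sum_l \sigma^2_{\mu,l} / \sum_l h^2_l$, where $\sigma^2_{\mu,l}$ is
the variance of the founder means at locus $l$, so each locus explains its
specified $h^2$ in expectation. Residuals are multivariate Gaussian: within
the planted-trait block their covariance tops the realised genetic
covariance up to the target total covariance (diagonals fixed at
$V(1-\sum h^2)$ so the noise-free limit $h^2 \to 1$ is exact), and traits
without QTL are generated by a Gaussian copula conditional on the
standardised planted traits, which places companion-trait correlations
(e.g. FLS–GS39 at 0.79) directly at their targets. Replicate noise is
drawn as per-line centred contrasts, so replicate means reproduce the line
values exactly and the replicate-averaged scale — the scale on which
scanning operates — carries the planted variances, correlations and $h^2$
without distortion. SM is thresholded from its latent Gaussian to a
right-skewed 0–4 ordinal score (most lines 0–2); the real score's
conversion table is not public, so the 0–4 coding is a declared convention.

Default sizes are a desk-scale stand-in for the real study: 208 RILs, 3
chromosomes ("4D", "5A", "5B") × 100 markers over 100 cM, two replicates.
The default planted architecture mirrors the published wheat phenology
results: a strong mid-5A locus for GS39 ($h^2 = 0.35$) and GS55 (0.33) at
which the founder Xi-19 is ~15 days early, a mid-4D height locus for SH
(0.38) and TIL (0.31) at which Robigus and Soissons are tall, and a weaker
mid-5B ear-length locus (0.22). The FLS line-level spread (sd 14 d) is set
so the derived interval d3 = FLS − GS55 correlates with FLS at about 0.7,
matching the reported phenotypic pattern.

**What the generator does not emulate.** No crossover interference, no
epistasis, no genotype-by-environment structure, no longitudinal growth
curves, and trait correlations are phenotypic only (no
genetic/environmental decomposition — the source study reports only
phenotypic correlations). Passing tests therefore demonstrate correctness
of the inference machinery under these idealised conditions, not robustness
to, say, segregation distortion or founder mis-specification in real data.

## Founder-descent reconstruction

The hidden state at each locus is the founder of descent. Because F5+ RILs
are nearly fully inbred, the default chain is haploid (S = 8 states); an
ordered founder-pair diplotype chain (S² states, independent homolog
kernels) is available for the full interaction model and for populations
with substantial heterozygosity.

* **Transitions.** Over d cM the chain stays on its founder with
  probability $e^{-gd/100} + (1 - e^{-gd/100})/8$, uniform otherwise, with
  $g$ = 8 effective meioses by default (3 funnel + 5 selfing; exposed as a
  parameter since the real breeding-design equivalent is not published).
* **Emissions.** Matching homozygote $1-\varepsilon$, mismatching
  $\varepsilon$ (default 0.01), heterozygous calls 0.5 (uninformative in
  haploid mode), missing 1.
* **Algorithm.** Scaled forward–backward per chromosome with a uniform
  founder prior at each chromosome start (funnel symmetry), vectorised
  across lines; per-locus rescaling keeps the recursion in linear space
  with no underflow for maps of 10k+ loci. The exactness contract is tested
  against brute-force enumeration over all founder paths on small
  instances (≤ 4 loci, ≤ 3 founders) at 1e-9.
* **Viterbi decoding** gives genome mosaics, with ties broken toward the
  lower founder index and segment boundaries placed at midpoints between
  markers where the decoded founder changes. Decoding accuracy is
  density-limited: around a true junction the two flanking founders often
  share alleles for a few markers, so per-marker accuracy > 99% requires a
  few markers per cM (the test uses 4/cM); at the default 1 marker/cM,
  expect ~95%.

## Genome scan

At each locus the additive design matrix is the posterior founder-dosage
matrix itself (haploid coding: rows sum to 1), so least-squares
coefficients read directly as founder trait-mean predictions — the
convention used for reported founder-effect tables. The locus test is a
nested-model F-test against the covariate-only null; `var_explained` is the
incremental R² of the locus term (this is how the reported per-locus "h²"
column is interpreted; the source text does not define it). The full
interaction model has one column per unordered founder pair,
$S(S-1)/2 + S = 36$ columns for S = 8, built from diplotype probabilities.

Replicates are averaged before scanning; missing phenotypes are dropped
casewise per trait. Rank deficiency is handled by QR rank detection (F-test
df adjust) and pseudo-inverse effect estimates with a warning. Scans run at
marker positions; each reported peak carries its flanking-marker interval.

A scan engine precomputes, per locus, an orthonormal basis of the dosage
columns residualised against the null space, so permutation scans reduce to
one matrix product per batch of permuted phenotypes — this is what makes
400-dataset calibration experiments affordable on one CPU.

## Significance

Genome-wide significance is by phenotype permutation: the phenotype vector
is shuffled across lines (covariates, when present, travel with it as a
unit; genotypes untouched), the whole scan repeated, and the maximum
−log₁₀ p recorded; the 95th percentile of the maxima is the genome-wide 5%
threshold, and the empirical p-value of an observed maximum uses the
add-one estimator $(r+1)/(n_{perm}+1)$, which never returns 0. FDR control
uses Storey q-values: $\pi_0$ from the smoother method (cubic smoothing
spline of $\pi_0(\lambda)$ over $\lambda = 0.05, \dots, 0.95$), falling
back conservatively to $\pi_0 = 1$ on vectors shorter than 100 or if the
smoother fails; the step-up construction then gives
$q_{(i)} = \min_{j \ge i} \pi_0 m p_{(j)}/j$, and the p-value at q = 0.05
is linearly interpolated on the sorted (p, q) pairs (absent when no q falls
below 0.05). QTL calls require both −log₁₀ p ≥ 4 and q ≤ 0.05; contiguous
super-threshold markers (bridging one sub-threshold gap marker) group into
a single QTL region with its peak marker, which reproduces the reading of
several close peaks on one chromosome as a single QTL without a formal
drop-interval method.

## Multiple-QTL modelling

Forward selection adds the genome-wide top marker's dosage block to the
covariate set whenever its conditional −log₁₀ p reaches the same threshold
of 4 used for single-locus calling, up to 10 covariates; no backward
elimination (the validation analysis this mirrors used forward selection
only). Collinear candidate blocks are skipped with a warning. Conditional
scans flag loci within 10 cM of a covariate (a documented default — the
window is not specified in the source) since their conditional signal is
dominated by the covariate itself. With no covariates selected the
procedure reduces exactly to the single-locus scan.

## Phenotype preparation

* Derived intervals d1 = GS55 − GS39, d2 = GS65 − GS55, d3 = FLS − GS55
  (days); missing operands propagate; negative intervals are kept but
  QC-logged (possible scoring errors are curated manually in practice,
  which code should not silently imitate).
* Chained-equation imputation: each incomplete column regressed on all
  others, missing cells replaced by prediction plus a residual-sd Gaussian
  draw, 10 sweeps, m = 5 completed tables averaged cell-wise; observed
  cells are never altered. Assumes missing-at-random. Replicates are
  averaged after imputation.
* Correlations are computed pairwise-complete before imputation and on the
  full matrix after (both emitted); trait PCA runs on unit-variance-scaled
  complete data and reports scores, loadings and variance fractions.
* The kinship matrix uses VanRaden frequency scaling of centred genotypes
  (the specific scaling behind "marker-based relationship matrix" is not
  stated in the source; VanRaden is the field default). Its leading
  eigenvalue fraction is the structure statistic: random-funnel simulations
  sit near 2% at 7 × 150 markers, and the < 4% check runs at that density
  because the eigenvalue share of PC1 is inflated at very low marker
  counts; a two-subpopulation control exceeds 20%.
* The FLS regression screen keeps d3 in the default predictor set because
  that reproduces the published analysis, but prints a circularity warning
  (d3 contains FLS arithmetically) and offers `exclude_derived = TRUE` for
  the stricter model. Outliers beyond 4 SD are flagged, never altered.

## Numerical and reproducibility choices

Positions are cM only, floating point, chromosome-local. Genotypes are
0/1/2 alternate-allele counts with `NA` sentinel. Every stochastic stage
takes an explicit seed; `run_pipeline()` is byte-deterministic given its
config and writes a manifest with an MD5 fingerprint per artifact (base R
ships MD5; no further hash dependency is taken). Viterbi ties break toward
the lower founder index; q-value $\pi_0$ falls back to 1 on short vectors;
rank-deficient designs fall back to pseudo-inverse effects with warnings.
The correlation target matrix is projected to the nearest PSD correlation
matrix by eigenvalue clipping; the residual factorisation preserves
variances exactly and lets off-diagonals absorb any clip distortion.

## Problem sizes

Validation experiments use sizes chosen to make Monte-Carlo error small
relative to the quantities checked while staying desk-scale: effect and h²
recovery use 100 replicate populations of 208 RILs on the 3 × 100-marker
map (Monte-Carlo SE ≈ 0.16 d on founder effects); permutation calibration
uses 400 null datasets × 200 permutations on one population; the structure
check uses one 7-chromosome × 150-marker population. The acceptance script
(`scripts/acceptance.R`) re-runs the recovery protocol from scratch at
those sizes.

## Known limitations

The HMM ignores the funnel pedigree (which founder entered which cross
arm) and does not phase residual heterozygosity; regression on posterior
dosages mildly attenuates effects when posteriors are diffuse (sparse maps,
high error rates); no kinship-corrected mixed-model scan is provided, by
design, since the unstructured-population check is part of the analysis; and
the simulator's idealisations listed above bound what green tests imply
about field data.
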