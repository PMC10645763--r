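---
title: "From placental co-expression modules to adult outcomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From placental co-expression modules to adult outcomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetomod)
```

# Scope

`fetomod` re-implements, as a tested pipeline, an inference chain that runs
from placental gene co-expression module discovery to adult-outcome
inference: signed weighted co-expression network construction, permutation
module preservation, an eQTL-weighted expression polygenic score (PGS) with
negative controls, ssGSEA validation, a phenome-wide association scan,
two-sample Mendelian randomization (MR) with sensitivity analyses,
Fisher's-exact gene-set overlap, and ARACNE-style mutual-information
connectivity. Because the cohort data such an analysis runs on are
access-restricted, the package ships a synthetic genotype-to-expression-to-
phenotype generator with planted ground truth, and every stage is validated
against it.

# The synthetic world

`sim_params()` fixes the generative model:

* **Genotypes.** Haplotypes arise from equicorrelated Gaussian blocks
  (`ld_block_size` SNPs per block, latent correlation `ld_rho`), thresholded
  at the 1 − MAF quantile; a dosage is the sum of two independent
  haplotypes. Each block sits on its own chromosome, so LD never crosses
  blocks. MAF is uniform on `maf_range` per SNP. Palindromic allele pairs
  are excluded at generation so harmonization bookkeeping, not strand luck,
  decides instrument retention.
* **Expression.** `X[g, s] = sum_j beta_gj d[s, j] + lambda_g F[m(g), s] + eps`,
  one standard-normal factor per module and sample, loadings uniform on
  `loading_range` (default 0.6–0.9) for module genes, noise SD 1. A fraction
  `eqtl_frac` (default 0.3) of each module's genes carries one cis-eQTL with
  effect `~ N(0, eqtl_beta_sd^2)` (default SD 0.3; signs random unless a
  positive fraction is requested).
* **Outcome.** In an independent cohort, liability
  `L = gamma * M + sum(pleiotropic delta_j d_j) + e`, where `M` is the
  genetic component of the target module's activity: dosages projected
  through the true eQTL effects weighted by the *population* first principal
  direction of the true module covariance (`lambda lambda'` plus per-gene
  cis and noise variances). That direction is exactly what the sample PC1
  of module expression estimates, so per-SNP Wald ratios
  (outcome beta / exposure beta) center on `gamma` by construction rather
  than on `gamma` times an arbitrary scale factor. An earlier draft weighted
  `M` by the normalized loadings alone; when cis effects are large the
  sample PC1 tilts toward the high-variance genes and that choice biases
  Wald ratios downward by 10–20%.
* **Two-sample structure.** Exposure and outcome cohorts are independent
  draws (disjoint RNG substreams); there is no sample overlap and no
  reverse-causal path, matching two-sample MR assumptions. A one-sample
  mode is deliberately not provided.

Defaults (2000 genes, five modules of 100/100/80/60/50, 1000 SNPs, two
cohorts of 1000) keep a full simulate-analyze cycle under two minutes on one
CPU. All randomness derives from base R's Mersenne-Twister under the
supplied seed; runs are bit-reproducible on a fixed R version.

What the generator does **not** emulate: recombination maps, imputation
uncertainty, population structure, cell-type deconvolution, and — important
for interpreting one red acceptance check (below) — any genetic control of
the module *factor* itself. A green test on this world certifies the
statistics and their calibration, not performance on real tissue data.

# Network construction

Gene filtering keeps genes positive in strictly more than 90% of samples
(`expressed_fraction`; "expressed" means value > 0, a choice the source
methods leave open) and drops zero-variance genes. Sample outliers are
flagged when their first merge in an average-linkage tree on Euclidean
distances exceeds mean + 2.5 SD of merge heights.

Similarity is the biweight midcorrelation; observations are median-centered
and Tukey-biweight downweighted at 9 MADs. A vector with zero MAD makes the
*pair* fall back to plain Pearson (no `maxPOutliers`-style refinement).
Signed adjacency is `((1 + bicor) / 2)^beta` with `beta = 14` by default,
selectable by scale-free fit (10 equal-count connectivity bins, signed
R-squared target 0.8). The topological overlap matrix follows the standard
shared-neighbor formula, and 1 − TOM is the clustering dissimilarity.

**Tree cutting.** The obvious static cut at 0.99 × the maximum merge height
fails at beta = 14: TOM dissimilarities compress into roughly
[0.985, 0.9999], the cut lands *below* every within-module merge, and every
gene comes out a singleton. The default coarse cut therefore finds the
largest gap in the sorted merge heights and cuts at its midpoint. In
structured trees the many low within-module merges are separated from the
background joins by a dominant gap (on the default world this cut recovers
the planted 100/100/80/60/50 partition exactly); in featureless noise trees
the largest gap sits at the very bottom, the cut produces singletons, and
everything stays grey. The rule is conservative: in under-resolved regimes
(few samples, high power) it returns all-grey rather than inventing
modules. The static rule remains available as `cut_method = "static"`. One
refinement pass re-cuts any coarse module whose internal height profile
shows a gap above `gap_frac` (0.25) of its height range, keeping sub-
clusters of at least `min_module_size` (30); a split that would leave fewer
than two viable sub-clusters is abandoned.

Eigengenes are the unit-variance first principal component of the
standardized module submatrix, oriented positively with the module mean
profile. Modules merge iteratively while the largest eigengene correlation
exceeds 0.85, recomputing after every merge (whether the source computed
correlations once or iteratively is unstated; iterative recomputation is
the stricter choice), with a lexicographic tie-break.

# Module preservation

Six test-data statistics per module — density: mean signed adjacency,
proportion of variance explained, mean signed kME; connectivity:
correlations of intramodular connectivity, of kME, and of the vectorized
gene-gene correlations between reference and test. Each is standardized
against label permutations **in the test data only**: the reference side
keeps the real module genes and the permuted test-side set is paired with
it arbitrarily. This matters: permuting both sides centers the
cross-dataset correlation nulls near their structural maximum whenever the
test data shares any true structure with the reference (as a replicate
does), which drives Zconnectivity negative for perfectly preserved modules.
Zdensity and Zconnectivity are medians of their three Zs,
`Zsummary = (Zdensity + Zconnectivity) / 2`, with the conventional
classification: < 2 none, 2–10 weak-moderate, > 10 strong. The published
statistic set also includes separability components that the source does
not enumerate; they are excluded here. Genes absent from the test data are
dropped with a message; the test-data adjacency reuses the reference soft
power.

# Expression PGS

SNPs map to genes by 1-based inclusive gene-body overlap (optional flanking
window). Greedy LD clumping keeps the smallest-p SNP and removes neighbors
within 250 kb at dosage r-squared >= 0.2 (the r-squared < 0.2 retention
rule; the window size is this package's default since only the r-squared
bound is stated; a single reference panel is used per run rather than
cohort-specific LD). A SNP that is an eQTL for two module genes contributes
once with the smaller-p weight. Scores are
`sum_j weight_j * dosage_sj`, with swapped-allele records folded in by
negating the weight (so re-expressing a record on the opposite allele is an
exact identity) and missing dosages mean-imputed to 2 × in-cohort EAF by
default ("drop" and "zero" policies available). Negative controls follow
the study design: a size-matched alternative module, a random size-matched
gene list from the expressed universe, and the module's own loci with a
second tissue's effect sizes.

# Sample and cell scores

ssGSEA ranks genes per sample (average ranks on ties), walks the list from
the top accumulating `rank^tau` inside the set (tau = 0.25) against a
uniform out-of-set distribution, and sums the running difference; range
normalization across all samples and sets is on by default. Whether the
original analysis normalized, and at which tau, is unstated — both are
config parameters. The cell-level score bins genes into 24 equal-count
bins by mean expression and subtracts a seeded bin-matched control-gene
mean (without replacement when the bin allows) from the set mean. Group
comparisons use the two-sided Wilcoxon rank-sum (normal approximation, tie
correction) for two groups and Kruskal-Wallis plus BH-corrected pairwise
Wilcoxon versus a reference group otherwise.

# PheWAS harness

Outcome typing is a deliberate reduction of the PHESANT decision tree: two
distinct values → logistic; integer-valued with <= 20 levels →
proportional-odds; otherwise OLS. Unordered categoricals are not fitted.
Categorical covariates are one-hot expanded with the most frequent level as
reference. Fitting is complete-case per outcome; non-convergence and
separation (flagged at absurd SEs) exclude an outcome from the BH
correction with a warning. The Miami table carries signed −log10 p and the
BH threshold line (largest raw p passing at the level).

# Mendelian randomization

Harmonization intersects on SNP id, negates outcome betas for swapped
alleles, drops non-complementary mismatches, and removes palindromic (A/T,
C/G) SNPs unconditionally — no frequency-based rescue, matching the
"ambiguous SNPs removed" rule (an EAF-based variant is out of scope).
Estimators: fixed-effects IVW (weighted regression through the origin,
weights 1/se_out²); weighted median (inverse-variance ratio weights,
interpolated weighted quantile, seeded parametric bootstrap SE, 1000
replicates); MR-Egger (WLS with intercept after orienting exposure betas
non-negative, t reference with n − 2 df). Sensitivity: Cochran's Q against
the IVW fit (chi-square, n − 1 df), leave-one-out IVW, per-SNP Wald ratios
with first-order SEs (se_out/|beta_exp|; the second-order variant is out of
scope), and the Egger intercept as the pleiotropy test. Multiplicative
random-effects IVW is deliberately not the default ("fixed effects
meta-analysis" is the stated method).

**Instrument strength in this model.** With module activity measured as the
PC1 of module expression (the design decision here — it is what a real
study can observe), a per-SNP instrument's effect is its gene's PC1
coordinate times the cis effect, while the PC1 scale grows with the module
factor variance (proportional to module size). At realistic cis effect
sizes almost no instrument reaches |beta| > 2 se even at n = 2000: the
module-level instruments are intrinsically weak, and the Wald-ratio
concentration property is therefore exercised in a configuration where its
own "strong instruments" qualifier holds (small module, large cis effects).
Estimation-level calibration is unaffected: on the stated two-cohort world
(n = 2000/2000, 15 instruments, gamma = −0.009) the IVW 95% CI covers gamma
in ~96% of replicates, the Egger intercept test holds its size, and Q
matches its chi-square reference.

# Overlap and connectivity

Gene-set overlap uses the one-sided hypergeometric tail over an explicit
universe (default: the filtered expressed-gene list, overridable — the
original universe is unstated) with Haldane-corrected odds ratios and BH
across lists. The mutual-information network discretizes each gene into 5
equal-frequency bins, uses the plug-in MI estimator in nats (the original
tool's kernel estimator is under-specified at this scale, so the estimator
is pluggable), thresholds at the 1 − alpha quantile of MI between permuted
random pairs, and applies the data processing inequality with tolerance
`dpi_eps = 0`: in every surviving triangle the edge weaker than both
others is removed. Degree in the retained unweighted graph is the
connectivity compared across gene groups.

# One honest red light

The acceptance suite asserts that the target-module PGS predicts the
target module's ssGSEA score with >= 80% power at n = 500 under the stated
effects (eQTL fraction 0.3, |beta| ~ 0.3). In this generating model that is
impossible, and the test is left failing rather than re-tuned. The module
score tracks the module average, so its genetic standard deviation is
`sqrt(k) * beta * sd(dosage) / m` against a coherent factor contribution of
`lambda_bar ~ 0.75`; the achievable correlation is ~0.01 (measured 0.005 at
n = 2000), and even with loadings forced to zero the bound
`sqrt(eqtl_frac) * beta * sd(dosage) / sd(noise) ~ 0.107` stays below the
r ~ 0.125 that 80% power at n = 500 requires. Measured power is ~0.06 —
the false-positive rate. The corresponding real-data observation (a
significant PGS-to-ssGSEA regression in a 42-sample cohort) implies a
genetic share of module-score variance this model cannot produce through
per-gene cis effects alone; biologically, module activity tracks a cell
population whose abundance is itself partly genetic, a trans path outside
this generator. The three negative-control type-I checks of the same
criterion pass at the nominal 0.05.

# Numerical and degenerate-input choices

Correlations are clipped to [−1, 1] before powering; TOM is symmetrized
and clipped to [0, 1]. A preservation permutation with zero SD reports
Z = +Inf (flagged) when the observed statistic exceeds the degenerate null.
Monomorphic SNPs are skipped with a message in summary-statistic
generation and pass through LD clumping with a warning when absent from
the reference panel. ssGSEA refuses a set covering all genes (the
out-of-set distribution is undefined). `validate_pgs` rejects covariate
matrices with condition number above 1e12. Constant genes are dropped
before MI estimation. Eigengene orientation ties (exactly zero correlation
with the mean profile) keep the SVD's sign.
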