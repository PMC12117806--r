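---
title: "Methods: metagenome relationship matrices and kernel REML for methane proxy traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metagenome relationship matrices and kernel REML for methane proxy traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmblup)
```

This vignette documents the models, the assumptions behind them, the
numerical choices, and the design decisions taken where more than one
reasonable implementation exists. It is the companion to the README's
worked example.

## The modelling problem

Portable-accumulation-chamber (PAC) gas traits — CH4 and CO2 in g/day and
the molar ratio CH4/(CO2+CH4) — are measured on lambs in lots of 12, and a
rumen sample taken at measurement yields a reference-free metagenome
profile: counts of unique 65-bp sequence tags. Two questions drive the
package: how much trait variance is captured by host genomics
(heritability, via the GRM) versus by the rumen community (microbiability,
via the MRM), and whether a trait *predicted* from the metagenome is a
usable selection proxy for the directly measured trait — which is a
question about the genetic correlation between the pair and the relative
efficacy $\rho_{u12}\sqrt{h^2_2}/\sqrt{h^2_1}$ of indirect selection.

## Tag profiling

A tag is the first 65 bases of a trimmed read; identity is exact string
match (no mismatch tolerance — the profiling is reference-free, and any
clustering of near-identical tags is deliberately out of scope). Reads
shorter than 40 bases are discarded. Reads of 40–64 bases are counted in a
sample's total (they are legitimate trimmed reads, and the 100,000-read
sample-QC threshold is defined on reads remaining after trimming) but
cannot yield a tag. The QC comparison is strict: a sample with exactly
100,000 reads is retained. Tag filtering keeps a tag present (at least one
read) in at least 25 % of a *reference* sample set — the training samples
under forward prediction, all samples under cross-validation — with an
inclusive comparison at the threshold.

## The metagenome relationship matrix

Four steps: add a pseudo-count of 1 and divide by the sample read total;
log10; standardise each tag to mean 0 / sd 1 within each cohort (flowcell x
flock x birth-year x sex); correlate the cohort-normalised profiles of each
animal pair. The diagonal is set to exactly 1.

Choices a reimplementer would need to know:

* The divisor in step 1 is the sample's read total (`rowSums(counts)` by
  default). Dividing instead by the pseudo-counted total would change each
  sample's log profile by an additive constant only, which the Pearson
  correlation in step 4 removes — the MRM is identical either way.
* Standard deviations use the n−1 denominator.
* A tag with zero variance within a cohort carries no information there;
  its normalised values are set to 0 for that cohort rather than dropping
  the tag globally, keeping the tag set aligned across cohorts. Counts of
  such tags are returned in the `zero_variance` attribute.
* Cohorts of size 1 are an error (a within-cohort sd is undefined).
* A `clr` mode replaces steps 1–2 with a centred log-ratio transform; on
  dense data the two MRMs agree closely (tested as a correlation of
  off-diagonals above 0.95, a repository choice of threshold), which is
  why ignoring strict compositionality is an acceptable approximation at
  realistic tag counts.

The cohort standardisation is the load-bearing step: it removes
environment, sampling-time and flowcell scale effects that otherwise
dominate metagenome profiles, under the assumption that animals rank
similarly across environments.

## The genomic relationship matrix

VanRaden method 1 with allele frequencies from the observed non-missing
calls of retained SNPs (MAF > 0.01, call rate ≥ 0.70). Under missingness,
both the numerator and the denominator of each entry are restricted to the
pair's shared non-missing SNP set, which keeps every entry a properly
scaled estimate under missingness-at-random; self-relationships use the
animal's own non-missing set. A pair sharing no SNPs is an error unless
`impute_zero = TRUE`. The diagonal is left as computed. Such a pairwise
GRM is only approximately positive semi-definite: `kernel_eigen` clamps
small negative eigenvalues (down to −2 % of the largest) to zero and
errors beyond that.

## Phenotype preparation

Gas traits are lot-scaled: each value divided by its lot mean and
multiplied by the overall population mean (defaults 7.5 g/day CH4,
623 g/day CO2, 0.032 CH4Ratio), making every within-lot mean equal the
overall mean exactly. Lot effects are treated as multiplicative because
between-lot differences arise mostly from time off feed, which scales
emissions; this also stabilises the heterogeneous variance. NA records are
excluded from lot means (only reliable measurements inform the scaling).
Fixed effects — birth/rearing-rank class, age-of-dam class (1, 2, 3+), the
birthday-deviation covariate, and a contemporary group concatenated from
flock x birth-year x sex — are removed by a rank-revealing least-squares
fit; the adjusted phenotype y* is the residual vector, orthogonal to the
design and idempotent under re-adjustment.

## Univariate kernel REML

`kreml` fits y = Xb + u + e, u ~ N(0, σ²ᵤK), e ~ N(0, σ²ₑI). Rotating by
the eigenvectors of K diagonalises the covariance, so the restricted
likelihood is profiled over log λ (λ = σ²ᵤ/σ²ₑ) with a bounded
one-dimensional search on [−16, 16] (tolerance 1e−10); each evaluation is
O(n) after the one-off eigendecomposition. The restricted likelihood
convention is
−½[(n−p)·log 2π + log|V| + log|X'V⁻¹X| + y'Py], under which the bivariate
likelihood with zero covariances separates exactly into the sum of the two
univariate likelihoods (a tested identity). Standard errors come from a
central-finite-difference observed information in (σ²ᵤ, σ²ₑ) (relative
step 1e−4), with the delta method for the ratio. Boundary estimates are
reported at the boundary (no negative components); the SE is NA there.
BLUPs for animals outside the training set are the conditional means
σ̂²ᵤ K₍target,train₎ V⁻¹(y − Xb̂).

## Bivariate proxy model

`kreml_bi` fits the stacked pair (y*, m̂) with random-effect covariance
K ⊗ B and residual I ⊗ C. After rotation the likelihood factorises into n
bivariate normal terms with 2×2 covariance dₖB + C, so evaluations are
O(n). B and C are parameterised by their Cholesky factors with
log-diagonals (clamped to ±15 on the log scale so line-search excursions
cannot overflow), which enforces positive semi-definiteness. Optimisation
is BFGS from two starts — the univariate fits with zero covariances, and
with the empirical trait covariance split between B and C in proportion to
the first trait's variance ratio — followed by a Nelder–Mead polish and a
final BFGS refinement; the polish guards against quasi-Newton line-search
blow-ups on near-ridge surfaces. A per-trait general mean is always
fitted: the adjusted phenotype and the BLUP proxy are centred only
approximately, and the two extra parameters cost nothing while removing a
numerical nuisance. Estimates with |ρ̂| > 0.999 or a vanishing genetic
variance are flagged as boundary fits (converged-with-warning); SEs are
not reported there. Otherwise SEs come from the observed information in
the six raw (co)variances with analytic delta-method gradients for ρ_g,
ρ_p, h², and the relative efficacy. A ratio trait can be analysed ×100 for
numerical stability; h² and both correlations are invariant to that
rescaling (tested).

## The synthetic-data generator

`simulate_population` emulates the study conditions the pipeline targets:
animals in lots of 12 with multiplicative log-normal lot factors; cohorts
from flock x birth-year x sex x flowcell blocks; genotypes Binomial(2, pₖ)
with pₖ ~ U[0.05, 0.5] (so all SNPs pass the default MAF filter; widen to
[0, 0.5] to exercise filtering), optionally with paternal half-sib family
structure; additive values g built from marker effects on centred
genotypes so cov(g) tracks the realised genomic relationships; microbial
values m correlated with g through `rho_gm` (the mechanism that induces a
genetic covariance between a trait and its microbial proxy); and the
observed trait y = μ · lot_factor · (1 + (g + m + e + fixed)/μ), which
exercises both the lot scaling and the fixed-effect adjustment.

`simulate_metagenome` generates counts from a log-linear latent model —
skewed tag baseline (sparsity), cohort-by-tag batch shifts, tag loadings
times the microbial value on a fraction `load_frac` of tags, latent noise —
followed by multinomial sampling at a log-normal depth, so row sums equal
depths and depth confounding is real. `simulate_reads` writes the counts
as FASTQ (Phred-40 placeholder qualities); tag extraction inverts it
exactly, a tested identity.

Deliberate omissions: restriction-site biology, PCR duplicates, sequencing
error within tag sequences, and real taxonomic composition. Consequently a
green test suite demonstrates the statistical machinery under the stated
generative assumptions — not robustness to laboratory artefacts beyond the
cohort effects modelled here.

The truth ratios reported by the generator use the total latent variance:
true h² = σ²_g/(σ²_g+σ²_m+σ²_e), so that the realised variance ratio of
simulated populations converges to it (verified at n = 5000 with
uncorrelated drivers).

## Recovery studies and their design

The acceptance-level simulation studies use 30 replicates each, at sizes
chosen to balance statistical resolution against a few minutes of
single-CPU runtime: heritability at n = 2000 animals × 5000 SNPs (truth
0.16), microbiability at n = 1000 × 3000 tags in a strong (0.64) and a low
(0.18) signal regime, and the bivariate genetic correlation at n = 1000
with B and C implied by heritabilities 0.21/0.37, phenotypic variances
2.27/0.66, genetic correlation 0.75 and phenotypic correlation 0.40.

Two design points deserve emphasis:

* **Relatedness.** The genotype simulations for the recovery studies use
  half-sib families (10 offspring per sire), the dominant relatedness
  structure of progeny-test sheep flocks. This is not cosmetic: with fully
  unrelated animals and a few thousand SNPs the GRM spectrum stays bounded
  away from zero, the genetic/residual decomposition — especially the
  six-parameter bivariate one — becomes weakly identified, and the REML
  surface can turn multi-modal. Family structure supplies the
  pedigree-like contrasts that identify genetic covariances in real
  datasets.
* **Kernel-conditional shrinkage.** Microbiability estimates under an MRM
  kernel show a small finite-sample shrinkage toward zero (of order 0.02
  at these sizes) that varies with the kernel realisation; it reflects the
  MRM's compressed eigenvalue spectrum, not an implementation defect — the
  same estimator is unbiased to Monte-Carlo precision when the kernel is
  held fixed.

## Numerical conventions, degenerate inputs, tie-breaks

* Convergence: univariate profile search tolerance 1e−10 on log λ;
  bivariate BFGS relative tolerance 1e−12 with a maximum of 200 iterations
  per start.
* Duplicate kernel eigenvalues need no special handling — nothing reported
  depends on individual eigenvectors.
* Zero-variance predictions within a validation group, groups smaller than
  3, singleton lots, and single-level fixed-effect classes are skipped or
  dropped with warnings, never silently.
* The cohort-blocked CV packer assigns whole cohorts greedily, largest
  flocks first, to the lightest fold, with a bonus (a quarter of the
  target fold size) for folds already holding the same flock; remaining
  ties break on fold index, and the cohort visit order is shuffled under
  the supplied seed, so plans are deterministic given (data, seed).
* PCA of a relationship matrix is reported up to component sign.

## Known limitations

Single records per animal (no repeatability models); one kernel per model
(no joint G + M fit, matching the separate-model analysis design); the
fixed-effects design is data-driven and does not reproduce any specific
national-evaluation adjustment; and the FASTQ writer emits placeholder
qualities, so quality-aware tools should not be benchmarked against it.
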