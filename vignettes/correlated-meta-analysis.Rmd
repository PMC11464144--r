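---
title: "Correlated meta-analysis of family-based kidney-function and sRAGE scans: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlated meta-analysis of family-based kidney-function and sRAGE scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleiocma)
```

# The problem

Kidney function is routinely estimated from two serum markers —
creatinine (eGFRcr) and cystatin C (eGFRcys) — and both estimates are
correlated with circulating levels of the soluble receptor for advanced
glycation end-products (sRAGE): strongly positively with each other
(about +0.70 after covariate adjustment) and moderately negatively with
sRAGE (about −0.25 and −0.30). When each trait is scanned separately for
genetic association in the *same* cohort, the three sets of p-values are
not independent: shared samples, correlated residuals, cryptic
relatedness and population structure all induce correlation between the
scans *under the null*. Naively combining the per-trait p-values
(Fisher's method) therefore inflates type-1 error exactly where
pleiotropy hunting is most tempting.

`pleiocma` implements the full workflow around this problem for a
family cohort:

1. a synthetic-cohort generator with pedigree kinship, a rare-variant
   MAF spectrum, the CKD-EPI phenotype algebra, correlated traits, and
   cis-eQTL expression counts;
2. per-trait kinship linear mixed model (LMM) association scans with
   genomic-control diagnostics;
3. gene-level (transcriptome) scans with empirical-null z-score
   correction;
4. correlated meta-analysis (CMA): empirical estimation of the
   between-scan null correlation and moment-matched combination of the
   dependent p-values;
5. locus post-processing: the three pleiotropy criteria, distance
   clumping, trait-subset classification, and novelty annotation
   against a catalog of known lead variants.

# The kinship mixed model

Each scan models the natural-log trait as
$$y = X\beta + g + e, \qquad g \sim N(0, \sigma^2_g\, 2K), \qquad
  e \sim N(0, \sigma^2_e I),$$
with fixed effects age, age², sex, field center and the first genotype
principal component. $K$ is the expected-kinship matrix computed
recursively from the pedigree; the factor 2 (numerator relationship) is
applied in exactly one place, `lmm_reml_fit()`, and nowhere else —
`build_kinship()` returns kinship $\phi$ itself (0.25 for
parent–offspring). The variance ratio
$\delta = \sigma^2_e/\sigma^2_g$ is profiled out by a one-dimensional
REML optimization over $\log\delta$ after a single eigendecomposition of
$2K$ (grid bracketing on $\log\delta \in [-12, 12]$ followed by local
refinement; eigenvalues of $2K$ in $[-10^{-8}, 0)$ are clipped to zero,
anything more negative is an error).

Per-variant tests hold the variance components fixed at the null fit and
apply generalized least squares to each dosage in the whitened
coordinates — the standard two-step approximation used by desk-scale
mixed-model GWAS tools. It trades a per-variant REML refit for a single
whitening, which is what makes a 10⁴-variant scan take seconds; the
approximation is exact under the null and slightly conservative for very
large effects. Two-sided p-values use the normal reference (recorded as
such); with the sample sizes the workflow targets (hundreds of
individuals, ~10 fixed effects) the difference from the t reference is
far below every tolerance tested. With $K = I$ the whole machinery
collapses to ordinary least squares, which the tests verify to six
significant digits.

Variants are filtered before testing: minor allele count below 20 is
excluded (strictly: MAC = 20 is kept), as are non-SNV alleles (any
allele string longer than one base).

# Transcriptome scans and the empirical null

Genes with fewer than 4 counts per million in at least 98.5% of samples
are removed (the boundary is inclusive: low in *exactly* 98.5% of
samples means dropped). Expression is transformed to
$\log_2(\mathrm{CPM} + 0.5)$ — a configuration choice recorded here, not
a claim about the emulated study — and residualized per gene on the
technical covariates by OLS. Each gene then enters the same
fixed-variance-component mixed-model test as a single predictor of the
covariate-adjusted trait. The trait's covariates must appear in the
trait-side design: residualized expression is orthogonal to the
covariate space, so covariate variance left in the trait inflates the
error variance estimate and *deflates* every z-score (we observed
λ ≈ 0.76 on null data before adopting this rule; with it, λ ≈ 1.0).

Test-statistic sets from transcriptome scans often carry residual bias
and inflation, so the z-scores are corrected against an *empirical*
null: a three-component normal mixture
$\pi_0 N(\mu_0,\sigma_0^2) + \pi_1 N(\mu_1,\sigma_1^2) +
 \pi_2 N(\mu_2,\sigma_2^2)$
is fitted and the dominant central component supplies
$(\hat\mu_0, \hat\sigma_0)$; corrected scores are
$(z - \hat\mu_0)/\hat\sigma_0$. We fit by maximum a posteriori EM with a
deterministic moment-based start (median/MAD for the null, side
components displaced by ±2 SD) rather than by Gibbs sampling: the
deterministic fit is reproducible and directly testable. Two devices
keep the fit identified when there is little or no signal, where the
unpenalized likelihood is flat and the side components otherwise eat the
null's own tails and bias $\hat\sigma_0$ downward:

* a Dirichlet prior on the weights centered on (0.99, 0.005, 0.005)
  with strength 0.2·n pseudo-observations — with real signal present the
  data overwhelm it (500 signal genes against 5 pseudo-counts), with
  pure null data it collapses the side components;
* the side components are constrained to be at least as wide as the
  null (true effects add variance to a component, they do not narrow
  it).

With these, the fit recovers $(\mu_0, \sigma_0)$ within ±0.05 on shifted
inflated nulls, restores λ to [0.95, 1.05], leaves a 10% signal
component intact, and is a fixed point on already-corrected scores.

# Correlated meta-analysis

## Estimating the between-scan null correlation

For each scan pair, markers with $p < 10^{-4}$ in either scan are
trimmed (so shared true signals do not masquerade as null correlation)
and the rest are cross-classified by $I(p < 0.5)$ — dichotomization at
the null median. From the 2×2 table, the latent correlation is
estimated by maximum likelihood.

A subtlety matters here. Association p-values are **two-sided**, so
$I(p < 0.5)$ dichotomizes $|z|$, not $z$. The classical (signed,
single-threshold) tetrachoric MLE applied to such a table estimates
neither the z-correlation nor anything the combiner can use: at a true
z-correlation of 0.7 it returns ≈ 0.38, and feeding that into the
combiner's covariance produced λ ≈ 0.89 and a 3.3-fold inflated
$10^{-4}$ exceedance in our null experiments. The default estimator
(`tetrachoric_twosided()`) therefore solves the both-tails orthant
equation
$$P(|Z_1| > c_1, |Z_2| > c_2;\ \rho) = a/n$$
for $|\rho|$, with thresholds fixed from the margins. The sign of
$\rho$ is not identifiable from magnitudes — and is not needed, because
the combiner's covariance for two-sided statistics is even in $\rho$.
This estimator recovers $|\rho| = 0.700$ from $10^6$ dichotomized draws
at truth 0.7. The classical signed tetrachoric (root-finding on the
single-threshold orthant probability, with the cosine closed form as a
fallback) remains available as `tetrachoric()` for one-sided inputs and
is validated to ±0.02 at $m = 10^5$.

The pairwise estimates are assembled into a correlation matrix,
eigenvalue-clipped to the nearest positive semidefinite matrix if
needed (and flagged when that happens). Estimated correlations are
capped at ±0.999; analytic inputs of exactly ±1 are honored by the
combiner so that the duplicate-scan identity holds to machine
precision.

## Combining dependent p-values

Fisher's statistic $T = \sum_{i} -2\ln p_i$ over a subset of $k$ scans
has mean $2k$ and, under dependence, variance
$4k + 2\sum_{i<j}\mathrm{cov}_{ij}$. The covariance of two Fisher terms
is computed by Gauss–Hermite quadrature of the bivariate-normal
expectation with a one- or two-sided p-value mapping; the one-sided
quadrature reproduces the familiar cubic approximation
$3.263\rho + 0.710\rho^2 + 0.027\rho^3$ to four decimals (the cubic is
retained as the `kost` option and as a cross-check). The two-sided
covariance — the relevant one for association scans — is markedly
smaller (e.g. 1.91 vs 2.64 at $\rho = 0.7$).

The null of $T$ is approximated by a gamma family matched on moments.
The classical scaled chi-square matches mean and variance
($f = 2E^2/\mathrm{Var}$, $c = \mathrm{Var}/2E$, `moments = "two"`). We
found its tail too light for two-sided statistics: at $\rho = 0.5$ and
$p = (0.01, 0.01)$ it returned 0.0025 against a Monte-Carlo truth of
0.0035, and in a $10^6$-draw null calibration the $10^{-4}$ exceedance
came out at $1.9\times10^{-4}$. The default (`moments = "three"`)
additionally matches the third central moment with a location-shifted
gamma; the extra pairwise and triple cross-moments are again exact
quadratures. This repairs the tail (MC agreement within 6%, exceedance
$1.0\times10^{-4}$, λ = 1.03) while collapsing *exactly* to the
two-moment fit in the symmetric cases that anchor the method:

* at $R = I$ both reduce to Fisher's $\chi^2_{2k}$, bitwise;
* at $\rho = 1$ (duplicated scans) both return the single-scan p-value
  to machine precision;
* the combined p is nondecreasing in any off-diagonal correlation.

A directional correlated-Stouffer combiner
($Z = \sum z_i / \sqrt{1^\top R 1}$) is provided for sensitivity
analyses.

## Subset enumeration and the pleiotropy criteria

Per marker, every trait subset of size ≥ 2 whose members all reach the
per-scan eligibility cut ($p < 0.01$) is combined; the subset with the
smallest combined p-value is the marker's headline record (ties toward
the larger subset, then lexicographic order), with all evaluated
subsets retained. With `eligibility = NULL` only the full trait set is
combined for every marker — the form used for genomic control and
calibration, where per-marker minimum-p selection over subsets would
itself inflate the null (we measured λ = 1.83 from exactly that
mistake).

A marker is called pleiotropic iff (i) every contributing scan p is
below 0.01, (ii) the combined p is below $5\times10^{-8}$, and
(iii) the combined p is strictly below the smallest contributing p. For
gene-level records the per-scan cut is dropped and the threshold is the
transcriptome Bonferroni value; the "strictly below the minimum"
reading of criterion (iii) is the default, with a documented
`rule = "any"` alternative — the bundled published gene table contains
exactly one gene (LSP1) that separates the two readings, and the
replay test pins that behavior.

Passing records are clumped greedily: the smallest combined p leads a
locus, absorbing all passing records within ±500 kb on the same
chromosome ("within a 1 Mb region"; the ±500 kb radius makes the locus
window and the novelty rule mutually consistent). Equal p-values break
toward the smaller genomic position. A locus is *novel* iff its lead is
strictly more than 500 kb from every catalog entry on the same
chromosome; builds are compared as metadata labels and a mismatch is an
error. Coordinates are 1-based inclusive throughout.

# The synthetic cohort

The generator's defaults encode the study conditions the analysis
assumes:

* **Pedigrees**: three-generation families (founder couple, married
  offspring, grandchildren), unrelated founders, no inbreeding.
* **Genotypes**: founder dosages Binomial(2, MAF), Mendelian
  transmission to descendants; the default MAF spectrum mixes 80%
  common (Uniform(0.05, 0.5)) with 20% rare variants below 0.5% — the
  frequency class in which family-based sequencing recovers loci that
  imputation-based scans miss.
* **Traits**: latent standardized trait vectors per individual with
  total cross-trait correlation fixed at C (+0.70 / −0.25 / −0.30 by
  default) for any heritability — the polygenic term (covariance
  $h^2 \cdot 2K$ per trait) and the residual share C, so the
  correlation target and the heritability knob are orthogonal.
  Defaults: $h^2 = 0.3$ per trait.
* **Concentrations**: the eGFR-directed latents are sign-flipped onto
  the concentration scale (eGFR falls as its marker rises) and mapped
  to lognormal serum creatinine (mean 1.05 mg/dL), cystatin C
  (1.08 mg/L) and sRAGE (601.8 pg/mL) with CV-matched log-SDs; age,
  age², sex, center and PC1 effects are added on the log-concentration
  scale with configuration-default magnitudes (the emulated study does
  not publish these coefficients, so the defaults are plausible values,
  not claims). eGFR is then recomputed through the CKD-EPI 2021
  race-free creatinine equation and the 2012 cystatin C equation, whose
  coefficients are fixed constants with hand-computed test values, and
  CKD is flagged strictly below 60 mL/min/1.73 m².
* **Expression**: negative-binomial counts (dispersion 0.1), lognormal
  library-size factors (CV 0.3), optional cis-eQTL log2-fold-change
  effects per dosage copy.
* **Overlap**: the scans of the emulated design share all individuals;
  `overlap < 1` analyses partially overlapping subsets of one cohort to
  probe CMA calibration at partial overlap.

Every stochastic operation takes an explicit seed; there is no hidden
global state, and re-running any stage with the same seed is
byte-identical.

What the generator does **not** emulate — and what passing tests on it
therefore cannot show — includes linkage disequilibrium between
variants (clumping here groups by distance only), genotyping and
sequencing error, X-chromosome inheritance, ascertainment of families
for longevity, and real covariate-trait confounding structure. Results
on real cohort data additionally depend on upstream variant calling and
RNA-seq processing that are outside this package's scope.

# Problem sizes and numerical choices

The test suite and the acceptance script run the simulations at sizes
chosen to make their tolerances meaningful on a single CPU in minutes:
null-scan calibration at 40 families × 10⁴ variants, combined-scan
calibration on 10⁶ correlated draws, tetrachoric recovery at 10⁵ draws
per correlation, heritability recovery over 50 replicates of a
210-member pedigree, and empirical-null recovery at 5,000 z-scores.
Quadratures use 96 Gauss–Hermite nodes for pairwise moments and 40³ for
the triple moment (both verified against Monte-Carlo); orthant
probabilities use `mvtnorm` with absolute error 10⁻¹⁰ and root-finding
tolerance 10⁻⁹.

Known limitations: the gamma tail approximation, although
third-moment-matched, is still an approximation — its far-tail error
grows again beyond roughly $p < 10^{-10}$; the EMMAX-style two-step
test slightly underestimates the variance of very large effects; the
empirical-null EM assumes the null component is the dominant central
one, which fails if a majority of genes carry signal; and the
between-scan correlation is assumed constant across the genome (an
LD-pruned or per-chromosome estimate would relax this but is not
implemented).

# A worked end-to-end run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(n_fam = 40, m = 10000, seed = 11, h2 = 0.3,
                       out_dir = "results")
res <- run_pipeline(cfg)
res$lambdas          # per-scan and combined genomic-control factors
res$correlation$rho  # estimated between-scan null correlation
nrow(res$loci)       # loci passing the three pleiotropy criteria
```

On a null cohort (no variant effects) this reports per-scan λ between
0.95 and 1.05, a correlation matrix close to (0.70, 0.25, 0.30) in
magnitude, and — in at least 95% of seeds — zero passing loci at the
$5\times10^{-8}$ threshold. The numbered scripts under `analysis/`
narrate the same workflow stage by stage, and
`scripts/acceptance.R` recomputes the headline quantities from scratch.
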