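---
title: "From cardiac motion to causal inference: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From cardiac motion to causal inference: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diastolr)
```

# Overview

`diastolr` implements an analysis chain for studying the genetics of
diastolic heart function on synthetic cohorts with known ground truth. The
chain mirrors a modern imaging-biobank study: cine-derived phenotypes
(peak early diastolic strain rates and indexed maximal left atrial volume),
covariate-adjusted genome-wide association with variant quality control,
LD-score regression for heritability and genetic correlation, small
instrument sets ("polygenic instrumental variable scores", PIVS) with a
phenome-wide scan, and bidirectional two-sample Mendelian randomization with
an explicit causal decision rule. Every stage is exercised against planted
truth from the package's own seeded generators.

# Diastolic phenotyping

## Strain and strain rate

Myocardial strain along direction $d$ is the fractional length change of a
tracked line segment relative to end-diastole,
$E_d(t) = (L_d(t) - L_d(0)) / L_d(0)$, computed per anatomical segment (16
segments by convention) and averaged with equal weights into a global curve.
The aggregation is a design choice: averaging segment strains is symmetric
and robust to single-segment jitter; the alternative (peak of the mean
curve versus mean of segment peaks) changes peak values only marginally for
the smooth curves considered here.

The strain rate is the first time-derivative of strain. Curves are sampled
at 50 phases with 31 ms spacing, so naive differencing amplifies
segmentation noise; `compute_strain_rate()` therefore differentiates a
local least-squares quadratic over `smooth_window = 5` phases (a
Savitzky-Golay slope), treating the cycle as periodic at the boundary.
`smooth_window = 1` reduces to central differences.

## Peak detection

The peak early diastolic strain rate (PDSR) is reported as a positive
magnitude although radial recoil has negative $dE/dt$: detection restricts
to phases strictly after the global peak of $|E|$, signs the strain rate so
that recoil is positive, and finds local maxima. Because the 5-point
smoothed derivative attenuates a ~200 ms recoil wave by several percent,
the magnitude is re-estimated by an interpolating parabola through the
unsmoothed central-difference derivative at the three phases around the
detected peak, with an analytic correction for the $O(\Delta t^2)$
central-difference bias. The refinement is used only when the peak is
resolved by the sampling (both neighbours at least half the centre value);
otherwise the sampled value is kept, which protects against step artefacts.
With these choices the worst-case recovery error for planted peaks of
1-6 s$^{-1}$ at zero noise is below 0.03 s$^{-1}$, within the 0.05 s$^{-1}$
validation band. When strain peaks on the final phase or no interior
extremum exists, a flagged missing value is returned rather than an error.

## Atrial volume and indexing

Left atrial volume uses the biplane area-length formula
$V = \frac{8}{3\pi} \, A_{2Ch} A_{4Ch} / L$; for areas and length taken
from an ellipsoid this is algebraically exact, which the tests exploit as a
machine-precision oracle. The maximal volume over the cycle is converted to
millilitres and indexed to the Du Bois body surface area
$0.20247 \, W^{0.425} H^{0.725}$ (weight in kg, height in m).

# Synthetic cohorts

## Genotypes

Genotypes come from a latent Gaussian copula: two haplotype layers with an
exchangeable within-block correlation are thresholded at each variant's
allele-frequency quantile and summed to dosages in $\{0,1,2\}$. This gives
controllable block LD, Hardy-Weinberg-consistent genotypes, and exact
reproducibility from one integer seed (all generators split a caller seed
through a counter-based scheme, so adding a stage never perturbs another
stage's draws). Thresholding attenuates the dosage correlation relative to
the latent correlation, as in any discretized copula; tests therefore
compare against an independently coded copula oracle rather than the latent
value. Blocks are separated by 2 Mb so a 1000 kb clumping or LD-score
window never spans two blocks.

## Traits, endpoints and geometry

Quantitative traits are built as covariate part + genetic value + residual.
The genetic value is a weighted sum of standardized causal dosages; the
residual is orthogonalized against it in-sample and both are rescaled so
the realized heritability equals the target exactly, which makes
heritability book-keeping testable to machine precision. Genetic
correlation between traits is induced by shared causal variants with
correlated effect sizes (the same bivariate architecture that LD-score
regression models). Binary endpoints follow a liability-threshold model
with an empirical-quantile cut at the requested prevalence, and cases are
split into baseline and incident (follow-up) flags; incident events use a
single follow-up window because the downstream comparison model is plain
logistic regression, not a time-to-event model.

Cine geometry plants trait values physically: the strain curve is the
integral of a systolic and an early-diastolic Gaussian strain-rate wave
(recoil width 0.08 s, a realistic E-wave duration) whose planted peak is
the subject's PDSR, and atrial areas are constructed self-consistently from
a planted volume curve with equal areas in both views, so the biplane
formula recovers the planted maximum exactly at zero noise. The geometry is
stylized in two respects: there is no atrial-kick (A-wave) component, and
strain amplitudes follow from the planted peak rate rather than being
matched to population strain tables. Passing tests therefore demonstrate
correct recovery of planted mechanics under the stated sampling, not
robustness to all features of real feature-tracking output (through-plane
motion, tracking drift, arrhythmia).

## The end-to-end study world

`simulate_study()` builds a two-cohort world (default 2,000 imaging +
8,000 non-imaging samples, 5,000 SNPs in 500 blocks) with the causal graph
pulse $\leftrightarrow$ PDSR$_{rr}$, PDSR$_{rr} \to$ heart failure,
LAV $\to$ atrial fibrillation, imposed by a linear structural-equation
step (the two-way pulse relation is solved as a 2x2 linear system).
Heritabilities default to the 12-21% range reported for diastolic traits,
concentrated in 8-15 loci per trait with bounded-magnitude, random-sign
effects ($|a|$ uniform in $[0.7, 1.3]$ before scaling). Concentration is
deliberate: it reproduces the instrument-strength regime of the study
design (instrument sets of 8-20 variants) at desk-scale sample sizes, and
the spread in $|a|$ keeps the MR-Egger slope identifiable. Endpoint
prevalences default to 15% so that logistic association scans in an
8,000-sample cohort yield instrument-grade signals; rarer, more clinically
typical endpoints would require far larger simulated cohorts without
changing any method.

# Association and genetic architecture

Variant QC removes MAF < 0.005 and exact Hardy-Weinberg p < 0.05 (the
printed filter direction; the threshold is a config argument because 0.05
is aggressive). The HWE test is the exact conditional test on heterozygote
counts, evaluated in closed form with vectorized log-gamma terms so whole
panels can be filtered cheaply.

Quantitative scans are ordinary least squares with covariate partialling
(Frisch-Waugh), vectorized across variants and traits; dosages are
mean-imputed per variant, mirroring score construction. Binary scans use a
hybrid standard in GWAS tooling: an efficient-score estimate from the
covariate-only null model for every variant, with a full per-variant IRLS
refit wherever the score p-value falls below $10^{-4}$, so instrument-grade
effect sizes are exactly the maximum-likelihood ones while the scan stays
linear-algebra bound. Mixed-model association is intentionally out of
scope: synthetic cohorts are unrelated by construction, and the
summary-statistics interfaces accept externally computed results.

Clumping is greedy: smallest-p variant below the threshold becomes an
index; unassigned variants within 1000 kb at $r^2 \ge 0.1$ join its clump;
ties break by (chromosome, position, id) for determinism. Correctness is
established against an exhaustive brute-force implementation on hundreds of
random instances.

LD-score regression regresses per-variant $\chi^2$ on window LD scores in
two passes: a first pass with weights $1/\max(\ell_j, 1)$, then a second
pass whose weights include the $\chi^2$ variance implied by the first-pass
heritability, $1/(\ell_j (1 + n \hat h^2 \ell_j / m)^2)$ — the standard
LDSC weighting. The slope times $m/n$ estimates SNP heritability, the
cross-trait z-score product version estimates genetic covariance, and
standard errors come from a 20-block delete-one jackknife in position
order (making the estimate invariant to row permutations). Because the
regression identifies the slope from variation in $\ell_j$, validation
panels draw each block's latent correlation from a range rather than a
constant — with uniform LD the regressor is nearly degenerate and the
estimator, while unbiased, is needlessly noisy.

Gene-level loss-of-function burden tests collapse qualifying variant flags
(MAF < 0.05) to a carrier indicator per gene, require at least two
carriers, and adjust per gene across the three diastolic traits with
Benjamini-Hochberg.

# PIVS and PheWAS

PIVS candidates are clump indices at $p < 10^{-6}$, $r^2 < 0.1$, 1000 kb.
Weights come from one joint linear model of the SD-1-scaled trait on all
candidate dosages plus covariates, so a unit score change corresponds to
one trait SD. Scores multiply dosages by weights and sum, with missing
genotypes imputed as twice the scoring allele frequency; scoring
frequencies are taken from the construction cohort (always available, and
the natural choice when the evaluation cohort may be external). Allele
flips are harmonized, and flip-plus-negate leaves scores invariant.

The PheWAS standardizes quantitative outcomes in the evaluation sample,
uses logistic regression for binary outcomes, and adjusts per score family
with Benjamini-Hochberg. The leave-one-SNP-out rule refits the full PIVS
without each instrument (a full refit, not a reweighting — the joint model
redistributes weight when an instrument is removed), re-runs the
association, adjusts the k leave-one-out p-values per (trait, phenotype)
with Benjamini-Hochberg, and passes only when all remain significant; this
vetoes associations driven by a single variant.

Stability selection for the observational models subsamples half the data
100 times and counts how often each predictor enters the lasso path. The
per-subsample path is truncated once more than $q = \lceil\sqrt{0.8p}\rceil$
variables are active, which bounds false selections in the
Meinshausen-Buhlmann manner; with an unbounded path every predictor
eventually enters and the selection frequency of noise predictors is no
longer controlled. The plain-subsampling variant is used (rather than
complementary pairs), with B = 100, fraction 0.5 and threshold 0.6 as
config defaults.

# Mendelian randomization

Both directions of each trait pair run the same pipeline: restrict to the
intersection of variant sets, clump the exposure statistics, harmonize
(swapped alleles flip the outcome beta; strand complements resolve through
the base-complement map; palindromic variants with allele frequency within
0.08 of 0.5 in either study are dropped as ambiguous, a reconstruction
documented as such), filter instruments associated with measured
confounders at $p < 10^{-5}$ (a suggestive-association convention, config
exposed), and apply Steiger filtering: an instrument is removed when its
approximate explained variance in the outcome, $2p(1-p)\beta^2$ on the SD
scale (log-odds effects use the logistic-liability approximation with
variance $\pi^2/3$, a documented caveat), significantly exceeds that in the
exposure by the Fisher-z test at 0.05.

Estimators:

* **IVW** (main analysis): weighted least squares of outcome on exposure
  betas through the origin, weights $1/se_{out}^2$; equivalently the
  weighted mean of Wald ratios. The standard error is inflated by
  $\sqrt{Q/(k-1)}$ only when Cochran's Q exceeds its degrees of freedom
  (multiplicative random effects); with one instrument it reduces to the
  Wald ratio.
* **Weighted median**: weighted median of Wald ratios with delta-method
  inverse-variance weights; parametric-bootstrap standard error (1000
  seeded replicates by default; the reference description leaves the SE
  method open).
* **MR-Egger**: weighted regression with free intercept after orienting
  exposure betas non-negative; the intercept tests directional pleiotropy;
  t-inference with $k-2$ degrees of freedom and multiplicative
  random-effects inflation floored at one.
* **MR-PRESSO-style**: leave-one-out IVW residual sum of squares compared
  with parametric simulations under no pleiotropy (global test),
  per-instrument outlier p-values from the same simulations with Bonferroni
  correction, outlier-corrected IVW, and a distortion test against random
  same-size removals.

The decision rule is applied verbatim: "potential causal" requires IVW
p < 0.01, at least two sensitivity analyses with p < 0.05 and the same
direction, and no sensitivity analysis suggestive in the opposite
direction (which instead yields "inconsistent"). No multiplicity
adjustment is applied across MR experiments. The verdict object stores all
per-method results so the classification can be reproduced from it.

For potential-causal relationships involving a disease endpoint, the
epidemiological comparison restricts to baseline-disease-free subjects and
fits logistic regression of the incident indicator on the SD-scaled trait
with age, sex, diabetes, diastolic blood pressure and BMI as covariates.

# Numerical and testing choices

Problem sizes were chosen so the whole validation suite runs comfortably on
one CPU: LD-score recovery uses one 10,000 x 5,000 panel with 50 trait
redraws; MR calibration uses 500 summary-statistic replicates (bootstrap
and simulation counts of 200-500 inside replicated tests, with the defaults
of 1000 retained for single analyses); the end-to-end study is rerun for 20
seeds. Determinism is enforced everywhere by explicit seeds; the bootstrap,
PRESSO simulations and subsampling are all reproducible.

Known limitations: the generator produces strand-unambiguous allele pairs
by default (palindromic handling is tested on constructed records); LD is
exchangeable within blocks rather than following a recombination map; the
logistic score-test path slightly shrinks extreme effect sizes for variants
that do not reach the refit threshold; binary-trait Steiger filtering uses
an approximation; and the incident-event model ignores censoring time.
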