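# diastolr

Diastolic function — the mechanics of ventricular relaxation, stiffness and
recoil during filling — predicts cardiovascular outcomes, but studying its
genetics requires a long analysis chain: strain-rate phenotyping from
cardiac cine imaging, genome-wide association, compact genetic instruments,
and Mendelian randomization against disease endpoints. `diastolr`
implements that chain as tested, reusable R functions, exercised end-to-end
on seeded synthetic cohorts with known ground truth, for methodologists and
students who want every stage of such a study to be reproducible and
checkable against planted answers.

## What it computes

**Phenotypes.** Per-segment myocardial strain `E(t) = ΔL/L`, strain rate as
the derivative of a local-quadratic fit at 31 ms resolution, peak early
diastolic strain rate (PDSR, radial and longitudinal, s⁻¹) by signed local
extremum detection with sub-frame refinement, left atrial volume by the
biplane area–length formula `V = (8/3π)·A₂Ch·A₄Ch/L`, and maximal volume
indexed to the Du Bois body surface area
`0.20247·W^0.425·H^0.725` (mL/m²).

**Genetic architecture.** Exact Hardy–Weinberg QC, covariate-adjusted
linear and logistic association scans, greedy LD clumping (p < 10⁻⁶,
r² < 0.1, 1000 kb), window LD scores, LD-score regression
(`χ²_j ≈ 1 + n·h²·ℓ_j/m`, slope → SNP heritability; cross-trait version →
genetic correlation, jackknife standard errors), and gene-level
loss-of-function carrier burden tests with per-gene FDR across the three
diastolic traits.

**Instruments and causality.** Polygenic instrumental variable scores
(jointly fitted weights on clumped candidates, unit = 1 trait SD), PheWAS
with Benjamini–Hochberg control and a leave-one-SNP-out veto for
single-variant-driven hits, and bidirectional two-sample Mendelian
randomization: harmonization, confounder and Steiger filtering, IVW (main),
weighted median, MR-Egger and an MR-PRESSO-style outlier test, classified
by the rule *potential causal ⇔ IVW p < 0.01, ≥ 2 sensitivity analyses
p < 0.05 with consistent direction, none suggestive in the opposite
direction*.

**Synthetic cohorts.** Seeded generators for block-LD genotypes (latent
Gaussian copula), polygenic traits with exact realized heritability and
shared-variant genetic correlation, liability-threshold endpoints with
baseline/incident flags, per-subject cine geometry with planted PDSR and
atrial volumes, and a two-cohort study world with the causal graph
pulse ↔ PDSR_rr, PDSR_rr → heart failure, LAV → atrial fibrillation.

## Worked example

```r
library(diastolr)

study <- simulate_study(seed = 42)          # ~10k samples, 5k SNPs, cine geometry
res   <- run_study_pipeline(study)

res$labels
#>    pdsr_rr_vs_hf        lav_vs_af pdsr_rr_vs_pulse
#>    "a_to_b_only"    "a_to_b_only"  "bidirectional"

res$mr$pdsr_rr_vs_hf$a_to_b
#> <causal_verdict> potential_causal (direction -1, IVW p = 2.21e-09, 3 sensitivity)
res$mr$pdsr_rr_vs_hf$b_to_a
#> <causal_verdict> not_causal (direction +1, IVW p = 0.273, 3 sensitivity)
```

The labels read: genetically lower radial strain rate (a stiffer ventricle)
raises heart-failure risk with no reverse effect; larger indexed atrial
volume raises atrial-fibrillation risk with no reverse effect; pulse rate
and radial strain rate influence each other — exactly the causal graph the
generator planted. The negative direction on the first verdict is the
protective sign: each SD of higher strain rate lowers the odds of heart
failure.

Individual stages are available directly:

```r
cine <- simulate_cine_series(100, noise_sd = 0, seed = 7)
ph   <- extract_phenotypes_cohort(cine$geometries,
          data.frame(subject_id = cine$truth$subject_id,
                     weight = 75, height = 1.72))
max(abs(ph$pdsr_rr - cine$truth$pdsr_rr))
#> [1] 0.02811  (s^-1, zero-noise recovery error)
```

## Testing

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "diastolr",
                               load_package = "installed")'
```

The suite contains per-module unit and property tests plus whole-method
validation (estimator calibration, oracle equivalence for clumping,
LD-score recovery, the end-to-end causal-graph study).

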