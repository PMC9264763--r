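# rsibreast

Voxel-wise three-compartment restriction spectrum imaging (RSI) analysis of
multi-shell breast diffusion-weighted MRI (DW-MRI), for imaging scientists who
want to separate malignant lesions from benign lesions and healthy tissue
without contrast agents — plus everything needed to exercise the analysis on
synthetic data: phantom simulation, preprocessing, ROI extraction and the
paired group statistics.

## The model

Over an extended b-value range the breast DW-MRI magnitude signal is modelled
as a linear combination of three exponential decays with *fixed* diffusivities:

    S(b) = C1 + C2 · exp(−b · 1.5e−3) + C3 · exp(−b · 10.8e−3)

with b in s/mm² and D1 = 0 (restricted diffusion, intracellular-like water),
D2 = 1.5 × 10⁻³ mm²/s (hindered, extracellular-like) and D3 = 10.8 × 10⁻³
mm²/s (pseudo-diffusion/flow). Because the diffusivities are constants of the
model, the per-voxel unknowns are only the non-negative signal contributions
C = (C1, C2, C3), estimated by exact non-negative least squares (NNLS) from
the shell-averaged signal-versus-b curve. Malignant tissue shows high C1;
the combination maps C1·C2 and √(C1·C2) sharpen that contrast. A conventional
mono-exponential ADC map (shells up to 1500 s/mm²) is computed alongside.

The surrounding pipeline: Rician noise-floor estimation from a background
histogram and subtraction; averaging of all diffusion directions per shell;
normalization by the 98th percentile of the b = 0 volume; ROI medians (one
data point per tissue type per patient, with a 500-voxel contralateral
healthy-control box); and the statistical battery — Shapiro–Wilk, Levene,
ranked two-way repeated-measures ANOVA (tissue × diffusion component), and
post hoc exact Wilcoxon signed-rank tests with Bonferroni correction
(family = 3, α = 0.05).

## Worked example

A single malignant-like voxel, synthesized noiselessly and recovered:

```r
library(rsibreast)
b   <- c(0, 500, 1500, 4000)
A   <- build_design_matrix(b)                     # shells x components
sig <- as.numeric(A %*% c(0.32, 2.6, 0.13))       # forward model
fit <- rsi_fit(matrix(sig, 1), b_values = b)
coef(fit)
#>   C1   C2   C3
#> 0.32 2.60 0.13
```

The recovered contributions equal the ground truth to numerical precision:
with four distinct shells the design has full column rank, so the noiseless
NNLS round trip is exact.

A full synthetic cohort — 12 patients, each with one malignant and at least
one benign lesion (14 benign lesions in total), Rician noise, complete
pipeline:

```r
coh <- generate_cohort(12, seed = 42)
res <- analyze_cohort(coh)
print(res$stats)
```

```
Ranked two-way repeated-measures ANOVA (tissue x component):
    comparison  statistic df        p_raw
        tissue   9.310388  2 1.176032e-03
        metric 136.847095  2 3.867041e-13
 tissue:metric  14.181947  4 1.634756e-07

Pairwise Wilcoxon signed-rank (Bonferroni-adjusted):
                     comparison statistic    p_raw p_adjusted
        C1: malignant vs benign        78 0.000488    0.00146
       C1: malignant vs healthy        78 0.000488    0.00146
          C1: benign vs healthy        24 0.266113    0.79834
      C1C2: malignant vs benign        78 0.000488    0.00146
     C1C2: malignant vs healthy        78 0.000488    0.00146
        C1C2: benign vs healthy        39 1.000000    1.00000
  sqrtC1C2: malignant vs benign        78 0.000488    0.00146
 sqrtC1C2: malignant vs healthy        78 0.000488    0.00146
    sqrtC1C2: benign vs healthy        32 0.622070    1.00000
```

(excerpt). Reading: tissue type and diffusion component both matter (ANOVA);
malignant lesions differ from benign lesions and healthy tissue in the
restricted compartment C1 and in both combination maps, while benign and
healthy tissue are statistically indistinguishable — the qualitative
behaviour the model is designed to expose. A statistic of 78 is the maximum
positive-rank sum at n = 12: every patient's malignant value exceeded the
paired benign/healthy value.

The disk-based pipeline (`run_rsi_pipeline(pipeline_config(seed = 1), "out")`)
externalizes every intermediate — DWI as 4D NIfTI + FSL-style `.bval` sidecar,
masks as uint8 NIfTI, one NIfTI per parametric map, the cohort table as CSV,
statistics as JSON and a checksummed manifest; identical config + seed gives
identical checksums. A thin CLI wrapper lives at `inst/cli/rsibreast.R`.

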