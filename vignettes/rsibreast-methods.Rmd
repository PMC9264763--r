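---
title: "Methods: fixed-spectrum compartment modelling of breast DW-MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fixed-spectrum compartment modelling of breast DW-MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsibreast)
```

## The model and its assumptions

Breast diffusion-weighted MRI acquired over an extended b-value range (here
0, 500, 1500, 4000 s/mm²) carries contributions from water pools with very
different mobility. The package models the shell-averaged magnitude signal of
each voxel as a three-compartment restriction spectrum,

$$S(b) = C_1 + C_2\,e^{-b\cdot 1.5\times 10^{-3}} + C_3\,e^{-b\cdot 10.8\times 10^{-3}},$$

with fixed diffusivities $D_1 = 0$ mm²/s (restricted diffusion:
intracellular-like water, elevated in cellular tumours), $D_2 = 1.5\times
10^{-3}$ mm²/s (hindered, extracellular/fibroglandular-like) and $D_3 =
10.8\times 10^{-3}$ mm²/s (pseudo-diffusion: flowing or free fluid). Fixing
the spectrum is what makes the per-voxel contributions $C_i$ comparable
across voxels and patients; the package deliberately does not re-estimate the
diffusivities (they can be overridden in `diffusion_spectrum()` but are
constants of the breast model). The model assumes isotropic diffusion within
a voxel and complete fat suppression; both are approximations of real breast
tissue, and fits on real data inherit them.

Estimation is by exact non-negative least squares. Two solvers implement the
same contract: `nnls_fit()` is the classical Lawson–Hanson active-set
iteration, and `nnls_batch()` solves whole volumes at once by enumerating all
$2^3$ candidate supports — the NNLS optimum must be the minimum-residual
feasible support-restricted least-squares solution, so for a three-column
design the enumeration is exact and reduces the volume fit to a handful of
dense matrix products. Tests cross-check both against each other, against an
independent NNLS implementation, and against a brute-force non-negative grid
search. Non-negativity of the estimates is a constraint of the optimization,
not a post hoc clip.

Derived outputs are the combination maps $C_1 C_2$ and $\sqrt{C_1 C_2}$ (the
root puts the combination on the scale of the individual maps) and a
conventional mono-exponential ADC map fitted by ordinary least squares of
$\log S$ on $b$ over shells up to 1500 s/mm² — the 4000 s/mm² shell never
enters the ADC. Voxels with non-positive signal on a used shell or a negative
fitted ADC are flagged invalid and excluded from ADC ROI statistics only.
Whether a two-point or three-shell ADC is preferable is not settled for this
protocol; the default is the three-shell OLS (it uses all the data below the
cutoff) and `mode = "two_point"` provides the alternative.

## Preprocessing

The chain runs in a fixed order: geometric-distortion and eddy-current hooks
(identity pass-throughs here — on real data these are done by external tools),
noise-floor estimation, floor subtraction, shell averaging, then
normalization.

* **Noise floor.** Magnitude MRI has Rician noise, so air background has a
  positive mean (the noise floor). The estimator histograms the mean b = 0
  volume into 256 equal-width bins, takes the lowest-intensity mode as the
  background peak and averages all voxels below the first local minimum after
  that mode. A user-supplied background mask bypasses the histogram. The
  subtraction clips at zero: downstream NNLS assumes non-negative magnitudes.
  As noise vanishes the estimate tends to the mean of the sub-threshold true
  signal tail — effectively zero relative to tissue, but not machine zero,
  which is why the tests assert the limit relative to a noisy-condition floor.
* **Shell averaging** is the voxel-wise arithmetic mean of all acquisitions
  sharing a b-value (diffusion directions and the two b = 0 polarities alike).
* **Normalization** divides every shell by the 98th percentile (linear
  interpolation between order statistics, R quantile type 7, pinned for
  reproducibility) of the full b = 0 volume. This preserves between-shell
  ratios exactly, so fitted contributions are all scaled by the same factor;
  rank-based group statistics are invariant to it. ADC uses the *unnormalized,
  not noise-corrected* shell averages and is scale-free anyway.

## What the phantom generator emulates

`generate_patient_phantom()` builds a two-breast voxel phantom: two ellipsoids
of fat-suppressed adipose background (low, nearly constant signal) with a
fibroglandular core (65% of each semi-axis, ~27% of breast volume) carrying
the healthy-tissue contrast; one malignant and one or more benign ellipsoidal
lesions with diameters drawn from reported radiology size ranges (malignant
1.9–6.2 cm in plane, benign up to ~3.5 cm, both thinner through-plane). The
default grid is 64 × 64 × 12 voxels of 2.5 × 2.5 × 5.0 mm — large enough to
hold both breasts, the lesions and a 500-voxel contralateral control box,
small enough that a 12-patient cohort simulates and analyses in seconds.

Compartment fractions are drawn per tissue from independent log-normal
distributions parameterized by target median and IQR (log-normality guarantees
non-negativity, and median/IQR is exactly the information available per
tissue). Sampling is hierarchical: half of the squared log-scale dispersion
sits between patients (each patient-tissue gets its own median) and half
within the lesion across voxels. The even split (`patient_share = 0.5`) is a
design choice made once: ROI medians of several hundred voxels average away
most within-lesion scatter, so the between-patient share is what drives the
paired statistics, while the within-lesion share keeps individual maps
realistically heterogeneous. Per-lesion heterogeneity is not an observable of
the summary tables the targets come from, so it is genuinely free here.

Noise is Rician — each acquisition value $s$ is replaced by
$\sqrt{(s+g_1)^2+g_2^2}$ with independent zero-mean Gaussians of sd
$\sigma$ — applied independently per acquisition before shell averaging. The
default $\sigma = 0.025$ in normalized-signal units puts fibroglandular
tissue (b = 0 signal ≈ 1.3) at SNR ≈ 50, a typical clinical level; the air
background then shows the expected Rayleigh floor $\sigma\sqrt{\pi/2}$, which
is what the noise-floor stage estimates — no separate additive offset is
simulated. The two b = 0 polarities are two identically distributed
acquisitions; geometric distortion is not simulated.

All randomness flows from one master seed: the cohort driver draws one
sub-seed per patient from the master stream, so cohorts are reproducible and
single patients can be regenerated in isolation. By default two patients of
a 12-patient cohort carry a second benign lesion (14 benign lesions total).

What the phantom does *not* emulate: anisotropic diffusion, coil-sensitivity
and B0-inhomogeneity effects, incomplete fat suppression, partial-volume
mixtures at lesion boundaries beyond voxelized ellipsoids, and any coupling
between a patient's tissues beyond the hierarchical draws (tissues are
sampled independently within a patient). Passing tests therefore demonstrate
correctness of the estimator and pipeline mechanics, and statistical
behaviour under an idealized cohort — not performance on scanner data.

A consequence of normalization worth knowing: fitted contributions are in
units of the patient's own 98th-percentile b = 0 signal, so cohort medians of
fitted maps are a patient-specific rescaling of the generator's targets. Rank
and signed-rank statistics are unaffected; absolute comparisons of fitted
medians against generator targets are made on unnormalized fits in the tests.

## ROI analysis

Lesion masks come from the generator (on real data they would be drawn
manually); the healthy control is a box of exactly 500 voxels grown around
the centroid of the eligible region in the x-half contralateral to the
malignant lesion's centroid, excluding every lesion mask and any exclusion
masks (for the phantom: everything outside the fibroglandular core; on real
data: axilla, large cysts, artifacts as user-supplied masks). The box is
grown axis-by-axis until it holds enough eligible voxels and trimmed to the
target count by distance to the box centre with a deterministic index
tie-break. On synthetic data the control box is constructed directly on the
DWI grid; no coarser reference grid exists to resample from, and the
500-voxel contract is what matters downstream. (At 31.25 mm³ per voxel this
is a 15.6 cm³ control region.)

Each patient contributes one median per tissue per metric
(C1, C2, C3, C1·C2, √(C1·C2), ADC). Multiple benign lesions are pooled at the
voxel level before the median — a single "benign tissue" data point per
patient; `benign_pooling = "median_of_medians"` gives the per-lesion
alternative. Even-sized ROIs use the midpoint of the two central order
statistics. ADC medians apply the validity mask first.

## Statistics

The battery mirrors a paired three-tissue design with n = 12 patients:
Shapiro–Wilk per tissue × metric and Levene (Brown–Forsythe, median-centred)
across tissues justify the rank-based approach; the main test is a ranked
two-way repeated-measures ANOVA — all values of the tissue × component table
are rank-transformed jointly once (Conover-style, mid-ranks for ties) and a
standard two-way within-subject ANOVA is fitted on the ranks with patient as
the repeated unit. Ranking once across the full table keeps the two factors
and their interaction on one scale and makes the statistics invariant under
any strictly increasing transform of the data. The two-way factor "component"
spans C1, C2, C3; marginal one-way analyses per metric (tissue effect) and
per tissue (component effect) accompany it. An all-constant table returns NA
p-values rather than an error.

Post hoc comparisons are exact two-sided Wilcoxon signed-rank tests on the
three tissue pairs within each metric. Zero differences are dropped before
ranking (classical convention; Pratt handling is available), ties get
mid-ranks, and for up to 25 pairs the p-value comes from the exact null
distribution of the positive-rank sum conditional on the observed absolute
ranks, computed by generating-function convolution — equivalent to
enumerating all $2^n$ sign assignments, which the tests verify directly for
n ≤ 12. Beyond the cutoff a normal approximation with tie and continuity
corrections takes over; at the cohort sizes this package targets the exact
branch is always used. The two-sided p doubles the smaller tail, capped at 1.
Bonferroni adjustment uses family size 3 — the three pairwise comparisons
within one metric, matching how per-compartment pairwise blocks are usually
reported; the family size is configurable. At n = 12 the exact test's
attained two-sided size at nominal 0.05 is 0.0425, which the type-I
simulation in the acceptance suite confirms empirically.

## Numerical choices and degenerate inputs

* NNLS: deterministic exact optimizers (active set / support enumeration);
  support enumeration declares a candidate feasible at coefficient
  $\ge -10^{-12}$ and clips to zero, ties in residual resolve to the first
  enumerated support — all deterministic.
* All-zero voxels (air after floor subtraction) fit to $C = (0,0,0)$ with
  zero residual; they are not errors because background voxels are most of
  any volume.
* Percentile definition: quantile type 7, stated above.
* Histogram floor: 256 bins; no background/tissue separation in the histogram
  is an error rather than a guess.
* Masks covering zero voxels, ROIs emptied by validity filtering, fewer than
  three shells, duplicate b-values, missing b = 0 — all hard errors with
  specific messages.

## Problem sizes used by the test and acceptance suites

Unit tests run on 32 × 32 × 8 phantoms with 60-voxel control ROIs; the
cohort-level acceptance checks use the full default conditions (64 × 64 × 12,
12 patients, 500-voxel control ROI) over 20 seeded cohorts, 500 null
replicates for type-I control, 200 random instances for the grid-search
oracle and 1000 voxels per SNR level for noise-robustness. These sizes were
chosen so the whole suite exercises the pipeline at the study's own scale
while remaining a desk-scale computation.

## Known limitations

The generator samples tissues independently within a patient (beyond the
hierarchical patient level), which under-represents the within-patient
coupling real paired designs exploit; with distribution targets matched to
published cohort summaries this makes some benign-versus-healthy contrasts
(notably the hindered compartment) reject more often than a real paired
cohort would, and the strict joint significance-pattern check in the
acceptance suite fails for that reason — the individual malignant contrasts
reproduce at high rates. Anisotropy, fat-suppression failure and distortion
are out of scope, as is any re-estimation of the diffusivity spectrum.
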