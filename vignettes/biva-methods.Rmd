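---
title: "Methods: impedance vector analysis with age- and sex-standardised scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: impedance vector analysis with age- and sex-standardised scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bivakit)
```

## The problem

Bio-electrical impedance vector analysis (BIVA) interprets a 50 kHz
whole-body impedance measurement qualitatively: impedance is split into
resistance (R) and reactance (Xc), each divided by standing height, and the
pair (R/H, Xc/H) is plotted on the "RXc plane". Under Piccoli's model, one
diagonal of the population ellipse indexes hydration and the orthogonal
diagonal indexes body cell mass; the vector's angle, the phase angle
PA = arctan(Xc/R) expressed in degrees, is read as a marker of cell mass and
membrane integrity. In children the raw components change strongly with age
and differ by sex, so any test of the model against measured body
composition must first remove age and sex. This package implements that
workflow end to end: duplicate-reading quality control, height-adjusted
vector components, 4-component body composition and fat-free-mass hydration,
LMS (Box-Cox) age-conditional references yielding standard deviation scores
(SDS), bivariate ellipse geometry with Hotelling's T² tests, and the
cohort-level correlation/regression/contrast analyses — plus a synthetic
cohort generator so the whole pipeline is testable without any subject data.

## Quality control

Records are excluded before analysis when

* the averaged phase angle exceeds 8.0° (healthy paediatric values lie
  between 5° and 7°; above 8° is treated as implausible even allowing for
  measurement error), or
* duplicate readings disagree: a phase-angle gap strictly above 0.5°, or a
  duplicate gap of at least 6.0 ohm/m for R/H or Xc/H.

The repeatability limit for R/H and Xc/H is applied to the absolute
difference of the duplicate ohm readings *after* division by height — the
components are only defined per height — and with a weak inequality,
following the printed symbol of the rule. The phase-angle rules use the
averaged value (strict `>`) and the duplicate gap (strict `>`) respectively.
A record may fail several rules; all reasons are kept. `qc_filter()`
partitions its input exactly (kept + excluded = input) and is idempotent.

## Body composition

Total body water is the deuterium dilution space divided by 1.044, the
standard proton-exchange overestimation factor. Fat mass comes from a
Fuller-type 4-component combination of body volume (BV, L), total body water
(TBW, kg), bone mineral content (BMC, kg) and weight (kg):

fm = 2.747·BV − 0.710·TBW + 1.460·BMC − 2.050·weight.

The coefficient set is a configuration item (`four_component()` records the
set used with its output) because published 4C formulations differ slightly
in their density assumptions. Fat-free mass is the complement
`ffm = weight − fm`, so mass closure is exact by construction; hydration of
fat-free mass is `h_ffm = tbw/ffm`, flagged (never rejected) outside the
healthy-child band 0.70–0.80. Physiologically impossible fat masses
(negative, or above weight) are flagged with a quality code rather than
raised as errors, since they are data problems, not programming errors.

## The LMS model and its fitting

For a positive trait *y* at age *t*, the LMS model assumes

z = ((y/M(t))^L(t) − 1) / (L(t)·S(t)),  z ~ N(0,1),

with the log form as L → 0: M is the median curve, S the coefficient of
variation, and L the Box-Cox skewness. `lms_fit()` maximises the resulting
likelihood by Fisher-scoring backfitting: each curve in turn is updated by
smoothing its working residual (score divided by expected information)
against age with a cubic smoothing spline at fixed effective degrees of
freedom (edf; 1 = constant, 2 = linear), with step-halving whenever a step
fails to reduce the deviance. The expected informations used are
1/S² for log M, 2 for log S, and 7S²/4 for L — the small-S approximations
standard for this model. L and log S are fitted on unbounded scales and
clamped to |L| ≤ 4 and S ≤ 2 for numerical safety.

Complexity is selected greedily in the order M → S → L (the median is the
best-supported curve, the skewness the least): starting from all-constant
curves, one extra edf on the current curve is accepted only if it reduces
the deviance by more than ln(N) — the Schwarz/BIC step — and the full
selection trace is stored in `fit$trace` so the choice is auditable. A
single-entry grid (`edf = c(M=, S=, L=)`) bypasses selection. Default
search ceiling is 6 edf per curve. Sexes are always fitted separately; the
package provides no pooled fit.

Fitted curves are tabulated on a 101-point grid over the observed age range
and evaluated elsewhere by monotone (Fritsch–Carlson) cubic interpolation,
which cannot overshoot between grid points; extrapolation outside the
support is refused rather than guessed. `predict(..., type = "sds")` and
`centile_curve()` are exact mutual inverses; the L → 0 branch switches at
|L| < 1e−7, far below the scale at which the two formulas differ
detectably (the continuity check in the test suite bounds the jump at
1e−4 for L = ±0.001). Centile curves where 1 + L·S·z_p ≤ 0 (possible for
strong skewness at extreme percentiles) are returned as flagged `NA` gaps.

Self-calibration is the operative guarantee: on the fitting sample the SDS
have mean within ±0.05 and SD within ±0.05 of 1, and the fraction below the
fitted median is 0.50 ± 0.03. These are verified in the acceptance suite on
5,000 simulated children, along with median recovery within 2% relative
error at interior ages against known generating curves.

## Ellipses and Hotelling's T²

Both ellipse kinds are centred on the sample mean with axes along the
sample-covariance eigenvectors; they differ in scale:

* confidence (for the mean): semi-axes √(λᵢ · p(n−1)/(n(n−p)) · F_{p,n−p}(level)),
* tolerance (for individuals): semi-axes √(λᵢ · p(n²−1)/(n(n−p)) · F_{p,n−p}(level)),

with p = 2. The exact F scalings are used rather than the large-sample
chi-square because the group sizes this workflow produces are a few dozen;
the chi-square variant is available via `scaling = "chisq"` for
cross-checking against other BIVA software. Orientation is reported in
[0°, 180°); the circular tie (equal eigenvalues) reports 0° by convention.
The two-sample Hotelling's T² uses the pooled covariance and the exact F
transform; a paired variant is deliberately not provided, since the group
comparisons here are between independent category groups. Tolerance
ellipses are conventionally drawn at 50/75/95%.

## Cohort analyses

Category schemes over FFM-SDS (cuts −1, 0, 0.75, 1.5) and hydration SDS
(cuts −1, −0.5, 0, 1) use left-open/right-closed intervals; the boundary
rule is stored in the scheme object so group counts are auditable, because
the published category descriptions do not state which side owns a
boundary. Group contrasts are pairwise pooled-variance t tests with
Bonferroni adjustment over all pairs (Welch available by flag); slope
heterogeneity is the dummy + interaction regression `y ~ x * group` with
the first level as reference, dropping groups under 3 members and noting
them. SDS columns enter regressions as-is — they are standardised by
construction, so coefficients are already on the SDS scale.

## The synthetic cohort generator

The generator exists because the analysis is defined on a cohort that
cannot be shipped. It draws ages uniformly on 4–20 y with balanced sexes,
one 7-dimensional standard-normal SDS vector per child (order: PA, R/H,
Xc/H, BMI, FFM, FM, hydration) with the target correlation structure, and
back-transforms each score through per-sex median curves with log-normal
spreads (L = 0). The default correlation target is the published
whole-cohort SDS correlation matrix; as printed it is not positive definite
(its FFM×FM entry is inconsistent with the BMI rows), so `nearest_pd()` —
a Higham alternating-projection wrapper — projects it before sampling, and
every closure check compares against the projected matrix, which the truth
table carries.

Internal consistency is exact where the pipeline can check it: weight is
the sum of the intended fat and fat-free mass; height is derived from
weight and the BMI score (so BMI = weight/height² reproduces its drawn SDS
exactly); TBW = h_ffm·ffm, dilution space = 1.044·TBW, BMC = 4.5% of FFM (a
typical paediatric bone-mineral fraction), and body volume solves the 4C
equation, so the composition stage recovers the intended FM/FFM and
hydration to machine precision. Duplicate R/Xc/PA readings carry Gaussian
noise of SD 2 Ω, 1 Ω and 0.1°; configured contamination fractions create
records violating one QC rule each, labelled in the truth table.

Default median anchors (interpolated monotonically between ages 4, 12 and
20) encode only the qualitative shapes a paediatric cohort shows: R/H
falling from ~600 to ~300 ohm/m and Xc/H from ~65 to ~35 ohm/m in a
curvilinear way, PA rising within the 5–7° healthy band, hydration of FFM
declining from ~0.766 to ~0.736 with chemical maturation, and heights, BMI
and fat fractions on conventional paediatric scales with small sex offsets.
They are invented fixtures, not estimates of any published reference, and
the spread CVs (7–13% for impedance traits and masses, 35% for fat mass,
1.2% for hydration) were chosen once as field-plausible values.

What the generator does *not* emulate: measurement error correlated across
traits, skewed trait distributions (all spreads are log-normal), secular
trends, ethnicity structure, or disease-state fluid perturbation. Passing
closure tests therefore demonstrates that the pipeline's stages are
mutually consistent and unbiased under the model's own assumptions — not
that the LMS fit or the BIVA model is correct for any real population.

Because back-transformation is log-normal, a correct LMS fit should select
L ≈ 0 with minimal complexity; this is a deliberate stress on the
selection rule, not a convenience.

## Determinism, problem sizes and numerical choices

All randomness flows from the single seed in `generator_config()` (the
caller's RNG state is restored), so identical configurations reproduce
byte-identical cohorts, and `run_pipeline()` itself is deterministic. The
verification suite uses the scales the method's claims are stated at:
200,000 draws per correlation-recovery pair (±0.01), 5,000 children for LMS
recovery, 5,000 replicates of n = 50 for confidence-ellipse coverage and
10,000 points for tolerance content (±0.01), 5,000 null replicates of
n = 30 per group for the T² size (±0.01), and a 50,000-child cohort for
whole-pipeline correlation closure (±0.02 entry-wise), run with a fixed
edf = (M 4, S 2, L 1) complexity — at that sample size the BIC search adds
cost without changing the selected shape class. Backfitting stops when a
full cycle improves the deviance by less than 1e−3; recovery results are
insensitive to this tolerance over several orders of magnitude.

## Known limitations

* The LMS expected informations are small-S approximations; for traits with
  S well above ~0.3 convergence slows and a finer complexity search may be
  warranted. Fat mass (CV 35%) still fits cleanly, but this is the edge of
  the comfortable range.
* The BIC-style ln(N) rule is applied per added edf greedily; it does not
  revisit earlier curves, so strongly interacting complexity choices (e.g.
  skewness absorbing a mis-specified median) could in principle settle in a
  local optimum. The stored trace makes such cases visible.
* The 4C coefficient default is one published formulation; studies using a
  different set should pass their coefficients explicitly, and comparisons
  across coefficient sets are the user's responsibility.
* `read_cohort()` expects decimal ages; no date arithmetic is performed.
* One-sample T² against a fixed reference mean and Mahalanobis migration
  plots are out of scope.
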