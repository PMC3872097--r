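---
title: "Quantitative echotexture diagnosis of biceps tendinitis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative echotexture diagnosis of biceps tendinitis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bicepsQUS)
```

## The diagnostic problem

B-mode ultrasound of the long-head biceps tendon is the standard bedside
examination for suspected biceps tendinitis, but its reading is strongly
operator-dependent: the same tendon can look hypo- or hyperechoic depending on
probe angle and examiner experience, and agreement between observers on
equivocal cases is poor. The quantitative approach implemented here replaces
the visual judgment with a single first-order texture score. A region of
interest (ROI) of fixed physical area — 2 mm², a circle on the transverse view
and a square on the longitudinal view, drawn at the center of the tendon — is
reduced to four numbers: the minimum, maximum, mean and standard deviation of
its 8-bit pixel intensities (0 = black, 255 = white). A healthy tendon has a
homogeneous fibrillar texture and therefore a low intensity standard deviation
(StdDev); an inflamed tendon accumulates hypoechoic sheath fluid next to
compressed, hyperechoic fiber bundles, so its ROI becomes heterogeneous: the
maximum rises, the minimum falls, the mean barely moves, and the StdDev — the
heterogeneity score — rises. A subject is called positive when the StdDev
strictly surpasses a per-view cut-off: 26.85 (transverse) or 21.25
(longitudinal) in the published calibration.

The reference standard against which the score is calibrated is itself
rule-based: tendon sheath swelling (transverse thickness ≥ 4.6 mm in women /
5.5 mm in men, or longitudinal thickness ≥ 2.5 / 2.8 mm), or a displaceable
and compressible sheath effusion at least 3 mm deep, in either case together
with increased Doppler color-flow signal, which is treated as essential.
`criteria_label()` implements that rule (the color-flow AND can be relaxed via
`require_color_flow = FALSE` for sensitivity analyses); the color-flow finding
is a boolean input, since Doppler signal processing is outside this package's
scope.

## ROI geometry and statistics

Pixel coordinates are 1-based `(row, col)` with pixel centers at integer
coordinates — the native convention of R's matrix ecosystem — and the physical
position of pixel `(r, c)` is `((r-1)·spacing_row, (c-1)·spacing_col)` mm.
A circle of area `A` has radius `sqrt(A/pi)`; a pixel belongs to the mask iff
its center lies within the closed disk, distances measured in millimetres so
anisotropic spacing is handled exactly. A square ROI has side
`round(sqrt(A)/spacing)` pixels per axis (computed per axis, minimum 1),
placed so its centroid is nearest the requested center with ties broken toward
smaller indices. Pixel-center inclusion with a closed boundary is the standard
deterministic rasterization rule and makes the degenerate one-pixel ROI
non-empty. An ROI that would leave the image raises an error rather than being
clipped, since a clipped ROI would silently change the area the statistics
refer to.

The protocol's "more than 2000 pixels" requirement is advisory
(`validate_roi()` warns rather than fails): at typical native B-mode
resolutions a 2 mm² region holds far fewer native pixels, so the count plainly
refers to zoomed screen pixels. The synthetic images use a fine 0.02 mm/px
spacing at which the constraint is literally satisfiable (≈ 5000 pixels).

The ROI StdDev uses the population convention (divide by *n*), matching PACS
ROI tools that summarize the drawn pixel population; at n > 2000 the
population/sample ratio `sqrt(n/(n-1))` is below 1.0003, which the test suite
asserts so the convention cannot affect any downstream threshold. Statistics
are computed on the raw integers — no smoothing, filtering or normalization,
since the clinical method applies none.

## Cut-off calibration

Calibration works on labeled per-subject scores. The AUROC is the rank-based
Mann–Whitney estimator (ties counted ½), which equals the trapezoidal area
under the empirical ROC curve; its standard error uses the Hanley–McNeil
formula with the exponential approximation `Q1 = A/(2-A)`, `Q2 = 2A²/(1+A)`,
and the 95% CI is the normal approximation clipped to [0, 1]. (SPSS's default
nonparametric SE differs in the third decimal at these sample sizes; the
difference is far below every tolerance used here.) Candidate thresholds are
the midpoints between consecutive distinct scores plus sentinels beyond the
extremes — consistent with the strict "surpasses" positivity rule, and
yielding cut-offs that never coincide with an observed score (the published
26.85 is of exactly this form). The operating point maximizes the Youden index
J = sensitivity + specificity − 1; ties are broken toward higher specificity
and then toward the lower threshold, a deterministic rule that mirrors the
specificity-heavy transverse operating point (90% specificity).

The per-predictor screen is a univariate logistic regression (intercept plus
one ROI statistic), fitted by iteratively reweighted least squares to
convergence `1e-8` within 25 iterations; standard errors come from the inverse
observed information, the Wald statistic is `(β/SE)²` against chi-square(1),
and the odds ratio is `exp(β)`. One fit per predictor matches the one-row-per-
predictor layout of the published screening table (whose statistic column,
though headed "R²", holds Wald chi-squares — e.g. `(0.335/0.068)² ≈ 24.5` —
and is implemented as such). Complete separation is flagged as non-converged
rather than reported as a finite estimate. Group comparisons use the pooled-
variance independent t-test and the 2×2 Pearson chi-square without continuity
correction (at the cohort's group sizes the correction does not move the sex
comparison's p-value materially).

## What the synthetic data emulate

No patient images are distributed, so the package generates its own inputs at
two levels.

**Score level.** `simulate_scores()` draws each subject's per-view StdDev from
the published group distributions — transverse 30.1 ± 6.8 (positive) vs
21.9 ± 4.1 (negative), longitudinal 26.5 ± 6.0 vs 18.7 ± 4.7, group sizes
136/200 — truncated to [0, 255] by redraw. Under this binormal model the
theoretical AUROC `pnorm((mu1-mu0)/sqrt(s1²+s0²))` is 0.849 (transverse) and
0.847 (longitudinal), and the theoretical sensitivity at the published
cut-offs is `pnorm((30.1-26.85)/6.8)` = 68.4% and `pnorm((26.5-21.25)/6.0)` =
80.9% — all within a percentage point or two of the published 0.856/0.852 and
68%/81%, which is the sense in which the synthetic pathway "reproduces" the
study.

**Image level.** `simulate_tendon_image()` builds a speckled image whose
centered 2 mm² ROI realizes a target (mean, StdDev) in expectation. Within the
ROI each pixel belongs to one of three Gaussian components sharing one speckle
SD: baseline tendon texture anchored at the target mean, a hypoechoic fluid
component (gray level 45, near the positive group's minimum), and a
hyperechoic component (200, near the positive group's maximum). The two
component fractions are the solution of the two mixture-moment equations
(mixture mean and second moment), a closed-form 2×2 linear solve
(`moment_match_mixture()`); infeasible targets — e.g. a target SD below the
speckle floor — raise an error naming the violated bound. Spatially the fluid
fraction forms a contiguous blob at the ROI margin (emulating sheath fluid
abutting the tendon) and the hyperechoic fraction a streak, rather than
salt-and-pepper noise, which leaves the per-pixel mixture identity — and hence
the moment calibration — intact. The longitudinal view adds a sinusoidal
fibrillar band modulation (amplitude 8, period 0.6 mm); its variance
contribution `amplitude²/2` is absorbed analytically into the baseline
component's effective SD before the fractions are solved, otherwise
longitudinal targets would be systematically overshot.

Two generator choices deserve emphasis. First, the baseline component is
anchored at each image's target mean rather than at one fixed gray level:
with a fixed baseline the longitudinal group means (94.2 / 102.9) are
algebraically unreachable (the solved fractions go negative), whereas
anchoring keeps the closed form feasible for every published target and
reduces the "healthy" image to pure speckle. Second, speckle is a Gaussian
first-two-moments proxy, not Rayleigh or log-compressed physics: the
diagnostic method consumes only first-order ROI statistics, so matching the
first two moments is the entire requirement. Consequently, passing tests show
that the pipeline recovers the assumed statistical structure; they cannot
show robustness to real acoustic phenomena (anisotropy dropout, shadowing,
reverberation), which the generator deliberately does not model.

**Study level.** `simulate_study()` writes a full cohort to disk: per subject
and view a PNG plus JSON sidecar (carrying spacing, view, label, and the
calibrated ROI), a subject CSV, and a manifest recording every parameter and
file. Demographics and per-view ROI-mean targets are drawn from the published
group summaries. (The positive group's longitudinal mean is printed with an
implausible SD of 99.2 in the source table; this generator uses 25, in line
with the other three mean SDs of 24.9/28.6/25.1.) Per-subject SD targets are
clamped to the moment-matching feasibility floor (effective baseline SD +
0.25) and mean targets to [60, 185]; the clamps bind for roughly 2–3% of
subjects in the lower tail and move those subjects by at most a few gray
levels. Reference criteria fields (sheath thicknesses, effusion, color flow)
are drawn straddling the sex-specific thresholds so that `criteria_label()`
agrees with the intended group label for ~95% of subjects, the remaining ~5%
emulating the equivocal cases that motivate the quantitative method. A single
root seed drives everything; per-image streams are derived by hashing
`(subject_id, view)`, so studies are byte-reproducible yet streams are
mutually independent.

## Numerical and testing choices

Problem sizes were chosen to keep the full suite within a few minutes on one
CPU while leaving Monte Carlo error well under each tolerance: large-sample
binormal checks use 200,000 draws per group (AUROC standard error ≈ 0.0008);
image-level moment checks use medians over 50 seeds against pre-registered
tolerances (ROI mean within ±1.0, StdDev within ±1.5 and 5%); cut-off
recovery uses 500 replicate 136/200 cohorts, whose median Youden-optimal
cut-off must land within ±1.5 of the binormal density-equality optimum
(26.55 for the transverse parameters — itself within 0.3 of the published
26.85). End-to-end checks that push full simulated studies through
image-writing, quantification and calibration average over 10 replicate
studies, because a single 136-positive cohort carries ≈ 4 percentage points
of binomial noise on a sensitivity — averaging separates pipeline fidelity
(which is tight: per-image StdDev tracks its target with SD ≈ 0.13 gray
levels) from single-cohort sampling noise.

Oracles in the test suite are deliberately naive and independent of the
implementation: brute-force lattice enumeration for circle masks, loop-based
statistics for `roi_stats()`, exhaustive threshold scans for the Youden
optimum, a 200×200 likelihood grid for the logistic fit, closed binormal
forms for AUROC and sensitivities, and `pROC`/`stats::glm` as third-party
cross-checks.

## Known limitations

* The image generator validates only first-order statistics; second-order
  texture (co-occurrence contrast/energy/homogeneity) is out of scope, as is
  any acoustic realism.
* The longitudinal cut-off is taken as 21.25; the source Results text prints
  23.25 once, which is inconsistent with its own abstract and accuracy table
  and is treated as typographical.
* Sheath thicknesses and Doppler findings are inputs, not image
  measurements: the package does not segment the sheath or process color
  flow.
* The published longitudinal Youden index (0.53) differs from
  0.81 + 0.73 − 1 = 0.54, presumably pre-rounding arithmetic; it is not used
  as a check.
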