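---
title: "Methods: the cortical decorrelation analysis in cdbold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the cortical decorrelation analysis in cdbold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdbold)
```

## The scientific problem

A visual stimulus drives its retinotopic representation in visual cortex, but
the BOLD response it evokes is not confined there: positive signal spreads
millimetres beyond the representation and turns negative at larger cortical
distances. When a center stimulus (C) and a surround stimulus (S) are shown
together, the combined response m(C,S) is not the sum of the component
responses — the summation is sublinear (suppressive) where the two activation
patterns overlap strongly and can be supralinear (facilitative) where they do
not. The cortical decorrelation (CD) account holds that this contextual
modulation serves to remove the correlation between the two macroscopic
activation patterns, so that the strength of modulation is predictable from
the Pearson correlation of the C and S patterns alone.

`cdbold` implements that analysis end to end on tabular per-voxel data: one
row per voxel carrying subject, hemisphere, functional area, eccentricity-ring
label, eccentricity, and percent-BOLD-change estimates for the five conditions
C, S_N (near surround), S_F (far surround), m(C,S_N) and m(C,S_F).

## The modulation index and the decorrelating coefficient

The per-voxel **measured modulation index** is

$$d_M = \frac{(C+S) - m(C,S)}{C+S}.$$

It is 0 under linear summation, 1 when the combined response vanishes (full
suppression), and −1 when the response doubles (strong facilitation).
Positive values are suppressive, negative facilitative. Because the
denominator can approach zero in voxels where neither stimulus is
represented, $d_M$ is heavy-tailed; following the original analysis
convention, `measured_d()` retains values beyond ±1 and only marks voxels
with an exactly zero denominator as undefined. Voxels whose |C+S| falls below
`denom_epsilon` (default 1e−9 percent-change units) are counted and flagged
but kept.

The **theoretical decorrelating coefficient** is the single scalar
$d_T \in [-1, 1]$ that removes the correlation of the two patterns under the
symmetric mixing $C' = C - d\,S$, $S' = S - d\,C$. Setting
$\mathrm{cov}(C', S') = 0$ gives the quadratic
$(1+d^2)\,\mathrm{cov}(C,S) - d\,(\mathrm{var}\,C + \mathrm{var}\,S) = 0$,
whose bounded root is

$$d_T = \frac{\mathrm{var}\,C + \mathrm{var}\,S -
  \sqrt{(\mathrm{var}\,C + \mathrm{var}\,S)^2 - 4\,\mathrm{cov}(C,S)^2}}
  {2\,\mathrm{cov}(C,S)},$$

with $d_T = 0$ at zero covariance (the continuous extension; the closed form
is 0/0 there). The discarded quadratic root is the reciprocal of the returned
one and lies outside [−1, 1]. Expressed through the correlation $r$ and the
variance ratio $\rho = \mathrm{var}\,S/\mathrm{var}\,C$, the same quantity is
the parameter-free CD curve `cd_curve(r, rho)`; at equal variances it reduces
to $(1 - \sqrt{1-r^2})/r$, odd in $r$.

```{r}
sol <- theoretical_d(c(1, 2, 3, 4), c(2, 1, 4, 3))
c(d_t = sol$d_t, residual_r = sol$residual_correlation)
cd_curve(0.6)
```

Because the mixing form of the decorrelation step is a modelling choice, the
package carries an independent verification route, `theoretical_d_search()`:
a literal dense grid over $d \in [-1, 1]$ minimising
$|\mathrm{cor}(C - dS,\; S - dC)|$ with bisection refinement. The test suite
requires agreement with the closed form within 1e−6 on a thousand random
pairs and residual correlations below 1e−8.

### Sensitivity to shared noise

Noise that is common to a voxel's condition estimates (as arises from
temporal autocorrelation) enters the numerator of $d_M$ once and the
denominator twice, pulling the index toward 0.5 when such noise dominates
the signal. The generator reproduces this with `shared_noise_sd`: one draw
per voxel added to C, S and m alike. Two regimes matter. While the signal
dominates, a second-order expansion of $(n_0+\eta)/(d_0+2\eta)$ shows the
*mean* index actually drifts slightly negative; the characteristic pull
toward 0.5 appears once denominators are noise-dominated, at which point
near-zero denominators also make the raw mean unstable. The property test
therefore uses three shared-noise levels in the noise-dominated regime (SD
0.5, 1 and 2 percent-BOLD against a 1.05 peak) and trims denominators within
0.05 of zero for stability; the trimmed mean then moves monotonically toward
0.5.

## The synthetic study generator

No imaging data ship with the package; `generate_study()` produces voxel
tables whose structure matches the study design the analysis assumes:

* **Design.** 15 subjects; five eccentricity rings with borders 1, 2.3, 4.0,
  6.1, 8.7, 12 degrees; areas V1–V3; a 1–2.3 degree center annulus, a
  2.5–4.0 degree near surround (small gap to the center), and an
  8.7–12 degree far surround.
* **Cortical geometry.** Eccentricity maps to a 1-D cortical position via the
  Schwartz magnification formula $k \ln((E+a)/a)$ with $a = 1$ degree,
  $k = 17$ mm. Voxel eccentricities are drawn uniformly *in cortical
  position* within each ring, emulating approximately uniform cortical
  sampling under magnification.
* **Point spread.** The noiseless response to a stimulus annulus is a
  difference of two Gaussians of cortical distance from the stimulus
  representation: a narrow positive lobe (`spread_sigma_mm`, default 6 mm)
  minus a wide lobe (`negative_lobe_ratio` × wider, default 3) scaled by
  `negative_lobe_gain` (default 0.3). This is the minimal form that yields
  the observed phenomenology — a maximal plateau inside the representation,
  graded positive spread beyond it, and a sign flip to negative BOLD at
  large distance. The sign-flip distance has the closed form exposed by
  `template_zero_crossing_mm()`. With gain 0 the template is everywhere
  non-negative. The plateau means that, with zero noise, voxels wholly
  inside a stimulus representation have *constant* response; degenerate
  inputs of that kind are rejected by `theoretical_d()` rather than
  silently propagated.
* **Amplitude.** The template peak is 1.05 percent signal change, a typical
  scale for low-contrast gratings at 3 T; no published axis calibration was
  attempted, so this is a free default.
* **Subjects.** Per-subject log-normal amplitude jitter (sdlog 0.15, per
  condition) and Gaussian retinotopic offset jitter (SD 1.5 mm) give the
  between-subject spread of pattern correlations that group scatters need.
* **Interaction rules.** m(C,S) is built per rule: CD
  $m = (C - dS) + (S - dC) = (1-d)(C+S)$; LINEAR $C+S$; MAX voxel-wise
  maximum; AVERAGE voxel-wise mean. `d_true = "auto"` resolves to the
  $d_T$ of each subject's noiseless patterns so the data sit exactly on the
  CD identity — the basis of the parameter-recovery tests.
* **Noise.** Independent Gaussian noise (default SD 0.15) per condition
  estimate, plus the optional shared draw described above.
* **Reproducibility.** All draws flow from one seed through named substreams
  keyed by (subject, area, stage), so enlarging the area list leaves
  existing subjects' draws untouched.
* **Correlation control.** With `target_correlation` set, the positive-lobe
  width is retuned by a deterministic search until the noiseless C/S_N
  correlation over suprathreshold voxels (evaluated on a grid matching the
  per-ring sampling density) lands within ±0.05 of the target.

What the generator does **not** emulate: time series and GLM estimation (it
works at the level of condition-wise estimates), 3-D volume or surface
geometry (eccentricity is the only spatial coordinate), vascular artefacts,
and draining-vein pooling. Passing tests therefore certify the analysis
machinery, not the physiological fidelity of any particular dataset.

## VOI selection and the modulation summary

`select_voi()` implements three selection families: condition-active VOIs
(center, near surround, far surround, and the all-areas union over the five
conditions), eccentricity-ring VOIs, and functional-area VOIs. Real studies
threshold on GLM statistics; with condition-level synthetic data the
suprathreshold criterion is absolute response magnitude, $|y| \ge \theta$
(default θ = 0.2 percent, matched to the default amplitude scale), exposed
everywhere as a parameter. `voi_modulation()` reports the VOI's mean and SE
of $d_M$, the count of flagged and undefined voxels, the pattern correlation
r(C,S), and the VOI's $d_T$; `modulation_scatter()` computes the same
quantities per subject, which is the default route to group scatters (the
alternative — correlating across-subject mean patterns — can be had by
pooling first).

## Model comparison

`compare_models()` scores four relations between r and mean $d_M$ on a
scatter: the CD curve (0 free parameters), the identity line $d = r$ (0), a
cubic polynomial (4), and a free line (2), all fitted by ordinary least
squares where applicable.

* **Orthogonal goodness of fit.** Because both coordinates carry error, the
  $R^2$ numerator uses squared *minimum Euclidean* distances to the curve
  (dense grid with step 1e−3 on the curve parameter, locally refined to
  1e−6); the denominator is the summed squared distance to the centroid of
  the points. The axes are treated as commensurate since both are
  dimensionless and bounded by [−1, 1].
* **Per-point and cross-validated errors.** Vertical absolute error is the
  default metric for per-point and leave-one-out errors (the conventional
  predictive reading of "error from the fitted curve to the omitted
  point"); the orthogonal metric is available via a switch. For
  parameter-free models the LOO error provably equals the plain mean error.
* **AIC.** The Gaussian least-squares form $n \ln(\mathrm{RSS}/n) + 2k$;
  zero RSS maps to −Inf with a warning. Rankings use AIC with ties broken
  toward fewer parameters; all pairwise winners are reported. AICc is not
  used because the analysis names AIC; with very small scatters the
  comparison should be read with that in mind. The model-recovery test runs
  50 replicates per generative rule at noise SD 0.05 with 60-point
  scatters: AIC's probability of preferring an overfitting nested model is
  asymptotically fixed (≈9% for +4 parameters, ≈14% for +2) but worsens at
  small n through the variance of log RSS, so a 15-point scatter cannot
  support a stable ≥80% recovery criterion while a 60-point one can.
* **Error normalisation.** For display and cross-condition aggregation,
  per-point errors are divided by the maximum error within their
  VOI/condition group, mapping each group's maximum to exactly 1; an
  all-zero group is defined as all zeros.
* **Response-combination models.** Separately from the scatter-level fits,
  `response_model_prediction()` predicts m(C,S) voxel-wise under MAX
  (component maximum), AVERAGE (component mean) and CD
  ($(1-d_T)(C+S)$ with $d_T$ from the same voxels), reporting the Euclidean
  norm of the prediction error.

## Retinotopic spread

`eccentricity_profile()` averages a condition per ring — across voxels at
subject level, across subject means at group level. Rings are placed at the
arithmetic midpoints of their borders (1.65, 3.15, 5.05, 7.4, 10.35
degrees); a logarithmic (cortical-midpoint) convention is available.
`zero_crossing()` fits a second-degree polynomial to the five ring means and
returns the real root nearest the stimulus edge in the travel direction;
when the quadratic coefficient vanishes the linear root is used, and when no
real root lies within the sampled 1–12 degree range the estimate is censored
("<1" or ">12"), never an exception. Confidence intervals are percentile
bootstrap over subjects (default 1000 resamples, seeded); the bootstrap
propagates censoring by mapping censored resamples to ±infinity before
taking quantiles. `spread_mm()` converts crossings to cortical millimetres
with the same Schwartz parameters; censored crossings yield lower bounds at
the range limit. Direct evaluation of the mapping is the only distance
notion offered — no surface geodesics — and published mm tables derived from
per-subject averaging conventions need not match direct formula values.

`resampling_error()` quantifies model fit comparably across VOIs of
different sizes: 100 seeded draws of 20 suprathreshold voxels, each scored
by $(\overline{d_M} - d_T)^2$ with $d_T$ recomputed on the drawn voxels.
Note that even noiseless CD data leave this error positive: the subsample's
decorrelating coefficient fluctuates around the generative one while the
mean $d_M$ equals it exactly; the per-repeat components are returned so the
two contributions can be separated. The direction of the error's response
to measurement noise is configuration-dependent (noise simultaneously
shrinks the subsample $d_T$ toward zero and inflates the dispersion of the
resampled means), so the property tests pin the monotone component — the
dispersion of resampled means grows with noise — rather than a trend of the
composite error.

## Sign statistics

`sign_contingency()` cross-classifies VOI voxels by C/S sign agreement and
by the sign of $d_M$. Voxels with an exactly zero response or an exactly
zero/undefined index are excluded from the 2×2 table (the convention is not
dictated by the analysis definition; exclusion with reported counts keeps
the table interpretable) and both pooled and per-subject-mean summaries are
offered, since "average counts across subjects" is ambiguous between the
two. The accompanying tests are thin, validated wrappers: exact binomial
sign test (zeros dropped), Mann–Whitney U (exact when $n\,m \le 400$ without
ties, tie-corrected normal approximation otherwise), two-sample
Kolmogorov–Smirnov (asymptotic), and Friedman (average ranks; complete
within-block ties yield statistic 0 rather than the 0/0 of the tie
correction). Their type-I error at α = 0.05 is verified at or below 6% over
2000 null replicates.

## Numerical choices collected

* Pearson machinery uses sample (n−1) moments throughout; every quantity
  used downstream depends only on moment ratios, so the normalisation
  cancels.
* $d_T$: covariance exactly 0 returns 0; the discriminant is clamped at 0
  against round-off near |r| = 1; results are clamped to [−1, 1]; constant
  input patterns raise errors rather than NaNs.
* Orthogonal distances: curve-parameter grid step 1e−3, refinement
  tolerance 1e−6; the search oracle for $d_T$ uses grid step 1e−4 and
  bisection to 1e−8.
* Zero crossings: quadratic coefficient below 1e−12 falls back to the
  linear root; two in-range roots resolve to the one nearest the reference
  edge in the travel direction.
* Substream seeds are derived by integer arithmetic modulo 2^31 − 1.

## Problem sizes used by the test-suite

The suite generates studies of 1–6 subjects with 10–67 voxels per ring per
area (201–6030 voxels), runs 20-seed recovery sweeps at 201 voxels each,
50-replicate model-recovery sweeps on 60-point scatters, 1000 random pairs
for the oracle-equivalence check, and 2000 replicates for the type-I
calibration; these sizes were chosen so each property is measured with
comfortable statistical margin while the whole suite stays quick on a
single CPU.

## Known limitations

* The generator's amplitude scale, jitter magnitudes and point-spread
  parameters are field-typical defaults, not calibrated to any specific
  dataset; quantities that depend on them (realised correlations, sign-table
  proportions, crossing eccentricities) are internally consistent rather
  than externally matched.
* The CD step assigns one $d_T$ per VOI; in large, functionally
  heterogeneous VOIs a single coefficient cannot capture clusters with
  different modulation strengths, and the mean $d_M$ is the only quantity
  the model claims to predict.
* $d_M$ is undefined where C + S = 0 and unstable nearby; summaries report
  flag counts, and analyses of regions where neither stimulus is
  represented should expect heavy tails.
* The 1-D Schwartz mapping ignores individual magnification differences and
  surface geometry; mm values are generic-template estimates.
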