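# cdbold

Cortical decorrelation analysis of center–surround interactions in
visual-cortex BOLD activation patterns.

## The problem and who this is for

When a visual "center" stimulus and a "surround" stimulus are presented
together, the BOLD response m(C,S) is not the sum of the component responses
C and S: summation is sublinear (suppressive) where the two activation
patterns overlap and can be supralinear (facilitative) where they do not.
The cortical decorrelation (CD) model explains this contextual modulation as
a mechanism that removes the correlation between the two macroscopic
activation patterns, which makes the modulation strength predictable from
the Pearson correlation of the patterns alone — with zero free parameters.

`cdbold` is for fMRI researchers who want to run that analysis on per-voxel
percent-signal-change tables (or on fully synthetic data with the same
structure): compute the modulation index, test the CD prediction against
linear, polynomial, MAX and AVERAGE alternatives, quantify how far BOLD
signals spread across the retinotopic map, and relate response signs to
modulation signs.

## The statistics at the core

Per voxel, the **measured modulation index** is

    d_M = ((C + S) − m(C,S)) / (C + S)

(0 = no interaction, positive = suppressive, negative = facilitative;
d_M = 1 means the combined response vanished, d_M = −1 that it doubled).

Per voxel set, the **fully decorrelating coefficient** d_T ∈ [−1, 1] makes
C′ = C − d·S and S′ = S − d·C uncorrelated:

    d_T = [var(C) + var(S) − sqrt((var(C) + var(S))² − 4 cov(C,S)²)] / (2 cov(C,S))

and, through correlation r and variance ratio alone, defines the
parameter-free CD curve (equal variances: `d_T = (1 − sqrt(1 − r²)) / r`).
The CD claim is that the VOI-mean d_M lies on this curve.

Around this core the package provides VOI selection rules, per-subject
correlation/modulation scatters, model comparison with orthogonal-distance
R², leave-one-out cross-validation and least-squares AIC, eccentricity
profiles with polynomial zero crossings, cortical distances via the Schwartz
magnification formula `k·ln((E + a)/a)` (a = 1°, k = 17 mm), sign
contingency tables, and the supporting nonparametric tests. A seeded
multi-subject generator (`generate_study()`) emulates the retinotopic,
correlational and interaction structure of a center/near-surround/
far-surround study, so the whole pipeline is testable without any imaging
data.

## Worked example

```r
library(cdbold)

study   <- generate_study(generation_config(n_subjects = 12, seed = 8))
scatter <- modulation_scatter(study$voxels, voi = "VOI_C", surround = "near")
scatter
#> # A tibble: 12 × 5
#>   subject     r  mean_d    se condition
#>     <int> <dbl>   <dbl> <dbl> <chr>
#> 1       1 0.444  0.316  0.109 VOI_C_near
#> 2       2 0.678 -0.0295 0.394 VOI_C_near
#> 3       3 0.119  0.239  0.345 VOI_C_near
#> 4       4 0.691 -0.137  0.594 VOI_C_near
#> # ℹ 8 more rows
```

One row per subject: the correlation between the center and near-surround
activation patterns over the center VOI, and the subject's mean measured
modulation index with its SE. Comparing the four candidate relations between
r and mean d_M:

```r
tidy(compare_models(scatter))[, c("model", "k", "loo_error",
                                  "orth_r_squared", "aic", "rank")]
#> # A tibble: 4 × 6
#>   model               k loo_error orth_r_squared   aic  rank
#>   <chr>           <int>     <dbl>          <dbl> <dbl> <int>
#> 1 CD                  0     0.212          0.735 -27.9     1
#> 2 LINEAR_IDENTITY     0     0.324          0.542 -22.0     3
#> 3 POLY3               4     0.282          0.732 -20.2     4
#> 4 LINFIT              2     0.263          0.574 -23.7     2
```

The parameter-free CD curve attains the lowest AIC (rank 1): on these
CD-generated data the decorrelation prediction beats the slope-one line, the
free line and the cubic once parameter counts are charged. `autoplot(scatter)`
draws the scatter over the CD curve.

Retinotopic spread of the center response in V1 — where the group-mean
profile crosses from positive to negative BOLD, moving peripherally from the
stimulus' outer edge at 2.3°:

```r
prof  <- eccentricity_profile(study$voxels, "V1", "C", "group")
cross <- zero_crossing(prof, "peripheral", reference_edge = 2.3,
                       n_boot = 500, seed = 1)
cross$label
#> [1] "5.8 (5.4 - 6.2)"
spread_mm(2.3, cross)
#> # A tibble: 1 × 2
#>   spread_mm lower_bound
#>       <dbl> <lgl>
#> 1      12.2 FALSE
```

The sign flip sits at 5.8° eccentricity (bootstrap 95% CI 5.4–6.2°), i.e.
the positive BOLD extends about 12 mm of cortex beyond the stimulus
representation under the Schwartz mapping. Crossings outside the sampled
1–12° range are reported censored ("<1", ">12") with lower-bound mm values.

`run_pipeline(out_dir)` chains generation → modulation → model comparison →
spread → sign statistics and writes CSV reports plus a JSON manifest with
seeds and a config hash.

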