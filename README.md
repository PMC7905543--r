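# fragdisp

Standardized 3D measurement of bone-fragment displacement, and an
inter-rater analysis pipeline for computer-assisted fracture-reduction
planning.

## The problem

When a fracture (the motivating application is the intra-articular distal
radius) is planned in 3D, each segmented bone fragment is moved by a rigid
motion from its displaced position to a reduced one. Comparing two such
plans — e.g. a rater's plan against a senior surgeon's gold standard —
requires a displacement measure that is automatic, reproducible and
independent of the coordinate system. Ad-hoc landmark distances do not
satisfy this; `fragdisp` implements a measure that does, and the study
machinery to quantify inter-rater variability with it.

## The measure

The displacement of a fragment between poses *p₁* and *p₂* is summarized by
two independent parameters:

- **TFS** (transformation shift, mm): the fragment center **c** is defined
  as the center of the minimal-volume oriented bounding box (OBB) of the
  fragment surface. The relative motion *M = p₂ ∘ p₁⁻¹* is recovered from
  the posed vertex sets by Horn's closed-form quaternion registration
  (rotation = dominant eigenvector of the 4×4 quaternion matrix of the
  cross-covariance). Then `TFS = ‖M(c) − c‖`.
- **TFA** (transformation angle, degrees): the rotation angle
  `φ = 2·atan2(‖(qx,qy,qz)‖, |qw|)` of *M*'s unit quaternion, in [0°, 180°].

TFS and TFA are independent: adding a translation never changes TFA, and
rotating about the current center never changes TFS. Both are invariant to
a common rigid change of world frame.

On top of the measure, the package provides the inter-rater study pipeline
(per-case and per-rater aggregation, one-way ANOVA with Bonferroni
post hoc tests over profession groups, ordinary-least-squares experience
regressions) and a synthetic fracture/rater simulator in which every
generator parameter is known, so slope recovery can be verified end to end.

## Worked example

```r
library(fragdisp)

# one synthetic 3-fragment case; measure the initial displacement of f1
case <- generate_case(seed = 7, n_fragments = 3)
measure_displacement(case$meshes$f1, case$initial_poses$f1, case$gold_poses$f1)
#> <displacement 'case7/f1': TFS 12.3932 mm, TFA 23.2762 deg (rms 3.4e-15 mm)>

# a full simulated study: 9-rater panel, 20 cases, default error model
model <- rater_error_model(seed = 42)
sim   <- simulate_study(model, n_cases = 20)
analyze_simulated_study(sim)
#> <study_result: 8 raters (gold '1' excluded), alpha = 0.05>
#>   rater_id profession mean_tfs sd_tfs mean_tfa sd_tfa n_cases
#> 1        2         BE    3.522 0.5950    7.536 1.2988      20
#> 2        3         BE    1.902 0.4686    4.271 1.3900      20
#> 3        4        SOR    1.933 0.7054    3.923 1.2654      20
#> 4        5        SOR    2.601 0.4178    4.793 1.2723      20
#> 5        6        SOR    3.502 0.5579    7.813 1.2453      20
#> 6        7        JOR    5.661 0.6171   12.065 1.4717      20
#> 7        8        JOR    4.932 0.6934   11.454 1.2222      20
#> 8        9        JOR    5.524 0.4654   12.412 0.9255      20
#> ANOVA tfs_mean: F(2, 5) = 11.813, p = 0.01275
#> ANOVA tfs_sd  : F(2, 5) = 0.146, p = 0.8678
#> ANOVA tfa_mean: F(2, 5) = 13.236, p = 0.01006
#> ANOVA tfa_sd  : F(2, 5) = 0.370, p = 0.708
#> regression tfs_planning: slope -1.0280/yr, R^2 0.597, F(1, 6) = 8.885, p = 0.02461
#> regression tfa_planning: slope -2.3524/yr, R^2 0.573, F(1, 6) = 8.065, p = 0.02957
#> regression tfs_clinical: slope -0.5718/yr, R^2 0.798, F(1, 4) = 15.846, p = 0.01639
#> regression tfa_clinical: slope -1.3358/yr, R^2 0.757, F(1, 4) = 12.430, p = 0.02433
```

Reading the output: TFS/TFA means are each rater's average deviation from
the gold-standard plan over 20 cases; the SDs are the consistency outcome.
Junior residents (JOR, no planning experience and little clinical
experience) deviate most; the ANOVA over the three profession groups and
the negative regression slopes (≈ −1.0 mm and −2.4° per year of 3D-planning
experience in this realization) quantify the experience effect. The
clinical-experience regression uses only the six raters possessing a
clinical-years value, hence F(1, 4).

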