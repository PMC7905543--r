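---
title: "Measuring 3D fragment displacement and inter-rater variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring 3D fragment displacement and inter-rater variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragdisp)
```

## The displacement model

A reduction plan moves each segmented bone fragment by a proper rigid
motion. `fragdisp` condenses the difference between two poses of one
fragment into two parameters chosen to be independent, coordinate-system
free, and computable without any manual landmarking:

- **TFS (transformation shift, mm).** A fragment needs a reproducible
  center point. We use the center of the minimal-volume oriented bounding
  box (OBB) of the fragment's vertices: it is defined by the geometry
  alone, requires no anatomical labelling, and is equivariant under rigid
  motion. If $M = p_2 \circ p_1^{-1}$ is the relative motion between the
  two poses and $c_1$ the OBB center in pose 1, then
  $\mathrm{TFS} = \lVert M(c_1) - c_1 \rVert$.
- **TFA (transformation angle, degrees).** The rotation angle of $M$,
  extracted from its unit quaternion $(w, x, y, z)$ as
  $\varphi = 2\,\mathrm{atan2}(\lVert(x,y,z)\rVert, |w|) \in [0, 180]$.

$M$ is recovered from the two posed vertex sets (vertex order is the
correspondence) by Horn's closed-form absolute orientation: the optimal
rotation is the eigenvector of the largest eigenvalue of the symmetric
$4\times4$ quaternion matrix built from the cross-covariance of the
centered sets, with unit weights; the translation follows from the
centroids. For exactly rigid input the residual is at rounding level, and
the reported `rms_residual` doubles as a data-quality diagnostic.

Key properties, all covered by the test suite:

- symmetry: measuring $p_1 \to p_2$ or $p_2 \to p_1$ gives the same
  (TFS, TFA);
- independence: composing an extra translation never changes TFA, and an
  extra rotation about the current center never changes TFS;
- global-frame invariance: one common rigid motion applied to both poses
  changes nothing;
- for a screw motion (rotation $\theta$ about an axis at perpendicular
  distance $d$ from the center, plus slide $s$ along the axis),
  $\mathrm{TFS} = \sqrt{s^2 + (2 d \sin(\theta/2))^2}$ and
  $\mathrm{TFA} = \theta$.

### Assumptions

The two vertex sets must be the *same* segmentation, rigidly moved — the
measure is not defined across different segmentations of a fragment. A
rigidity guard rejects input whose pairwise distances are distorted by more
than $10^{-6}\times$ the fragment diameter (sub-sampled to 150 vertices for
large meshes); this catches accidentally mixed-up fragments long before
they corrupt a study.

## Numerical choices

**OBB algorithm.** The minimal box is found by generating candidate
orientations from the convex-hull face normals — for each normal the box
face is flush with that hull face and the in-plane orientation is solved
exactly by rotating calipers over the 2D hull — and then polishing the best
three candidates with a Nelder–Mead search over a local rotation vector.
The exact $O(n^3)$ edge-triple algorithm is deliberately out of scope; the
flush-face + polish combination lands below a 2°-resolution brute-force
rotation grid on every fixture family we generate (the grid's own
discretization excess is first-order in the step, so the grid is the looser
of the two).

**OBB uniqueness and tie-breaking.** "The" minimal box is not unique for
symmetric shapes (a cube admits 24 equivalent boxes). We canonicalize by
sorting half-extents descending, orienting the first two axes toward the
positive lexicographic direction and completing a right-handed frame.
Crucially, only the *center* is consumed downstream, and the center agrees
across all equal-volume minimal boxes in these symmetric cases, so TFS is
unaffected by the tie-break.

**Mapped versus recomputed center.** $c_2$ is obtained by mapping $c_1$
through the recovered motion rather than recomputing the OBB in pose 2.
The two are mathematically identical for rigid motion; mapping makes TFS
exactly invariant to tie-breaking and floating-point orientation jitter.
`measure_displacement(check_center = TRUE)` recomputes the pose-2 OBB as a
diagnostic and warns if the centers disagree beyond
$10^{-6}\times$ diameter.

**Angle extraction** uses `atan2`, not `arccos`, for stability near 0° and
180°, and canonicalizes the quaternion sign ($w \ge 0$) so that $q$ and
$-q$ never disagree.

**Pose validation.** Pose files carry a 4×4 homogeneous matrix, convention
$v' = Rv + t$, right-handed axes, millimetres. The rotation block must be
orthonormal within $10^{-6}$ and is then projected onto SO(3) by SVD;
reflections are rejected outright — a reduction plan cannot mirror a
fragment.

## The study pipeline

Per-fragment deviations of each rater from the designated gold-standard
plan are averaged per (rater, case); case means are aggregated to a
per-rater mean and standard deviation (sample SD, $n-1$), read as the
rater's average performance and consistency. Analyses, each run separately
for TFS and TFA:

- one-way fixed-effects ANOVA of the per-rater means over the three
  profession groups (biomedical engineers BE, senior orthopedic residents
  SOR, junior orthopedic residents JOR; the gold-standard senior surgeon is
  excluded), and the same ANOVA on the per-rater SDs for the consistency
  question;
- Bonferroni-corrected post hoc tests: all pairwise two-sample $t$ tests
  with pooled variance within the pair, $p_{adj} = \min(1, 3 p_{raw})$;
- univariate OLS of per-rater means on 3D-planning years (all eight
  non-gold raters, hence denominator df 6) and on clinical years (only the
  six raters possessing a clinical-years value — the engineers have none —
  hence denominator df 4). A negative slope is an improvement;
  `improvement_per_year` reports its magnitude.

With eight raters in three groups the one-way ANOVA has df $(2, 5)$; the
package always reports the classical degrees of freedom. When every rater
reproduces the gold plan exactly the pipeline reports a "no variability"
note instead of failing on the degenerate variance.

The standard fits are delegated to `stats::lm`, `stats::t.test` and
`stats::pf`; the test suite checks every statistic against hand-coded
sums-of-squares, pooled-$t$ and normal-equations oracles, so the delegation
is verified rather than assumed.

## The synthetic study generator

The generator exists so the entire pipeline — geometry included — can be
validated with known ground truth.

**Cases.** A 12-sided prism (radius 12 mm, length 40 mm), a convex stand-in
for a metaphysis, is split by random planes into 1–6 convex polytope
fragments; per-case fragment counts are drawn from the empirical
distribution of the packaged demographics table (mean 2.55 included
fragments per case over 20 cases). Gold poses are the identity (fragments
are generated reduced); initial poses displace each fragment by 2–15 mm and
5–45°. Cases are pure functions of their seed.

**Rater error.** A rater's expected per-fragment deviation decreases
linearly with experience. Magnitudes are drawn as folded normals
$|N(\mu, \sigma)|$ — non-negative with tunable spread; the translation is
applied in a uniform random direction and the rotation about a uniform
random axis *through the fragment center*, which keeps the simulated TFS
and TFA independently controllable.

**Slope parameters are expected univariate regression slopes.** The
defaults are 0.943 mm and 2.472° per planning year and 0.560 mm and 1.394°
per clinical year. Because planning and clinical experience are correlated
across a real rater panel (engineers have planning years but no clinical
years), feeding these numbers directly into an additive model
$\mu = \beta_0 - a_p\,py - a_c\,cy$ would *not* make the pipeline's
univariate regressions recover them — the univariate slope absorbs part of
the other variable's effect through the panel's covariance. Since the
quantities of interest are precisely the univariate slopes the pipeline
estimates, the generator solves, once at construction, the $2\times2$
linear system for the additive coefficients $(a_p, a_c)$ whose induced
univariate OLS slopes over the configured panel equal the requested
values. With zero requested slopes the coefficients are zero, and the
calibration is exact in the noiseless linear regime (a dedicated test
checks the induced slopes to $10^{-9}$).

**Free parameters.** Baselines (6 mm, 14°) are chosen so that no rater of
the default panel truncates at $\mu \le 0$, keeping the panel in the linear
regime, and so that the least-experienced raters show deviations of a few
millimetres and around twelve degrees — a realistic error scale for manual
intra-articular reduction planning. The folded-normal spreads (0.8 mm,
2.0°) keep the folded-mean bias negligible relative to the smallest panel
means. Neither dispersion is an empirical estimate: no published per-rater
dispersion exists to fit them to, and they are documented as free modelling
choices.

**What the generator does not emulate.** Fragments are convex plane-cut
polytopes, not anatomical bone; there is no segmentation noise, no
cartilage, no articular-congruency structure, and rater error is isotropic
and case-independent. Passing tests therefore demonstrate the correctness
of the *measurement and analysis machinery* under known rigid-body ground
truth — not that real raters behave like the error model.

## Problem sizes and runtime choices

The shipped tests run the geometry oracles at sizes that keep the whole
suite in a few minutes on one CPU: 60-point clouds against the 2° rotation
grid (20 seeded clouds), 1000 random rigid motions for registration
recovery, a 120-combination closed-form screw sweep at $10^{-9}$ tolerance,
and 50 simulated replicates of the full 9-rater × 20-case study for slope
recovery (recovered planning slopes required within ±20% of their
configured values). `scripts/acceptance.R` reruns the pipeline on ten
fresh replicates and reports the recovered slopes, $R^2$, and ANOVA $F$
statistics alongside the packaged-table arithmetic.

```{r, eval = FALSE}
model <- rater_error_model(seed = 42)
sim <- simulate_study(model, n_cases = 20)
analyze_simulated_study(sim)
```

## Known limitations

- The OBB is near-minimal, not provably minimal; only its center matters
  downstream, and the center is stable across near-minimal boxes on the
  fixture families we generate. The caveat is inherited from choosing an
  approximate algorithm and is flagged rather than hidden.
- Eight raters give the group ANOVA little power, and the group sizes
  (2/3/3) are unbalanced; the pipeline applies the standard unbalanced
  one-way analysis with no heteroscedasticity correction.
- Reliability coefficients (e.g. ICC) are out of scope; with two or three
  raters per group they would not be estimable anyway.
- The clinical- and planning-experience regressions are univariate by
  design, mirroring how such studies report experience effects; with a
  correlated panel they do not identify the additive coefficients, which
  is exactly why the generator calibrates as described above.
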