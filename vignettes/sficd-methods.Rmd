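---
title: "Short-range fiber connectivity density: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Short-range fiber connectivity density: models, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sficd)
```

This vignette explains the science and the numerical design of the
package: what each stage computes, which tunable parameters matter and
why their defaults were chosen, what the synthetic phantoms and cohorts
emulate (and what they do not), and where genuinely open design choices
were settled.

## The measure

Short-range (U) fibers connect adjacent gyri through juxtacortical white
matter; typical lengths are around 10–15 mm, and short association
fibers as a class are usually taken to end below ~65 mm. The package
quantifies their density over the cortex in three steps. First,
whole-volume deterministic tractography is restricted to fibers of
10–65 mm. Second, the gray–white interface mesh is tiled into K
contiguous cortical units (CUs) of near-equal area, and the voxel layer
directly beneath each CU is extracted. Third, each CU's short-range
fiber connectivity density is

$$\mathrm{SFiCD} = \frac{\sum_{f=1}^{N} \mathrm{FA}_f}{V_{CU}}
\quad [\mathrm{mm}^{-3}],$$

with the sum over the \(N\) fibers terminating in the CU's voxel layer,
\(\mathrm{FA}_f\) the fiber's mean fractional anisotropy, and
\(V_{CU}\) the layer volume. FA-weighting makes the measure sensitive to
both how many fibers terminate under a patch and how coherent they are;
dividing by \(V_{CU}\) removes patch-size differences. The per-CU values
are projected to the vertices (piecewise constant), carried to a template
surface through a supplied vertex correspondence, and smoothed with a
15 mm FWHM geodesic Gaussian kernel before group statistics.

## Tracking

`tracking_params()` defaults: FA threshold 0.14, turning-angle threshold
35°, step size 0.5 mm, momentum (smoothing) 0.5, one seed per voxel at
voxel centers, length bounds 10–65 mm. These are standard deterministic
(FACT-style) settings for short-fiber extraction. Design choices where
conventions vary:

* **Step units.** "Step 0.5" is interpreted as 0.5 mm (half the in-plane
  voxel size of a typical 1 × 1 × 2 mm diffusion acquisition);
  configurable.
* **Momentum.** `smoothing = 0.5` blends half the previous step direction
  into the next: `normalize(0.5·prev + 0.5·voxel_dir)`. The turning-angle
  check uses the *raw* voxel direction against the previous step, because
  momentum would otherwise mask sharp turns.
* **Antipodal symmetry.** Diffusion directions are axial; at every step
  the voxel direction is sign-aligned to the previous direction, and the
  phantom generator deliberately randomizes per-voxel sign so the tests
  exercise this path.
* **Sampling.** FA and directions are looked up at the nearest voxel by
  default (trilinear FA optional). Nearest-voxel keeps the analytic
  oracles exact: in a straight bundle every step reproduces the chord
  direction bitwise.
* **Termination.** The violating point is never appended; tracks end at
  the last valid point. Seeds below the FA threshold produce no
  streamline (not an error).

One numerical property matters for validation design: explicit Euler
integration along a curved field drifts radially outward by roughly
`step²/(2R)` per step, plus a comparable momentum-lag term. Over a
semicircle of radius 5 mm at step 0.5 this accumulates to under a
millimetre — negligible against a well-resolved bundle, but enough to
exit a tube thinner than one voxel. Arc-recovery checks therefore seed
the canonical trajectory (the bundle apex) inside a tube a few voxels
wide; whole-volume seeding of sub-voxel tubes is used only where the
geometry is straight.

## Phantoms

Bundles are tubes around circular arcs defined by chord and sagitta, so
ground-truth length has the closed form \(2R\alpha\) with
\(R = (c^2/4 + s^2)/(2s)\), \(\alpha = \operatorname{atan2}(c/2, R-s)\).
Tubes have flat end caps (a point must project onto the arc), so every
line through a straight bundle has in-tube extent exactly equal to the
chord — without caps, off-axis seeds would gain up to two tube radii of
length and no exact oracle would exist. Direction noise is applied as a
random small rotation (unit norm preserved exactly); FA noise is additive
Gaussian clipped to [0, 1]. Given the seed, generation is bit-identical.

## Parcellation and the voxel layer

The mesh is partitioned by farthest-point sampling of K seeds on the
edge graph (Euclidean edge weights) followed by geodesic Voronoi labeling
and a contiguity repair pass; the RNG seed only picks the first sample,
so the result is deterministic. Graph geodesics rather than exact
polyhedral geodesics are used: at patch scale the error is bounded
(≤ ~8% on a right-triangulated sheet) and irrelevant to near-equal-area
tiling. On a 2562-vertex sphere with K = 100 the max/min CU area ratio
comes out near 2.4.

The "subcortical voxel layer" is sampled along inward vertex normals at
half-voxel spacing down to `depth_mm` (default 2 mm, one voxel of a
typical 2 mm slice pitch, on the reading that a "layer" is one voxel
deep). A voxel reached from several CUs goes to the CU with the nearest
claiming vertex (ties to the lower id), so masks are disjoint and border
fibers are never double-counted. **The mesh must be at least as fine as
the voxel grid** for the layer to be gap-free; the synthetic sheets used
in the examples match the 0.5 mm grid. CUs that capture no voxels are
flagged and excluded (never zero-filled: zero would conflate "no data"
with "no connectivity"); their vertices carry missing values through
projection, smoothing, and statistics.

Fibers are assigned to CUs by *terminal points only*: the package tracks
the volume once and assigns each fiber to the CU(s) containing its
endpoints, rather than re-seeding per CU mask. This yields the same
"connecting fibers" set at a fraction of the cost and without duplicating
fibers across overlapping seed runs. A fiber with endpoints in two CUs
counts for both; a fiber with both endpoints in one CU counts once.

## Smoothing

`smoothing_operator()` builds a sparse row-stochastic matrix with
Gaussian weights in graph-geodesic distance, σ = FWHM/√(8 ln 2),
truncated at 2.5σ (< 1% of kernel mass, removed by renormalization).
Constants are exact fixed points; the operator is linear and
positivity-preserving; missing vertices are excluded with the remaining
weights renormalized. On a 1 mm sheet the measured impulse-response FWHM
of the 15 mm kernel is 15.01 mm.

## Vertexwise statistics

`build_dods_design()` gives each group its own intercept and its own
slope per covariate. Covariates are demeaned, so the offset contrast is
the group difference at the cohort-mean covariates; without demeaning the
"offset" would be an extrapolation to age 0 and TIV 0 with enormous
variance. A moderator (serum homocysteine in the motivating application)
is binarized at the pooled cohort median — values strictly above the
median code 1, ties go low — and entered as a per-group slope; the
slope-difference contrast is the group × moderator interaction.

`fit_glm_vertexwise()` is ordinary least squares per vertex with
\(t = c^\top\hat\beta / \sqrt{\hat\sigma^2\, c^\top(X^\top X)^{-1}c}\),
df = n − rank(X), two-sided p. Vertices with missing subjects are refit
listwise with adjusted df. Longitudinal change is reduced to per-vertex
rates (map units per month) before a one-sample test, rather than a
repeated-measures covariance model — rates absorb the within-subject
correlation at two timepoints exactly.

### Monte Carlo cluster correction

Observed t-maps are thresholded two-sided at the vertex-level p (default
0.01), positive and negative clusters kept separately, and cluster extent
measured in mm² of vertex area. The null distribution is the maximum
cluster area of unit Gaussian noise smoothed to the target FWHM with the
package's own operator, restandardized per vertex (the smoothed variance
\(\sum_j w_{ij}^2\) is known exactly), thresholded identically.
Cluster-wise p uses the permutation-style estimator
\((1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{iter})\), which never
returns zero. Each contrast is corrected independently, with no
cross-contrast correction. Because the null depends only on (mesh, FWHM,
vertex threshold), `null_max_cluster_areas()` can be computed once and
shared across contrasts and cohorts — the calibration experiments rely on
this; it is an exact reuse, not an approximation.

### Residual smoothness

The raw neighbor-difference estimator
\(\mathrm{FWHM} = h\sqrt{-2\ln 2 / \ln(1 - \Delta/2)}\) (with
\(\Delta\) the ratio of neighbor-difference variance to map variance,
computed per edge-length class) assumes a continuum Gaussian
autocorrelation. On a triangulated graph the geodesic metric is
anisotropic, and the raw value underestimates the FWHM of fields made by
the package's own smoother by 10–15%. `estimate_smoothness()` therefore
applies one fixed-point correction by default: synthesize noise at the
raw estimate, re-estimate, rescale. This makes estimator and null
generator mutually consistent, which is what cluster-level inference
actually requires. The uncorrected statistic remains available
(`calibrate = FALSE`), and a fixed-FWHM override is accepted everywhere,
since whether the original correction family used residual-estimated or
fixed smoothness is not determinable.

## The synthetic cohort as study conditions

`cohort_spec()` emulates the kind of cohort that motivates the method: a
two-group (32 + 38 at baseline in the motivating study; 20 per group by
default here), two-timepoint (27-month) sample of older diabetic adults.
Covariates are drawn at that population's scale — age uniform 69–83 y,
education ~5 ± 3 y, total intracranial volume ~1.45 × 10⁶ ± 1.2 × 10⁵ mm³,
homocysteine lognormal around 17 μmol/L (right-skewed, which is why the
pipeline median-splits it rather than entering it linearly). Noise is
white Gaussian smoothed to 15 mm FWHM and standardized to a per-vertex SD
of 0.05 map units. Injected signals — a group offset, a group × moderator
interaction, a rate per month — enter the mean structure exactly, so
recovery can be checked against truth.

For the effect-recovery experiments the injected offset is 0.1 map units
in a 10 mm-radius disc, i.e. twice the noise SD: a deliberately
well-powered regional effect (a power-design choice, fixed before the
recovery experiments were treated as validation), so that a detection
rate below ~90% over 20 seeds indicates a pipeline defect rather than
sampling luck. The familywise-error experiment uses 500 null cohorts of
40 subjects on a 961-vertex sheet with a shared 1000-iteration null
distribution at the known noise FWHM.

What the cohort generator does **not** emulate: registration error and
inter-subject anatomical variability (the template correspondence is the
identity), non-Gaussian or spatially non-stationary noise, FA-dependent
noise coupling between timepoints, and missing data mechanisms. Passing
tests therefore demonstrate correctness of the estimators and calibration
of the inference under the stated model, not robustness to real-world
registration or acquisition artifacts.

## Problem sizes

The test suite and the acceptance script use desk-scale problems chosen
as the smallest sizes at which each property is meaningfully testable:
phantoms of 40–80 voxels per axis at 0.5 mm, sheets of 961–3721 vertices,
a 2562-vertex icosphere for parcellation, cohorts of 40 subjects, 500
null cohorts against a shared 1000-iteration null, and 20 cohort seeds
for effect recovery. At application scale (K = 1000 CUs, ~10⁵-vertex
hemispheres, 10⁴ Monte Carlo iterations) the same code paths apply; the
dense geodesic distance computation inside `smoothing_operator()` is the
main cost and would be the first thing to block-decompose.

## Known limitations

* Euler integration drift bounds accuracy for strongly curved fibers at
  coarse steps (see Tracking); reduce `step_size` for tighter arcs.
* Graph geodesics overestimate distances anisotropically; the smoothing
  kernel is calibrated in the axis directions and the smoothness
  estimator is bias-corrected against the package's own smoother, but
  neither equals exact polyhedral geodesic smoothing.
* `normalize_to_template()` transports values through a *given*
  correspondence; spherical registration itself is out of scope and must
  come from surface-reconstruction tooling.
* Whether a fiber looping within one CU should count once or twice is
  ambiguous in the field; it counts once here.
* V_CU is the voxel-layer volume, not patch area × cortical thickness.
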