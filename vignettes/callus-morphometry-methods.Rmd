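---
title: "Methods: phantom-validated callus morphometry, torsion analysis and group statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom-validated callus morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette describes the models and numerical choices behind
`callusmorph`: what each stage assumes, which parameters matter and why
their defaults are what they are, what the synthetic phantoms do and do
not emulate, and the decisions taken where the underlying experimental
workflow leaves the procedure open.

## The measurement problem

In plated osteotomy healing studies, the quantity of interest is newly
mineralizing callus around a standardized transverse gap in a loaded long
bone. In calibrated micro-CT (densities in mg of hydroxyapatite per cm³),
forming callus occupies a density band below native cortical bone, so a
dual threshold separates the tissue classes; the spatial pattern of the
callus — how much sits on the plate-side (cis) cortex versus the far
(trans) cortex, and how far from the bone axis it accretes — carries the
biological signal, and the per-slice polar moment of inertia summarizes
its contribution to torsional rigidity. Torsion-to-failure testing and
group statistics complete the picture.

## Segmentation model

* **Thresholds.** Callus is the closed band [250, 1000] mgHA/ccm; bone is
  (1000, ∞). Ties at 1000 go to callus, a deliberate convention: the
  upper band edge is quoted inclusively for the callus range, and
  assigning the boundary consistently makes `segment()` idempotent and
  bit-reproducible. Both thresholds are parameters.
* **Denoising.** A separable discrete Gaussian (SD in voxels) runs before
  thresholding, and only there: all density statistics are computed on
  the raw volume, so the filter can never bias reported densities, only
  stabilize labels. The default `sigma = 0.4` voxel keeps two-sided step
  edges on the right side of both thresholds at the phantom's contrast
  (air 0 / callus ~650–700 / cortex 1200) while attenuating 50 mgHA/ccm
  noise to a level where marrow and cortex essentially never cross a
  threshold. Larger sigmas (0.8+) visibly erode the bone label at the
  endosteal wall because the blurred cortex-marrow step dips below
  1000 mgHA/ccm one voxel into the cortex. Near volume borders the
  truncated kernel is renormalized, which preserves constant fields but
  not impulse mass within `support` voxels of a border.
* **Refinement.** The mask-cleaning series is one opening then one
  closing per label with digital-ball structuring elements (default
  radius 1 voxel) followed by a connected-component filter (default
  27 voxels, 6-connectivity), the smallest series consistent with an
  "opening and closing" refinement; every knob is exposed. Precedence
  bone > callus restores disjointness if closing makes labels collide.
  Opening removes isolated misclassified voxels but also costs a thin
  layer at sharp edges, so refinement pays off when label noise is
  impulsive (the tests quantify this with a paired comparison) and is
  close to neutral on already-clean masks. Out-of-volume voxels count as
  foreground for erosion — objects are assumed to continue beyond the
  scanned field — and background for dilation.
* **Mature callus.** Callus that mineralizes above the bone threshold is
  indistinguishable from cortex by density alone. The package
  operationalizes the slice-wise recovery as: in slices at least
  `standoff` (default 5 mm) away from the gap, the periosteal contour of
  the bone label is sampled as the maximum radius in angular bins around
  the slice centroid; contour and centroid are interpolated linearly
  across the gap region; bone voxels radially outside the interpolated
  envelope (plus one in-plane voxel diagonal of slack) are relabelled
  callus. This is a declared surrogate — the scanner-side macro series it
  stands in for is not published — and it assumes the native cortex is
  quasi-cylindrical over the plated segment.
* **Metal.** Screws are explanted before scanning in the in-vivo
  workflow, so the metal cut (default off, threshold 2000 mgHA/ccm when
  enabled) exists for phantoms and cadaver scans that include hardware.

## Regions of interest and the cis/trans cut

The whole-bone ROI is the axial span of the plate; the gap ROI runs from
the innermost proximal screw to the innermost distal screw. Both are
half-open intervals [start, end) in mm over voxel centres, which avoids
double-counting boundary slices; screw and plate geometry come from
configuration or phantom truth, never from image detection. The cis/trans
partition cuts each slice by a plane through the per-slice bone centroid
(robust to bone curvature, unlike a single global plane) with the
in-plane normal pointing toward the plate; the two halves partition any
mask exactly, which the tests assert as a conservation invariant. The
bone long axis itself is the principal direction of the per-slice
centroid track — centroids follow the shaft exactly even where the scan
truncates the bone obliquely, which keeps the axis stable across voxel
pitches (< 0.5° in the tests).

## Polar moment of inertia

Each slice contributes J = Σ [(x − x̄)² + (y − ȳ)²]·a over the included
labels, centroid-referenced (hence translation-invariant), with positions
reported as percent of scan length. The point-sample form (no per-voxel
self-inertia term) matches a hollow-cylinder closed form π(D⁴ − d⁴)/32 to
well under 2% at 0.1 mm pitch and is what the brute-force oracle in the
tests reproduces to machine precision. Whether callus should carry
torsional credit is a modelling choice: the default section is
bone + callus, because periosteal callus distant from the axis is exactly
what drives between-group rigidity differences, and the label set is a
parameter for users who want bone only.

## Torsion metrics

Curves are deduplicated to strictly increasing angle, then:

* **Failure** is the first sample where the running maximum torque
  exceeds the current torque by the stop criterion (default 3 Nm, the
  testing machine's abort condition). Rotation to failure is the angle at
  the pre-drop peak.
* **Apparent stiffness** is the maximum least-squares slope of a window
  sliding over the pre-ultimate curve. The window covers 20% of the
  pre-ultimate angle range, translated into a fixed sample count (floor
  of 5) — fixed-count windows avoid degenerate short windows at the range
  end whose slopes fit noise rather than stiffness. This is a
  deterministic, parameter-logged surrogate for a manually chosen "linear
  region".
* **Yield** uses the offset method: the stiffest-window fit line shifted
  by 0.5° along the angle axis; yield is the torque at the first
  post-window sample falling below the shifted line, flagged `no_yield`
  (and set to the ultimate torque) if the curve never deviates. Torsion
  protocols rarely publish an exact yield criterion; the offset angle is
  configurable and the flag is always reported.
* **Energy** is the trapezoidal integral of torque over angle up to
  failure; **normalization** reports each variable as
  100 × operated/contralateral.

On noiseless synthetic curves all five metrics recover the construction
within one sample step or 1%; the yield offset intersects the post-yield
branch slightly above the true yield torque by k₂·Δθ with
Δθ = offset·k/(k − k₂), which is why generator defaults keep the
post-yield slope shallow relative to stiffness.

## Group statistics

The ANOVA and Tukey engines run from group summaries (mean, SD, n)
because published tables are often the only accessible data; the
summary-statistics formulas are algebraically identical to a raw-data
one-way ANOVA on any moment-matched sample, and the tests verify the
equivalence against `aov()`/`TukeyHSD()` to machine precision. The study
design being balanced (n = 6 per group), the equal-n studentized-range
form is exact; unbalanced input falls back to Tukey-Kramer. Percent
differences round half away from zero (integer for volume comparisons,
one decimal for biomechanical columns), matching how printed tables are
tabulated; base `round()`'s round-half-even would disagree on exact .5
cases. Zero within-group variance with unequal means is reported as
p = 0 with an explicit flag rather than an error. The non-parametric
branch (paired signed rank) exists only as a raw-data path — it cannot
run from summaries — and defaults to the cis-vs-trans within-group
comparison where a paired test is the natural choice.

## The phantom: what it emulates, and what it does not

The phantom is an osteotomized cortical shaft: a hollow cylinder (default
outer/inner diameter 20/14 mm, shaft length 40 mm) of cortical density
1200 mgHA/ccm with marrow at 100, interrupted by a 3 mm transverse gap —
the standardized parallel osteotomy — with six screw axial positions and
an optional plate-side metal rendering. Callus compartments are accreted
shell-wise outward from the periosteal surface on the requested side,
within an axial extent centred on the gap, until the voxelized volume is
closest to the target; the truth records exactly the achieved voxel
count × voxel volume, so downstream recovery can be asserted exactly.
Noise is additive Gaussian in density units applied after labelling, the
simplest model consistent with a calibrated reconstruction. Between-animal
variability in `generate_group_dataset()` is lognormal with CV 0.25,
chosen once to match the coefficient-of-variation range of published
callus-volume tables (roughly 0.18–0.30), and group effect multipliers
default to the published whole-bone callus-volume ratios (1 : 1.40 :
1.93).

Deliberately not emulated: X-ray physics (no projections, beam hardening
or metal artifacts), partial-volume blur at tissue interfaces, trabecular
microstructure, irregular anatomical cross-sections, and endosteal callus
— the latter is only qualitatively characterized in vivo, so the phantom
places a thin endosteal lining behind an off-by-default flag without
claiming fidelity. Consequently, passing recovery tests demonstrates that
the measurement pipeline is unbiased on geometrically ideal, calibrated
inputs; it does not certify segmentation accuracy on scanner data, where
partial-volume and beam-hardening effects dominate the error budget.

The default voxel pitch is 0.2 mm rather than the scanner's nominal
0.0607 mm so that full-pipeline runs complete in seconds at desk scale;
pitch is a free parameter, and the voxelization error of any compartment
volume shrinks monotonically with pitch (tested at three pitches). Tests
and the acceptance script run phantoms at 0.2–0.6 mm pitch
(1.4–5.1 million voxels) and Monte-Carlo power checks at 200 replicates;
these sizes are the package's chosen verification scale.

## Numerical and degenerate-input conventions

* Volumes are reported in ccm (cm³); all internal lengths are mm, areas
  mm², pMOI mm⁴; the ccm conversion happens in one place.
* The density of an empty mask is `NA` (missing), never 0 — zero is a
  valid density and must not be conflated with absence.
* A slice with no included voxels records J = 0 in the profile rather
  than raising an error.
* `denoise(sigma = 0)` is the identity; refinement with radii 0 and
  `min_component = 1` is the identity; re-running `segment()` on the same
  volume is bit-identical.
* Phantom generation, curve generation and group draws are fully
  seeded; identical seeds give bit-identical outputs, and noise seeds
  never alter truth labels.
* Callus targets that do not fit the field of view fail fast with the
  limiting dimension (transverse margin vs axial extent) named in the
  error.

## Known limitations

The native-envelope reassignment assumes a quasi-cylindrical cortex and
linear interpolation across the gap; strongly curved or flared segments
would need a higher-order envelope. The yield and linear-region criteria
are declared surrogates, so absolute yield values are comparable within
this package but not necessarily with other laboratories' conventions.
Summary-statistics ANOVA inherits the rounding of published tables —
p-values recomputed from two-significant-figure means and SDs carry an
irreducible uncertainty of a few units in the fourth decimal. Percent
claims published alongside such tables occasionally disagree with values
recomputed from the printed means (rounding of the underlying raw data);
the package always reports the recomputed value.
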