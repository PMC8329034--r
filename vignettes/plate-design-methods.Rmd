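---
title: "From femoral morphometry to a customized plate: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From femoral morphometry to a customized plate: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(femplate)
```

femplate turns a table of femoral morphological measurements into the
geometry of a lateral proximal-femur locking plate (the "eagle-shaped"
plate used for 31A3/32A3-type fractures). This vignette explains the
statistical model, the feature model of the plate, the synthetic data that
makes the pipeline testable without patient scans, and the numerical
choices behind the implementation.

## The morphometric model

A cohort is a subjects-by-parameters table over 28 named measurements — 9
proximal (`H_fh` femoral head height, `A_fn` collodiaphyseal angle, `L_fhs`
eccentric distance, `L_fn` neck length, `D_fh`/`D_fn` head and neck
diameters, `L_t` trochanter length, `H_t1`/`H_t2` trochanter bump height
and medial offset), 3 shaft (`D_fs` coronal shaft diameter, `H_fs` shaft
length, `A_fs` shaft bending angle) and 16 distal condyle measurements —
plus the overall femur length `H_f`. Lengths are in mm, angles in degrees.

Each region is analyzed separately:

1. **Standardization** to z-scores (sample SD, $n-1$ denominator). The
   measurements mix scales (mm vs degrees), so the analysis runs on the
   correlation rather than covariance matrix.
2. **Sampling adequacy.** The KMO statistic compares squared simple
   correlations against squared partial correlations obtained from the
   inverse correlation matrix; values near 1 mean shared structure that
   PCA can compress. Bartlett's sphericity test
   ($\chi^2 = -(n-1-\tfrac{2p+5}{6})\ln\det R$, $df = p(p-1)/2$) rejects
   the identity hypothesis. The shaft block is never reduced: it has only
   three, weakly correlated parameters, and they pass through the pipeline
   unreduced.
3. **Eigendecomposition and retention.** Components are retained by a
   two-part rule: the smallest $k$ whose cumulative variance contribution
   rate $\sum \lambda_i/p$ reaches 0.90 (inclusive), subject to every
   retained eigenvalue exceeding 0.5 (strict floor; the floor wins
   conflicts with a warning). On the published contribution rates this
   yields 4 proximal components (cumulative 90.474%) and 7 distal
   components (93.241%).
4. **Scores and rotation.** Component scores are the plain linear forms
   $p_i = \sum_j a_{ij} X_j$ (and $q_i = \sum_j b_{ij} Y_j$ distally).
   For interpretation the retained loadings are varimax-rotated
   (Kaiser-normalized, via `stats::varimax` with a tight 1e-10 criterion
   tolerance); rotation preserves per-variable communalities, which the
   tests verify to 1e-8. Each parameter is then attributed to the
   component holding its largest absolute rotated loading; ties within
   1e-9 go to the lower component index and are flagged.
5. **Composite score and classification.** A subject's composite score is
   the contribution-rate-weighted sum of its component scores (raw rates
   by default; a `normalized` flag rescales the weights to sum to one).
   Cohorts are stratified into three morphological classes by composite
   tertiles — the stratification rule is not prescribed by the source
   method, so tertiles were chosen as the simplest reproducible rule, with
   ties broken by subject order. One-way equal-variance ANOVA per
   parameter (no multiple-testing correction, mirroring per-parameter
   significance reporting) verifies that the classes differ.

`reconstruct_parameters()` inverts the scoring by least squares:
$\hat x = A^\top s$ is the orthogonal projection onto the span of the
retained components, valid only for raw (orthonormal-row) loadings —
rotated loadings are refused.

## Synthetic cohorts

No subject-level data is published, only per-parameter means/SDs, two
loading matrices and the variance contribution rates. The generator
reconstructs a correlation matrix from what is published:

$$R_0 = \sum_k (r_k\,p)\, v_k v_k^\top \;+\; c\,(I - V V^\top),
\qquad c = \frac{p - \sum_k r_k p}{p - k}$$

i.e. the retained rank-$k$ part with the published eigenvalues, plus the
residual variance spread isotropically over the orthogonal complement so
that the reconstruction's leading eigenvalues equal the published ones
exactly before the diagonal is re-unitized. Eigenvalues are then clipped
at zero, the matrix re-symmetrized and its diagonal reset to 1; the
Frobenius norm of this repair is reported (it is ~0 for the proximal
block). Design choices worth knowing:

* Cross-block correlations (proximal–distal, shaft) are **zero**: nothing
  is published about them, so blocks are assembled block-diagonally.
* The printed distal loading table contains an impossible entry (1.588 in
  its last column), so it ships verbatim only as an I/O fixture; for
  reconstruction its rows are renormalized to unit norm.
* `H_f` is drawn with exactly the published moments
  (420.072 ± 22.968 mm) and correlation 0.8 with shaft length — femur
  length and shaft length are tightly coupled anatomically, and a plate
  two-thirds of femur length must physically fit on the shaft.
* The synthetic cohort is exactly Gaussian. The real reference data is
  very slightly left-skewed (−0.07 in femur length); that skew is *not*
  injected, and `validate_cohort()` documents the difference. Passing
  tests therefore show correctness of the pipeline under Gaussian
  conditions, not robustness to real-data artifacts (measurement error,
  digitization bias, non-normal tails).

At $n = 5000$ a cohort drawn from the reconstructed proximal correlation
returns the four published contribution rates within a fraction of a
percentage point and retains $k = 4$, which is the package's own
end-to-end recovery check.

## The synthetic femur surface

The fit pipeline needs a curved contact region with correct gross
dimensions, not an anatomical mesh. `generate_bone_surface()` builds a
smooth parametric proxy of the lateral femur face:

* a generalized cylinder of arc length `H_fs` and radius `D_fs/2`;
* a uniform coronal bow of total angle $180° - A_{fs}$ with apex at
  mid-shaft (constant curvature; real femoral bowing is continuous, and a
  localized kink would not be representable by the 11-station loft);
* a greater-trochanter bump rising to height `H_t1` at the proximal end:
  a quintic smoothstep axially (C2, compact support of extent
  `0.55 * L_t`, so the distal shaft is an exact circular cylinder) and a
  Gaussian azimuthally with spread $\sigma_\phi = H_{t2}/(D_{fs}/2)$.

The axial bump support is deliberately confined to the region covered by
the densely spaced head stations: a transverse-station loft can only
reproduce axial variation that its stations sample, so the generator
keeps the trochanter inside the plate-head window, which is also where
the plate's own bump heights live. Mesh generation is pure: identical
parameters give identical vertex buffers.

## The plate feature model

The plate skeleton is twelve feature curves: one closed boundary (`C0`),
two open ridge curves (`C1` tail, `C2` head) meeting end-to-end at the
neck junction, and nine transverse costal curves (`C3..C11`). Pairwise
topological relations are labeled `BI_*` (boundary–internal, by
intersection count: 0, 1, or 2) and `II_*` (internal–internal, by
intersection position: `II_11` endpoint–endpoint, `II_12`
endpoint–interior, `II_13` interior–interior; with several hits the
highest class wins). The digit semantics are an inference — the source
names the types without defining the suffixes — but this encoding is the
unique simple one consistent with the published 12×12 adjacency matrix,
which the shipped template reproduces cell for cell.

Intersections are found by coarse polyline screening (segment–segment
distances, 0.5 mm threshold), clustering, and a grid-shrink plus
Gauss–Newton refinement on the parameter pair down to the 1e-6 mm
tolerance; "endpoint" means within that tolerance of a curve terminus.
Colinear overlap of positive length is refused as degenerate.

**Semantic parameters.** The plate is described by total length `L`
(= tail `l1` + head `l2`), total width `W`, local station widths
`w0..w8`, local bump heights `h0..h8`, thicknesses `t1`/`t2`, hole
diameters `d1..d3` and tail-hole clear spacing `s1`. Hierarchy identities
(`L = l1 + l2`, `W >= max w_i`, positivity) are checked exactly;
bone-derived parameters get admissible ranges of ±3 linearly propagated
SDs around their value at the reference mean. Constraint checking returns
violations as data; the derivation entry point turns them into errors.

**Derivation (primary mapping).** `L = α_L H_f`, `W = α_W D_{fs}`,
`l2 = β L_t`, `l1 = L - l2`; local widths are fixed fractions of `W`
scaled by a size factor averaging six reconstructable proximal/distal
size parameters (equal to 1 at the mean), and local heights are fixed
fractions of the trochanter bump height `H_t1`. The default coefficients
are calibrated once so the reference mean femur derives exactly the
published Plate A (`l1 = 229`, `l2 = 39`, `w5 = 29`, `t = 3 mm`, ...);
all are user-overridable. The published plate lists print only five of
the nine widths and omit the tail heights; the gaps in the shipped
presets are smooth interpolations and are labelled synthetic.

**Component mapping.** The score-to-plate mapping composes score-space
reconstruction with the parametric derivation: scores
$P_4 = \{p_1..p_4, q_1..q_7\}$ → standardized bone parameters (least
squares through the raw loadings) → de-standardization with the cohort
moments → semantic derivation. Zero scores reproduce the base mean-shape
plate *exactly* (bit-equal), and the mapping is linear in the scores up
to the fixed coefficient structure. Parameters outside the retained span
(the shaft block and `H_f`) stay at their cohort means — with no
published cross-block correlations there is no defensible way to move
them; the width size-factor deliberately mixes proximal and distal
parameters so that every element of $P_4$ influences the derived plate.

## Geometry: stations, loft, solid, fit

**Stations.** The feature-point grid has 11 transverse stations spanning
exactly `l1 + l2`: a narrow tail tip, two tail stations (`w0`, `w1` at
`l1/3` and `2l1/3`), the neck junction (`w2`), six head stations
(`w3..w8`, uniform over `l2`) and a narrow head tip. Station widths are
measured as *arc length along the bone surface* (the physical width of a
bent plate); on a plane arc equals chord. Nine of the stations carry the
costal curves; the tips anchor the boundary.

**Heights, two modes.** Built on a bone surface (`"measured"`), profile
points are exact surface samples — this is what makes the sub-0.1 mm fit
possible — and the attained apex heights are recorded against the
semantic `h_i`, which act as descriptive attributes. Built without a bone
(`"parametric"`, used for the shipped template), the `h_i` lift each
station apex off the plane with a smooth transverse bump. The two modes
agree when the bone is a plane and all `h_i = 0`.

**Loft.** The undersurface interpolates the full station×profile grid
with a tensor-product *local* cubic Hermite scheme, chord-length
parameterized in both directions. Knot tangents are quadratic Lagrange
derivatives; at strongly nonuniform knots (the junction, where a ~76 mm
tail span meets 5.6 mm head spans) the tangent is taken one-sided from
the longer-span side. This matters: a globally C2 spline (or a centered
slope at the junction) lets the trochanter-region curvature leak across
the long tail span and produces hundreds of microns of sag — measured
0.8 mm at the plate edge — while the local one-sided scheme keeps the
worst-case deviation below 0.1 mm. The interpolation is linear in the
data, so evaluation uses precomputed cardinal bases and is exactly
interpolating at the grid (machine precision); the loft is C1, which the
downstream offsetting and projection need. A Jacobian-orientation sweep
on a sample grid rejects self-intersecting lofts.

**Fit deviation.** Point-to-surface distance by damped Gauss–Newton in
the parameter plane, vectorized over all points and seeded from a dense
41×17 sampling; non-converged points (iteration cap 100) fall back to the
dense-sample distance and are flagged. The standard protocol samples 500
bone points strictly *between* stations across 90% of the local width.
For the reference mean femur the maximum deviation is ~0.07 mm, and
across 20 seeded femurs spanning ±2 SD of overall size it stays below
0.1 mm — within the 0.16 mm acceptance bound the method targets. The
report is invariant under rigid motion of the whole scene to 1e-9.

**Solid and holes.** The shell offsets the undersurface along its unit
normals by a thickness field blending `t1` into `t2` with a quintic
smoothstep over a neck region 10% of `L` wide (the published instances
all use `t1 = t2 = 3 mm`, so the blend is unexercised by fixtures but
continuous by construction); side walls are stitched to a watertight
triangle mesh (Euler characteristic 2, every edge in two faces). Tail
holes (ø`d1`) are centered on the tail ridge with clear rim spacing `s1`
— centers `s1 + d1` apart in arc length, count
$\lfloor (l_1 - d_1)/(s_1 + d_1) \rfloor + 1$ — and two head holes
(ø`d2`, ø`d3`) sit at the `w4`/`w6` stations. Hole axes are local surface
normals. Holes are specification metadata (JSON hole table); boolean
subtraction from the shell is out of scope.

**Mesh I/O.** Binary STL (float32, mm) by default, ASCII OBJ and PLY;
readers weld STL soup back to indexed meshes on exact coordinate matches.
Round trips are exact to float32 quantization at the plate's coordinate
magnitude.

## Sampled test femurs

`sample_femur_parameters()` draws plausible subjects for end-to-end
testing: a shared isometric size factor spanning ±2 SD of `H_f` scales
every length (overall size dominates real femoral variation), small
independent jitter (0.2 SD) perturbs the remaining lengths, and angles
are jittered without scaling. `H_fs` and `H_f` carry no independent
jitter so that the derived plate length always fits the shaft — the mean
femur leaves only ~1 mm of axial margin, exactly as the published
geometry does.

## Problem sizes and determinism

Defaults keep every computation interactive: 11×9 feature grids, 41×17
shell sampling, 500-point fit sets, 48-ring bone meshes, cohorts of
100,000 for moment checks and 5,000 for spectrum recovery. All
randomness flows through explicit integer seeds; cohort generation,
mesh generation and fixture emission are bit-reproducible under a fixed
seed.

## Known limitations

* The synthetic femur is a smooth proxy; nothing here validates fit on
  segmented patient anatomy, cortical ridges, or the linea aspera.
* The distal block's published loading matrix is internally inconsistent;
  distal reconstruction quality is correspondingly approximate.
* Classification into three morphological classes uses tertiles; if the
  original work clustered differently, class boundaries (not the
  significant between-class differences) would change.
* Constraint ranges are linearized ±3 SD bands, adequate near the cohort
  center but not a substitute for surgeon review at the extremes.
* Screw trajectories, plate material, and mechanical (FE) behaviour are
  out of scope.
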