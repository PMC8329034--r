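# femplate

Bone-morphology-driven design of customized femoral plates in R.

Designing a plate that actually sits on a patient's femur means first
understanding how femoral shape varies. femplate implements a two-stage
method for orthopedic device engineers and skeletal morphometricians:

1. **Morphometric feature extraction.** Principal component analysis of 28
   named femoral parameters (9 proximal, 3 shaft, 16 distal; mm and
   degrees), with the standard adequacy tests (KMO, Bartlett sphericity), a
   two-part retention rule (cumulative variance contribution rate
   ≥ 90%, every retained eigenvalue > 0.5), varimax rotation for
   interpretation, component scores $p_i = \sum_j a_{ij} X_j$, a
   variance-contribution-weighted composite score, tertile stratification
   into three morphological classes, and per-parameter ANOVA validation.
2. **Parametric plate generation.** A feature model of the "eagle-shaped"
   lateral proximal-femur plate: a twelve-curve skeleton (closed boundary
   `C0`, ridge curves `C1`/`C2`, costal curves `C3..C11`) with a formal
   curve-topology adjacency matrix, a semantic parameter hierarchy
   (`L = l1 + l2`, `W`, station widths `w0..w8`, bump heights `h0..h8`,
   thickness and screw-hole parameters), a principal-component-weighted
   mapping from bone parameters (or the score set
   `P4 = {p1..p4, q1..q7}`) to plate parameters, lofting of the plate
   undersurface, watertight solid extrusion with hole layout, and a
   point-to-surface fit-deviation report against the bone contact region.

Because no subject-level cohort is publicly deposited, the package also
ships a synthetic-data module: cohorts drawn from a correlation structure
reconstructed from the published loading matrices and contribution rates,
and a parametric synthetic femur surface (bowed shaft + trochanter bump)
for end-to-end geometry testing.

## Worked example

```r
library(femplate)

# a synthetic cohort with the reconstructed correlation structure
cohort <- generate_cohort(cohort_spec(n = 5000, seed = 6))
fit <- femur_pca(cohort, region = "proximal")
fit
#> <femur_pca: proximal region, n = 5000, k = 4 components (90.6% cumulative)>
#>   KMO = 0.747, Bartlett p = 0
round(100 * fit$eigen$rates[1:4], 2)
#> [1] 43.69 24.82 14.23  7.90
```

Four components are retained and the recovered variance contribution
rates sit within a fraction of a percentage point of the published
(43.054, 25.449, 14.176, 7.795)%. `tidy(fit)` returns the rotated
loadings in long form; `autoplot(fit)` draws the scree/cumulative plot.

```r
# end-to-end plate build for the reference mean femur
design <- design_plate(mean_femur_parameters())
design$semantic
#> <semantic_parameters: L = 268.0 (l1 229.0 + l2 39.0), W = 29.0 mm>
#>   w: 12.0 14.0 16.0 20.0 25.0 29.0 22.0 13.0 12.0
#>   h: 0.4 0.4 1.6 2.4 7.9 8.3 5.2 0.8 0.7
#>   t1 3.0 t2 3.0 | d 7/5/5 s1 6
design$fit
#> <fit_report: n = 500, max 0.0689 mm, mean 0.0090 mm, RMS 0.0163 mm>
design$solid
#> <plate_solid: 1394 vertices, 2784 faces, 20 holes>
```

The mean femur derives exactly the published Plate A dimensions
(tail 229 mm + head 39 mm, maximum width 29 mm, 3 mm thickness, ø7 mm
tail holes at 6 mm clear spacing), and the lofted undersurface deviates
from the bone contact region by at most 0.069 mm over 500 dense samples —
inside the 0.16 mm fit bound the method targets. `export_mesh()` writes
the shell as binary STL (or OBJ/PLY); `write_solid_json()` records the
hole table with centers, normals, and diameters.

A thin command line lives in `inst/cli/femplate` with subcommands `pca`,
`cohort`, `surface`, `build`, `topology`, `fit`, `fixtures` (exit codes:
0 ok, 2 input, 3 statistics, 4 constraints, 5 geometry).

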