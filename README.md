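# neckangle

Direct CT-based measurement of rotational malalignment (malrotation) in
basicervical femoral neck fractures, with a synthetic goniometer phantom
and the reliability statistics to validate it.

## The problem

CT techniques for femoral torsion conventionally use the femoral neck as
a pointer and report its version against the distal condylar plane. In a
basicervical femoral neck fracture the neck itself is broken, so the
pointer is gone: rotation of the head fragment against the trochanteric
massif is invisible to condyle-referenced methods. The *direct*
measurement works on a single neck-aligned 5 mm axial slab instead:

- a tangent `T` along the ventral cortex of the greater trochanter, and
  its parallel `P` at the dorsal border crossing the lesser trochanter;
- a best-fitting circle in the femoral head (center `C_h`) and a circle
  centered in the lateral opening of the head (center `C_o`): the
  **medial axis** `m = C_o C_h`;
- two circles inscribed between `T` and `P` in the lateral neck (centers
  `C_1`, `C_2`): the **lateral axis** `l = C_2 C_1`;
- the torsion across the fracture is the signed acute angle
  `theta = angle(m, l)`, anteversion positive.

The package implements the full pipeline (oblique reformat, slab
projection, contour labeling, the geometric construction), a parametric
voxel phantom of a proximal femur whose head fragment can be dialed from
30 degrees retroversion to 30 degrees anteversion about a goniometer
axis with exact ground truth, and the statistics used to validate the
method: per-level descriptives, single-measures absolute-agreement
intraclass correlation ICC(A,1) with F-based confidence intervals,
Pearson correlation, and per-level paired t-tests.

## Worked example

```r
library(neckangle)

# a left femur with the head fragment dialed to +20 degrees anteversion,
# 0.8 mm voxels, CT-like noise
vol <- buildPhantom(PhantomSpec(setAngle = 20, voxelSpacing = rep(0.8, 3),
                                seed = 7))
m <- measureTorsion(vol)   # hints default to the phantom's ground truth
m
#> TorsionMeasurement: +20.38 deg (anteversion positive)
constructionCircles(m)$head
#> Circle2D: center (6.562, 0.032) mm, radius 23.198 mm
```

The measured +20.38 degrees recovers the dialed +20 within half a degree;
the head circle's 23.2 mm radius is the 24 mm head sphere seen 7.7 mm off
its equator. `plotTorsionConstruction(m)` renders the slab with the
tangent, parallel, all four circles and both axes.

A small end-to-end study — phantom per level, two simulated raters with
perturbed landmark hints, blinded randomised order, full battery:

```r
cfg <- runConfig(levels = c(-30, -20, -10, 10, 20, 30), replicates = 2,
                 raters = 2, seed = 11,
                 phantom = list(voxelSpacing = rep(1.2, 3)))
st <- runStudy(cfg)
st
#> Phantom validation study
#>   6 levels x 2 replicates x 2 raters
#>   set  -30.0 deg -> mean measured  -30.02 deg
#>   set  -20.0 deg -> mean measured  -18.51 deg
#>   set  -10.0 deg -> mean measured  -10.03 deg
#>   set  +10.0 deg -> mean measured   +9.99 deg
#>   set  +20.0 deg -> mean measured  +19.68 deg
#>   set  +30.0 deg -> mean measured  +28.80 deg
#> Validation battery
#>   pooled ICC(A,1): 0.998
#>   per-replicate ICC range: 0.998-0.998
#>   paired-test |mean diff| range: 0.02-1.30 deg
```

Per-level means track the dial, and the two simulated raters agree almost
perfectly (ICC near 1, paired mean differences around a degree) — the
behaviour the method was designed to show. The example above uses coarse
1.2 mm voxels for speed; accuracy tightens at clinical resolution.

A thin command-line front end lives in `inst/scripts/neckangle.R`
(subcommands `phantom`, `measure`, `stats`, `validate`).

## Package layout

- `R/geometry.R` — circle fit (Pratt + Gauss-Newton polish), supporting
  tangent, parallel, inscribed circles, signed axis angle
- `R/phantom.R` — goniometer phantom and fast series simulator
- `R/measurement.R` — frame alignment, slab reformat, contour labeling,
  `measureTorsion()`
- `R/stats.R` — descriptives, ICC(A,1), Pearson, paired t,
  `runValidationBattery()`
- `R/study.R`, `R/io.R` — end-to-end study, NIfTI/CSV/JSON/YAML I/O
- `vignettes/direct-torsion-measurement.Rmd` — the methods vignette:
  model, phantom design decisions, numerical choices, limitations
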