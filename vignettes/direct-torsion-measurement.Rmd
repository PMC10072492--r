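---
title: "Direct CT measurement of femoral neck malrotation: model, phantom and statistics"
author: "neckangle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct CT measurement of femoral neck malrotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neckangle)
```

## The problem and the method

Every established CT technique for femoral torsion treats the femoral neck
as a pointer and reads its version angle against the distal condylar
plane. In a basicervical femoral neck fracture the pointer itself is
broken: the head fragment can rotate against the trochanteric massif, and
no condyle-referenced measurement can see it. The *direct* measurement
sidesteps the condyles entirely. On a single neck-aligned axial CT slab it
constructs

1. a **tangent** along the ventral (frontal) cortex of the greater
   trochanter,
2. a **parallel** to that tangent at the dorsal border of the neck,
   crossing the lesser trochanter,
3. a best-fitting **circle in the femoral head** and a circle **in the
   lateral opening of the head** (the aperture where the neck stump
   leaves the head); the line through their centers is the *medial* neck
   axis,
4. **two circles inscribed** between tangent and parallel in the lateral
   neck; the line through their centers is the *lateral* neck axis,
5. the signed acute **intersection angle** of the two axes — the
   rotational displacement across the fracture, anteversion positive.

Because both axes are drawn in the image, the result is invariant under
in-plane rotations of the viewing frame; the slab orientation only enters
through a second-order projection effect. That property is what makes the
measurement operator-robust, and the implementation preserves it (see
*Tangent direction* below).

`measureTorsion()` runs the whole chain and returns the full construction
(circles, lines, axes, slab) for audit; `plotTorsionConstruction()` draws
it.

## The goniometer phantom

`buildPhantom()` emulates the physical validation set-up: a radiopaque
left femur with a basicervical osteotomy, clamped in a jig that dials the
head fragment to a known version angle in 10-degree steps between 30
degrees of retroversion and 30 degrees of anteversion.

The anatomy is deliberately parametric — sphere head (radius 24 mm),
tapering frustum neck (13 to 16 mm radius over 50 mm), cylindrical shaft,
ellipsoidal trochanters — so every landmark has a closed-form ground
truth, attached to the volume as metadata. Two choices deserve
explanation:

* **Displacement axis.** The jig rotates the head fragment about an axis
  through the osteotomy center, tilted in the frontal plane, centered
  axially. We take that axis perpendicular to the native neck axis by
  default (`axisTiltDeg = neckShaftAngle - 90`, i.e. 40 degrees from the
  shaft for a 130-degree neck-shaft angle). Only then does a dialed
  rotation of $\theta$ produce a true inter-fragment version change of
  exactly $\theta$ — which is how an angle scale on such a jig is
  calibrated, and what makes "set angle" and "true angle" synonymous in
  the validation. A shaft-parallel axis would make a 30-degree dial
  correspond to a 22.9-degree true angle. The tilt is configurable.

* **Osteotomy gap.** Rotating a flat transverse cut about an in-plane
  axis swings the cut face out of its plane; with a neck radius of
  ~15 mm, a 30-degree swing needs roughly $r \sin 30^\circ \approx 7.5$
  mm of clearance. The jig therefore holds the fragments 10 mm apart
  (`osteotomyGap`), and `buildPhantom()` refuses physically impossible
  configurations (fragment collision) rather than rendering them.

* **Anterior trochanteric facet.** The tangent is drawn "along" the
  ventral trochanteric cortex, which is only well defined if that cortex
  is flattish — as it is on a real femur. The greater trochanter
  ellipsoid is therefore cut flat at `gtVentralFacet` (20 mm ventral of
  the neck-axis plane), giving the tangent a genuine cortical line to
  follow.

Voxelisation assigns a 1.5 mm cortical shell (intensity 1200) over
trabecular interior (300) on background 0, plus additive Gaussian noise
(sd 20 by default) under the spec's seed; identical spec and seed give
voxelwise identical volumes. Default spacing is a clinical
0.6 x 0.6 x 1.0 mm.

What the phantom does **not** emulate: Hounsfield calibration, beam
hardening and streaks, soft tissue, osteosynthesis hardware, cancellous
texture, and anatomical variation beyond its parameters. Passing the
validation battery therefore demonstrates that the *geometry* of the
construction is sound and numerically stable at clinical resolution — not
that segmentation would survive metal artefacts in postoperative scans.

## Measurement pipeline choices

**Frame alignment** (`alignNeckFrame()`). The head center is initialised
as an iterated bone centroid in a head-sized ball and then refined by an
algebraic sphere fit to cortical-shell voxels, which is unbiased even
though the shell is incomplete at the head-neck aperture. The neck
direction is refined **on the lateral fragment only**: everything beyond
a head-sized exclusion ball is treated as lateral; its medial tip (the
osteotomy face, whose centroid lies on the lateral neck axis by the
stump's mirror symmetry) anchors a corridor that is iterated around the
evolving axis estimate. Using the whole head-plus-neck region instead
would let the displaced head drag the reference axis and absorb a large
part of the very rotation being measured. The section normal is the
scanner superior axis orthogonalised against the neck axis, so the axial
plane contains the neck axis; the frame origin is shifted 10 mm distally
(`calcarOffsetMm`) so the section runs down near the calcar (Adam's bow),
as the clinical protocol prescribes.

**Slab** (`extractAxialSlab()`). A 5 mm slab (the clinical slice
thickness) is resampled by trilinear interpolation at the finest voxel
spacing and reduced by mean-intensity projection.

**Contours** (`extractCortexContours()`). Plain global thresholding
(default 150, between background and trabecular intensity) is adequate
for the phantom's bimodal histogram. Labeling is deterministic: the
connected component containing the head center is medial, the largest
other is lateral; medial boundary pixels are classified by their distance
from the head center in units of the estimated head-disk radius (the disk
arc near 1.0, the stump silhouette beyond ~1.05), lateral ones by
along-axis windows for the greater-trochanter and dorsal
(lesser-trochanter) regions. Each missing landmark raises an error naming
it.

**Tangent direction.** The supporting line of the trochanter contour in
the ventral direction fixes the *touching point*; the tangent's
*direction* is then refined by fitting a line to the subpixel ventral
cortex profile near that point, with iterative trimming (floor 0.1 mm) so
the curved shoulders at the facet ends cannot tilt it. This mirrors what
the operator does — aligning the drawn tangent with the imaged cortex,
not with the screen axes — and is what keeps the measurement insensitive
to the landmark hints: a frame-locked tangent direction would inherit
every frame error one-for-one.

**Head-opening circle.** The stump silhouette is two near-parallel
aperture edges plus the cut face; an unconstrained least-squares circle
on such a set is ill-posed *along* the stump axis (its center can slide
by tens of millimetres under pixel noise). The opening circle is instead
inscribed between the two robustly fitted aperture edge lines, centered
at their mid-line at the silhouette's mean along-axis position — on the
medial neck axis by symmetry, which is the only property the construction
uses.

**Neck stations.** The operator places the two inscribed circles freely;
we default to fractions 0.35 and 0.65 of the band's extent between the
lateral head opening and the lateral cortex (`stations`). The measured
angle does not depend on the stations (both centers lie on the band
mid-line); they are kept configurable for fidelity of the rendered
construction.

**Circle fit.** `fitCircle()` is a Pratt algebraic fit (stable for
partial arcs) polished by a few Gauss-Newton steps on the radial
residuals; it is exact on noise-free circles and matches a brute-force
grid search on noisy ones.

**Sign conventions.** World coordinates are femur-centric and LPS-like:
+x medial (left femur), +y ventral, +z superior; slices are indexed
row-major with physical (mm) coordinates; anteversion is positive. A
right femur is mirrored geometry with the ventral reference flipped, so
the same dialed anteversion yields the same positive angle.

## Rater simulation and the statistics battery

`runStudy()` reproduces the validation design: one phantom per level and
replicate (each with its own noise seed derived from the master seed),
measured by each simulated rater through the *full* pipeline with
independently perturbed landmark hints (head center sd 1.5 mm, direction
sd 2 degrees). Inter-rater differences thus arise through the geometry,
as they do for human investigators; `simulateGoniometerSeries()` offers
the fast alternative (set + bias + Gaussian noise) for purely statistical
experiments. Measurements are logged in a blinded randomised order per
rater, reproducible from the seed.

The battery (`runValidationBattery()`) mirrors the published analysis:

* per (rater, level) descriptives (n, min, max, mean, sd, variance);
* per-replicate ICC and Pearson correlation across the six levels, one
  row per "investigation";
* a per-level paired t-test between the raters across replicates.

The ICC is pinned to **ICC(A,1)** — two-way model, absolute agreement,
single measures — because each cell is a single measurement and absolute
agreement is the stated model; the confidence interval uses the
F-distribution approach of McGraw and Wong with a Satterthwaite df, and
the p-value tests ICC = 0 via $F = MSR/MSE$ on $(n-1, (n-1)(k-1))$ df, as
SPSS reports for this model. Whether a "mean of all" ICC pools all
level-replicate pairs or averages the per-replicate ICCs is ambiguous, so
both are computed and labeled. Zero-variance cells (possible in noiseless
simulations) are reported as exact agreement with a `degenerate` flag
rather than as undefined F ratios. No multiple-testing correction is
applied across the six paired tests, matching the original analysis. One
published inconsistency is worth noting: the abstract and results section
of the source analysis disagree on one CI bound (0.03 vs 0.026) and
recomputation from the printed summaries gives a third value, so that
pair is excluded from exact parity checks.

## Problem sizes and determinism

The package's own validation (the acceptance suite and
`scripts/acceptance.R`) uses the study design at 0.8 mm isotropic voxels:
six levels x ten replicates x two raters, 60 phantom builds and 120 full
measurements, plus 200 simulated series for the ICC distribution and a
grid-search circle oracle at 0.001 mm resolution. Unit tests use 1.2 mm
phantoms, which are about four times faster and correspondingly noisier;
their tolerances are set for that resolution. All randomness — phantom
noise, hint perturbations, measurement order — derives from explicit
integer seeds, and identical inputs give bit-identical results.

## Known limitations

* The formalisation of the "lateral opening of the femoral head" is our
  stated interpretation of a visually defined landmark.
* Global thresholding presumes phantom-like bimodal intensities; real
  postoperative CTs (metal, soft tissue) would need a segmentation front
  end, which is out of scope.
* The displacement-axis tilt of the physical jig is not quantified in its
  description ("slightly angulated in the frontal view"); we chose the
  perpendicular-to-neck default on calibration grounds and left it
  configurable.
* Landmark hints are required; there is no automatic detection.
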