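---
title: "Transverse-plane vertebral morphometry: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transverse-plane vertebral morphometry: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertemetry)
```

## The measurement model

Scoliotic vertebrae rotate and translate within the trunk
cross-section. On an axial CT slice this package quantifies that with
three quantities, all computed in mm in a patient-centred frame where
`+x` is patient-left and `+y` is posterior (image rows grow posterior,
columns grow patient-left; positions are 0-based pixel indices times
the per-axis spacing).

Inputs per slice are two annotator-placed markers — the vertebral-body
centre `m1` and the spinous-process tip `m2` — and the CT image itself.

1. **Body contour.** The trunk outline is extracted as the iso-contour
   of the HU image at a threshold of −300 HU (`extractBodyContour`),
   using marching squares with sub-pixel linear interpolation
   (`grDevices::contourLines`). −300 HU sits comfortably between air
   (≈ −1000) and any tissue (fat ≈ −100 and above), so the contour
   position is insensitive to the exact choice; the threshold is a
   pipeline parameter (`runConfig(thresholdHU=)`) nonetheless. Among
   closed iso-lines the largest-area one is taken as the body. An open
   iso-line larger than every closed one means the trunk leaves the
   field of view, which is reported as an error rather than silently
   measuring a truncated contour.

2. **Distances.** `L12 = |m1 − m2|`. The skin point `m3` is the first
   crossing of the ray from `m1` through `m2`, *beyond* `m2`, with the
   contour polygon (exact segment–segment intersection; the crossing
   with the smallest ray parameter `t > 1` wins). `L13 = |m1 − m3|`.
   If no such crossing exists the markers are inconsistent with the
   contour and the vertebra is flagged, not guessed. When `m2` is
   missing, L12 and L13 are `NA` unless a substitute posterior
   direction is supplied, which restores L13 only.

3. **Quadrant areas.** The contour polygon is clipped by the
   axis-aligned cross-hair through `m1` (Sutherland–Hodgman half-plane
   clipping) into `a1` anterior-right, `a2` anterior-left, `a3`
   posterior-left, `a4` posterior-right. Areas are signed shoelace
   sums; clipping slivers below 1e-9 mm² are zeroed. The *aspects*
   `f_back = (a3 + a4)/total` and `f_left = (a2 + a3)/total` are
   dimensionless and describe the vertebral position relative to the
   trunk mass, independent of girth.

   The quadrant labelling (a1 starting anterior-right, proceeding
   counter-clockwise in the `(+x left, +y posterior)` frame) is a
   convention; only the two aspect sums are consumed downstream, and
   both are pinned by oracle tests (a mirrored contour must map
   `f_left → 1 − f_left` and leave `f_back` unchanged).

4. **Equal-area ellipse mapping.** To place vertebrae from differently
   shaped trunks in one normalized frame, the aspects are mapped into
   the unit ellipse via the chord-area fraction
   `F(t) = 1/2 − (t·sqrt(1 − t²) + asin t)/π`, the fraction of an
   ellipse's area on one side of a chord at normalized offset `t`.
   `F` is affine-invariant, so it holds for any ellipse, not just the
   circle it is derived on. The normalized position is
   `v = F⁻¹(f_back)`, `u = F⁻¹(f_left)`. The sign convention (posterior
   displacement → positive `v`, patient-left → positive `u`) is fixed
   by a round-trip requirement: for an exactly elliptical trunk with
   semi-axes `(a, b)` and the vertebra at `(x, y)`, the mapping must
   return `(u, v) = (x/a, y/b)`; this is enforced by tests on digitized
   ellipses (50 random interior points, 1 % tolerance) and exactly at
   the centre (`(0.5, 0.5) → (0, 0)` to 1e-9).

## Cohort statistics

Curves are classified by maximal Cobb angle — mild < 20°, strong
> 40°, medium otherwise (both boundary values 20° and 40° fall in
*medium*) — and by region from the apex level: T2–T11 thoracic, T12 or
L1 thoraco-lumbar, L2–L5 lumbar; a patient with both a thoracic and a
lumbar apex is *combined*, otherwise the main (largest-angle) curve
decides, ties broken toward the cranial apex.

`aggregateLevels` builds per-level n/mean/SD tables of L12 and L13 per
group (none, severity, region, gender); `regionalMeans` adds pooled
rows for "all", "T2…T11", "T12/L1" and "L2…L5". Conventions:

* SDs are *sample* SDs (`n − 1` denominator) and are reported only for
  cell counts ≥ 2.
* Regional rows pool the underlying raw values, not the per-level
  SDs: they are recombined exactly from the per-level cells via
  `SS = Σ[(nᵢ−1)sᵢ² + nᵢ(mᵢ−M)²]`, which equals brute-force pooling
  of raw values (verified to 1e-12 on random cohorts).
* The "all" row spans every level the table carries, including C7 and
  T1 when present.
* Missing L12 values (no identifiable spinous tip) reduce `nL12` only;
  L13 cells are unaffected.

## The phantom and what it does (not) emulate

`phantomSpec` describes an analytic trunk: an ellipse with semi-axes
`semiAxisLR = 150`, `semiAxisAP = 100` mm, optionally deformed by a
Gaussian rib hump in polar angle (`humpAmplitude` mm, default 0;
`humpCenter = π/2 + 0.6` rad, i.e. posterior-left; `humpWidth = 0.5`
rad), containing a circular vertebral body (`vertebraCenter = (0, 20)`
mm, `vertebraRadius = 15` mm) with a posterior spinous process
(`processLength = 55` mm, `processAngle = 0`). Rasterization
(`makePhantom`) uses `pixelSpacing = (1.5, 1.5)` mm on a 256×256 grid,
HU values −1000 (air), +40 (soft tissue), +1000 (bone), plus Gaussian
noise (`noiseSD = 15` HU) truncated at ±4 SD so a single outlier pixel
cannot cross the contour threshold. The same seed yields a
bit-identical volume and truth.

The analytic truth carries the densely sampled contour polygon, the
markers `m1`, `m2`, `m3`, the distances (L12 equals `processLength` by
construction; L13 from exact ray–contour root finding) and the
quadrant fractions.

The phantom emulates exactly what the measurement chain consumes: a
closed trunk outline of realistic scale and asymmetry, a bright
vertebra with a posterior process, CT-like HU levels and noise, and
anisotropic-capable pixel spacing. It does *not* emulate lungs, ribs,
arms, couch or clothing artifacts, beam hardening, partial-volume
blur, or non-convex trunk shapes beyond the single rib hump; the
contour-extraction guarantees are therefore only validated for
star-shaped outlines. Severity/region classification operates on given
Cobb angles; the phantom does not produce a 3-D curved spine.

## Numerical choices

* **Quadrant-fraction truth oracle**: polar composite-Simpson
  integration of `ρ(θ)²/2` about the vertebral centre, one quarter-turn
  per quadrant with `n = 1024` intervals, where `ρ(θ)` comes from a
  60-step vectorized bisection on the analytic radius function
  (star-shapedness makes the root unique). Agreement with the ellipse
  closed form is ≈ 1e-13, far inside the 1e-6 the tests demand. An
  entirely independent 0.1 mm pixel-counting oracle cross-checks the
  polygon-clipping path to 0.5 %.
* **Chord-fraction inversion**: `F` is strictly decreasing on [−1, 1];
  `invertAreaFraction` bisects 200 steps to tolerance 1e-10 (verified
  round trip ≤ 1e-9 over `f ∈ {0.01, …, 0.99}` against
  `integrate()` quadrature at 1e-13).
* **Contour polygon density**: truth contours are sampled at 3600
  vertices (0.1° steps), making polygonal-chord area error ≪ the 1e-6
  invariant; test suites use 360–20000-gon digitizations depending on
  the tolerance being exercised.
* **Tie-breaking and edge cases**: boundary Cobb angles 20°/40° →
  medium; equal-angle curves → cranial apex wins; points exactly on a
  cross-hair line belong to the `≥` side consistently in both the
  clipper and the pixel-counting oracle; slice selection for volumes
  uses round-half-down of the middle index.
* **Determinism**: all CSV floats are formatted with `%.6g`; outputs
  carry provenance headers (package version, md5 of the serialized
  configuration excluding the output directory, md5 of each input
  file), and the pipeline is byte-identical across runs on identical
  inputs.

## Known limitations

* Contour extraction assumes the trunk is fully inside the field of
  view and forms the largest closed iso-line; metal artifacts or air
  pockets connected to the outline would need preprocessing.
* The ellipse mapping is exact only for elliptical trunks; for real
  outlines it is a normalization, not an inverse — its output should
  be compared across patients, not back-projected to mm.
* L13 depends on the annotated ray direction; a mis-placed spinous tip
  moves `m3` along the skin. The substitute-direction fallback
  mitigates missing, not misplaced, tips.
* NIfTI storage squeezes single-slice volumes to 2-D, so their slice
  step is not round-tripped (in-plane spacing is; the step is restored
  as 1 mm and is irrelevant for single-slice measurement).
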