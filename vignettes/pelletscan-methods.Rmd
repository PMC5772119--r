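---
title: "Whole-slide pellet morphometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-slide pellet morphometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelletscan)
```

pelletscan quantifies mycelial particles — dense pellets and loose
fragments of filamentous microorganisms — in phase-contrast whole-slide
images. This vignette documents the models behind each stage, the
parameters that matter, the numerical choices, and what the synthetic
test bed does and does not establish about real slides.

## The imaging model

In phase contrast a pellet images as three concentric zones: dark
protruding hyphae and a low-density fringe at the rim, a bright ring where
the dense region starts, and a darker interior. The slide background is a
mid-grey plateau (we use 70 on an 8-bit scale); hyphae fall below it and
the dense-edge ring above it. The synthetic generator
(`synth_spec()`, `generate_image()`) renders exactly this structure:

* a pellet body disk of radius *R* with the bright ring centred at depth
  fraction *f* of *R* from the edge (half-width 0.08 *R*, floor 1.5 px, so
  the ring is a substantial band rather than a hairline);
* hyphae as jagged radial polylines — random walks of 2 px steps with
  Gaussian angular jitter (SD 0.12 rad) at fixed thickness — which
  reproduce the perimeter-dominating protrusions that break
  perimeter-based circularity measures;
* artifacts: air bubbles (a dark rim plus bright halo annulus, diameter
  constrained > 900 µm), fibers (thick, slightly bent polylines with
  elongation ≥ 10) and sub-200 px debris specks;
* additive Gaussian sensor noise (SD 2 grey levels by default), clipped to
  the bit depth and rounded to integer grey values.

The generator is deliberately *not* an optics simulation: there is no
point-spread function and no phase-contrast transfer function. Ground
truth is the set of painted pixels per object, stored at master-image
coordinates. A fixed seed renders bit-identical output.

`standard_slide_spec()` fixes the reference study conditions used by the
test suite: a 2048 × 2048 px canvas at 0.78 µm/px (the calibration of a
×10 objective on the reference instrument), 10 pellets with body radius
75–115 µm, ring depth fraction 0.15–0.25, core grey 55–68, ring 110–140,
fringe 35–45, 8–16 hyphae of 15–35 µm; one bubble of 920–1000 µm, one
fiber of 300–420 × 4 px, three debris specks of 60–150 px. Radii and
intensities are drawn once per slide from these ranges; placement is
rejection sampling with clearance so objects never touch. Pellet body
diameters of 150–230 µm are typical of young streptomycete cultures;
the canvas holds a workable population while keeping a full slide's
segmentation under ~10 s, which is the problem size the pipeline tests
and the acceptance script use (20 slides, 200 ground-truth pellets).

What passing tests on this bed shows: the chain of operations implements
its stated contracts, exactly gated at the printed parameter values, with
sub-pixel-scale agreement against independent geometric oracles. What it
does not show: robustness to real-slide phenomena the generator omits —
focus drift, uneven illumination within one tile, overlapping or
out-of-focus particles, halo artifacts of strongly refractile objects.

## Mosaic assembly

Tiles are placed at their nominal stage offsets (step =
`round(tile_width × (1 − overlap))`), in meander order; no
cross-correlation registration is attempted because the grid geometry
comes from a motorized stage, and in overlap zones the later-placed tile
wins — a deterministic rule that leaves seams visible for debugging
rather than blending them away. The 20 × 20 grid with 10 % overlap and
0.78 µm/px is the default protocol; all of it is overridable.

Brightness is normalized multiplicatively: illumination fluctuation is a
gain effect, so each tile is scaled by `reference / background(tile)`,
where the background estimate is the histogram mode over integer grey
values (ties to the lowest mode — deterministic, and biased toward the
darker plateau rather than bright debris). The default reference is the
median of all tile backgrounds. Normalizing twice with the same reference
is a no-op up to integer rounding.

Calibration travels with every TIFF in a small JSON sidecar
(`<file>.tif.json`), since the TIFF writer used does not expose
resolution tags.

## Segmentation

The chain is: dual-sided threshold → hole filling → bubble guard →
blurred-mask watershed with an interface veto → Voronoi border
subtraction → 8-connectivity components → size filter.

* **Threshold.** Background is the closed band [50, 90]; foreground is
  strictly below or strictly above. Both bounds belong to the background —
  the inclusive reading of "between" — and are configurable for users who
  want the complementary convention.
* **Hole filling** converts detected edges into solid objects: every
  background region not 4-connected to the image border becomes
  foreground. Foreground uses 8-connectivity and holes 4-connectivity,
  the standard complementary pair that avoids topological paradoxes.
* **Bubble guard.** Connected components already above the 6 × 10⁵ µm²
  cap before any splitting (filled air bubbles) are removed up front, so
  a bubble can neither be fragmented into below-cap pieces nor distort
  its neighbours' separation. The cap is applied again after splitting.
* **Watershed.** The binary mask is Gaussian-blurred (σ = 5 px by
  default — about 4 µm at the default calibration, enough to merge
  hyphal texture without bridging distinct pellets) and watershedded on
  the blurred landscape, with basins grown from its regional maxima. Two
  basins whose saddle is shallower than the tolerance (0.1 on the 0–1
  blurred mask) share one maximum plateau and stay merged; the
  implementation finds the plateaus `blur > 1 − tolerance` directly and
  grows them with a seeded watershed (`EBImage::propagate`), run per
  connected component on its cropped window. A proposed cut is applied
  only if the interface between the two particles — operationalized as
  the larger side's count of 4-adjacent boundary pixels times the pixel
  size, since the source protocol does not define how the interface is
  measured — is shorter than 150 µm; longer interfaces mean one
  irregularly shaped pellet and the regions are re-merged. Each proposed
  cut is evaluated independently.
* **Voronoi borders.** The influence-zone partition assigns every pixel
  to its nearest label (exact Euclidean distance, ties to the lower
  label); the 1-px inter-zone border is subtracted from the mask so
  touching objects become disjoint components. Inside the mask the
  Voronoi border reduces to the inter-label adjacency of the watershed
  map (a mask pixel's nearest label is its own), which is what `segment()`
  computes; the full-image partition (`voronoi_zones()`) is validated
  against a brute-force nearest-seed scan.
* **Size filter.** Objects under 200 px or over 6 × 10⁵ µm² are removed,
  both bounds strict ("smaller than" / "larger than"); survivors are
  relabelled by descending area, a stable human-friendly ordering. Both
  the pre-filter and post-filter label maps can be written, so false
  negatives can be rescued manually.

## Per-particle descriptors

* **Perimeter** is a traced boundary chain with corner-corrected Freeman
  weights (0.980 axial, 1.406 diagonal, −0.091 per corner). The naive
  √2-weighted chain runs ~5 % long on smooth shapes, which alone would
  push a disk's circularity to 0.91; with the correction a rasterized
  disk scores 1.00 within discretization error. Circularity is capped
  at 1.
* **Fitted ellipse**: the same-second-moments ellipse (population
  moments plus the 1/12 per-pixel variance term, so 1-px-wide shapes stay
  non-degenerate), rescaled to the mask area. Roughness divides the
  traced perimeter by this ellipse's Ramanujan-II perimeter.
* **Maximum Feret diameter**: the mask's convex-hull vertices are rotated
  in 2° increments over 0–178° and the vertical pixel extent
  (max − min + 1, so a single pixel has extent 1) recorded; the maximum
  is the particle's length. The hull restriction is exact — extents are
  attained on the hull — and the 2° grid is within 0.02 % of the
  continuum for convex shapes; tests hold it within 0.5 % of a
  maximum-pairwise-distance oracle.
* **Morphology number** Mn = 2√(A/π)·S / (Feret·E) with solidity S and
  elongation E: a dimensionless composite that is 1 for a disk and falls
  toward 0 for elongated or ragged particles. This disk-normalized form
  is our concrete reading of the composite; solidity uses the convex hull
  over pixel corners so a rectangle scores exactly 1.
* **Fractal dimensions** by box counting over dyadic box sizes
  2 … side/4 on the bounding-box square: least-squares slope of log N
  versus log(1/s). D_BM uses the filled mask, D_BS its 1-px 4-boundary,
  FQ = D_BM/D_BS (the quotient's orientation is our choice). Bounding
  boxes under 16 px leave fewer than two usable box sizes, so the metrics
  are flagged undefined rather than raised as errors.
* **Polar circularity** C = min(1, 2 r_eq/(3 r̄)) with r̄ the mean
  distance of all mask pixels from the unweighted centroid and
  r_eq = √(A/π): a disk scores exactly 1 (its mean radius is 2R/3).
  Because every pixel contributes, protruding hyphae barely move it,
  unlike 4πA/P² — the property that motivates using it for mycelial
  particles, and which the test suite asserts on a hypha-length series.
* **Radial bands**: the Euclidean distance-to-edge transform inside the
  mask, normalized by its maximum, splits the particle into 20 donut
  bands that follow the outline (band 1 outermost); distance-transform
  depth was chosen over polygon shrinking because it is well defined for
  any mask topology. The **halo width** is the mean depth of the
  maximum-intensity band — ties resolve to the outermost band, a
  conservative halo — and the **density ratio** divides the
  count-weighted mean intensity of bands 1…peak by that of the interior
  bands, separating dense-core pellets (> 1) from open "mat" formers. If
  the peak sits in the innermost band the ratio is taken against that
  band alone and flagged degenerate.

Per-particle failures (tiny masks, degenerate profiles) are recorded in a
`flags` column; `measure_all()` never aborts a slide for one particle.

## Filtering and reporting

Filters are ordered rule sets — metric, inclusive min, inclusive max,
AND-combined — serialized losslessly to YAML. The shipped streptomycete
default implements the two exclusions such slides need: non-circular
contaminants (elongation ≤ 6, polar circularity ≥ 0.2) and abnormal
density (intensity SD ≥ 3 grey levels, density ratio in [0.2, 5]); its
values are package defaults validated on the synthetic bed, and every
bound is user-replaceable.

Populations split into fragments (< 150 µm maximal Feret length,
strictly) and pellets. Confidence ellipses eigendecompose the 2 × 2
sample covariance; semi-axis i is √(q λᵢ) with q the χ² quantile at the
requested level with 2 degrees of freedom (5.991 at 95 %). Two-sample
comparisons use Welch's unequal-variance *t*-test — the safe default
where equal variances cannot be assumed — two-sided.

## Known limitations

* Nominal-offset stitching cannot absorb stage positioning error; tiles
  from poorly calibrated stages will show seam discontinuities.
* The blur-based watershed only proposes cuts across necks thinner than
  roughly 2 × 1.28 σ px, so at σ = 5 the 150 µm interface veto is a
  safety net rather than the primary separator; larger σ shifts work
  toward the veto.
* Box-counting slopes on masks a few hundred px across carry ±0.1
  discretization bias; comparisons are meaningful within one pipeline,
  not against literature values measured at other scales.
* The density ratio is undefined for particles whose intensity peak sits
  at the innermost band (flagged), and halo width saturates for particles
  thinner than one band.
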