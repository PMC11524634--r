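---
title: "cfzkit methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cfzkit methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cfzkit)
```

`cfzkit` covers three layers of an automated cell-free zone (CFZ, "wound")
migration/proliferation assay: designing and rasterizing wounds, simulating
the wounded monolayer, and analyzing nuclear-stain time-lapse images into
wound metrics and single-cell tracks. This vignette explains the models
behind each layer, the parameters that matter, and the choices made where
the design was genuinely open. It states no empirical result that the test
suite does not itself compute.

## Coordinate conventions

One convention is used everywhere and every raster-bearing object carries its
physical scale:

* Rasters are image-oriented: row 1 is the top, y points down. Pixel (i, j)
  (1-based) has its centre at `origin + (j-1, i-1) * scale`.
* Well-centric design coordinates: mm, x right, y down, origin at the well
  centre.
* Analysis/field coordinates: µm, pixel (1,1) centred at (0,0); a centroid in
  µm is its 0-based pixel coordinate times the pixel scale.

## Wound design

### Plate calibration

`calibrateWells()` reconstructs all well centres of an `rows × cols` plate
from the measured stage-frame coordinates of the four corner wells by
bilinear interpolation in normalized grid coordinates
`u = (col-1)/(cols-1)`, `v = (row-1)/(rows-1)`; z is interpolated the same
way, so plate tilt is handled. Whether the original instrument software uses
bilinear interpolation or assumes a rigid uniform grid is not documented
anywhere we could verify; bilinear is the strictly more general choice — it
is exact (to machine precision, tested to 1e-9 mm) whenever the true centres
are any affine image of the integer grid, which includes every rigid uniform
grid. One-row or one-column plates degenerate to linear interpolation.

### Toolpaths

A dispensing tip of *effective* width `w` sweeps a stadium of radius `w/2`
along each pen-down stroke. The effective width is deliberately not the tip's
outer diameter: tips deform during scratching, and the package defaults to
`w = 0.66 × OD` of a 0.48 mm precision tip (≈ 0.318 mm), the user overriding
it per tip after calibration. Tip speed and acceleration are carried as
metadata only — their observed effect on scratch width is minor and there is
no kinematic model here.

For filled shapes the open question is how to cover a 2-D region with a round
tip. The package uses **boundary + serpentine infill**:

1. the shape outline is inset by `w/2` (exact half-plane intersection for
   convex outlines — circle, square, triangle, convex polygon; non-convex
   polygons are rejected at validation, since exact insetting of arbitrary
   polygons needs a computational-geometry stack that would dwarf this
   module), and the inset outline is one pen-down stroke;
2. horizontal infill passes cross the inset region. The nominal pass spacing
   `d = w × (1 − overlap)` (overlap 0.25 by default) fixes the pass count
   `n = ⌈span/d⌉ + 1` over the *full* shape span; the n passes are then
   placed evenly across the *inset* span. The distinction matters: passes at
   exactly spacing d anchored on the full span would overshoot the outline by
   `w/2` at both ends. With the placement used, the actual spacing is ≤ d, so
   the swept region both stays inside the shape (up to rasterization) and
   covers it — the rasterized sweep reproduces the shape with Jaccard ≥ 0.98
   for shapes at least 4 tip-widths across (tested).

Shapes no larger than the tip collapse to a single dwell point. Designed
z-depth is ignored: wounds are planar.

### Rasterization

`rasterizeWound()` tests pixel centres: analytically for discs and line
stadiums, by even-odd scanline fill for polygons, and by
distance-to-segment ≤ `w/2` for toolpath sweeps. Pixel-centre counting makes
the area error `O(perimeter × pixel scale)` with a fluctuating sign
(Gauss-circle behaviour), so the error bound tests assert per-shape
tolerances at two scales (1 % at 10 µm/px, 0.25 % at 2.5 µm/px) and
monotone improvement of the summed error, not per-shape halving.

## The synthetic assay

The simulator stands in for the robot and microscope so that every analysis
stage can be scored against exact ground truth. It emulates nuclear-stain
(Hoechst-like) time-lapse imaging at 5×-magnification pixel scales of a
fibroblast-like monolayer; it does **not** attempt mechanobiology (no
traction, purse-string or curvature–actin coupling), cell death, realistic
oblique-contrast physics, or 3-D culture. A green end-to-end test therefore
establishes that the pipeline recovers the geometry and kinematics of a
*plausible* wounded monolayer, not that it handles every artifact of real
microscopy (debris, drift, uneven illumination, out-of-focus frames).

* **Seeding** — dart throwing with a minimum inter-nucleus distance
  (15 µm default; rejection bounded, so densities beyond the
  random-sequential-adsorption regime fail loudly; densities beyond disc
  close-packing are rejected at validation). The default density,
  0.40 × 10⁵ cells/cm², sits mid-range of the emulated experiments
  (0.22–0.63 × 10⁵).
* **Motion** — per-cell AR(1) velocity `v ← ρ v + η`, persistence ρ = 0.7,
  with the noise scaled so the stationary speed distribution (Rayleigh) has
  mean `speedMean`. Cells within `biasRadius` (200 µm) of the current wound
  receive an additional bias of magnitude `biasStrength × speedMean` pointing
  at their *nearest wound pixel* — the nearest-pixel target (rather than the
  wound centroid) is what lets elongated wounds close from their whole edge,
  not only near the centroid. Overlapping cells are pushed apart to the
  minimum distance; border cells reflect.
* **Division** — each cell divides with probability `divisionProb` per frame;
  the mother keeps her identity and a daughter appears at the minimum
  distance with a parent link. (The alternative bookkeeping — retiring the
  mother and creating two new identities — describes the same biology; the
  mother-persists form matches how a tracker actually experiences a division:
  one track continues, one track is born.)
* **Rendering** — nuclei are anisotropic Gaussian spots (sd = nucleus radius,
  default 8 ± 1 µm; mild aspect 1.15 ± 0.08), peak amplitude = per-cell stain
  level over a constant background, with Poisson noise on expected counts.
  Gaussian spots (not star-convex outlines) are sufficient because the
  detector contract only requires approximately round bright blobs.
* **Ground truth** — per-frame cell table, lineage edges, and a per-frame
  true wound mask obtained by density-thresholding the *true* positions with
  the same density-contour routine the analysis uses on detections (see
  below). For line wounds the true width statistics are measured on that mask
  with the package's own estimator. End-to-end checks therefore compare
  detected against true points through identical geometry, which is exactly
  what they should isolate: detection and linking fidelity, not the shared
  contour definition.

**Calibration of the stated world.** Fibroblast motility parameters for this
assay are not published; speed 20 µm/h and division 0.002/frame (at 30 min
frames) are placeholders. The one free parameter, `biasStrength`, was set
once to 0.03 so that the default ~0.32 mm line wound closes in ≈ 30 h —
matching the benchmark that a line wound of that scale closes in about a day
and a half of frames — and was not revisited. No claim of biological fidelity
is made; tests that need faster closure set the bias explicitly.

## Preprocessing

Steps run in the fixed order flatten → spatial rescale → intensity rescale →
median filter → adaptive equalization, each individually disableable, the
composite deterministic. Choices the source material leaves open:

* Grayscale flattening uses ITU-R 709 luminance weights.
* Intensity rescaling is per channel over the **whole series** by default so
  temporal intensity trends survive; per-frame mode is available.
* The median footprint is a disc (radius 1 px default).
* CLAHE uses 256 bins, 64 px tiles and clip limit 0.01 (a conservative clip
  that bounds noise amplification in empty wound regions; stray detections it
  still produces are exactly what the isolation filter exists to remove).
  Equalization runs after intensity rescaling, per the pipeline's step order.

## Segmentation

The reference experiments used a pretrained star-convex deep detector;
shipping trained weights is out of scope here, so detection is a defined
classical operator with the same output contract (label mask + one property
row per nucleus), behind which any external detector can be substituted:

1. normalize the frame to [0, 1];
2. scale-normalized Laplacian-of-Gaussian responses at four log-spaced scales
   spanning the expected radius range (4–12 µm default; for a Gaussian spot
   of sd σ_b the response peaks at σ = σ_b with height ≈ amplitude/2, hence
   the default threshold 0.05 ≈ detecting blobs at ≥ 10 % of full scale);
3. local maxima (non-maximum suppression at the minimum radius) seed a
   marker-controlled watershed on the smoothed image, restricted to a robust
   foreground (median + max(3 × MAD, 2 % of dynamic range) — the absolute
   floor keeps noise-free synthetic frames from flooding);
4. objects outside [30, 4000] µm² are dropped; properties (centroid, area,
   axis lengths from normalized second moments, eccentricity, per-channel
   mean intensity) follow the regionprops conventions.

The **isolation filter** removes stray detections from the wound bed: a
nucleus is dropped when the mean (default; max available) distance to its
k = 3 nearest neighbours exceeds a threshold, by default the scale-free
4 × median nearest-neighbour spacing of the frame. The filter is monotone in
the threshold and verified against brute-force all-pairs computation.

## Wound metrics

* **Wound mask** — nucleus centroids are binned on a grid (20 µm default)
  and smoothed with a Gaussian kernel (bandwidth 2 × grid step); pixels below
  `threshold × median density` (threshold 0.3) are wound candidates; the
  largest candidate component overlapping the designed wound locus (or the
  largest overall) is kept, components smaller than ~20 missing cells and
  nucleus-sized holes are cleaned up, and the boundary is regularized by
  smoothing the binary component (Gaussian sd = bandwidth, re-threshold at
  0.5). The regularization is the one step beyond the bare density rule: at
  monolayer density 0.40 × 10⁵ cells/cm² a 40 µm kernel averages ≈ 1.6 cells,
  so raw contours wiggle by tens of µm; smoothing the mask suppresses that
  sampling noise without biasing the edge position. Resolving the *absolute*
  geometry of a feature to better than ~10 % requires a bandwidth well below
  the feature width (the 0.3-level contour sits ≈ 0.5 bandwidth inside a
  sharp edge); the defaults favour robustness, and the tests that score
  absolute IoU against a 300 µm band use grid 10 µm / bandwidth 25 µm /
  threshold 0.4 / smoothing 60 µm.
* **Edges** — marching squares at the 0.5 level (`grDevices::contourLines`);
  contours are classified closed when their endpoint gap is small relative to
  their length (binary rasters make marching squares close loops with coarse
  final steps), minor contours (< 15 % of the dominant length — holes,
  speckles) are ignored; in scratch mode the two longest flank contours are
  fit by total-least-squares lines, a single closed band contour being split
  at its principal-axis extremes first. Shape mode returns the boundary
  polygon for area work.
* **Width** — the scratch axis is the bisector of the two fitted lines; local
  widths are measured between the *raw contours* perpendicular to that axis
  at uniform arc positions over the contours' common projection. The fitted
  lines only define the axis: using raw contours preserves edge roughness in
  σ, which is the assay's reproducibility metric. Width is perpendicular
  distance (not horizontal), and σ² is the sample variance of w(s).
* **Closure** — area(t) is mask pixel count × pixel area; percent closure is
  100·(1 − area(t)/area(0)); the closure time is the first frame with
  area ≤ ε × area(0), ε = 0.005, because discretization leaves stray pixels
  long after biological closure; times are reported at frame resolution, and
  "not closed" is reported as beyond the observation horizon. The ε
  definition is recorded in the curve object itself.

## Tracking

A transparent simplification of Bayesian multi-hypothesis tracking, with the
same inputs and outputs: per-track linear-Gaussian (Kalman) prediction —
constant-velocity by default, Brownian available — and one global
minimum-cost assignment per frame transition. Costs are observation negative
log-likelihoods (Mahalanobis distance under the predicted observation
covariance plus the normalization term); candidates beyond the Euclidean gate
(30 µm default) are forbidden — the gate is Euclidean, not Mahalanobis, for
interpretability. Dummy rows/columns price track death and birth so the
assignment chooses among link/death/birth globally; tracks unobserved longer
than `maxGap` terminate. Observations are processed in label order and the
assignment is a global optimum, so within-frame row order cannot affect the
result. Division linking records a track birth as the child of the nearest
track that existed before the birth frame and lies within `divisionMaxDist`
(measured at the birth frame when the candidate is present there — the
mother has already moved by then). Multi-hypothesis optimization over longer
windows and appearance features are out of scope.

## Pipeline

`runPipeline()` validates the whole config before touching any input, then
processes each stack independently (failures are isolated per input),
writing per-input outputs, a one-row-per-input summary CSV, a plain-text log
with ISO-8601 timestamps, and a run record containing the md5 hash of the
canonical config JSON. All analysis stages are deterministic; the single
global seed is stretched into per-input seeds by stable hashing so that
identical configs reproduce identical outputs byte for byte (tested). The
worker-pool option uses forked processes; orchestration is in-process rather
than an external workflow engine so the toolkit stays self-contained.

## Numerical notes and limitations

* TIFF I/O is a minimal baseline implementation (little-endian, uncompressed,
  8/16-bit grayscale, multi-page, JSON metadata in the ImageDescription tag).
  It round-trips the package's own files exactly but does not read compressed
  or tiled vendor TIFFs.
* The width estimator assumes a scratch-like geometry: two dominant flank
  contours with overlapping projections. Strongly curved or fragmented wounds
  should use shape mode (area only).
* Segmentation assumes bright, approximately round nuclei on a darker
  background; heavy overlap (spacing below ~3 nucleus sd) merges blobs and
  undercounts — the density-based wound metrics are insensitive to moderate
  undercounting because they threshold *relative* to the same frame's median
  density.
* Half-pixel quantization: a rasterized edge can only be localized to half a
  pixel, so two-edge widths carry up to one pixel of fixture-induced error;
  exactness tests place true edges on the half-pixel lattice.
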