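---
title: "Quantifying membrane localization and vesicle trafficking with VesiQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane localization and vesicle trafficking with VesiQuant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(VesiQuant)
```

# The measurement problem

Membrane transporters such as the dehydroascorbic-acid transporter GLUT10
move between compartments: they are inserted at the plasma membrane,
endocytosed into RAB5-positive early endosomes, and can be routed onward to
other organelles. Establishing such a route microscopically requires four
kinds of quantification, and VesiQuant implements each as a reusable,
tested pipeline stage:

1. **Membrane versus cytosol fluorescence** from confocal z-stacks — how
   much of a GFP-tagged transporter sits at the cell edge
   (`quantifyMembrane()`).
2. **Vesicle–endosome colocalization over time** in two-channel TIRF
   movies of the plasma-membrane zone (`analyzeTirfSeries()`).
3. **Percent-volume colocalization** of two confocal channels
   (`percentVolumeOverlap()`).
4. **Vesicle motion classification** from tracked positions
   (`linkDetections()`, `classifyTracks()`) and **line-scan profiles**
   (`lineProfile()`).

Because raw microscopy movies backing such figures are rarely deposited,
the package ships synthetic generators (`simulateTirfSeries()`,
`simulateConfocalCell()`, `simulateTracks()`) that produce every input the
stages need together with exact ground truth, so each stage can be
validated by recovery rather than by eye.

# Raster conventions

All stages share one set of conventions, stated here once:

* Pixel coordinates are 0-based `(y, x)`, y increasing downward; physical
  positions are `index * pixelSize` in micrometres. Frames and z-slices
  reported in outputs are 0-based.
* Connected components are 8-connected. The one deliberate exception is
  the background flood in `fillHoles()`, which is 4-connected — the
  topological dual of an 8-connected foreground — so that a one-pixel
  closed ring fills to a solid disk instead of leaking through its
  diagonal steps.
* Automatic thresholds (`autoThreshold()`) are computed on a histogram of
  256 equal-width bins spanning `[min, max]` of the image, regardless of
  bit depth, which makes them invariant to uniform intensity rescaling.
  The returned value is the lower edge of the first *foreground* bin and
  binarization is strict (`intensity > value`); for a perfectly bimodal
  image the threshold therefore falls strictly between the two modes. All
  objective ties break toward the lower gray level.
* Gaussian blurs truncate the kernel at 4 sigma and reflect the image at
  its borders; the median filter uses a discrete disk footprint (all
  offsets with Euclidean norm at most the radius) with the same reflect
  rule; erosion treats pixels outside the image as background.

# The membrane quantification model

`quantifyMembrane()` reproduces a whole-cell/cytosol/membrane mask
construction: sum-project the z-stack (preserving total signal), binarize
the projection with a Huang threshold, fill holes, size-filter, erode the
surviving cell mask for `erodeCycles` cycles to get the cytosol mask, and
subtract to get a peripheral membrane band roughly `erodeCycles` pixels
wide. Intensities are measured on the unmodified projection. Since the
band width is fixed in pixels, it is resolution-dependent: at 0.1 um/px
the default 10 cycles probe a 1 um rim.

The headline statistic is `meanMembrane / meanWhole` (relative membrane
intensity). The normalizer is a genuine design choice — cytosol
normalization is equally defensible — so `meanMembrane / meanCytosol` is
reported alongside.

Two defaults deserve explanation because measurement on synthetic ring
cells showed the obvious choices to be biased:

* **Pre-threshold blur sigma defaults to 0.** The Huang objective places
  its threshold just above the background cluster, so the mask boundary
  lands where the *blurred* edge decays to near-background — roughly 2–4
  sigma outside the true cell edge. Those extra pixels carry background
  intensity on the measurement image and sit exactly in the fixed-width
  membrane band, depressing the membrane mean by 10–25% at sigma 2. A sum
  projection is already shot-noise averaged, and stray supra-threshold
  noise pixels are eliminated by the size filter, so no blur is the better
  default; raise it for noisy single planes.
* **The erosion element defaults to the 4-connected cross.** Iterating a
  3x3 square element measures erosion depth in the Chebyshev metric: after
  10 cycles the band is 10 px deep across axis-aligned edges but
  `10 * sqrt(2) = 14` px across diagonal ones, deep enough to cross a
  narrow membrane ring and blend cytosol into the band. The cross element
  (Manhattan metric) stays within 10 px Euclidean everywhere. Both
  elements are available; the macro language this procedure originated in
  does not document its element, so the choice is ours and is recorded
  here.

Per-cell invariants are enforced by the `MembraneQuantResult` validity
method: the cytosol mask is contained in the whole-cell mask, the membrane
mask is exactly their difference, and areas add up exactly.

# The TIRF colocalization model

For each frame of a two-channel movie, `analyzeTirfSeries()`:

1. builds a **cell mask** — externally supplied per-frame masks (e.g. from
   a trained segmenter) are first-class inputs; the built-in fallback
   median-filters the reference channel (disk radius 4), applies a
   triangle threshold, fills holes and keeps the largest component. The
   fallback assumes one bright cell on a dark background and is not a
   substitute for a real segmenter on crowded fields;
2. enhances the **query channel** with a difference-of-Gaussians filter
   (defaults 1 and 4 px), multiplies by the cell mask, and segments spots
   with **Voronoi-Otsu labeling**: local maxima of a sigma-1 blur seed a
   nearest-seed expansion (8-connected, ordered by exact squared Euclidean
   distance, ties to the lower label) over the Otsu foreground of a
   sigma-1.5 blur. Plateau maxima collapse to one seed at the plateau's
   row-major-first pixel, making segmentation fully deterministic;
3. binarizes the DoG-filtered **reference channel** with a triangle
   threshold inside the cell mask — this *vesicle* mask, not the cell
   mask, is the reference for scoring;
4. scores every query label `P` as `|P ∩ ref| / |P|` — the fraction of the
   vesicle covered by the reference mask, 1 meaning full overlap — and
   classifies: score ≥ 0.5 colocalized, score < 0.01 non-colocalized,
   otherwise partial. The published rule leaves scores in (0, 0.01) and
   exactly 0.5 unassigned; the package closes the classes as above so the
   three of them partition [0, 1];
5. reports per frame the counts, the colocalization ratio
   (colocalized / total query vesicles), and the mean raw intensity of
   both channels inside the cell mask.

With `reciprocal = TRUE` the analysis also runs the other way
(reference-channel vesicles against the query-channel mask), yielding
query-positive and query-negative endosome counts. The figure-style
"positive : negative" ratio is reported as colocalized : zero-overlap,
with partially overlapping vesicles counted but excluded from the ratio —
the source procedure does not define the quantity precisely, so all three
counts are emitted and the ratio's definition is documented rather than
presumed.

Because thresholds are histogram-shape based and the DoG is linear,
overlap scores are invariant to uniform rescaling of the query channel;
this is asserted by a property test.

# Percent-volume colocalization

`percentVolumeOverlap()` implements the intensity-threshold statistic:
with supra-threshold voxel sets `A` and `B`,
`percentAinB = 100 * |A ∩ B| / |A|`. It is asymmetric by construction and
both directions are always reported. Supra-threshold is strict
(`> threshold`). Thresholds are user-supplied — the original analyses
adjusted them manually per image, which is why published percentages are
not reproducible from definitions alone — or an automatic method
(`"auto:otsu"` etc.). An empty `A` yields `NA` (undefined), never 0. An
optional mask restricts the statistic to one cell. Pearson- or
Manders-style intensity-weighted coefficients are deliberately out of
scope.

# Tracking and the displacement taxonomy

`linkDetections()` uses greedy globally-nearest-first bipartite linking:
all (active track, detection) pairs within `maxLinkDistanceUm` are sorted
by (distance, track id, detection index) and accepted greedily; gaps up to
`maxFrameGap` frames are bridged, and speeds across a bridged gap use the
true elapsed time. Greedy linking is deterministic and exact at the
densities the generators produce; globally optimal assignment linking is a
possible extension, not an oversight.

`classifyTracks()` applies the displacement taxonomy: a track is
*stationary* when its net first-to-last displacement is at most 0.67 um
and *dynamic* above. Two conventions are worth making explicit: the
published rule states strict inequalities on both sides, leaving equality
unassigned — the package counts a displacement of exactly 0.67 um as
stationary; and "displacement" is net displacement, not path length
(which is also computed, and always at least the displacement).

`lineProfile()` samples a segment at unit-pixel spacing by bilinear
interpolation, averaging across `width` parallel offset lines; offset
samples beyond the border are clamped.

# What the generators emulate — and what they do not

* `simulateTirfSeries()`: an elliptical cell footprint with a diffuse
  cytosolic pool (80 counts) over camera background (100 counts),
  diffraction-limited Gaussian spots (sigma 1.5 px, amplitude 600),
  Brownian motion (0.05 um/frame), 1 frame/10 s, 0.1 um pixels, Poisson
  shot noise plus Gaussian read noise (sd 10) — the standard camera model,
  since no noise statistics are published for the original acquisitions.
  A chosen fraction of query spots is co-centred on reference spots with
  0.5 px jitter, small enough to exercise the 0.5 score cut-off
  meaningfully; all other query spots are kept at least 3 PSF sigmas from
  every reference spot at every frame by rejection sampling, so the truth
  flag remains meaningful as spots diffuse.
* `simulateConfocalCell()`: an elliptical cell of uniform cytosol
  intensity with a sharp peripheral ring of chosen width and
  membrane:cytosol ratio, a Gaussian focal envelope along z, and the same
  noise model. The noiseless stack, its sum projection and the geometric
  cell/ring masks are stored in the truth object.
* `simulateTracks()`: stationary and dynamic tracks starting on a wide
  grid (8 um spacing, so linking is unambiguous), with net displacements
  drawn uniformly in (0, 0.8) or (1.2, 5) times the threshold and imposed
  exactly by a linear path correction; 30 frames at 1 s intervals,
  matching the acquisition cadence such cohorts are tracked at.

Features of real data deliberately *not* emulated: optical blur of
extended structures (the confocal ring has a hard edge; real membranes
are PSF-spread, which actually softens the mask-dilation bias discussed
above because the halo then carries genuine signal), evanescent-field
depth dependence in TIRF, photobleaching, uneven illumination, camera
gain calibration, multiple or touching cells, and vesicle appearance or
disappearance within a movie. Passing the recovery tests therefore
demonstrates correctness of the *procedures* under controlled conditions,
not robustness to every artifact of real acquisitions — external cell
masks and the exposed parameters are the intended escape hatches there.

# Validation design and problem sizes

The test suite validates every primitive against an independent
brute-force oracle (exhaustive search over all candidate histogram splits
for the three thresholds; per-pixel loop implementations of erosion,
hole-filling, component size filtering, disk medians and Gaussian
convolution) and every stage against generator ground truth. The sizes
used are the package's own validation choices: 100 random histograms per
threshold method; 50 random 64x64 masks; ring cells of 192x192x5 at
membrane ratios 1, 2 and 4 (recovery within 10% of the truth-raster
ratio, strictly increasing); TIRF movies of 256x256 with 100 query and
100 reference vesicles over 20 frames at true colocalized fractions 0.2,
0.5 and 0.8 (mean per-frame ratio within 0.10 of truth, strictly
increasing, counts conserved on every frame); a 320 stationary / 109
dynamic cohort recovered exactly (429 tracks in total); random 16^3
volumes against a voxel-loop overlap oracle; and bit-identical re-runs of
every generator stage from its manifest. `scripts/acceptance.R` re-runs
this validation end to end from a seed and writes the recovered numbers
as JSON.

# Known limitations

* The Huang threshold is generous by construction; on images with soft
  edges it can include a halo of near-background pixels in the cell mask.
  The membrane band then underestimates enrichment. Controlling the
  pre-threshold blur (and, on real data, supplying externally curated
  masks) is the practical remedy.
* The fallback TIRF cell mask handles a single bright cell only.
* Greedy linking can mis-assign crossing vesicles that pass within the
  link radius of each other in the same frame interval.
* Published colocalization percentages from manually thresholded volumes
  cannot be reproduced without the manual thresholds; only the statistic's
  definition is implemented.
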