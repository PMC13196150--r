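# VesiQuant

Quantification pipelines for fluorescence microscopy of membrane-protein
trafficking. When a tagged transporter (a GLUT10/GFP construct, say) is
followed from the plasma membrane through RAB5-positive early endosomes,
the quantitative claims rest on four measurements, each of which VesiQuant
implements as a tested, scriptable stage:

* **Membrane vs cytosol fluorescence** from confocal z-stacks: sum-slices
  projection, Huang-threshold whole-cell mask, hole filling and size
  filtering, a cytosol mask from 10 cycles of binary erosion, and the
  membrane band as their difference. Headline statistic: relative membrane
  intensity `mean_membrane / mean_whole` (the cytosol-normalized ratio is
  reported too).
* **TIRF vesicle–endosome colocalization** in two-channel time series:
  difference-of-Gaussians spot enhancement, Voronoi–Otsu labeling of query
  vesicles, a triangle-threshold reference vesicle mask, per-vesicle
  overlap scores `|P ∩ ref| / |P|`, three-way classification at the
  0.5 / 0.01 cut-offs, and the per-frame colocalization ratio
  `n_colocalized / n_total`.
* **Percent-volume colocalization** of two channels:
  `100 · |A ∩ B| / |A|` over supra-threshold voxel sets, both directions,
  with manual or automatic (`huang`/`triangle`/`otsu`) thresholds.
* **Single-particle tracking**: greedy nearest-first linking of per-frame
  detections, net displacement / path length / speeds per track, and the
  stationary–dynamic taxonomy at a 0.67 µm displacement threshold; plus
  bilinear line-scan intensity profiles.

Because studies of this kind rarely deposit raw movies, the package also
ships synthetic generators (TIRF movies with a controlled colocalized
fraction, confocal membrane-ring cells, track cohorts) that record exact
ground truth, so every stage is validated by recovery. The methods
vignette (`vignettes/quantifying-vesicle-trafficking.Rmd`) documents the
models, conventions, parameter defaults and their rationale.

## Worked example

```r
library(VesiQuant)

## a confocal ring cell with 2x membrane enrichment, quantified
sim <- simulateConfocalCell(list(membraneRatio = 2), seed = 11)
membraneTable(quantifyMembrane(sim$stack), image = "ring_cell")
#>       image cellId areaWhole areaCytosol areaMembrane meanWhole meanCytosol
#> 1 ring_cell      1     16368       12382         3986      1515        1294
#>   meanMembrane relativeMembraneIntensity membraneCytosolRatio
#> 1         2202                     1.453                1.702
```

The detected cell covers 16,368 px; the 10-cycle erosion band (3,986 px)
has mean intensity 2202 against 1515 for the whole cell, giving a relative
membrane intensity of 1.453 — within 3% of the 1.496 ratio measured on the
generator's noiseless raster.

```r
## a 5-frame TIRF movie with half the query vesicles on endosomes
tir <- simulateTirfSeries(list(colocFraction = 0.5, nFrames = 5), seed = 42)
out <- analyzeTirfSeries(tir$stack)
head(out$frames)
#>   frame nTotal nColoc nPartial nNon colocRatio
#> 1     0     95     47       11   37      0.495
#> 2     1     97     49       12   36      0.505
#> 3     2     94     46       13   35      0.489
#> 4     3     95     46       12   37      0.484
#> 5     4     95     48       10   37      0.505
mean(out$frames$colocRatio)
#> [1] 0.496
```

Of ~95 detected vesicles per frame, about half score ≥ 0.5 against the
endosome mask; the mean colocalization ratio 0.496 recovers the true
fraction 0.5.

```r
## a 320 stationary / 109 dynamic cohort, relinked and classified
st <- simulateTracks(320, 109, 0.67, seed = 7)
classifyTracks(linkDetections(st$detections, trackingConfig(),
                              pixelSizeUm = 0.1, frameIntervalS = 1))$counts
#> nStationary    nDynamic      nTotal
#>         320         109         429
```

`runPipeline()` exposes the same stages through config lists or YAML and
writes CSV tables plus a reproducibility manifest;
`inst/scripts/vesiquant.R` is a thin command-line wrapper over it.

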