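---
title: "Methods: automated plot delineation and trait extraction from UAS imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated plot delineation and trait extraction from UAS imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Row-crop breeding trials are phenotyped from unmanned aerial system (UAS)
imagery: an RGB orthomosaic and a co-registered digital surface model
(DSM) of a field of small two-row plots planted on raised beds. The
bottleneck is plot delineation — knowing which pixels belong to which
experimental unit — and terrain correction, which turns surface elevation
into canopy height. `fieldpheno` automates the whole chain:

1. **Field localization.** Candidate masks from a promptable-segmentation
   backend are filtered to those centered in frame, ranked by the mean of
   predicted IoU and stability score, and the winner's minimum oriented
   bounding rectangle gives the field extent and orientation.
2. **Plot segmentation.** Vegetation pixels (ExG − ExR > 0) are summed
   into column and row profiles; profile valleys separate crop ranges and
   profile peaks locate crop rows. Row centroids become foreground point
   prompts (with neighboring centroids as background points) for per-row
   segmentation masks.
3. **Terrain model.** Two terrain points are sampled beside every row
   mask, on the bed top in the bare alleys; a Delaunay triangulation
   interpolates them into a digital terrain model (DTM), and
   nDSM = DSM − DTM isolates canopy height above the local bed surface.
4. **Plot grid.** Tractor tracks between beds are depressions in the
   nDSM; a Hough transform restricted to near-horizontal lines finds the
   bed boundaries, which together with the range limits tile the field
   into two-row plot cells. Each cell's mask center of mass gets a
   224 × 224 px bounding box.
5. **Traits.** Canopy height (CH) is the mean of the two per-row maxima
   (or upper percentiles) of the nDSM inside the box, in cm. Growth habit
   (GH: bunch vs spreading) and mainstem prominence (MP: apparent vs not
   apparent) are binary classifiers on the plot patches, optionally
   fusing height into the green channel (G' = min(255, G + 100·nDSM)).

## Backends

The segmentation surface is pluggable. The **classical backend** —
vegetation-index thresholding plus connected components, with component
solidity (area / bounding-box area) standing in for predicted IoU and
stability — is deterministic, dependency-free and is what all shipped
results use. Solidity favors compact, complete regions, so the whole-field
union candidate or a solid central region wins the ranking the same way a
foundation model's most stable mask does. A **foundation adapter** slot
accepts an external promptable-segmentation checkpoint; without a
checkpoint it errors and points at the classical backend.

## The synthetic field generator

Real orthomosaics cannot ship with a package, so `generate_field()`
renders a complete trial with known ground truth. Its defaults are the
study conditions of the trial the pipeline was designed around:

| parameter | default | meaning |
|---|---|---|
| `bed_width_m` | 1.82 | raised-bed width |
| `row_spacing_m` | 0.91 | two rows per bed |
| `plot_len_m` | 0.5 | planted plot length |
| `alley_m` | 2.0 | bare-soil alley between ranges |
| `gsd_cm` | 1.0 | ground sampling distance |
| `ch_mean_cm`, `ch_sd_cm` | 24.8, 6.37 | canopy-height law |
| `ch_range_cm` | 16–40 | observed height range |
| `gh_spreading_prob` | 0.508 | class frequency, growth habit |
| `mp_apparent_prob` | 0.657 | class frequency, mainstem prominence |
| `furrow_depth_m` | 0.05 | track depression between beds |
| `missing_plot_rate` | 0.02 | plots lost to germination failure |
| `single_row_rate` | 0.03 | plots with one surviving row |

Canopy heights are drawn from a truncated normal with the exact [16, 40]
cm range, by rejection sampling. Because the window is asymmetric around
24.8, naively truncating a normal(24.8, 6.37) would shift the mean to
about 25.6 cm; the generator therefore calibrates the pre-truncation
parameters (closed-form truncated-normal moments, Nelder–Mead) so that
the **generated** heights have mean 24.8 cm and SD 6.37 cm — the reported
numbers are sample moments of range-limited field data, and that is what
the synthetic crop reproduces. Canopies are smooth
super-elliptic height bumps (bunch: compact and domed; spreading: wider
and flat-topped; apparent mainstem: a narrow central spike reaching the
canopy top), colored green with per-pixel jitter over a soil background;
the jitter amplitudes are chosen so ExG − ExR is strictly positive on
canopy and strictly negative on soil, which is the signal the prompting
stage consumes. The DSM is an affine terrain surface, minus 5 cm furrow
strips at every bed boundary, plus the canopy height field, plus optional
i.i.d. Gaussian noise. Missing and single-row plots are drawn
independently per plot; the phenomenon is real, the rates are the
package's own choice of a realistic magnitude.

What the generator does **not** emulate: weeds, lodging, senescent
vegetation, shadows, photogrammetric reconstruction artifacts, and canopy
texture. Passing tests therefore demonstrate the pipeline's geometric and
numerical correctness under the stated layout, not robustness to every
nuisance a real field supplies; on real data the segmentation backend, not
the geometry, is the accuracy-limiting component.

## Numerical choices

* **Pixel convention.** 0-based `(x = column, y = row)`, pixel centers at
  integer coordinates, half-open boxes. One pixel↔world conversion pair is
  used everywhere, so the mapping is a bijection.
* **Raster storage.** Plain TIFF plus a JSON sidecar for gsd, origin,
  nodata and the linear offset/scale used to pack float elevations into
  the [0, 1] range the TIFF writer stores; local, non-georeferenced
  coordinates throughout, matching orthomosaics produced without surveyed
  ground control.
* **Orientation.** Minimum-area enclosing rectangle via rotating calipers
  over the convex hull of mask pixels, long-side angle reported modulo
  180° (a field has no front/back). The principal-component angle is also
  computed; disagreement beyond 2° logs a warning — with randomly missing
  plots the covariance tilts while the enclosing rectangle does not,
  which is exactly why the rectangle is primary.
* **Mod-90 disambiguation.** Long-axis alignment leaves open which image
  axis carries the beds. After rotation, the vegetation profile along the
  across-bed axis repeats at the row spacing (0.91 m); along the bed axis
  it repeats at the much larger plot + alley pitch (2.5 m). The axis whose
  median profile-peak spacing is closer to the configured row spacing is
  taken as the across-bed axis.
* **Center filter.** The 5 px candidate filter operates in resized
  (≤ 1024 px) coordinates — the scale at which candidates are generated —
  and the radius is exposed as `center_radius_px`.
* **Profile processing.** Moving-average smoothing with window
  0.25 × row spacing; valleys below 0.1 × profile maximum; peaks above
  0.3 × maximum with minimum separation 0.5 × row spacing. No published
  values exist for these; all are exposed in `pipeline_config()`.
* **Terrain sampling.** Offset 0.25 × alley width from the mask bounding
  box, nudged off vegetation, single-pixel reads with an optional 3 × 3
  median. Samples sit on the bed top, so the DTM models the bed surface
  and furrow tracks show up negative in the nDSM — which is what the bed
  line detector consumes (depth threshold 1 cm, angular window ±2°).
* **Delaunay DTM.** Bowyer–Watson triangulation with a deterministic
  ~1e-4 px coordinate jitter to break the exact cocircularity of
  grid-aligned samples; piecewise-linear interpolation is exact for any
  affine terrain regardless of sample placement, and nearest-sample
  extrapolation covers pixels outside the convex hull. The jitter moves
  interpolated elevations by less than terrain-gradient × 1e-6 m,
  far below the 1 cm decisions the nDSM feeds.
* **Degenerate inputs.** Both-empty masks, constant observations, absent
  classes and zero denominators yield `NA` (or an error), never a silent
  0 — zeroing would bias aggregated error rates.
* **Single-row plots.** The plot center of a one-row plot is the centroid
  of its only row, so the half-split would bisect the blob; the height
  statistic is taken over the whole patch instead, which coincides with
  the two-half rule whenever the row straddles the split.

## Trait classifiers

No deep-learning runtime ships with the package, so the classifier is a
**frozen convolutional random-feature embedding plus a trainable fully
connected softmax head** — the protocol "freeze the backbone, fine-tune
the final fully connected layers" applied to a seeded, untrained filter
bank (`model_name` selects 8/16/24 filters; images are resampled to
28 × 28, convolved, rectified and pooled). Training uses cross-entropy,
AdamW, dropout 0.5, weight decay 0.01, and a one-cycle cosine schedule
decaying to 0.001 × the initial learning rate. Hyperparameters come from
a grid over batch {16, 32} × epochs {10, 15, 20} × learning rate
{1e-5, 1e-4, 1e-3}, scored by mean macro-F1 under stratified 5-fold CV on
the 80 % training split (validation folds see unaugmented images;
training folds see the horizontal-flip, vertical-flip and transpose
augmentations), and the winner is retrained and tested repeatedly
(`runs`, default 10) with different initializations; accuracy is reported
as mean ± SD. The nDSM-only modality replicates the ×100-scaled height
map into three channels so the same embedding applies unchanged; whether
to feed raw meters or centimeters is an open choice — centimeters keep
the channel scale comparable to RGB.

This head is linear in fixed random features: it demonstrates the
protocol and the information ordering between modalities (height-bearing
inputs dominate when classes differ in structure), but it is not a
substitute for a deep pretrained backbone on real imagery.

## Problem sizes used by the shipped checks

The test-suite and the acceptance script run: a 5 × 8-bed field at
2 cm/px swept through 0–180° in 5° steps for orientation and boundary
IoU; 5 × 12 and 9 × 12 fields at 1 cm/px for segmentation quality and
exact plot recovery; a 5 × 12 field with a 10 cm terrain tilt, 5 cm
furrows and 0.5 cm DSM noise for canopy-height RMSE; and 60–100-plot
synthetic patch sets for the classifier protocol. These sizes exercise
every code path at a few percent of a production field's pixel count;
the pipeline is linear in pixels, so larger mosaics change runtime, not
behavior.

## Known limitations

* The classical backend assumes the vegetation index separates crop from
  background; senescent or weedy vegetation violates this and requires
  the foundation backend plus its checkpoint.
* Single-field scenes with the field roughly centered; multi-field
  mosaics and curved rows are out of scope.
* The Hough stage assumes beds are straight and parallel after rotation.
* CH regression by CNN is deliberately absent: tens of ground-truth
  measurements cannot train a robust regressor, so CH comes from the
  nDSM directly.
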