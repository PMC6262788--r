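---
title: "Quantifying anisotropic cell shape and microtubule dynamics in a folding neuroepithelium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying anisotropic cell shape and microtubule dynamics in a folding neuroepithelium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldshape)
```

## The measurement problem

During early brain morphogenesis the neuroepithelium folds towards its
basal surface to form the midbrain-hindbrain boundary (MHB); the deepest
point of the fold is the MHB constriction (MHBC). The cells driving this
fold are pseudostratified and span the full apical-basal depth of the
tissue. Their shape is three-dimensional: length runs apical-basal
(y-axis), width anterior-posterior (x-axis) and depth dorsal-ventral
(z-axis). `foldshape` implements the orthogonal-slice protocol for
quantifying shape anisotropy in the xz plane, the ROI-based intensity
normalizations used for filament reporters and immunostains, the EB3
comet pipeline for microtubule plus-end dynamics, and the statistical
layer used to compare treatment groups — together with synthetic-data
generators that produce all of these inputs with known ground truth.

## The orthogonal-slice shape protocol

Given an aligned stack in which the cell of interest runs parallel to y,
the protocol is:

1. **Alignment.** `estimate_alignment_angle()` computes the principal
   axis of the cell's xy projection from second moments and returns the
   in-plane rotation that makes it parallel to y; `rotate_stack_xy()`
   applies it (bilinear for intensities, nearest-neighbour for labels).
2. **Length.** `cell_length_y()` measures apical-basal length as the
   cell's y-index span times the y spacing.
3. **Slice positions.** The length is divided into six equal sections;
   digital xz slices are cut at the section points immediately inside
   the apical (1/6) and basal (5/6) surfaces (`slice_positions()`).
   For cells 30-42 um long these sit about 5-7 um inside either surface.
   The apical surface is the minimum-y end after alignment (the
   ventricle side); `apical_min_y = FALSE` in the config flips this.
4. **Slices.** `extract_xz_slice()` takes the single voxel plane nearest
   the requested y position (a y-averaging window is available for noisy
   data but defaults to off, matching the single-plane digital
   cross-section of the imaging software).
5. **Metrics.** On the cell's mask in each slice, `mask_area()` is pixel
   count times pixel area; `max_depth_chord()` finds the longest
   straight segment that stays inside the mask and whose direction is
   within 45 degrees (inclusive) of the z-axis;
   `max_width_perpendicular()` finds the longest in-mask chord
   perpendicular to the realized depth chord; and `xz_ratio()` divides
   width by depth. A ratio different from 1 (tolerance 0.05, config)
   marks anisotropic shape.

### Chord search on pixel masks

Manual depth/width measurements are line-tool chords, so the package
defines the chord metrics directly on the pixelated mask: candidate
endpoints are boundary pixels (a 4-neighbour touches background or the
image edge), and a segment is "inside" when every pixel cell touched by
its closed supercover rasterization belongs to the mask — grazing a cell
corner counts as touching, which makes the definition conservative and
unambiguous. Lengths and angles are physical, so the anisotropic voxel
spacing (x is typically sampled 2.5x finer than z) is handled
correctly. Ties in length are broken by the chord closer to the target
direction and then by smaller endpoint coordinates, making the result
unique and testable: the compiled implementation is checked against an
independent plain-R exhaustive search, exactly, on hundreds of random
masks.

Two readings of "width" are defensible: strictly along the x-axis, or
perpendicular to the realized depth chord. The two coincide when the
depth chord is z-aligned; the perpendicular reading is self-consistent
when it is not, and is the default (`width_mode = "x_axis"` restores the
literal reading). Because exact perpendicularity is rarely realizable
between pixel centres, chords within 3 degrees of the perpendicular are
admitted (doubling the tolerance if none exists); the 45-degree depth
bound is inclusive, so a square mask reports its diagonal at exactly
45 degrees.

### The tissue fold angle

`measure_mhb_angle()` quantifies the basal fold: total-least-squares
lines are fitted to the basal-surface points within 20 um (config) of
the vertex on each side, and the interior angle between the fitted
directions is reported; collinear points give 180 degrees. The basal
surface is used to define the angle, and each side needs at least three
points inside the fit span.

## Intensity normalizations

All region intensities are means over rectangular ROIs whose pixels are
selected by the half-open centre-in convention, so adjacent ROIs tile an
image without double counting. The filament-reporter normalization works
on a 10 um average intensity projection: the MHBC ROI mean (40 x 50 um
by default) is divided by the mean of the midbrain and hindbrain ROI
means — the mean of the two region means, not a pooled pixel mean, which
differs when the ROIs contain different pixel counts. Apical/basal
polarity ratios divide the apical and basal box means by the middle box
mean; the boxes are squares of area 10 um^2 (a "10 um^2 box" is read as
area, not side length; the side is a config value away) placed at
fractional positions 1/6, 1/2 and 5/6 along the cell axis, mirroring the
slice convention, since the protocol does not pin their positions.
Western-blot quantification takes pre-integrated band intensities and
divides the target band by the loading-control band
(`band_normalize()`); gel image processing is out of scope. All ratios
are invariant to rescaling the image intensities, which the tests
enforce.

## The comet pipeline

The pipeline reproduces the two-branch Fiji workflow. `prepare_movie()`
keeps the first 200 s of the acquisition (50 frames at 4 s/frame), crops
to a 50 x 40 um ROI and min-max rescales the whole series to 8-bit.
Comet **number** and **size** come from the thresholding branch:
`otsu_threshold()` maximizes between-class variance over the 256-bin
histogram (verified exactly against an exhaustive search),
`segment_particles()` labels 8-connected components and keeps those with
area in 0.08-3 um^2. Comet **speed** comes from the detection/tracking
branch: `detect_log()` computes the scale-normalized
Laplacian-of-Gaussian response at sigma = (blob diameter / 2)/sqrt(2)
with blob diameter 1 um, calibrated so a matched Gaussian blob of
amplitude A scores about A on the 0-1 intensity scale, finds strict
local maxima and refines them by separable quadratic interpolation
(typical localization error is a few hundredths of a pixel).
`link_tracks()` is a linear-motion predictive linker: each open track
predicts its next position from its last position and velocity, frame
links are chosen by a globally minimal linear assignment (cost = squared
distance to the prediction, start/stop alternative cost
1.05 x radius^2), unmatched tracks coast for up to 2 frames, and tracks
shorter than 3 spots are discarded. `track_speed()` averages per-step
displacement over elapsed time and reports um/min; apparent speed is the
2D projected speed, as in single-plane acquisition.

Two thresholds deserve comment. The printed quality threshold "0.5 um"
carries a unit a quality cannot have; the package treats 0.5 as a
response threshold on the normalized quality scale and documents that
calibration. The workflow additionally applies an automatic initial
quality filter, and that is the pipeline default
(`log_quality = "auto"`): an Otsu-style split of the candidate-maximum
qualities over the movie. The auto filter is robust to an artefact of
fixed thresholds on min-max-normalized series — a single frame in which
two comets overlap doubles the series maximum and halves every
normalized quality. Linking defaults (search radius 1.5 um = 5x the
expected 0.3 um per-frame displacement, 2 gap frames, minimum 3 spots)
are chosen from the motion regime; the protocol itself does not state
them.

## The synthetic generators

`generate_epithelium_stack()` builds a single-layer folded epithelium:
two sheets of columnar cells whose basal ends sit on the two limbs of a
V with interior angle `fold_angle` (180 degrees gives a flat sheet).
Cell axes fan gently around the fold — they radiate from a focal point
`focal_depth` below the basal vertex, so vertex cells are nearly
vertical and peripheral cells tilt progressively in xy, giving the
alignment step real work. Each cell is a prism along its axis with an
elliptical xz cross-section: constant depth (12 um), width interpolating
linearly along the axis and calibrated so the cross-sections **at the
1/6 and 5/6 measurement planes** have exactly the requested apical and
basal x:z ratios — the ground-truth table therefore states precisely
what the measurement protocol should recover. Cells are spaced so that
neighbouring ellipses (and the mirror pair at the vertex) keep a 1 um
gap; overlapping layouts are an error, not a silent artefact. The
membrane channel is the label-boundary shell blurred with a Gaussian PSF
(sigma 0.3 um), peak-normalized, plus additive Gaussian noise
(sd 0.1 = peak SNR 10 by default). Defaults — 6 cells per side, length
36 um, apical ratio 0.7, basal ratio 0.5, fold 90 degrees, voxels
0.2 x 0.2 x 0.5 um — describe the 18-24 somite-stage MHBC tissue and
typical 40x confocal sampling.

`generate_comet_movie()` renders comets as unit-peak Gaussian blobs
(sd 0.4 um, FWHM about 1 um — the nominal comet diameter) moving
ballistically with per-comet speeds N(4.5, 0.5^2) um/min by default, at
1 frame / 4 s for 10 min in a 60 x 50 um field; comets leaving the field
are replaced at random positions so the expected count (30) holds. The
background is a detector offset (10% of peak) plus Gaussian noise of sd
peak/snr, clipped at zero. The default snr is 20. This is a deliberate
inference about the data the protocol was used on: a global histogram
threshold can only separate comets occupying ~0.6% of the ROI from the
background when the pixel peak-SNR exceeds roughly 15 (below that, the
between-class variance maximum provably sits inside the noise and any
correct Otsu implementation mis-segments); since the published workflow
did count comets this way, the underlying movies must have been in that
high-contrast regime. The LoG/tracking branch is far more robust and is
verified down to SNR 5. `generate_region_intensity_stack()` builds
piecewise-constant stacks for the normalization workflow, with
background equal to the mean of the stated region means so that equal
means give a uniform stack.

What the generators deliberately do not emulate: pseudostratified
nuclear packing and cytoplasmic texture, out-of-focus haze, elongated
(non-isotropic) comet shapes, photobleaching, drift, and mechanically
simulated folding. Passing the recovery tests therefore shows that the
measurement chain is correct on geometry it was designed for, not that
segmentation of real membrane signal is solved — cell labels are an
input to the shape pipeline, matching the manual outlining of the
original protocol.

## Statistics

Two-group comparisons use Welch's t-test (`welch_t()`, verified against
a longhand reference and `t.test()` to 1e-10). Multi-group designs use
one-way ANOVA with experimental batch as an additive **fixed** effect —
with 3-8 batches a random effect is neither needed nor well estimated —
tested with Type-II sums of squares, which equal Type-I under balance
and are robust to mild imbalance (`anova_with_batch()`; a design in
which group is aliased with batch is an error). When the ANOVA rejects
at 0.05, `tukey_hsd()` runs Tukey-Kramer pairwise comparisons using the
batch-adjusted error mean square, with adjusted p-values from R's
studentized-range distribution (`ptukey`); with two groups this reduces
to the pooled t-test, which the tests verify to 1e-6. Significance
stars follow the convention * p < 0.05, ** p < 0.01, *** p < 0.005.
The unit of analysis is the embryo: `aggregate_embryos()` averages
cell-level and left/right replicates within embryo first, since the
reported n counts embryos; per-cell rows are kept in the measurement
tables so other aggregations remain possible.

Calibration is checked by simulation: the batch-adjusted ANOVA rejects
true nulls (with real batch effects present) at 5% +/- 1.5% over 2000
simulated tables, and the family-wise error of Tukey at k = 3 stays at
or below the nominal 5%.

## Numerical choices and problem sizes

Voxel indices are 0-based in formulas; a voxel's physical position is
its centre; ROIs are half-open in um. Stacks are written as 32-bit float
TIFF rescaled to [0, 1] with the scale recorded in a YAML sidecar
(round trips are exact to 32-bit precision; label volumes round-trip
exactly as 16-bit integers). Angle-window comparisons in the chord
search carry a 1e-7 degree epsilon so the inclusive 45-degree bound
survives floating-point degree conversion; segment-cell intersection
uses a closed Liang-Barsky test with a 1e-12 parameter epsilon, mirrored
exactly in the test oracle. The quadratic sub-pixel offset is clamped to
half a pixel. Test and acceptance runs use 200 random masks for the
chord oracle, four stacks of 12 cells for the anisotropy sweep, 600 s
movies with 30 comets (analyzed over 200 s) for the comet recovery and
ten movies per condition for the speed contrast, and 2000 null tables
for the ANOVA calibration; these sizes keep every guarantee measurable
in minutes on one core while leaving sampling error well inside the
stated tolerances.

## Known limitations

The chord metrics are defined on the pixel grid without sub-pixel
boundary refinement; at the default sampling this quantizes depth and
width by about one pixel, visible as a ~0.4 um downward bias of the
measured depth of a 12 um ellipse — the x:z ratio, the quantity of
interest, is much less affected. Nearest-neighbour label rotation
redistributes single voxels at mask edges. The comet linker performs
one-step constant-velocity prediction without track merging, splitting,
or full Kalman smoothing; crossing comets at high density can still
swap. The Otsu counting branch requires the high-contrast regime
discussed above — at low SNR its counts are meaningless even though the
speed branch keeps working. The fold-angle fit assumes the vertex index
is known (it is, for generated surfaces; from measured surfaces it
should be taken at the depth extremum).
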