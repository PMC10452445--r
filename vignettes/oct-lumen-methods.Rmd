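---
title: "Quantifying microvessel lumens in OCT stacks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microvessel lumens in OCT stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octlumen)
```

## The measurement problem

Self-organized microvascular networks in fibrin-gel transwell cultures (as
used for in-vitro blood-brain-barrier models) are perfused through lumen
openings at the gel bottom, where an endothelial monolayer grows. Assessing
barrier permeability requires the total endothelial surface area `A` of the
*open* (bottom-connected) vessels, because the effective permeability
coefficient is the normalized permeability-surface-area product,

    Pe = PSe / A.

Optical coherence tomography can image the whole construct non-invasively:
lumens appear as dark, pore-like cross-sections inside bright, speckled
tissue. `octlumen` turns such a stack into vessel-level numbers in five
stages: geometry conversion and preprocessing, lumen segmentation, patch
plumbing for external detectors, agreement scoring against reference masks,
and 3D quantification.

## Stack geometry and preprocessing

The instrument acquires x-z cross-sections stacked along y; analysis runs on
x-y frames stacked along depth. `convert_axes()` is a pure index permutation
(no interpolation anywhere in the package), with frame 1 of the converted
stack fixed to the gel bottom -- the side the monolayer grows on and the
anchor for the open/closed decision. The convention matters: the instrument
never stores it, and every downstream "open" call depends on it.

Converted stacks are truncated to the visible depth with strict floor
semantics: a frame at depth `(i-1) * frame_spacing_um` survives when that
depth is strictly below `max_depth_um` (default 350 um, the depth beyond
which open structures essentially never extend and frames blur out). A
60-frame stack at 10 um spacing truncated at 350 um keeps 35 frames.

`equalize_histogram()` implements the standard cumulative-distribution
remap at 256 levels. It is **per frame** by default: OCT brightness decays
roughly exponentially with depth, so a single stack-wide map would spend
most of its range undoing the decay instead of enhancing in-frame contrast.
A stack-wide variant (`per_frame = FALSE`) is provided. Constant frames are
returned unchanged (the remap denominator is degenerate), and the remap is
monotone, so intensity ordering within a frame is never disturbed.

## The synthetic phantom: what it emulates, and what it does not

No public OCT stacks of these cultures exist, so the package carries its
own study conditions in `phantom_spec()`: 600 x 600 px frames at 10 um/px,
10 um frame spacing, 35 frames (350 um); a bright culture-insert ring at
radius 250 px; a central surface depression (radius 80 px) on the first 3
frames; open tubes anchored at frame 1 and closed lumens floating inside
the gel, radii 20-40 um, centerlines jittered 1 px/frame; tissue mean
decaying as `exp(-depth / 150 um)`; multiplicative log-normal speckle
(sigma 0.25); an additive, depth-independent detector noise floor (sd 0.02,
added after the optical blur -- this is what makes deep frames unreliable
once the decayed signal approaches it, reproducing the characteristic
mid-depth quality peak); and per-frame Gaussian blur growing from 0.8 px by
0.05 px/frame. The truth mask marks exactly the noise-free lumen voxels,
and the tube table carries analytic diameters and lateral cylinder areas
`pi * d * h` for parameter-recovery tests.

The phantom deliberately does **not** model: branching or anastomosing
vessel trees (centerlines are monotone in depth, one cross-section per
frame), physically accurate coherent speckle statistics, refraction or
shadowing artifacts, or tissue texture. The last point has a practical
consequence: histogram equalization of a texture-free phantom frame
stretches the near-constant tissue mass so that blur halos around lumens
land on lumen-level ranks. The detector benchmarks in the test-suite and
acceptance script therefore segment the raw render, while the real-data
pipeline keeps equalization on by default. Passing benchmarks show the
pipeline machinery is correct at the acquisition geometry; they do not
certify detector accuracy on real tissue texture.

## The morphological detector

`segment_mip()` runs, per frame: Gaussian blur; local-mean adaptive
threshold (window `adaptive_block_px`, default 51 px, with a subtractive
offset on the [0,1] scale); inversion so dark lumens become foreground;
binary erosion (disc, default 1 px); binary opening (disc, default 2 px);
8-connected component area filtering (defaults 10-5000 px); and
intersection with the ROI mask. The erosion step earns its place: any
threshold of an optically blurred dark disc over-segments by a halo ring,
and a 1 px erosion trims it back. Defaults suit lumens tens of pixels
across; for the phantom's 2-4 px radii the benchmarks shrink the
structuring elements (no pre-blur, erosion 1 px, opening 1 px, minimum
area 3 px), mirroring how the detector is re-tuned per dataset in practice.

`adaptive_offset` is the one parameter that cannot be fixed a priori --
it trades false lumen pixels in speckle against missed dim lumens --
so `calibrate_threshold()` grid-searches it against reference masks,
scoring by mean per-frame Cohen's kappa, with ties broken toward the
smaller absolute offset (the less aggressive setting).

The ROI mask (`build_roi_mask()`) is the centered disc of radius 250 px
(excluding the bright insert edge) intersected with a per-frame
tissue-presence mask. The published description of the ROI procedure is
incomplete, so the tissue mask is a stated reconstruction: threshold the
blurred frame at half the mean of its clearly-lit pixels (with a 0.1
floor), drop speck noise with a 3 px opening, fill enclosed holes **up to
2000 px** -- lumens are exactly the holes that must stay analyzable --
while larger vacancies such as the surface depression stay excluded, keep
the largest connected region, and erode a conservative 2 px margin so the
partial-volume band around vacancies is not scored either way.

## The random-forest pixel classifier

`extract_features()` computes a deterministic multi-scale filter bank
(Gaussian, gradient magnitude, Laplacian, difference-of-Gaussians with the
conventional 1.6 ratio, and local variance, at sigmas 1/2/4/8 px, plus raw
intensity -- 21 features). `train_rf()` fits a probability forest (100
trees default) on sparsely labeled pixels of both classes; labels are
canonicalized by position before fitting so the model depends on the label
*set*, not collection order, and a fixed seed with single-threaded fitting
makes training bit-reproducible. `rf_segment()` thresholds the lumen
probability at 0.5 (ties foreground) and applies morphological closing.
`refine_labels()` retrains on the union of old labels and corrections
(corrections win at conflicting pixels), the programmatic form of the
usual interactive correct-and-retrain loop.

Two properties of this detector are worth knowing. First, per-pixel
classification places boundaries within the blur halo, so on strongly
blurred stacks it trails the erosion-equipped morphological chain by
~0.1 kappa; on crisp scenes the two are equivalent. Second, the classifier
learns intensity polarity: trained on inverted-polarity frames it scores
kappa near zero on normal frames -- the package reproduces this known
transfer failure rather than guarding against it.

## Patch plumbing and external detectors

Patch-based translation networks consume fixed 256 x 256 inputs.
`split_patches()` covers a frame with the minimal uniform grid of
overlapping patches -- `ceil(dim/256)` per axis, offsets evenly spaced
from 0 to `dim - 256` -- which for 600 px frames is the classic 3 x 3
nine-patch layout at offsets 0/172/344. `stitch_patches()` averages
overlaps and is an exact inverse of splitting; a binary stitch thresholds
at >= 0.5 with ties to foreground. `augment_flips()` yields
original + horizontal + vertical flips (3x; the double flip is an option,
off by default since 3x matches the conventional count). Network training
itself is out of scope: `external_segment()` accepts any producer of
per-frame probability maps (a file path or an R function), validates
geometry, and thresholds at 0.5, so externally trained models plug into
evaluation and quantification unchanged.

## Agreement scoring

`cohen_kappa()` uses the closed binary form
`2(TP*TN - FN*FP) / ((TP+FP)(FP+TN) + (TP+FN)(FN+TN))`, algebraically
identical to `(po - pe)/(1 - pe)`; the tests verify the identity to 1e-12
over random confusion tables. A variant of the ratio without the factor 2
circulates in print but reaches only 0.5 at perfect agreement; it is
available as `variant = "printed"` for auditing and is never used
internally. Frames where both masks are constant have an undefined kappa
and score 0, flagged `degenerate` rather than dropped, so depth profiles
keep one entry per frame at `(i-1) * frame_spacing_um`.
`summarize_kappa()` reports the grand mean over all frames with min/max of
the per-dataset means as the spread, the error-bar convention of
multi-sample detector comparisons. Whether scoring should be restricted to
the ROI is not settled; full-frame is the default and an ROI argument is
provided.

## 3D quantification

`label_components()` labels foreground voxels under 6/18/26-connectivity
(default 26 -- the most permissive standard choice, so segmentation
dropout along a tube is least likely to split one vessel into several),
deterministically in scan order, via a vectorized frontier flood fill on
the padded volume. A component is **open** iff it has a voxel in frame 1;
because single-frame dropout at the bottom would demote a truly open
vessel, `anchor_frames` can widen the anchor.

**Diameter.** The per-frame cross-section width is the minimum caliper
(min Feret) width -- "the minimum x-y distance across" the object --
computed by rotating calipers over the convex hull with each pixel treated
as a unit square. The square support matters: pixel-center calipers
underestimate a rasterized disc of radius r by ~1 px on average (and 2 px
worst-case), while the square-support width is unbiased to within 0.1 px
under sub-pixel centering and yields the natural 1 px for a single-pixel
section. Per-frame widths are averaged over the frames the component
occupies, then scaled by the pixel pitch.

**Lateral surface area.** "Circumference times depth" is accumulated as a
Riemann sum: per occupied frame, the cross-section perimeter (4-direction
Crofton estimator, the standard 2 x 2-configuration lookup table) times
pixel pitch times frame spacing, summed. Crofton was chosen over
pixel-edge counting for its low bias on curved contours -- within 5% on
discs of radius >= 6 px and within ~2% in the mean under sub-pixel jitter
at the phantom's 2-4 px radii. Its one systematic weakness is axis-aligned
polygons, underestimated by ~6.5% at any size (the four fixed directions
resolve no flat axis-parallel edges exactly); vessel cross-sections are
curved, so the disc behavior is the relevant one. Mesh-based (marching
cubes) areas are out of scope.

`summarize_vessels()` emits one record per component (open flag, voxel
count, frames spanned, diameter, lateral area) plus totals; the total open
lateral area is the `A` for `effective_permeability()`.

## Numerical and degenerate-input conventions

- Kappa of a doubly-constant frame: 0, flagged, never dropped.
- `paired_equivalence_test()` with zero-variance differences: p = 1 with a
  warning (identical summaries are as equivalent as measurable); otherwise
  a two-sided paired t-test.
- Equalization of a constant frame: identity.
- Caliper of a single pixel: 1 px; collinear pixel runs get their
  square-support width (1 px straight, sqrt(2) px diagonal).
- Probability ties at 0.5: foreground, everywhere (rf, stitch, external).
- Binary TIFFs: 8-bit 0/255; intensity TIFFs: 16-bit (8-bit sources
  round-trip exactly since 65535 = 255 x 257).
- Calibration ties: smaller absolute offset, then grid order.

## Problem sizes used by the shipped benchmarks

Unit tests exercise 200 x 200 x 20 phantoms (the same optics at a quarter
of the frame area) so the suite stays fast; the acceptance script and the
acceptance-level tests run the full 600 x 600 x 35 geometry: parameter
recovery on a noise-free phantom (5 open + 2 closed tubes, radii
20-40 um), a calibrated morphological detector on a low-noise phantom
(speckle 0.1), and a three-dataset ground-truth-vs-detector equivalence
comparison of counts, total areas and mean diameters by paired t-tests.
Open-structure counts are recovered exactly, diameters within one pixel
pitch, lateral areas within a few percent, and the kappa-depth profile
peaks in the 50-200 um band and declines beyond 200 um.

## Known limitations

- The phantom's tissue is texture-free; detector scores on it bound
  plumbing correctness, not real-data accuracy (see above).
- Diameters of detector-segmented (as opposed to truth-mask) vessels are
  biased low when erosion trims halos asymmetrically -- visible in the
  equivalence benchmark as the diameter comparison being the least
  equivalent of the three summaries.
- The per-frame area filter is 2D, per the per-image description of the
  method; a 3D variant would keep thin tubes that occupy few pixels per
  frame but many frames.
- Surface areas ignore the end caps and assume one cross-section per
  component per frame; heavily oblique or branching vessels violate this.
- `read_stack()` trusts lexicographic file order in frame directories.
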