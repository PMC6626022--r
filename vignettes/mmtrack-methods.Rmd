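---
title: "Methods: automated mother-machine image analysis with mmtrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated mother-machine image analysis with mmtrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmtrack)
```

## The problem

The mother machine is a microfluidic device with thousands of parallel
dead-end channels, each trapping a "mother" bacterium at the closed end
while its progeny are pushed out the open end. Time-lapse microscopy of
such devices produces thousands of frames per experiment; extracting
per-cell growth, division, death and fluorescence trajectories by hand is
the bottleneck. `mmtrack` automates the whole chain for brightfield or
phase-contrast detection images with any number of associated fluorescence
planes: it finds the channels, segments the bacteria inside them, tracks
channels and bacteria through time, and emits a lineage-resolved
measurement table.

The pipeline deliberately uses only the transmitted-light image for
detection, so fluorescence remains a free reporter channel and cells need
no fluorescent tag to be measured.

## Pipeline and model choices

### Modality classification

Brightfield images are a bright field with sparse dark structures;
phase-contrast images are the contrast-inverse. The sign of the
intensity-histogram skewness separates the two. With megapixel samples the
bias-corrected and uncorrected skewness differ negligibly, so the
uncorrected moment ratio \(G_1 = m_3 / m_2^{3/2}\) is used; a positive
value is classified as phase contrast, a non-positive value as brightfield
(zero is a measure-zero tie, assigned to brightfield because only the
positive branch is characteristic of phase optics). The statistic is
invariant under positive affine intensity maps and flips sign under
reflection, which the test suite asserts on random images. Within one
area the per-frame decisions are reconciled by majority vote: one
acquisition has one modality, and the vote protects against a single
out-of-focus frame.

### Channel detection

Channel walls are thin dark lines (brightfield) or strong edges (phase).
The walls are enhanced with a multi-scale Frangi vesselness filter tuned
to dark ridges (scales 1--3 px at the default magnification, ridge-ratio
parameter `beta = 0.5`, the noise scale set per image to half the maximal
Hessian norm) or, for phase contrast, with the Sobel gradient magnitude.
The response is binarised with Li's minimum cross-entropy threshold,
computed by fixed-point iteration after shifting intensities to a positive
baseline; that canonicalisation makes the resulting mask invariant under
affine rescaling of the input. Components are filtered by area
(500--50,000 px^2 by default; the bounds bracket one channel outline),
dilated by a 2-px disc to close small breaks, hole-filled, and the
interiors recovered by subtracting the wall mask. Two details matter in
crowded channels:

* the dilation is undone after filling (a morphological closing), so the
  interiors are not biased inward;
* holes and cracks that the ridge response of hosted bacteria leaves in an
  interior are re-filled and re-connected, because the interior must cover
  the cells for the downstream segmentation to see them.

Each interior's axis is the segment between its two farthest-apart
boundary pixels; interiors are kept when the axis length is 100--400 px
and the perpendicular extent 5--40 px (all length-dimensioned defaults
multiply by the single `scale_factor` knob, areas by its square). At
least three channels must survive or the frame is rejected (a condition,
not an error: batch runs skip the frame and continue).

The channel-to-channel spacing is estimated from consecutive centroid
separations projected on the cross-axis direction. Rather than the plain
median of separations -- which fails when half the gaps are doubled by a
missing channel -- the smallest separation anchors a multiplicity estimate
(each gap is rounded to an integer multiple) and the spacing is the
total span divided by the summed multiplicities; on clean geometry this
recovers the pitch to well under a pixel. Interior gaps of about
\(m\times\) the spacing receive \(m-1\) stamped copies of the average
channel shape (the pixelwise majority of the detected interiors after
translation to a common centroid and rotation to the common axis), flagged
`interpolated`. Channels whose detected interior is much shorter than the
median (below 90%) are also re-stamped at their position predicted from
the good channels' centroid line: a short interior means cells ate it, and
an eaten interior would hide exactly those cells. Stamping is confined to
the span between the outermost detections; extrapolating outside the field
of evidence is not attempted. Final labels are renumbered left to right.

### Bacteria segmentation

Per channel, the crop is inverted (cells become bright), and the
background -- estimated by a rolling-ball filter implemented as grayscale
opening with a disc of radius 10 px, about twice a cell width so it cannot
erode cells -- is subtracted. This flattens the illumination so one
segmentation recipe works anywhere along the channel. Because the channel
masks are deliberately oversized (recall-oriented), their margin can reach
onto the dark walls; the margin within the watershed marker distance of
the mask edge is zeroed, since cells sit centred in the channel and only
wall signal lives there.

The flattened image is filtered with a scale-normalised Laplacian of
Gaussian at scales 1.5--3.5 px and max-projected across scales, so rods of
different widths all reach their best response. One Li threshold is
computed per frame over the pooled in-channel responses of all channels --
a per-channel threshold would slice noise in empty channels into phantom
objects, which is the reason for the frame-level pooling. Components
smaller than the minimum bacterium area are dropped before marker
generation (they would otherwise be glued to cells by the watershed).
Markers are the connected regions of the distance transform at least 3 px
from the mask background; a marker-controlled watershed on the response
delineates touching cells, and regions are filtered by width (2--15 px,
width measured as twice the maximal inscribed-disc radius) and area
(20--2,000 px^2).

Two refinement stages with a shared statistical basis follow. Robust
thresholds are computed from all initially detected bacteria of the frame:
medians and median absolute deviations of skeleton-local widths and
intensities, with cuts at median \(-\,k\cdot\)MAD (\(k = 2\)). The MADs
are floored at 15% of their medians: on a nearly homogeneous synthetic
population the raw MAD collapses to zero and "below median \(- k\)MAD"
would degenerate to "below median", splitting cells at every noise dip; a
genuine division neck constricts and dims to about half the body values,
far below the floored cuts.

* **Merging.** A genuine boundary between two cells passes through a dim
  gap. For every pair of nearby regions the interface zone is examined;
  if its minimum (3x3-smoothed) intensity never drops below the intensity
  cut there is no gap there -- the boundary is a watershed artifact (a
  boundary placed inside a cell body, or a cap severed by a response dip)
  and the regions are merged.
* **Splitting.** Each region is skeletonised (Zhang--Suen thinning, the
  longest endpoint-to-endpoint walk taken as the medial path) and cut
  transversally where the local width *and* the local intensity both fall
  below their cuts for at least two consecutive skeleton pixels -- the
  conjunction is deliberate: a dim point without a constriction (e.g. a
  vacuole) or a constriction without dimming (mask noise) must not split
  a cell. Children partition the parent's pixels exactly, by nearest
  skeleton segment. A cut is only accepted if every child retains an
  interior core at least as wide as a watershed marker (with one pixel of
  slack for cuts landing slightly inside a small cell's cap); otherwise
  the cut merely severed a thin appendage and is undone.

### Tracking

The global frame shift is the argmax of the FFT cross-correlation of the
mean-subtracted frames; a normalised peak below 0.3 means the frames share
no structure (a stage jump, a dropped frame) and the shift falls back to
zero with a warning. Channels are then linked by mutual nearest
neighbours on shift-corrected centroids -- each must be the other's
closest counterpart -- and current labels are renamed to the stable ids of
their predecessors; unmatched new channels receive fresh ids.

Bacteria are tracked per channel with a multiple-hypothesis model. Each
previous cell either lyses (0 children), persists (1 child) or undergoes
\(m\) divisions (\(2^m\) children, capped at \(m \le 2\) per interval;
more than four-fold growth between frames is implausible at realistic
imaging cadence). Two physical constraints collapse the hypothesis space:
cells cannot pass each other in a channel (assignments are
order-preserving along the axis, each cell's children a contiguous block)
and new cells can only enter at the open end. For a hypothesis, each cell
contributes the product of three probabilities:

* a Gaussian penalty on the relative change of total area between the
  cell and its offspring, \(\exp[-((A_c/A_p - 1)/\sigma_A)^2/2]\) with
  \(\sigma_A = 0.2\);
* a Gaussian penalty on the centroid displacement, whose expectation
  is half an average bacterium length per division (the average taken as
  the median detected length in the previous frame) and whose scale
  defaults to half that length;
* the prior of the event type: 0.9 persistence, 0.07 per division, 0.03
  lysis; a cell entering at the open end carries the lysis-scale prior,
  so rare events stay rare but possible.

The per-cell terms multiply into the hypothesis probability and the argmax
is applied; ties (within relative 1e-12) break deterministically by
fewest events, then fewest divisions, then lexicographic order of the
child-count vector. Persisting cells keep their global id; division
children and new cells get fresh ids, with the parent recorded. The
functional forms are the package's own choice -- only the three-factor
structure and the half-length displacement rule are inherent to the
method; Gaussian penalties are the least-structured choice with the
stated scales.

### Quantification

Length and width are the major and minor axis lengths of the mask's
second-moment ellipse (the standard region-property convention,
rotation-invariant; a geodesic skeleton length would differ for strongly
bent cells, which are out of scope). Area is the pixel count. Per
fluorescence plane, the background is the mean over the empty parts of the
same channel in the same frame, and each cell reports its mean intensity
minus that background (the mean, not the median, keeps the report linear
in the plane's intensity, which the tests assert); a fully occupied
channel borrows the frame-level background of the other channels with a
warning. All outputs are in pixels; physical calibration is a CSV-level
multiplier the acquisition metadata owns, not the package.

## The synthetic generator

Every stage is validated against `mm_generate_series()`, which renders a
row of dead-end channels (default: 8 channels of 150x12 px at 40 px
pitch, inside the detector's default length bounds so the defaults are
exercised, not tuned around), populated with rod-shaped cells (rectangles
with semicircular caps, 7 px wide, initial lengths 18--28 px) that grow
linearly (2 px/frame), divide at a length threshold or on schedule into
two half-length children, and lyse (vanish) on schedule. Growth pushes
cells towards the open end only -- the dead end blocks the other
direction -- and the gap left by a lysed cell persists rather than letting
downstream cells slide up, matching the physics the tracker assumes.
Brightfield frames are a bright field (0.75) with dark walls (0.30) and
dark cells (0.35); phase frames invert the scheme and add a 1.5-px halo.
Gaussian pixel noise defaults to 5% of the background-to-cell contrast,
plus a 5% linear illumination ramp; fluorescence planes carry per-cell
levels (mean 100, s.d. 20, inherited at division) over background 10 with
additive noise. The scene drifts rigidly by a per-frame offset and the
device can be tilted. The generator returns the exact channel and
bacteria label images, lineage and shifts it rendered, so detection,
tracking and the evaluation metrics are all checked against constructed
truth rather than against the pipeline itself.

What the generator does not emulate: the optical point-spread function
and phase-ring artifacts, cell crowding and mechanical deformation,
filamentous or bent morphologies, focus drift, and photobleaching.
Passing on these fixtures therefore demonstrates the algorithmic chain is
correct and self-consistent at realistic contrast and noise, not that any
particular microscope's images will segment equally well; on real data
the scale factor and the size/width bounds are the knobs to revisit.

## Numerical and robustness choices

* Problem sizes: validation runs use 8-channel frames of roughly
  230x400 px, series of 3--5 frames, and 10-series pools for efficiency
  estimates -- large enough for stable percentages, small enough that the
  whole suite runs in minutes on one core.
* Li's threshold is iterated to a 1e-7 relative tolerance with a 200-step
  cap; on pathological multimodal histograms the fixed point is a local
  optimum of the cross-entropy, which is the standard behaviour of the
  iterative algorithm (the tests compare against exhaustive search on
  clearly bimodal data).
* Watershed determinism: region growing and all tie-breaks are
  deterministic, and the whole pipeline is re-run-identical (asserted
  bit-for-bit on labels and CSVs).
* The two-digit year in the filename protocol pivots to 2000--2099; the
  technology postdates 2000.
* Fluorescence planes are taken from the pages of the same TIFF after the
  detection plane; a sibling-file layout can be handled by loading planes
  separately and constructing frames in code.
* Degenerate inputs: constant images are rejected for skewness and
  thresholding (undefined); empty channels yield zero detections by
  construction of the frame-level threshold; a channel fully covered by
  cells borrows its fluorescence background from the frame.

## Known limitations

* A newborn daughter lying against a much longer neighbour can still be
  mis-partitioned in a minority of frames (the response mask bridges the
  2-px gap and the recovery cut lands a few pixels off); on synthetic
  series this leaves single-frame split/merge errors in roughly one in
  ten runs, with link-level tracking efficiency staying above 95%. This
  mirrors the known behaviour of this class of pipeline, where detection
  efficiency is high but single-label accuracy is the weaker number.
* Tracking scores consecutive frame pairs only; a cell lost for one frame
  is not re-linked across the gap.
* Curved or branched channel geometries, and devices open at both ends,
  are out of scope by design.
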