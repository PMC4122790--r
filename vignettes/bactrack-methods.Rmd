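---
title: "Methods: skeleton-guided tracking of packed worm-shaped bacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: skeleton-guided tracking of packed worm-shaped bacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

Mycobacteria and similar organisms grow as closely packed microcolonies
of worm-shaped cells. In phase contrast the colony interior often shows
no intensity contrast between adjacent cells, and division produces no
visible constriction, so watershed- or contour-based segmenters that work
for *E. coli* or *Caulobacter* fail. What these movies do offer is
temporal continuity: at typical acquisition intervals (here 10 min) a
cell's outline changes only slightly between frames.

bactrack therefore treats segmentation as *propagation*. The model
assumptions are:

* cells are tubes of roughly constant width `2w + 1` px around a curved
  midline, growing (almost) only at their poles;
* frame-to-frame changes in shape and position are small compared with
  the cell width;
* most, but not all, boundaries between juxtaposed cells show at least
  some edge contrast;
* division events are identified by the user (there is no reliable image
  cue), as are the founder outlines on the first frame.

# The propagation step

For a new frame the edge map is computed once: Sobel gradient magnitude
(3×3 kernels, border replicated, rescaled to 0–255), an automatic
threshold, and Zhang–Suen thinning to one-pixel-wide edges. IsoData
(iterative intermeans) is the default threshold; `threshold_gallery()`
renders all six supported methods side by side so a user can pick the one
that suits their contrast, which mirrors how an analyst would choose
interactively.

Each cell then goes through four stages:

1. **Skeletonize** the previous outline (Zhang–Suen again). A mask that
   thins to a single pixel is treated as two coincident poles.
2. **Re-fit** the skeleton to the new edges. A pixel within `w` of the
   skeleton is admitted iff the Euclidean distance `d` to the nearest
   edge pixel satisfies `w - 0.5 ≤ d ≤ w + 2`. The lower bound is the
   disk-fit condition — the disk of radius `w` centred on the pixel fits
   inside the detected boundary — with a half-pixel tolerance because a
   thinned diagonal edge line passes within `sqrt(2) (w-1)`-ish of the
   true midline on a discrete grid (for `w = 3` the midline of a
   diagonal tube sits at `d = 2.83`). The upper bound stops the band
   from wandering into edge-free background (through a local gap in the
   halo, say). The admitted set is a narrow band along the cell's new
   medial axis; only the connected components nearest the previous
   skeleton are kept, with the contact radius widening from 1 to `w` to
   tolerate displacement.
3. **Elongate the poles.** The band is thinned; from each endpoint the
   pole direction is the unit vector from the skeleton pixel `k = 5`
   steps inward (walking along the skeleton; at a branch or short limb
   the farthest available pixel is used; a zero vector falls back to a
   full disc). Candidates in the outward half-disc of radius `p` are
   admitted in order of increasing distance from the endpoint if they
   pass the same disk-fit test and are 8-connected to the cell (so
   elongation cannot jump across an edge or halo ring); admission stops
   the moment the projected reconstructed area would exceed
   `area(prev) + a`.
4. **Reconstruct** by smearing the Euclidean disk of radius `w` along
   the fitted axis (band plus elongation pixels), clip to the image,
   keep the largest 8-connected component. If re-fitting shifted the
   axis enough that the result still exceeds the cap, pixels farthest
   from the axis are trimmed until it holds, so
   `area(new) ≤ area(prev) + a` on every automatic propagation.

## Why the disk-fit (≥ w) reading

The admission test in stage 2 could plausibly be "within `w` of an
edge" (≤ w) rather than "the disk fits" (≥ w − ½). We implemented both.
With ≤ w the admitted set is the whole tube cross-section plus pixels on
the far side of the thinned edge line; smearing a disk of radius `w`
along that set then inflates every mask up to its area cap on every
frame, and the error compounds until masks are twice their true size.
With the disk-fit reading, reconstruction is an opening-like operation
that reproduces the tube up to its detected boundary, and the propagation
is a fixed point on a static movie (verified in the tests: a zero-growth,
zero-noise movie propagates with IoU exactly 1 between consecutive
frames). The disk-fit reading is also the only one under which "smear the
disk along the adjusted area" reconstructs the cell rather than a larger
one, so we regard it as the intended semantics.

## Round-robin order and contested pixels

Cells are processed in alphabetical name order. Ownership is resolved in
three passes: the re-fitted bands of *all* cells are computed first and
contested band pixels go to the nearest previous-frame skeleton; pole
elongation may not enter the body zone within `w − 1` of a neighbour's
band; and pixels reconstructed by several cells go to the nearest band.
Exact ties everywhere follow the processing order, so for a genuinely
ambiguous joint area (no edge, equal distances) the alphabetically
earlier cell wins — the algorithm is order-dependent precisely and only
there. A pure first-come rule (earlier cell keeps everything it can
reach) was tried first and rejected: at junctions without edge contrast
the earlier cell's reconstruction creeps ~3 px per frame along its
neighbour's axis, and over ten frames can swallow it entirely. The
proximity rule anchors the boundary to the previous frame's geometry, so
mis-assignments do not compound.

## Parameters

| parameter | meaning | unit | default |
|---|---|---|---|
| `cell_width` (`w`) | disk radius for the fit test and reconstruction; cell half-width | px | 3 |
| `max_pole_elongation` (`p`) | half-disc radius probed beyond each pole | px | 10 |
| `max_area_increase` (`a`) | hard cap on area growth per frame step | px | 35 |

`w` is a radius: at 0.129 µm/px the default gives a 7-px ≈ 0.9 µm wide
cell, appropriate for mycobacteria. `a` is interpreted as absolute pixels
per frame step (it is configured alongside two pixel-valued parameters,
and an absolute cap is what the admission loop needs); 35 px ≈ 3× the
true per-frame growth of a default synthetic cell, leaving slack for
re-fitting without allowing runaway. The pole-direction depth `k = 5` and
the band upper tolerance `+2` px are fixed implementation constants, not
user parameters.

# Registration

Stage drift is modelled as integer whole-frame translation between
consecutive frames, estimated on the phase channel by maximizing the
normalized cross-correlation over all shifts up to `max_shift`, with ties
broken by smallest `|dy| + |dx|`, then `dy`, then `dx` (so two constant
images yield (0, 0)). Pairwise shifts are accumulated relative to frame 0
and the inverse is applied identically to every channel; vacated pixels
take the frame's modal intensity. A correlation peak below 0.2
contributes a zero shift and a logged warning. Sub-pixel and rotational
registration are out of scope.

# Lineage conventions

The annotated division frame is the first frame of the daughters'
existence; the parent's last frame is the one before. Daughter "A" is
simply the first mask the user supplies — no pole identity is implied,
but the order is recorded. Founder cells present at frame 0 are flagged
left-censored for interdivision statistics. `dead` cells keep their last
outline for display; `ignored` cells are dropped from processing
entirely; both leave measurement aggregates.

# Measurements

Statistics are always taken on the original images (any bit depth); the
8-bit working copies — produced by one global min–max rescale over the
whole sequence, so that temporal intensity dynamics survive — exist only
for tracking and display. Optional erosion (exact Euclidean disk)
excludes the membrane region. Background correction subtracts the mean
of one user-defined cell-free region, per frame and channel; no
flat-field model. Cell length is the skeleton pixel count times the
pixel size, which is consistent with the tracking machinery but
imprecise near the poles by about `w` pixels.

Because the source material does not fix a growth-rate formula, two
complementary definitions are stored: the linear elongation rate (slope
of length vs time, µm/h) and the exponential area rate (slope of
log area vs time, 1/h). Overwriting a stored outline deletes its
measurements — they describe the old pixel set — so measuring always
follows segmentation.

The shipped ratio query (`ratio_query()`, also under `inst/sql/`)
computes, per frame, the across-cell mean and SD of the
background-corrected numerator/denominator ratio in pure SQL, excluding
cells with non-positive denominator; `ratio_timecourse()` is the R
equivalent and the two are cross-checked in the tests.

# Lineage trees

`layout_tree()` gives each leaf a unit lane and each internal cell the
midpoint of its daughters, daughter A left of B, which is deterministic
and crossing-free for any lineage (verified by brute force up to four
complete generations). Branch length is lifetime in minutes. Styling is
per-frame piecewise constant: each frame of each branch is one SVG line
segment whose width is an affine map of one variable and whose colour
comes from a sequential palette over another; segments carry
`data-cell`/`data-frame` attributes so figures are machine-checkable.
Frames lacking a styled variable are drawn as neutral grey hairlines and
reported, not invented. Annotated frames (e.g. a medium switch) appear
as dashed horizontal lines at their times.

# The synthetic movie generator

`simulate_movie()` exists because validating a semi-automated tracker
needs ground truth that real movies cannot provide without the very
manual labour the tool is meant to remove. It emulates the features that
make these movies hard:

* constant-width tubes around elongating poly-line backbones, growth
  strictly polar with a small direction wander;
* growth directed away from the septum after division (the new pole
  lags, as in mycobacteria), so daughters stay abutting end to end with
  no division-site cue;
* chain packing: pole-to-pole contacts relax axially — polar growth at
  a blocked septum pushes the chain apart — and flank contacts relax
  laterally to tube tangency, both under a 1.75 px/frame displacement
  budget so apparent motion stays in the slight-change regime;
* a configurable fraction (default 0.5) of touching cell pairs whose
  shared boundary shows *no* edge contrast, the rest getting a thin
  bright separation line;
* phase rendering as dark tubes with a smoothly decaying halo
  (exponential, 1.5 px scale), so the only sharp contour is the cell
  boundary, as in defocused phase contrast;
* two fluorescence channels: an inducible one that steps up
  `induction_fold` (default 6) at `switch_frame`, and a constitutive
  reference, both with ~10 % cell-to-cell lognormal heterogeneity and
  partition noise at division.

Defaults describe a slow-growing mycobacterium-like colony at
0.129 µm/px and 10 min/frame: width 0.9 µm, elongation 1.2 µm/h,
division near 6 ± 0.4 µm, additive Gaussian noise of 4 grey levels
(clipped to 8 bit). An `exponential_area` growth mode (straight cell, no
wander, area following `exp(rate · t)` exactly up to pixel quantization)
supports parameter-recovery tests. A fixed seed determines every pixel.

What the generator does *not* emulate: phase-contrast optics (no PSF,
no shade-off), shot noise, photobleaching, illumination gradients,
V-snapping division geometry, cell death or lysis, and debris. Passing
the synthetic benchmarks therefore shows that the algorithm is correct
under its own assumptions and robust to packing, missing edges and
moderate noise — not that any particular real movie will track at the
same accuracy; on real data the manual-correction workflow remains part
of the method.

# Numerical choices and degenerate inputs

* Coordinates are (row, col), 0-based, origin top-left, everywhere
  including the datastore; masks serialize as row-wise run-length text.
* Frame index comes from the last integer group in the file name, ties
  broken lexicographically; frame times must be strictly increasing.
* The IsoData iteration starts at the midpoint of the occupied range,
  and a (rare) limit cycle accepts the current iterate; the returned
  threshold always satisfies the intermeans fixed point (checked against
  an exhaustive scan in the tests). Single-valued images are a
  degenerate-histogram error; the threshold gallery reports, rather than
  propagates, per-method failures.
* A constant image has zero gradient everywhere, hence no edges: every
  cell on such a frame is flagged `needs-attention` rather than guessed.
* Erosion larger than the mask radius is an explicit error, not an
  empty result.
* Li's threshold operates on intensities offset by +1 so the logarithms
  are defined for images containing 0.
* SQL access through `run_sql()` is read-only (single SELECT/WITH
  statement); CSV export serializes doubles with 17 significant digits
  so values round-trip exactly.

# Problem sizes in the test suite

The suite validates against independent oracles at sizes chosen to keep
a full run near a minute: 200 random 64×64 blobs for thinning, 100
random histograms for IsoData, 100 random guide sets for reconstruction
geometry, 100 noisy registration trials, one 30-frame 192×192 colony
(three divisions, seven cells) for end-to-end tracking, and 1000 random
masks for datastore round-trips. The acceptance script repeats the same
computations from scratch under a caller-supplied seed.

# Known limitations

* Integer-pixel registration only; large rotations or elastic drift
  need external preprocessing.
* The tracker cannot split a cell: divisions are user-annotated by
  design, and a missed division shows up as one over-long cell.
* Boundaries between cells with no edge contrast are assigned by
  proximity and order; they are plausible, not evidential, and are the
  places where manual correction is expected.
* Masks can shrink only where edges or a neighbour's claim push them
  back; a cell that shrinks rapidly in truth will lag by a few frames.
* Cell length via skeleton pixel count undercounts curved cells
  slightly and is uncertain near the poles by about `w` px.
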