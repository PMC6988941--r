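---
title: "Simulated prosthetic vision: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated prosthetic vision: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spvtools)
```

## Why process the camera image at all

A retinal implant converts a camera feed into electrical stimulation of a
small electrode array. Perceptually this yields a grid of phosphenes — dots
of light — at very low spatial resolution, with a few distinguishable
brightness levels, a narrow field of view, and a fraction of electrodes that
elicit nothing. Downsampling a raw photograph into that budget destroys most
of what makes an indoor scene legible: clutter becomes noise and object
boundaries dissolve. The alternative studied here is to spend the bandwidth
deliberately, transmitting only a schematic of the scene: the silhouettes of
a few large objects and the structural edges of the room.

`spvtools` implements that schematic representation (SIE-OMS), the two
standard baselines it is compared against (Direct and Edge), the phosphene
simulator that turns any of the three into a percept, and the experiment
machinery for measuring how well observers recognize objects and rooms from
the percepts.

## The phosphene simulator

The simulator is a four-stage pipeline, each stage a separate exported
function so any of them can be studied in isolation
(`sample_activations()`, `quantize_levels()`, `make_dropout()`,
`render_phosphenes()`; `simulate_phosphenes()` composes them).

**Sampling.** The stimulus image is partitioned into `rows × cols`
rectangular tiles; tile sizes are `floor(n/k)` pixels with edge tiles
absorbing remainders, and each electrode takes the arithmetic mean of its
tile. Mean pooling (rather than max or center sampling) is the choice
consistent with driving the implant from average regional brightness, and it
makes the Direct method exactly "average the brightness over the region
covered by each phosphene".

**Quantization.** Intensities in [0, 1] map to `L` integer levels (default
`L = 8`, the number of luminance levels attainable in implant wearers) as
`round(x · (L − 1))` with halves rounded *up*. Half-up rounding is a
deterministic, documented tie-break; the map is monotone and idempotent on
already-quantized values, which the tests assert by enumerating the bin
edges `k/(L−1) ± 1/(2(L−1))`.

**Dropout.** Electrodes that elicit no phosphene are modelled as i.i.d.
Bernoulli(`dropout_rate`) dead sites (default 10%, the standard literature
value). One mask is drawn per *session* and reused across stimuli — dead
electrodes are damage to the implant, not noise in the frame. The seed is
part of the configuration, so a session is exactly reproducible; the
alternative (resampling per image) was rejected because it would let
information leak through dropout averaging over a trial sequence.

**Rendering.** An alive electrode at level `ℓ > 0` draws an isotropic
Gaussian dot at its lattice point with peak `ℓ/(L−1)`. Both brightness and
size grow with the sampled intensity; with no stated functional form for the
size law, linear scaling was chosen and exposed through the configuration
(`σ_ℓ = sigma_fraction · spacing · ℓ/(L−1)`). Defaults
`sigma_fraction = 0.25` make adjacent max-level dots just touch at 2σ, a
geometry that keeps the grid legible without visible gaps. Dots are
truncated at `truncate_sigmas = 3` σ so the background far from any lit
electrode is exactly zero, and overlapping dots combine by pointwise
maximum, which guarantees luminance never exceeds 1 (summation would
saturate and bloom). The `field_of_view_deg` parameter (default 20°, the
viewing geometry of a screen at 1 m) is carried as metadata; rendering
itself works in pixels.

## The three stimulus methods

All three methods are shape-preserving maps from a scene raster to a
stimulus raster in [0, 1]; resizing real photographs to a working resolution
(short side 512 px, comfortably above the 32×32 grid) is done by
`load_scene()` *before* the methods, so the methods themselves stay exact on
toy inputs.

**Direct** converts color to luminance with ITU-R BT.601 weights
(0.299 R + 0.587 G + 0.114 B) and passes it through; the per-phosphene
averaging lives in the simulator's sampling stage.

**Edge** runs a Canny detector (Gaussian σ = 1, hysteresis thresholds
0.1/0.2 — the defaults of the widely used reference implementation) and
dilates the binary edges with a radius-1 disc so 1-px edges survive
phosphene-resolution rendering (a 1-px line becomes 3 px). The detector is
implemented in the package (no installed R package provides one): smoothing
and Sobel gradients use direct separable convolution rather than FFT
filtering, because exact summation keeps the two-pixel plateaus of sharp
step edges exactly tied and the non-maximum suppression tie-break then thins
them deterministically to a single closed contour; hysteresis uses
8-connected components.

**SIE-OMS** is built in three steps with the intermediate objects exposed:

1. `filter_instances()` keeps only classes whose silhouette is identifiable
   at implant scale (the default set: chair, table, couch, toilet, bath,
   sink, bed, oven, microwave, refrigerator, laptop).
2. `stack_instances()` sorts ascending by detector confidence and
   `render_oms()` paints in that order, so the most confident instance owns
   every contested pixel. The justification is empirical: detection
   confidence falls with occlusion (an occluded object presents an
   incomplete shape), so score order approximates depth order without a
   depth sensor. Interiors are painted gray (0.5) and silhouettes white
   (1.0) — the contour is the morphological gradient of the mask, thickened
   to ~2 px — and the layer is finally closed with a radius-1 disc to reduce
   aliasing. All levels and radii are configurable; none are prescribed
   numerically by the source experiments, so the defaults are package
   choices documented here.
3. `compose_sie_oms()` binarizes the structural-edge probability map at 0.5,
   thickens it to ~2 px, draws it at full white, then overwrites with every
   nonzero OMS pixel: edges are always background, objects always
   foreground. Bright (1.0) edges were chosen over an intermediate gray
   because the layout lines are the only depth cue in the representation.

## The synthetic scene generator

Testing the pipeline end-to-end needs scenes with *exact* ground truth, so
`generate_scene()` builds them rather than downloading them. A scene is a
one-point-perspective box room: the pinhole projection of a cuboid interior,
with the back wall a centered rectangle (its size set by the camera
parameter, drawn from [0.35, 0.55] of the frame) and the wall/floor/ceiling
intersections projecting to that rectangle's edges plus the four segments to
the frame corners. Those segments *are* the ground-truth structural-edge
map, rasterized at one pixel; the five projected faces get distinct
luminances, scaled by a lighting-contrast parameter, so the Canny baseline
has real gradients to find.

Objects are parametric silhouettes — unions of rectangles and ellipses per
class (a toilet is a cistern rectangle, a bowl ellipse and a base; a
refrigerator is a plain tall rectangle) — placed on the floor band,
far-to-near. This is sufficient fidelity because every downstream consumer
uses only masks and luminance, never texture. Visible masks are computed by
z-buffering, and each instance's confidence score is
`clamp(1 − 0.8 · occluded_fraction + ε, 0, 1)` with ε ~ U(−0.05, 0.05): the
0.8 slope and ±0.05 noise are generator choices (the modelled premise is
only that confidence falls with occlusion; the tests assert a Spearman
correlation below −0.5 across 200 random scenes). Scenes default to
256 × 256 px — 8 × 8 px per phosphene tile at the default grid, enough
resolution for every method while keeping a 300-scene batch cheap — and are
bit-reproducible from their seed. `generate_batch()` derives per-scene seeds
from one master seed and emits balanced room categories (50 per room
reproduces the 300-scene, 900-stimulus bookkeeping of a full study).

What the generator does *not* emulate: photographic texture, lighting
variation within a surface, curved or cluttered room geometry, and detector
mask errors (synthetic masks are pixel-perfect; real instance segmentation
is not). Passing tests therefore demonstrate the correctness of the
*pipeline arithmetic* — compositing, simulation, scoring — not the
recognition performance obtainable on photographs.

## Experiment scheduling and scoring

`make_plan()` reproduces the trial protocol: a seeded random permutation
interleaving the three methods (stratified so method counts differ by at
most one), each scene shown at most once per subject, 10 s per image and a
30 s pause every 15 images. The published protocol shows 54 images per
subject across 18 subjects against 900 stimuli, which only reconciles if
stimuli are shared between subjects; the planner therefore takes
`images_per_subject` as a parameter and permits cross-subject overlap.

`score_objects()` grades a trial correct when *any* reported class matches a
ground-truth class after synonym mapping (per-image grading; ovens and
microwaves form one group, "dining table" matches "table" — the table is
user-editable). An empty or timed-out response is "not answered" (NA),
tallied separately from incorrect.

`score_rooms()` builds the 6 × 7 room confusion matrix (six actual rooms ×
six predicted rooms + NA) and derives recall in two variants — over answered
trials only, or over all trials — and precision as correct over
times-predicted. NA never counts as a prediction, so precision is identical
in both variants; a never-predicted room yields `NaN` precision, flagged
rather than zeroed. Percentages are reported half-up to two decimals, which
is what makes the published cell values (e.g. a recall of 88.64 from 39
correct of 44 answered) exactly reproducible from integer counts.
`summarize_responses()` reports per-method percentage correct with a
normal-approximation 95% CI half-width `1.96·sqrt(p(1−p)/n)` — the pooled
binomial approximation, since the published tables report a mean ± value
without naming the interval method.

## Numerical choices and degenerate inputs

- Quantization ties: half-up, asserted at every bin edge.
- Rendering: dot overlap by maximum; truncation radius 3σ; background
  exactly 0 beyond it.
- Canny: direct convolution for exact plateau ties; NMS direction quantized
  to 4 sectors (sub-pixel interpolation would marginally relocate edges but
  none of the package's guarantees depend on it).
- Empty instance lists render an all-zero OMS layer; an empty edge map
  leaves the OMS layer unchanged.
- Confusion rows with no answered trials and columns with no predictions
  produce `NaN`, never silent zeros.
- All user-facing errors carry condition classes (`spv_input_error`,
  `spv_config_error`, `spv_missing_file_error`, `spv_malformed_json_error`,
  `spv_mask_mismatch_error`, `spv_generation_error`, `spv_planning_error`,
  `spv_validation_error`) so callers can branch on them.

## Problem sizes used in the test suite

The dropout calibration is checked over 10,000 seeded masks (binomial mean
and variance within 3 SE); the batch bookkeeping over the full 300-scene,
900-stimulus study size at the generator's native 256 px; oracle
equivalences (z-buffer compositing, brute-force rendering, tile means,
confusion tallies) on small instances (16 × 16 masks, 4 × 4 grids, 1,000
trial logs) where exhaustive per-pixel loops are feasible.

## Known limitations

- Phosphene distortions observed in patients (elongated "comets", temporal
  fading, eccentricity-dependent size) are not modelled; dots are static,
  isotropic Gaussians.
- The simulator renders to a square frame with the grid centered;
  non-square electrode layouts are supported but rendered on the same
  square canvas.
- The Canny implementation targets the standard parameterization but is not
  a bit-exact clone of any particular library.
- Human recognition performance cannot be reproduced computationally;
  the experiment module reproduces the *arithmetic* of published accuracy
  and confusion tables from response counts, not the responses themselves.
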