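---
title: "Methods: the segmentation network, the synthetic data, and the pupillometry pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the segmentation network, the synthetic data, and the pupillometry pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pupilkit measures pupil size, eye position and blinks from grayscale eye
videos. This vignette documents the model and the procedures in enough
detail to reimplement them, states every tunable that matters with its
default and rationale, and is explicit about what the synthetic benchmarks
do and do not show about real recordings.

## The segmentation network

The segmenter is a constant-width "hourglass" encoder–decoder. All hidden
convolutions have 16 kernels of size 3×3, ReLU activations and same-shape
zero padding. The layout, for an input of side $N$ (default 128, any
multiple of 4 works):

* **Encoder** — 3 resolution levels with 2 convolutions each; after levels
  1 and 2, a 2×2 max pooling halves the resolution, giving feature maps at
  $N$, $N/2$ and $N/4$ (the bottleneck).
* **Decoder** — per level: parameter-free nearest-neighbour ×2 upsampling,
  channel concatenation with the same-resolution encoder output (32
  channels), then a 3×3 fusion convolution back to 16 channels and one more
  3×3 convolution.
* **Pixel head** — a 1×1 convolution maps the final 16 channels to one
  logit per pixel.
* **Eye/blink head** — global average pooling of the 16-channel bottleneck
  map, then a fully connected 16→2 layer (34 parameters) for the eye and
  blink logits.

All three outputs pass through an element-wise sigmoid at inference. The
published architectural constraint for this network family is its parameter
budget: 0.03 M. The layout above sums to 25,699 trainable scalars
(weights + biases), which `build_segmenter()` asserts rounds to 0.03 M at
construction time for the default topology. The depth (3 levels) and the
two-convolutions-per-level pattern are the package's own choice: they are
the smallest classic-U-Net layout whose parameter count lands on that
budget. Nearest-neighbour upsampling (rather than transposed convolution)
and the absence of normalization layers are likewise choices made to stay
within the budget and keep the layer inventory to exactly the pieces listed
above.

The forward and backward passes are implemented in C++ (RcppArmadillo):
feature maps are stored as $(HW) \times C$ matrices in column-major pixel
order, so each 3×3 convolution is an im2col gather followed by one BLAS
matrix product. Internals run in single precision — standard practice for
CNN training and about 4× faster here; parameters and gradients cross the R
boundary in double precision. The backward pass is verified in the test
suite against finite differences of an independent double-precision
direct-convolution reference implementation.

## Loss, optimizer, training recipe

The loss is the sum of binary cross-entropies over all outputs: the
pixel-wise **mean** BCE of the probability map plus the BCEs of the eye and
blink outputs. Inside the C++ training path the BCE is computed from logits
in the numerically stable form $\max(z,0) - zy + \log(1+e^{-|z|})$; the
R-level `total_loss()` (on probabilities) clips to $[10^{-7}, 1-10^{-7}]$,
so a perfectly confident correct prediction scores at most
$-3\log(1-10^{-7})$.

Optimization uses AdaBelief with learning rate 0.001 for 750 epochs (both
the published recipe and the package defaults), $\beta_1 = 0.9$,
$\beta_2 = 0.999$, and the stabilizer $\epsilon = 10^{-16}$ added inside the
second-moment update — the reference AdaBelief formulation; a larger
$\epsilon$ noticeably slows convergence on this model. Batch size is not
published; the default is the conventional 32 and it is exposed in
`train_config()`. Datasets are split 70%/20%/10% into train/validation/test
by a seeded uniform shuffle, with floor rounding for train and validation
and the remainder to test (so 100 frames split 70/20/10 and 10 frames split
7/2/1). After every epoch the mean Dice on the validation set (map
thresholded at 0.5) is recorded, and `train()` returns the parameter
snapshot that maximized it.

**Dice.** For binary masks $A, B$: $2|A \cap B| / (|A| + |B|)$, defined as 1
when both masks are empty — blink frames carry empty reference masks, and
empty-versus-empty is a perfect prediction, not a 0/0. mDice is the mean of
per-image Dice over a set.

**Augmentation.** Training-time transforms: rotation about the image
centre, scaled random crops, horizontal/vertical flips, and Pillow-style
brightness/contrast/sharpness enhancement, then resizing to the network
input. Geometric transforms are applied identically to image and mask, the
image resampled bilinearly and the mask by nearest neighbour so labels stay
binary; photometric transforms touch only the image. The magnitudes
(±30°, crop scale 0.7–1.0, flip probability 0.5, photometric factors
0.7–1.3) are not published for this family of models; they are defaults
exposed in `augment_policy()`, not claims about the original recipe.
Validation and test frames instead get a deterministic 128×128 crop centred
on the ground-truth pupil centroid (`eval_crop()`), clamped to the image,
falling back to the image centre for empty masks.

## Synthetic eye data

The generator stands in for the annotated eye-image corpus the model family
was developed on (thousands of IR dark-pupil mouse, two-photon bright-pupil
mouse, and IR human eye images, with roughly 13.4% blink frames — the
default `blink_fraction = 0.134`). Each frame is composed on a $[0,1]$
gray canvas: sclera background, iris disk centred on the pupil, rotated
pupil ellipse (darker than the iris for the IR regimes, brighter for the
two-photon regime), optional specular highlights, an eyelid occluding from
the top by $1 - \text{openness}$ with a dark lash line at its margin, and
additive Gaussian noise. Per-class level, size and noise ranges are fixed
in `random_appearance()`; a small fraction of eye-absent noise frames gives
the eye head negative examples.

Conventions, stated once and used everywhere: coordinates are 0-based,
x rightwards, y downwards, pixel centres at integer coordinates; a pixel
belongs to the ellipse iff its centre satisfies the ellipse inequality (no
subsampling), so the rasterized area matches $\pi a b$ to within one
perimeter band of pixels, which is what the tests assert. Intensities are
floats in $[0,1]$ and are quantized to 8 bits only on PNG export. A frame
whose eyelid openness is below 0.15 is labelled a blink and rendered fully
closed — raters flag blinks without a quantitative criterion, and this
cutoff keeps the labelling consistent with the all-zero mask invariant
(blink ⇒ empty mask).

Sequences (`make_sequence()`) drive the pupil area as baseline plus
event-locked transients (difference-of-exponentials kernels, default rise
0.5 s and decay 2 s, normalized to their analytic peak) plus an optional
reflected random walk; blink epochs are half-open intervals
$[\text{onset}, \text{onset}+\text{duration})$ in frame time, avoiding
double counting at boundaries. The ground-truth table carries the analytic
per-frame area with blink frames flagged. An optional slow sinusoidal
centre wander (`center_drift_px`) exercises ROI tracking.

**What passing on synthetic data shows — and does not.** The generator
reproduces the geometry and the photometric contrasts of the three imaging
regimes, blinks, occlusion, specular spots and modest noise. It does not
reproduce eyelashes, fur, wet reflections, motion blur, compression
artefacts, off-axis gaze foreshortening or genuinely deformable lids. A
model reaching Dice ≈ 0.9 here demonstrates that the architecture, loss,
optimizer and pipeline plumbing are correct and sufficient for this image
family; it says nothing about performance on real eyes, which requires
training on the real annotated corpus with the full 750-epoch recipe.

## The measurement pipeline

Per frame: crop the ROI window (network input size) → preprocess → predict
→ threshold the map → morphological refinement → measure. Choices that were
genuinely open and are fixed here:

* **Preprocessing order**: inversion first (`1 - image`), then
  `image * contrast + brightness`, clip, then the gamma power, clip. The
  feature set is given by the tool family; the order is not, so it is fixed
  and documented.
* **Thresholding** is closed at the cutoff (`map >= t`), making `t = 0` the
  all-ones mask — a clean boundary case, and mask area is non-increasing in
  `t` (property-tested).
* **Morphology** (when enabled): binary opening with the 3×3 cross, then
  keep only the largest 8-connected component. This is the minimal
  "refinement" that removes speckle and enforces a single pupil; the exact
  recipe is unpublished, so it is a package decision. Opening is applied
  before component selection; the output never adds pixels outside the
  input mask and is idempotent.
* **Species presets** for offline video analysis: threshold 0.25 with
  morphology off ("human"), 0.15 with morphology on ("mouse"), 0.5 with
  morphology on ("2P-mouse") — the published preset triple.
* **ROI following** re-centres on the current frame's measured centroid
  with no temporal smoothing, clamped to the frame; the simplest faithful
  reading of centre tracking. Empty masks leave the ROI unchanged.
* **Area and centroid**: area is the raw foreground pixel count (px²);
  the centroid is the mean 0-based pixel coordinate mapped to source-frame
  coordinates; a zero-area frame has an undefined centroid, exported as
  empty CSV fields rather than zeros.
* **CSV contract**: header exactly
  `frame,time_s,area_px,pupil_x,pupil_y,eye_prob,blink_prob,trig1,trig2,trig3,trig4`,
  numerics at 6 significant digits, lossless round-trip at that precision.
  Four boolean trigger channels reproduce the push-button event interface;
  events are supplied as a `(time_s, channel)` table and land on the frame
  containing the timestamp.

Video input is a directory of PNG/TIFF frames, an in-memory list, or a 3-D
array; frame rate comes from `--fps`/the `fps` argument.

## Time-series analysis

* **Blink epochs**: maximal runs with blink probability ≥ 0.5, merged when
  separated by fewer than 2 frames. Both numbers are unpublished internals
  of the embedded blink detector; 0.5 is the symmetric default for a
  sigmoid output and the merge suppresses single-frame flicker.
* **Deblinking**: samples inside epochs are replaced by linear
  interpolation between nearest valid neighbours (edge epochs hold the
  nearest valid value), then the whole trace is median filtered over 0.5 s.
  The window is `round(0.5 · fps)` samples forced odd by +1 (15 samples at
  30 fps): the duration is published, the discretization is not.
* **Event alignment**: one row per event on the trace's frame grid; a 15 s
  window at 30 fps gives exactly 450 samples. Events whose window leaves
  the trace are dropped with a warning. The baseline defaults to the full
  pre-onset half of the window; the published analyses centre a 15 s window
  on the stimulus without printing the baseline span, so the span is an
  exposed parameter.
* **Z-scoring**: per trial, $z = (x - \bar{x}_\text{baseline}) /
  s_\text{baseline}$ with the trial's own baseline mean and SD (n−1
  denominator); zero-SD trials are excluded with a warning rather than
  producing infinities.
* **Locomotion**: a sample is "moving" iff speed ≥ 10% of the session
  maximum (closed at the boundary); the tag is invariant to positive
  rescaling, and an all-zero trace is all-stationary (the 10%-of-zero rule
  would otherwise tag everything moving).
* **Pointwise significance**: for each post-onset timepoint, the paired
  differences between trial values and trial baseline means are tested with
  a t statistic (computed vectorised; verified against `stats::t.test`),
  and p values are Benjamini–Hochberg adjusted across timepoints via
  `stats::p.adjust`. At least 3 trials are required. Under a pure-noise
  null the suite checks that on average ≤ 5% of timepoints are flagged, and
  that injected 5-SD effects are found.
* **Cross-device agreement**: both traces min–max normalized to $[-1,1]$,
  the lower-rate trace linearly interpolated onto the higher-rate grid
  (e.g. 15 fps camera data onto a 1000 Hz tracker grid), mean absolute
  error over the common support. Constant traces are rejected (their
  normalization is undefined).

## Problem sizes used by the automated checks

The suite trains the full recipe at reduced scale: 500 synthetic frames at
64×64 (the network is resolution-independent; its parameter count does not
change), batch 32, 20 epochs, one fixed seed — about two minutes on one CPU
core — and requires held-out mean Dice ≥ 0.85 (typical result ≈ 0.91). The
pipeline check processes a 40 s, 30 fps sequence (1200 frames) with two
+30% dilation events and two blinks, requiring r ≥ 0.95 between deblinked
and true area on non-blink frames and the event amplitude within 10%.
Reproducing the published test-set mDice of the real corpus is out of scope
for the automated checks: it needs the annotated deposit and the full
750-epoch schedule.

## Known limitations

* No video-container (MP4/AVI) decoding in-process; extract frames to
  PNG/TIFF first.
* The deposit reader auto-detects two layouts (image+mask pairs; annotation
  tables with mask paths, ellipses, or polygons) and fails loudly on
  anything else rather than guessing.
* Gaze is reported in pixels; no calibration to degrees of visual angle and
  no pupil-foreshortening correction.
* The synthetic benchmark bounds implementation correctness, not real-world
  accuracy (see above).
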