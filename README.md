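# pupilkit

Camera-based pupillometry for mice and humans, built around a compact
encoder–decoder segmentation network, for labs that need pupil size, eye
position and blink detection from plain grayscale eye videos — head-fixed
mice under IR illumination (dark pupil), mice under two-photon imaging
(bright pupil), or humans filmed with an IR webcam.

## The model

The core is a small "hourglass" U-Net variant for `128 × 128` grayscale
inputs. Every hidden convolution has 16 kernels of size `3 × 3` with ReLU and
same-shape padding. The encoder halves the resolution twice with `2 × 2` max
pooling; the decoder upsamples by 2 (nearest neighbour) and fuses each level
with the same-resolution encoder map by channel concatenation followed by
convolutions. Three outputs are produced, all through element-wise sigmoid:

- a `128 × 128` map `p(x, y)` of the probability that pixel `(x, y)` belongs
  to the pupil,
- `P(eye)` — the probability the image contains an eye,
- `P(blink)` — the probability the eye is blinking,

the two scalars coming from global average pooling of the bottleneck map
followed by a 2-output fully connected layer. The training loss is the sum
of the binary cross-entropies of all outputs (pixel-wise mean for the map),
minimized with the AdaBelief optimizer (defaults: 750 epochs, learning rate
0.001, 70%/20%/10% split, best validation-Dice snapshot kept). The whole
network has **25,699 trainable parameters (0.03 M)** — small enough to train
in minutes on a CPU.

Downstream, the package measures pupil area as the pixel count of the
thresholded, morphologically refined map; tracks the ROI on the measured
centroid; removes blinks by linear interpolation plus 0.5 s median
filtering; z-scores event-aligned trials by their own baseline
(`z = (x − x̄_baseline) / s_baseline`); tags locomotion ("moving" when speed
≥ 10% of the session maximum); and compares each post-stimulus sample with
the baseline using paired t statistics under Benjamini–Hochberg FDR
correction.

A seeded synthetic-eye generator (`make_training_set()`, `make_sequence()`)
renders all three imaging regimes with exact ground-truth masks, blink
epochs and area dynamics, so every stage is testable end to end without
recorded data.

## Worked example

Train on 500 synthetic frames (64 × 64 for speed; a couple of minutes on one
CPU core), then run the pipeline on a 40 s synthetic recording with two +30%
dilation events and two blinks:

```r
library(pupilkit)

frames <- make_training_set(500, blink_fraction = 0.134, seed = 123,
                            image_size = 64, no_eye_fraction = 0.05)
sp  <- split_dataset(frames, seed = 123)         # 350 / 100 / 50
net <- build_segmenter(segmenter_config(input_size = 64), seed = 123)
fit <- train(net, sp$train, sp$val,
             train_config(epochs = 20, batch_size = 32, seed = 123))
evaluate_dice(fit$model, sp$test)$mean
#> [1] 0.9125461
```

Held-out mean Dice 0.91: the predicted pupil masks overlap the ground truth
almost completely. Now the recording:

```r
spec <- sequence_spec(fps = 30, duration = 40,
                      events = list(list(onset = 10, peak = 0.3),
                                    list(onset = 25, peak = 0.3)),
                      blink_epochs = list(c(5, 0.4), c(32, 0.5)),
                      image_size = 64, seed = 99)
sq    <- make_sequence(spec)
trace <- run_video(sq$frames, fit$model, post = "mouse", fps = 30)

ep <- blink_epochs(trace)   # detected from the network's blink output
ep
#>   start end
#> 1   150 162
#> 2   960 975

db <- deblink(trace, ep)    # linear fill + 0.5 s median filter
ok <- !sq$truth$blink
cor(db$area_px[ok], sq$truth$area_px[ok])
#> [1] 0.9824888
```

The two blink epochs land exactly on the injected ones (5.0–5.4 s and
32–32.5 s at 30 fps), and the deblinked area trace correlates at r = 0.98
with the analytic ground truth. Event-aligned averaging recovers the
injected dilation amplitude:

```r
m   <- event_align(db, c(10, 25), window = c(7.5, 7.5))  # 15 s windows
avg <- colMeans(m$values)
(max(avg[m$time >= 0]) - mean(avg[m$time < 0])) / mean(avg[m$time < 0])
#> [1] 0.3006187
```

i.e. a +30.1% peak versus the +30% injected.

`inst/cli/pupilkit.R` exposes the same functionality as `simulate`,
`describe`, `train`, `eval`, `run` and `analyze` subcommands for shell use.

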