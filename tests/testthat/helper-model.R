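# Shared expensive fixtures, built once per test run. The scaled-down
# training recipe mirrors the full one (AdaBelief, lr 0.001, batch 32,
# summed BCE, best-snapshot selection) on 500 synthetic 64x64 frames for 20
# epochs — sized for a single CPU while leaving the recipe itself intact.

.shared <- new.env(parent = emptyenv())

trained_fixture <- function() {
  if (is.null(.shared$fit)) {
    frames <- make_training_set(500, blink_fraction = 0.134, seed = 123,
                                image_size = 64, no_eye_fraction = 0.05)
    sp <- split_dataset(frames, seed = 123)
    model <- build_segmenter(segmenter_config(input_size = 64), seed = 123)
    fit <- train(model, sp$train, sp$val,
                 train_config(epochs = 20, batch_size = 32, seed = 123))
    .shared$fit <- fit
    .shared$splits <- sp
  }
  list(fit = .shared$fit, splits = .shared$splits)
}

# 40 s dilation/blink sequence processed end to end with the trained model
e2e_fixture <- function() {
  if (is.null(.shared$e2e)) {
    fit <- trained_fixture()$fit
    spec <- sequence_spec(fps = 30, duration = 40,
                          events = list(list(onset = 10, peak = 0.3),
                                        list(onset = 25, peak = 0.3)),
                          blink_epochs = list(c(5, 0.4), c(32, 0.5)),
                          image_size = 64, seed = 99)
    sq <- make_sequence(spec)
    trace <- run_video(sq$frames, fit$model, post = "mouse", fps = 30)
    .shared$e2e <- list(spec = spec, seq = sq, trace = trace)
  }
  .shared$e2e
}
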