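test_that("ellipse_area matches the closed form and rejects bad axes", {
  expect_equal(ellipse_area(10, 5), pi * 50)
  expect_equal(ellipse_area(1, 1), pi)
  expect_error(ellipse_area(0, 5), "positive")
  expect_error(ellipse_area(3, -1), "positive")
})

test_that("rendered mask area agrees with rasterization within a perimeter band", {
  app <- eye_appearance(image_size = 64, pupil_center = c(32, 30),
                        pupil_semi_axes = c(12, 7), pupil_angle = 0.4,
                        noise_sigma = 0)
  f <- render_frame(app, seed = 1)
  count <- sum(f$mask)
  expect_equal(count,
               oracle_ellipse_pixel_count(64, c(32, 30), c(12, 7), 0.4))
  expect_lt(abs(count - ellipse_area(12, 7)), 2 * pi * 12)
})

test_that("closed eyes render as blinks with empty masks", {
  app <- eye_appearance(image_size = 32, eyelid_openness = 0)
  f <- render_frame(app, seed = 1)
  expect_true(f$blink)
  expect_equal(sum(f$mask), 0)
  # below the closure cutoff counts as a blink too
  f2 <- render_frame(eye_appearance(image_size = 32,
                                    eyelid_openness = 0.1), seed = 1)
  expect_true(f2$blink)
  expect_equal(sum(f2$mask), 0)
  # just above the cutoff it is an open (partially occluded) eye
  f3 <- render_frame(eye_appearance(image_size = 32,
                                    eyelid_openness = 0.9), seed = 1)
  expect_false(f3$blink)
})

test_that("dark polarity renders every pupil pixel darker than the iris", {
  app <- eye_appearance(image_size = 48, pupil_polarity = "dark",
                        noise_sigma = 0)
  f <- render_frame(app, seed = 1)
  expect_true(all(f$image[f$mask == 1] < app$iris_level))
  expect_error(eye_appearance(pupil_polarity = "dark", pupil_level = 0.5,
                              iris_level = 0.4), "dark polarity")
  expect_error(eye_appearance(pupil_polarity = "bright", pupil_level = 0.2,
                              iris_level = 0.4), "bright polarity")
})

test_that("training sets honour blink fractions and are seed-reproducible", {
  set0 <- make_training_set(100, blink_fraction = 0, seed = 5,
                            image_size = 32)
  expect_equal(sum(vapply(set0, function(f) f$blink, logical(1))), 0)

  a <- make_training_set(20, seed = 11, image_size = 32)
  b <- make_training_set(20, seed = 11, image_size = 32)
  expect_identical(a, b)

  # 99% binomial interval for n = 1000, p = 0.134 (the deposit's blink rate)
  big <- make_training_set(1000, blink_fraction = 0.134, seed = 2,
                           image_size = 16)
  nb <- sum(vapply(big, function(f) f$blink, logical(1)))
  expect_gte(nb, 100)
  expect_lte(nb, 170)
})

test_that("blink flag and empty mask coincide on generated frames", {
  frames <- make_training_set(60, blink_fraction = 0.3, seed = 3,
                              image_size = 32, no_eye_fraction = 0.1)
  for (f in frames) {
    if (f$blink) expect_equal(sum(f$mask), 0)
    if (sum(f$mask) > 0) expect_true(f$eye_present)
  }
})

test_that("training set mix validation rejects bad fractions", {
  expect_error(make_training_set(10, mix = c("dark-mouse" = 0.5,
                                             "bright-2P" = 0.3,
                                             "human" = 0.3)), "sum to 1")
  expect_error(make_training_set(10, mix = c(a = 0.5, b = 0.5)), "named")
})

test_that("sequences follow the analytic area trace", {
  flat <- make_sequence(sequence_spec(fps = 10, duration = 2,
                                      baseline_area = 150, seed = 1,
                                      image_size = 48, noise_sigma = 0))
  expect_equal(flat$truth$area_px, rep(150, 20))
  expect_equal(nrow(flat$truth), 20)

  ev <- make_sequence(sequence_spec(
    fps = 20, duration = 20, baseline_area = 150,
    events = list(list(onset = 5, peak = 0.3)), seed = 1, image_size = 48))
  expect_equal(max(ev$truth$area_px), 1.3 * 150, tolerance = 1e-3)
  # rendered mask area tracks the analytic trace within a perimeter band
  i_peak <- which.max(ev$truth$area_px)
  a_sem <- sqrt(max(ev$truth$area_px) / pi)
  expect_lt(abs(sum(ev$frames[[i_peak]]$mask) - ev$truth$area_px[i_peak]),
            2 * pi * (a_sem / 0.9) + 4)
})

test_that("blink epochs are half-open in frame time", {
  sq <- make_sequence(sequence_spec(fps = 30, duration = 4,
                                    blink_epochs = list(c(2.0, 0.3)),
                                    seed = 1, image_size = 32))
  expect_equal(sum(sq$truth$blink), 9) # frames 60..68
  expect_true(all(which(sq$truth$blink) == 61:69))
  for (i in which(sq$truth$blink))
    expect_true(sq$frames[[i]]$blink)
})

test_that("sequences are bit-identical under a fixed seed", {
  s <- sequence_spec(fps = 10, duration = 1, drift_sigma = 2, seed = 42,
                     image_size = 32)
  expect_identical(make_sequence(s), make_sequence(s))
})

test_that("datasets round-trip through the PNG + CSV dialect", {
  frames <- make_training_set(6, blink_fraction = 0.3, seed = 9,
                              image_size = 24)
  dir <- withr::local_tempdir()
  idx <- write_eye_dataset(frames, dir)
  expect_equal(nrow(idx), 6)
  expect_true(file.exists(file.path(dir, "index.csv")))
  loaded <- load_deposit(dir)
  expect_equal(nrow(loaded), 6)
  lf <- load_labeled_frames(loaded)
  for (i in seq_along(frames)) {
    expect_equal(lf[[i]]$mask, frames[[i]]$mask,
                 ignore_attr = TRUE)
    expect_equal(lf[[i]]$blink, frames[[i]]$blink)
    expect_lt(max(abs(lf[[i]]$image - frames[[i]]$image)), 1 / 255)
  }
})
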