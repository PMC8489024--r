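make_ellipse_frame <- function(n = 64, center = c(n / 2, n / 2),
                               axes = c(12, 8), angle = 0) {
  app <- eye_appearance(image_size = n, pupil_center = center,
                        pupil_semi_axes = axes, pupil_angle = angle,
                        noise_sigma = 0)
  render_frame(app, seed = 1)
}

test_that("split sizes follow the 70/20/10 rule and are deterministic", {
  frames <- as.list(seq_len(100))
  sp <- split_dataset(frames, seed = 1)
  expect_equal(lengths(sp), c(train = 70, val = 20, test = 10))
  expect_setequal(unlist(sp), 1:100)

  sp10 <- split_dataset(as.list(1:10), seed = 1)
  expect_equal(lengths(sp10), c(train = 7, val = 2, test = 1))

  expect_identical(split_dataset(frames, seed = 9),
                   split_dataset(frames, seed = 9))
  expect_error(split_dataset(frames, split = c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(split_dataset(list()), "empty")
})

test_that("identity policy leaves a 128-sized frame unchanged", {
  f <- make_ellipse_frame(128)
  out <- augment(f, identity_policy(128), seed = 1)
  expect_equal(out$image, f$image, tolerance = 1e-12)
  expect_equal(out$mask, f$mask)
  expect_equal(out$blink, f$blink)
})

test_that("a certain horizontal flip applied twice is the identity", {
  f <- make_ellipse_frame(64, center = c(20, 40))
  pol <- augment_policy(rotation_range = 0, crop_scale_range = c(1, 1),
                        horizontal_flip_p = 1, vertical_flip_p = 0,
                        brightness_range = c(1, 1),
                        contrast_range = c(1, 1),
                        sharpness_range = c(1, 1), output_size = 64)
  once <- augment(f, pol, seed = 1)
  twice <- augment(once, pol, seed = 2)
  expect_equal(twice$image, f$image, tolerance = 1e-12)
  expect_equal(twice$mask, f$mask)
  expect_false(isTRUE(all.equal(once$image, f$image)))
})

test_that("rotation preserves mask area within 2% and stays synchronized", {
  f <- make_ellipse_frame(96, axes = c(18, 10), angle = 0.3)
  pol <- augment_policy(rotation_range = 0, crop_scale_range = c(1, 1),
                        horizontal_flip_p = 0, vertical_flip_p = 0,
                        brightness_range = c(1, 1),
                        contrast_range = c(1, 1),
                        sharpness_range = c(1, 1), output_size = 96)
  for (ang in c(90, 37, -60)) {
    rot_mask <- pupilkit:::rotate_image(f$mask, ang, "nearest")
    expect_lt(abs(sum(rot_mask) - sum(f$mask)) / sum(f$mask), 0.02)
  }
  # geometric transforms never desynchronize image and mask: the dark
  # pupil pixels of the rotated image sit where the rotated mask says
  rot_img <- pupilkit:::rotate_image(f$image, 45, "nearest")
  rot_mask <- pupilkit:::rotate_image(f$mask, 45, "nearest")
  expect_equal((rot_img < 0.2 & rot_img > 0) * 1, rot_mask,
               ignore_attr = TRUE)
})

test_that("eval_crop centres on the pupil and clamps to bounds", {
  f128 <- make_ellipse_frame(128)
  expect_identical(eval_crop(f128, 128), f128)

  f256 <- make_ellipse_frame(256, center = c(64, 64))
  crop <- eval_crop(f256, 128)
  expect_equal(dim(crop$image), c(128, 128))
  expect_equal(crop$image, f256$image[1:128, 1:128])

  blinkf <- render_frame(eye_appearance(image_size = 256,
                                        eyelid_openness = 0), seed = 1)
  crop2 <- eval_crop(blinkf, 128)
  expect_equal(crop2$image, blinkf$image[64 + 1:128, 64 + 1:128])
})

test_that("total_loss matches closed forms and the element-wise oracle", {
  n <- 8
  target <- structure(list(image = matrix(0, n, n),
                           mask = matrix(rbinom(n * n, 1, 0.5), n, n),
                           eye_present = TRUE, blink = FALSE),
                      class = "labeled_frame")
  # uniform 0.5 prediction: ln 2 per component, three components
  flat <- structure(list(pupil_map = matrix(0.5, n, n), eye_prob = 0.5,
                         blink_prob = 0.5), class = "prediction")
  expect_equal(total_loss(flat, target), 3 * log(2), tolerance = 1e-12)

  # perfectly confident prediction: bounded by the clipping floor
  perfect <- structure(list(pupil_map = target$mask, eye_prob = 1,
                            blink_prob = 0), class = "prediction")
  expect_lte(total_loss(perfect, target), 3 * -log(1 - 1e-7) + 1e-12)

  set.seed(21)
  rnd <- structure(list(pupil_map = matrix(runif(n * n), n, n),
                        eye_prob = runif(1), blink_prob = runif(1)),
                   class = "prediction")
  expect_equal(total_loss(rnd, target),
               oracle_bce_sum(rnd$pupil_map, target$mask, rnd$eye_prob, 1,
                              rnd$blink_prob, 0),
               tolerance = 1e-6)
  bad <- rnd; bad$pupil_map <- matrix(0.5, 4, 4)
  expect_error(total_loss(bad, target), "shape")
})

test_that("dice follows its set-arithmetic definition", {
  a <- matrix(0, 10, 10); a[1:5, 1:5] <- 1
  expect_equal(dice(a, a), 1)
  b <- matrix(0, 10, 10); b[6:10, 6:10] <- 1
  expect_equal(dice(a, b), 0)
  # |A| = |B| = 100, overlap 50
  a2 <- matrix(0, 20, 20); a2[1:10, 1:10] <- 1
  b2 <- matrix(0, 20, 20); b2[6:15, 1:10] <- 1
  expect_equal(dice(a2, b2), 0.5)
  # both empty: perfect match by convention
  expect_equal(dice(matrix(0, 4, 4), matrix(0, 4, 4)), 1)
  # symmetry and range on random masks
  set.seed(3)
  for (i in 1:20) {
    x <- matrix(rbinom(64, 1, 0.4), 8, 8)
    y <- matrix(rbinom(64, 1, 0.4), 8, 8)
    expect_equal(dice(x, y), dice(y, x))
    expect_gte(dice(x, y), 0)
    expect_lte(dice(x, y), 1)
    expect_equal(dice(x, y), 2 * sum(x & y) / (sum(x) + sum(y)))
  }
})

test_that("one-epoch training returns a single history row", {
  frames <- make_training_set(12, seed = 7, image_size = 16,
                              blink_fraction = 0.2)
  model <- build_segmenter(segmenter_config(input_size = 16), seed = 7)
  fit <- train(model, frames[1:8], frames[9:12],
               train_config(epochs = 1, batch_size = 4, seed = 7))
  expect_equal(nrow(fit$history), 1)
  expect_equal(fit$best_epoch, 1L)
  expect_error(train(model, list(), frames[9:12],
                     train_config(epochs = 1)), "nonempty")
})

test_that("zero learning rate freezes the validation metric", {
  frames <- make_training_set(12, seed = 8, image_size = 16,
                              blink_fraction = 0.2)
  model <- build_segmenter(segmenter_config(input_size = 16), seed = 8)
  fit <- train(model, frames[1:8], frames[9:12],
               train_config(epochs = 3, batch_size = 4,
                            learning_rate = 0, seed = 8))
  expect_equal(fit$history$val_dice,
               rep(fit$history$val_dice[1], 3), tolerance = 1e-12)
})

test_that("snapshot selection is the argmax of the recorded metric", {
  fx <- trained_fixture()
  h <- fx$fit$history
  expect_equal(fx$fit$best_epoch, which.max(h$val_dice))
  ev <- evaluate_dice(fx$fit$model, fx$splits$val)
  expect_equal(ev$mean, max(h$val_dice), tolerance = 1e-6)
})
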