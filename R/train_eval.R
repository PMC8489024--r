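#' Augmentation policy
#'
#' Random geometric and photometric transforms applied during training:
#' rotation about the image centre, scaled cropping, horizontal/vertical
#' flips, and brightness/contrast/sharpness changes, followed by resizing to
#' the network input size. Geometric transforms are applied identically to
#' image and mask (mask resampled with nearest neighbour so labels stay
#' binary); photometric transforms touch the image only.
#'
#' @param rotation_range Max absolute rotation in degrees.
#' @param crop_scale_range Range of the crop side as a fraction of the
#'   shorter source side.
#' @param horizontal_flip_p,vertical_flip_p Flip probabilities.
#' @param brightness_range,contrast_range,sharpness_range Ranges of the
#'   photometric enhancement factors (1 = unchanged).
#' @param output_size Output side in pixels.
#' @return An object of class `augment_policy`.
#' @export
augment_policy <- function(rotation_range = 30,
                           crop_scale_range = c(0.7, 1.0),
                           horizontal_flip_p = 0.5, vertical_flip_p = 0.5,
                           brightness_range = c(0.7, 1.3),
                           contrast_range = c(0.7, 1.3),
                           sharpness_range = c(0.7, 1.3),
                           output_size = 128) {
  stopifnot(rotation_range >= 0,
            horizontal_flip_p >= 0, horizontal_flip_p <= 1,
            vertical_flip_p >= 0, vertical_flip_p <= 1,
            length(crop_scale_range) == 2,
            crop_scale_range[1] > 0, crop_scale_range[2] <= 1,
            crop_scale_range[1] <= crop_scale_range[2])
  structure(list(rotation_range = rotation_range,
                 crop_scale_range = crop_scale_range,
                 horizontal_flip_p = horizontal_flip_p,
                 vertical_flip_p = vertical_flip_p,
                 brightness_range = brightness_range,
                 contrast_range = contrast_range,
                 sharpness_range = sharpness_range,
                 output_size = as.integer(output_size)),
            class = "augment_policy")
}

#' Identity augmentation policy (no randomness)
#' @param output_size Output side in pixels.
#' @return An `augment_policy` whose transforms are all no-ops.
#' @export
identity_policy <- function(output_size = 128) {
  augment_policy(rotation_range = 0, crop_scale_range = c(1, 1),
                 horizontal_flip_p = 0, vertical_flip_p = 0,
                 brightness_range = c(1, 1), contrast_range = c(1, 1),
                 sharpness_range = c(1, 1), output_size = output_size)
}

# sample img at fractional 0-based coords (xs, ys); out-of-range -> bg
sample_bilinear <- function(img, xs, ys, bg = 0) {
  h <- nrow(img); w <- ncol(img)
  valid <- xs >= 0 & xs <= w - 1 & ys >= 0 & ys <= h - 1
  xs <- pmin(pmax(xs, 0), w - 1); ys <- pmin(pmax(ys, 0), h - 1)
  x0 <- floor(xs); y0 <- floor(ys)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- xs - x0; fy <- ys - y0
  at <- function(yy, xx) img[cbind(as.vector(yy) + 1, as.vector(xx) + 1)]
  out <- (1 - fx) * (1 - fy) * at(y0, x0) + fx * (1 - fy) * at(y0, x1) +
    (1 - fx) * fy * at(y1, x0) + fx * fy * at(y1, x1)
  out[!valid] <- bg
  matrix(out, nrow = nrow(xs))
}

sample_nearest <- function(img, xs, ys, bg = 0) {
  h <- nrow(img); w <- ncol(img)
  xi <- round(xs); yi <- round(ys)
  valid <- xi >= 0 & xi <= w - 1 & yi >= 0 & yi <= h - 1
  xi <- pmin(pmax(xi, 0), w - 1); yi <- pmin(pmax(yi, 0), h - 1)
  out <- img[cbind(as.vector(yi) + 1, as.vector(xi) + 1)]
  out[!valid] <- bg
  matrix(out, nrow = nrow(xs))
}

# rotate about the image centre; canvas unchanged; angle counter-clockwise
rotate_image <- function(img, angle_deg, filter = c("bilinear", "nearest")) {
  filter <- match.arg(filter)
  h <- nrow(img); w <- ncol(img)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  th <- angle_deg * pi / 180
  x <- matrix(rep(0:(w - 1), each = h), nrow = h)
  y <- matrix(rep(0:(h - 1), times = w), nrow = h)
  # inverse map: rotate output coords by -theta around the centre
  xs <- cos(th) * (x - cx) + sin(th) * (y - cy) + cx
  ys <- -sin(th) * (x - cx) + cos(th) * (y - cy) + cy
  if (filter == "bilinear") sample_bilinear(img, xs, ys)
  else sample_nearest(img, xs, ys)
}

# resize with pixel-centre alignment; scale 1 is the exact identity
resize_image <- function(img, out_size, filter = c("bilinear", "nearest")) {
  filter <- match.arg(filter)
  h <- nrow(img); w <- ncol(img)
  sx <- w / out_size; sy <- h / out_size
  x <- matrix(rep(0:(out_size - 1), each = out_size), nrow = out_size)
  y <- matrix(rep(0:(out_size - 1), times = out_size), nrow = out_size)
  xs <- (x + 0.5) * sx - 0.5
  ys <- (y + 0.5) * sy - 0.5
  if (filter == "bilinear") sample_bilinear(img, xs, ys)
  else sample_nearest(img, xs, ys)
}

#' Augment one labelled frame
#'
#' Applies one random draw of the policy. The same geometric transform is
#' applied to image and mask; blink/eye labels are preserved; output is
#' `output_size` x `output_size`.
#'
#' @param frame A `labeled_frame`.
#' @param policy An [augment_policy()].
#' @param seed Integer seed, or `NULL` to draw from the current RNG state.
#' @return The augmented `labeled_frame`.
#' @export
augment <- function(frame, policy, seed = NULL) {
  stopifnot(inherits(policy, "augment_policy"))
  with_seed(seed, {
    img <- frame$image; mask <- frame$mask
    if (policy$rotation_range > 0) {
      ang <- runif(1, -policy$rotation_range, policy$rotation_range)
      img <- rotate_image(img, ang, "bilinear")
      mask <- rotate_image(mask, ang, "nearest")
    }
    s <- runif(1, policy$crop_scale_range[1], policy$crop_scale_range[2])
    csize <- max(2, round(s * min(dim(img))))
    if (csize > min(dim(img))) stop("crop larger than source image")
    if (csize < min(dim(img))) {
      x0 <- sample.int(ncol(img) - csize + 1, 1)
      y0 <- sample.int(nrow(img) - csize + 1, 1)
      img <- img[y0:(y0 + csize - 1), x0:(x0 + csize - 1)]
      mask <- mask[y0:(y0 + csize - 1), x0:(x0 + csize - 1)]
    }
    if (runif(1) < policy$horizontal_flip_p) {
      img <- img[, ncol(img):1]; mask <- mask[, ncol(mask):1]
    }
    if (runif(1) < policy$vertical_flip_p) {
      img <- img[nrow(img):1, ]; mask <- mask[nrow(mask):1, ]
    }
    # photometric (image only), Pillow-style: out = base + f*(img - base)
    bf <- runif(1, policy$brightness_range[1], policy$brightness_range[2])
    img <- img * bf
    cf <- runif(1, policy$contrast_range[1], policy$contrast_range[2])
    img <- mean(img) + cf * (img - mean(img))
    sf <- runif(1, policy$sharpness_range[1], policy$sharpness_range[2])
    if (sf != 1) {
      blur <- blur3(img)
      img <- blur + sf * (img - blur)
    }
    if (nrow(img) != policy$output_size) {
      img <- resize_image(img, policy$output_size, "bilinear")
      mask <- resize_image(mask, policy$output_size, "nearest")
    }
    structure(list(image = clip01(img), mask = (mask > 0.5) * 1,
                   eye_present = frame$eye_present, blink = frame$blink),
              class = "labeled_frame")
  })
}

# 3x3 box blur with edge replication
blur3 <- function(img) {
  h <- nrow(img); w <- ncol(img)
  pad <- rbind(img[1, , drop = FALSE], img, img[h, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, w, drop = FALSE])
  out <- matrix(0, h, w)
  for (dx in 0:2) for (dy in 0:2)
    out <- out + pad[dy + 1:h, dx + 1:w]
  out / 9
}

#' Deterministic evaluation crop centred on the pupil
#'
#' Validation/test frames are reduced to a `size` x `size` crop centred on
#' the ground-truth mask centroid (image centre when the mask is empty),
#' clamped to the image bounds.
#'
#' @param frame A `labeled_frame`.
#' @param size Crop side in pixels.
#' @return The cropped `labeled_frame`.
#' @export
eval_crop <- function(frame, size = 128) {
  h <- nrow(frame$image); w <- ncol(frame$image)
  if (h < size || w < size) stop("image smaller than the requested crop")
  if (h == size && w == size) return(frame)
  if (sum(frame$mask) > 0) {
    ys <- (row(frame$mask) - 1)[frame$mask > 0]
    xs <- (col(frame$mask) - 1)[frame$mask > 0]
    cx <- mean(xs); cy <- mean(ys)
  } else {
    cx <- (w - 1) / 2; cy <- (h - 1) / 2
  }
  x0 <- min(max(round(cx - size / 2), 0), w - size)
  y0 <- min(max(round(cy - size / 2), 0), h - size)
  structure(list(image = frame$image[y0 + 1:size, x0 + 1:size],
                 mask = frame$mask[y0 + 1:size, x0 + 1:size],
                 eye_present = frame$eye_present, blink = frame$blink),
            class = "labeled_frame")
}

#' Split a dataset into train/validation/test subsets
#'
#' Seeded uniform shuffle, then sizes `floor(n * split[1])`,
#' `floor(n * split[2])`, remainder to test.
#'
#' @param frames List of frames (any objects).
#' @param split Fractions summing to 1, default `c(0.70, 0.20, 0.10)`.
#' @param seed Integer seed.
#' @return List with elements `train`, `val`, `test` (disjoint cover).
#' @export
split_dataset <- function(frames, split = c(0.70, 0.20, 0.10), seed = 1) {
  if (length(frames) == 0) stop("empty dataset")
  if (length(split) != 3 || any(split < 0) || abs(sum(split) - 1) > 1e-8)
    stop("the three split fractions must sum to 1")
  n <- length(frames)
  with_seed(seed, {
    idx <- sample.int(n)
    n_train <- floor(n * split[1])
    n_val <- floor(n * split[2])
    list(train = frames[idx[seq_len(n_train)]],
         val = frames[idx[n_train + seq_len(n_val)]],
         test = frames[idx[(n_train + n_val + 1):n]])
  })
}

bce <- function(p, y, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -(y * log(p) + (1 - y) * log(1 - p))
}

#' Summed binary cross-entropy training loss
#'
#' Mean pixel-wise binary cross-entropy of the pupil map plus the binary
#' cross-entropies of the eye and blink outputs, summed. Probabilities are
#' clipped to `[1e-7, 1 - 1e-7]` for numerical safety.
#'
#' @param pred A `prediction` (probabilities).
#' @param target A `labeled_frame`.
#' @return Nonnegative scalar loss.
#' @export
total_loss <- function(pred, target) {
  if (!all(dim(pred$pupil_map) == dim(target$mask)))
    stop("prediction and target shapes differ")
  mean(bce(pred$pupil_map, target$mask)) +
    bce(pred$eye_prob, as.numeric(target$eye_present)) +
    bce(pred$blink_prob, as.numeric(target$blink))
}

#' Dice overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)` between two binary masks; defined as 1 when both
#' masks are empty (blink frames have empty reference masks, and
#' empty-vs-empty is a perfect match).
#'
#' @param mask_a,mask_b Same-shape binary masks (nonzero = foreground).
#' @return Fraction in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b))) stop("mask shapes differ")
  a <- mask_a > 0; b <- mask_b > 0
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Training configuration
#'
#' Defaults follow the published recipe: AdaBelief for 750 epochs at
#' learning rate 0.001 with a 70%/20%/10% split; batch size (not published)
#' defaults to 32.
#'
#' @param epochs Number of passes over the training set.
#' @param learning_rate AdaBelief step size.
#' @param batch_size Minibatch size.
#' @param split Train/val/test fractions.
#' @param seed Integer seed controlling shuffling and augmentation draws.
#' @param beta1,beta2,eps AdaBelief moment decay rates and stabilizer.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 750, learning_rate = 0.001,
                         batch_size = 32, split = c(0.70, 0.20, 0.10),
                         seed = 1, beta1 = 0.9, beta2 = 0.999, eps = 1e-16) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate >= 0)
  if (abs(sum(split) - 1) > 1e-8) stop("split must sum to 1")
  structure(list(epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), split = split,
                 seed = as.integer(seed), beta1 = beta1, beta2 = beta2,
                 eps = eps), class = "train_config")
}

frames_to_arrays <- function(frames, n) {
  b <- length(frames)
  imgs <- array(0, dim = c(n, n, b))
  msks <- array(0, dim = c(n, n, b))
  eye <- numeric(b); blink <- numeric(b)
  for (i in seq_len(b)) {
    imgs[, , i] <- frames[[i]]$image
    msks[, , i] <- frames[[i]]$mask
    eye[i] <- as.numeric(frames[[i]]$eye_present)
    blink[i] <- as.numeric(frames[[i]]$blink)
  }
  list(images = imgs, masks = msks, eye = eye, blink = blink)
}

#' Mean Dice of a model over a set of labelled frames
#'
#' Thresholds the predicted pupil map at `threshold` and computes the Dice
#' coefficient against the reference mask per image; mDice is their mean.
#'
#' @param model A `segmenter`.
#' @param frames List of `labeled_frame`s at the model input size.
#' @param threshold Probability cutoff for the map.
#' @return List with `per_image` (vector) and `mean` (mDice).
#' @export
evaluate_dice <- function(model, frames, threshold = 0.5) {
  arr <- frames_to_arrays(frames, model$config$input_size)
  pred <- unet_predict_cpp(model$params, cfg_list(model), arr$images)
  per <- vapply(seq_along(frames), function(i)
    dice(pred$maps[, , i] >= threshold, frames[[i]]$mask), numeric(1))
  list(per_image = per, mean = mean(per))
}

#' Train the segmentation network
#'
#' Minimizes the summed binary cross-entropy with the AdaBelief optimizer,
#' recording per-epoch training loss and validation mean Dice, and returns
#' the parameter snapshot that maximizes the validation metric.
#'
#' @param model A freshly built (or partially trained) `segmenter`.
#' @param train_set,val_set Nonempty lists of `labeled_frame`s at the model
#'   input size.
#' @param config A [train_config()].
#' @param policy Optional [augment_policy()] applied to training frames
#'   each epoch; `NULL` trains on the frames as given.
#' @param verbose Print one line per epoch.
#' @return List with `model` (best snapshot), `history` (data frame of
#'   `epoch`, `train_loss`, `val_dice`), and `best_epoch`.
#' @export
train <- function(model, train_set, val_set, config = train_config(),
                  policy = NULL, verbose = FALSE) {
  if (length(train_set) == 0 || length(val_set) == 0)
    stop("train and validation sets must be nonempty")
  stopifnot(inherits(config, "train_config"))
  n <- model$config$input_size
  cfg <- cfg_list(model)
  val_arr <- frames_to_arrays(val_set, n)
  params <- model$params
  m <- lapply(params, function(p) p * 0)
  s <- lapply(params, function(p) p * 0)
  tstep <- 0
  best_dice <- -Inf; best_params <- params; best_epoch <- 1L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_dice = numeric(0))
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      idx <- sample.int(length(train_set))
      losses <- c()
      for (start in seq(1, length(idx), by = config$batch_size)) {
        take <- idx[start:min(start + config$batch_size - 1, length(idx))]
        fr <- train_set[take]
        if (!is.null(policy)) fr <- lapply(fr, augment, policy = policy)
        arr <- frames_to_arrays(fr, n)
        res <- unet_batch_grad_cpp(params, cfg, arr$images, arr$masks,
                                   arr$eye, arr$blink)
        losses <- c(losses, res$loss)
        tstep <- tstep + 1
        g <- res$grads
        bc1 <- 1 - config$beta1^tstep
        bc2 <- 1 - config$beta2^tstep
        for (nm in names(params)) {
          m[[nm]] <- config$beta1 * m[[nm]] + (1 - config$beta1) * g[[nm]]
          s[[nm]] <- config$beta2 * s[[nm]] +
            (1 - config$beta2) * (g[[nm]] - m[[nm]])^2 + config$eps
          params[[nm]] <- params[[nm]] - config$learning_rate *
            (m[[nm]] / bc1) / (sqrt(s[[nm]] / bc2) + config$eps)
        }
      }
      pred <- unet_predict_cpp(params, cfg, val_arr$images)
      vd <- mean(vapply(seq_along(val_set), function(i)
        dice(pred$maps[, , i] >= 0.5, val_set[[i]]$mask), numeric(1)))
      history[ep, ] <- list(ep, mean(losses), vd)
      if (vd > best_dice) {
        best_dice <- vd; best_params <- params; best_epoch <- ep
      }
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val mDice %.4f", ep,
                        mean(losses), vd))
    }
  })
  best <- structure(list(config = model$config, params = best_params),
                    class = "segmenter")
  list(model = best, history = history, best_epoch = best_epoch)
}

#' Write / read a training history CSV (`epoch, train_loss, val_dice`)
#' @param history Data frame as returned by [train()].
#' @param path File path.
#' @export
write_history_csv <- function(history, path) {
  write.csv(history, path, row.names = FALSE)
  invisible(path)
}
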