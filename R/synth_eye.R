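#' Synthetic eye-image appearance parameters
#'
#' Describes one rendered eye frame. The renderer draws, on a square
#' gray-level canvas in `[0, 1]`: a sclera background, an iris disk centred on
#' the pupil, an elliptical pupil (darker or brighter than the iris depending
#' on the imaging regime), optional specular highlights, an eyelid occluding
#' the image from the top by a fraction `1 - eyelid_openness`, and additive
#' Gaussian noise. Coordinates are 0-based, x rightwards (columns),
#' y downwards (rows), with pixel centres at integer coordinates.
#'
#' @param image_size Side of the square image in pixels.
#' @param pupil_center Numeric `(x, y)` pupil centre in pixels.
#' @param pupil_semi_axes Numeric `(a, b)` ellipse semi-axes in pixels.
#' @param pupil_angle Ellipse rotation in radians.
#' @param pupil_polarity `"dark"` (IR-lit mouse/human: pupil darker than
#'   iris) or `"bright"` (two-photon backscatter: pupil brighter than iris).
#' @param iris_radius Iris disk radius in pixels.
#' @param iris_level,pupil_level,sclera_level Gray intensities in `[0, 1]`.
#' @param eyelid_openness Fraction in `[0, 1]`; 0 is fully closed. Values
#'   below the blink cutoff (0.15) are rendered fully closed and the frame is
#'   flagged as a blink.
#' @param specular_spot_count Number of small bright corneal reflections.
#' @param noise_sigma Standard deviation of additive Gaussian noise.
#' @return An object of class `eye_appearance`.
#' @export
eye_appearance <- function(image_size = 128,
                           pupil_center = c(image_size / 2, image_size / 2),
                           pupil_semi_axes = c(0.15, 0.12) * image_size,
                           pupil_angle = 0,
                           pupil_polarity = c("dark", "bright"),
                           iris_radius = 0.4 * image_size,
                           iris_level = if (match.arg(pupil_polarity) == "dark") 0.45 else 0.35,
                           pupil_level = if (match.arg(pupil_polarity) == "dark") 0.08 else 0.85,
                           sclera_level = 0.75,
                           eyelid_openness = 1,
                           specular_spot_count = 0,
                           noise_sigma = 0) {
  pupil_polarity <- match.arg(pupil_polarity)
  stopifnot(image_size >= 8, length(pupil_center) == 2,
            length(pupil_semi_axes) == 2)
  if (any(pupil_semi_axes <= 0))
    stop("pupil semi-axes must be positive")
  if (eyelid_openness < 0 || eyelid_openness > 1)
    stop("eyelid_openness must be in [0, 1]")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (specular_spot_count < 0) stop("specular_spot_count must be >= 0")
  if (eyelid_openness == 1 && max(pupil_semi_axes) > iris_radius)
    stop("pupil ellipse must fit inside the iris disk")
  if (pupil_polarity == "dark" && pupil_level >= iris_level)
    stop("dark polarity requires pupil_level < iris_level")
  if (pupil_polarity == "bright" && pupil_level <= iris_level)
    stop("bright polarity requires pupil_level > iris_level")
  structure(list(
    image_size = as.integer(image_size), pupil_center = pupil_center,
    pupil_semi_axes = pupil_semi_axes, pupil_angle = pupil_angle,
    pupil_polarity = pupil_polarity, iris_radius = iris_radius,
    iris_level = iris_level, pupil_level = pupil_level,
    sclera_level = sclera_level, eyelid_openness = eyelid_openness,
    specular_spot_count = as.integer(specular_spot_count),
    noise_sigma = noise_sigma
  ), class = "eye_appearance")
}

# cutoff below which a frame counts as a blink and is rendered fully closed
BLINK_OPENNESS_CUTOFF <- 0.15

#' Analytic area of an ellipse
#'
#' @param a,b Semi-axes in pixels, both positive.
#' @return Area `pi * a * b` in squared pixels.
#' @export
ellipse_area <- function(a, b) {
  if (any(a <= 0) || any(b <= 0)) stop("semi-axes must be positive")
  pi * a * b
}

# binary pupil mask: pixel centre (x, y) belongs to the rotated ellipse
ellipse_mask <- function(image_size, center, semi_axes, angle) {
  x <- matrix(rep(0:(image_size - 1), each = image_size),
              nrow = image_size) # x constant down a column
  y <- matrix(rep(0:(image_size - 1), times = image_size),
              nrow = image_size)
  dx <- x - center[1]; dy <- y - center[2]
  u <- (dx * cos(angle) + dy * sin(angle)) / semi_axes[1]
  v <- (-dx * sin(angle) + dy * cos(angle)) / semi_axes[2]
  (u^2 + v^2 <= 1) * 1
}

#' Render one labelled synthetic eye frame
#'
#' @param appearance An [eye_appearance()] object.
#' @param seed Integer seed for noise and specular-spot placement, or `NULL`
#'   to use the current RNG state.
#' @return A `labeled_frame`: list with `image` (matrix in `[0, 1]`), `mask`
#'   (0/1 matrix of visible pupil pixels), `eye_present`, `blink`.
#' @export
render_frame <- function(appearance, seed = NULL) {
  stopifnot(inherits(appearance, "eye_appearance"))
  a <- appearance
  with_seed(seed, {
    n <- a$image_size
    blink <- a$eyelid_openness < BLINK_OPENNESS_CUTOFF
    openness <- if (blink) 0 else a$eyelid_openness

    img <- matrix(a$sclera_level, n, n)
    x <- matrix(rep(0:(n - 1), each = n), nrow = n)
    y <- matrix(rep(0:(n - 1), times = n), nrow = n)
    iris <- (x - a$pupil_center[1])^2 + (y - a$pupil_center[2])^2 <=
      a$iris_radius^2
    img[iris] <- a$iris_level
    mask <- ellipse_mask(n, a$pupil_center, a$pupil_semi_axes, a$pupil_angle)
    img[mask == 1] <- a$pupil_level

    if (a$specular_spot_count > 0) {
      for (i in seq_len(a$specular_spot_count)) {
        ang <- runif(1, 0, 2 * pi)
        rad <- runif(1, 0, 0.6 * a$iris_radius)
        cx <- a$pupil_center[1] + rad * cos(ang)
        cy <- a$pupil_center[2] + rad * sin(ang)
        r <- runif(1, 1, 2.5)
        spot <- (x - cx)^2 + (y - cy)^2 <= r^2
        img[spot] <- 0.95
      }
    }

    # eyelid occludes rows y < lid_y; a dark lash line marks the lid margin
    lid_y <- round((1 - openness) * n)
    if (lid_y > 0) {
      lid_level <- 0.75 * a$sclera_level + 0.1
      img[y < lid_y] <- lid_level
      mask[y < lid_y] <- 0
      margin <- y >= (min(lid_y, n - 2) - 1) & y <= min(lid_y, n - 2)
      if (lid_y >= 1) img[margin] <- 0.2
    }

    if (a$noise_sigma > 0)
      img <- img + matrix(rnorm(n * n, 0, a$noise_sigma), n, n)
    img <- clip01(img)
    if (blink) mask[] <- 0

    structure(list(image = img, mask = mask, eye_present = TRUE,
                   blink = blink), class = "labeled_frame")
  })
}

# featureless frame with no eye (negative example for the eye head)
render_no_eye_frame <- function(image_size, level = 0.5, noise_sigma = 0.05,
                                seed = NULL) {
  with_seed(seed, {
    img <- clip01(matrix(level + rnorm(image_size^2, 0, noise_sigma),
                         image_size, image_size))
    structure(list(image = img, mask = matrix(0, image_size, image_size),
                   eye_present = FALSE, blink = FALSE),
              class = "labeled_frame")
  })
}

# draw one randomized appearance for a given imaging class
random_appearance <- function(class_tag, image_size, blink) {
  n <- image_size
  ctr <- n / 2 + runif(2, -0.12 * n, 0.12 * n)
  axes <- sort(runif(2, 0.09 * n, 0.2 * n), decreasing = TRUE)
  angle <- runif(1, 0, pi)
  openness <- if (blink) runif(1, 0, 0.12) else runif(1, 0.75, 1)
  if (class_tag == "bright-2P") {
    eye_appearance(
      image_size = n, pupil_center = ctr, pupil_semi_axes = axes,
      pupil_angle = angle, pupil_polarity = "bright",
      iris_radius = runif(1, 0.32, 0.42) * n,
      iris_level = runif(1, 0.2, 0.4), pupil_level = runif(1, 0.7, 0.95),
      sclera_level = runif(1, 0.1, 0.3), eyelid_openness = openness,
      specular_spot_count = 0, noise_sigma = runif(1, 0.01, 0.05))
  } else {
    spots <- if (class_tag == "human") sample(1:3, 1) else sample(0:2, 1)
    eye_appearance(
      image_size = n, pupil_center = ctr, pupil_semi_axes = axes,
      pupil_angle = angle, pupil_polarity = "dark",
      iris_radius = runif(1, if (class_tag == "human") 0.36 else 0.32,
                          0.44) * n,
      iris_level = runif(1, 0.3, 0.55), pupil_level = runif(1, 0.02, 0.15),
      sclera_level = runif(1, 0.55, 0.85), eyelid_openness = openness,
      specular_spot_count = spots, noise_sigma = runif(1, 0.01, 0.05))
  }
}

#' Generate a labelled synthetic training set
#'
#' Draws `n` frames from a mixture of the three imaging classes the network
#' must handle — IR dark-pupil mouse, two-photon bright-pupil mouse, and
#' IR-lit human — with a given fraction of blink frames (the released
#' annotated dataset has 1596 blinks among 11,897 images, about 13.4%) and
#' optionally a fraction of eye-absent frames.
#'
#' @param n Number of frames.
#' @param mix Named fractions over `c("dark-mouse", "bright-2P", "human")`;
#'   must sum to 1.
#' @param blink_fraction Probability that a frame is a blink.
#' @param seed Integer seed; the same seed reproduces the set exactly.
#' @param image_size Rendered side in pixels.
#' @param no_eye_fraction Probability that a frame contains no eye at all.
#' @return List of `labeled_frame`s; each carries a `class_tag` attribute.
#' @export
make_training_set <- function(n,
                              mix = c("dark-mouse" = 1 / 3,
                                      "bright-2P" = 1 / 3,
                                      "human" = 1 / 3),
                              blink_fraction = 0.134, seed = 1,
                              image_size = 128, no_eye_fraction = 0) {
  stopifnot(n >= 1)
  if (is.null(names(mix)) ||
      !setequal(names(mix), c("dark-mouse", "bright-2P", "human")))
    stop("mix must be named over dark-mouse, bright-2P, human")
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
    stop("mix fractions must be nonnegative and sum to 1")
  if (blink_fraction < 0 || blink_fraction > 1)
    stop("blink_fraction must be in [0, 1]")
  with_seed(seed, {
    classes <- sample(names(mix), n, replace = TRUE, prob = mix)
    blinks <- runif(n) < blink_fraction
    no_eye <- runif(n) < no_eye_fraction
    lapply(seq_len(n), function(i) {
      f <- if (no_eye[i]) {
        render_no_eye_frame(image_size, level = runif(1, 0.2, 0.8))
      } else {
        render_frame(random_appearance(classes[i], image_size, blinks[i]))
      }
      attr(f, "class_tag") <- if (no_eye[i]) "no-eye" else classes[i]
      f
    })
  })
}

#' Specification of a synthetic pupil-dynamics sequence
#'
#' Defines a video-like sequence in which the pupil area follows a baseline
#' plus a sum of event-locked dilation transients (exponential rise and
#' decay), a seeded random-walk drift, and blink epochs during which the eye
#' is rendered closed.
#'
#' @param fps Frame rate, frames/s.
#' @param duration Length in seconds.
#' @param baseline_area Baseline pupil area in squared pixels.
#' @param events List of events, each
#'   `list(onset = s, peak = fractional dilation, tau_rise = s, tau_decay = s)`.
#' @param blink_epochs List of `c(onset_s, duration_s)` pairs; frames whose
#'   time falls in the half-open interval `[onset, onset + duration)` are
#'   rendered closed.
#' @param drift_sigma Per-frame standard deviation of the area random walk
#'   (squared pixels).
#' @param seed Integer seed.
#' @param image_size Rendered frame side in pixels.
#' @param center_drift_px Amplitude of a slow sinusoidal wander of the pupil
#'   centre, in pixels (0 = static centre).
#' @param noise_sigma Per-frame additive image noise.
#' @param polarity Pupil polarity of the rendered frames.
#' @return An object of class `sequence_spec`.
#' @export
sequence_spec <- function(fps = 30, duration = 10,
                          baseline_area = NULL, events = list(),
                          blink_epochs = list(), drift_sigma = 0, seed = 1,
                          image_size = 128, center_drift_px = 0,
                          noise_sigma = 0.02, polarity = "dark") {
  if (fps <= 0) stop("fps must be positive")
  if (duration <= 0) stop("duration must be positive")
  baseline_area <- baseline_area %||% round(pi * (0.12 * image_size)^2)
  if (baseline_area <= 0) stop("baseline_area must be positive")
  for (b in blink_epochs) {
    if (length(b) != 2 || b[2] <= 0) stop("blink epoch must be (onset, duration > 0)")
    if (b[1] < 0 || b[1] + b[2] > duration)
      stop("blink epochs must lie within [0, duration]")
  }
  structure(list(fps = fps, duration = duration,
                 baseline_area = baseline_area, events = events,
                 blink_epochs = blink_epochs, drift_sigma = drift_sigma,
                 seed = as.integer(seed), image_size = as.integer(image_size),
                 center_drift_px = center_drift_px,
                 noise_sigma = noise_sigma, polarity = polarity),
            class = "sequence_spec")
}

# double-exponential transient, normalized to peak 1 at its analytic maximum
event_kernel <- function(dt, tau_rise, tau_decay) {
  k <- numeric(length(dt))
  pos <- dt >= 0
  if (abs(tau_rise - tau_decay) < 1e-12) {
    k[pos] <- (dt[pos] / tau_rise) * exp(1 - dt[pos] / tau_rise)
  } else {
    tstar <- tau_rise * tau_decay / (tau_decay - tau_rise) *
      log(tau_decay / tau_rise)
    peak <- exp(-tstar / tau_decay) - exp(-tstar / tau_rise)
    k[pos] <- (exp(-dt[pos] / tau_decay) - exp(-dt[pos] / tau_rise)) / peak
  }
  k
}

#' Render a synthetic eye sequence with exact ground truth
#'
#' @param spec A [sequence_spec()].
#' @return List with `frames` (list of `labeled_frame`s) and `truth`, a
#'   data frame `(frame, time_s, area_px, blink)` carrying the analytic
#'   per-frame pupil area; `area_px` is still reported during blink epochs
#'   but flagged by `blink = TRUE` (the pupil is not visible there).
#' @export
make_sequence <- function(spec) {
  stopifnot(inherits(spec, "sequence_spec"))
  nfr <- round(spec$fps * spec$duration)
  t <- (0:(nfr - 1)) / spec$fps
  area <- rep(spec$baseline_area, nfr)
  for (ev in spec$events) {
    tr <- ev$tau_rise %||% 0.5
    td <- ev$tau_decay %||% 2
    area <- area + spec$baseline_area * ev$peak *
      event_kernel(t - ev$onset, tr, td)
  }
  with_seed(spec$seed, {
    if (spec$drift_sigma > 0) {
      walk <- cumsum(rnorm(nfr, 0, spec$drift_sigma))
      area <- pmin(pmax(area + walk, 0.4 * spec$baseline_area),
                   2 * spec$baseline_area)
    }
    blink <- rep(FALSE, nfr)
    for (b in spec$blink_epochs)
      blink <- blink | (t >= b[1] & t < b[1] + b[2])

    n <- spec$image_size
    aspect <- runif(1, 0.8, 0.95)
    angle <- runif(1, 0, pi)
    phase <- runif(2, 0, 2 * pi)
    iris_r <- 0.42 * n
    cx <- n / 2 + spec$center_drift_px * sin(2 * pi * 0.05 * t + phase[1])
    cy <- n / 2 + spec$center_drift_px * sin(2 * pi * 0.07 * t + phase[2])
    frame_seeds <- sample.int(.Machine$integer.max - 1, nfr)

    frames <- lapply(seq_len(nfr), function(i) {
      a_semi <- sqrt(area[i] / (pi * aspect))
      a_semi <- min(a_semi, 0.95 * iris_r)
      app <- eye_appearance(
        image_size = n, pupil_center = c(cx[i], cy[i]),
        pupil_semi_axes = c(a_semi, aspect * a_semi), pupil_angle = angle,
        pupil_polarity = spec$polarity, iris_radius = iris_r,
        eyelid_openness = if (blink[i]) 0 else 1,
        noise_sigma = spec$noise_sigma)
      render_frame(app, seed = frame_seeds[i])
    })
    truth <- data.frame(frame = 0:(nfr - 1), time_s = t, area_px = area,
                        blink = blink)
    list(frames = frames, truth = truth)
  })
}

#' Write a labelled frame set as 8-bit PNGs plus an index CSV
#'
#' Creates `images/`, `masks/` and `index.csv`
#' (`filename, class, blink, eye_present, mask`) under `dir`. Intensities are
#' synthesized as floats in `[0, 1]` and quantized to 8 bits on write.
#'
#' @param frames List of `labeled_frame`s.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the index data frame.
#' @export
write_eye_dataset <- function(frames, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  idx <- data.frame(filename = character(0), class = character(0),
                    blink = logical(0), eye_present = logical(0),
                    mask = character(0))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    img_name <- sprintf("images/frame_%05d.png", i - 1)
    msk_name <- sprintf("masks/frame_%05d.png", i - 1)
    png::writePNG(round(f$image * 255) / 255, file.path(dir, img_name))
    png::writePNG(f$mask, file.path(dir, msk_name))
    idx[i, ] <- list(img_name, attr(f, "class_tag") %||% "unknown",
                     f$blink, f$eye_present, msk_name)
  }
  write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  invisible(idx)
}

#' Write a synthetic sequence as frame PNGs plus a ground-truth CSV
#'
#' @param seq Output of [make_sequence()].
#' @param dir Output directory.
#' @return Invisibly, the truth data frame.
#' @export
write_eye_sequence <- function(seq, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(seq$frames))
    png::writePNG(round(seq$frames[[i]]$image * 255) / 255,
                  file.path(dir, sprintf("frame_%05d.png", i - 1)))
  write.csv(seq$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(seq$truth)
}
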