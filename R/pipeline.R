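#' Region-of-interest state
#'
#' The square window (network input size) cut from each source frame,
#' optionally re-centred each frame on the tracked pupil centroid.
#'
#' @param center Numeric `(x, y)` centre in source-frame pixels (0-based).
#' @param size ROI side in pixels (the network input size).
#' @param follow Re-centre the ROI on the measured pupil centroid.
#' @return An object of class `roi_state`.
#' @export
roi_state <- function(center, size = 128, follow = TRUE) {
  stopifnot(length(center) == 2, size >= 2)
  structure(list(center = as.numeric(center), size = as.integer(size),
                 follow = isTRUE(follow)), class = "roi_state")
}

#' Preprocessing settings (inversion, contrast/brightness, gamma)
#'
#' Applied in the fixed order: inversion (`1 - image`) if enabled, then
#' `image * contrast + brightness`, clipping to `[0, 1]`, then the gamma
#' power, clipping again.
#'
#' @param brightness Additive offset.
#' @param contrast Multiplicative gain.
#' @param gamma Power-law exponent, must be positive.
#' @param invert Invert gray levels first.
#' @return An object of class `preproc_settings`.
#' @export
preproc_settings <- function(brightness = 0, contrast = 1, gamma = 1,
                             invert = FALSE) {
  if (gamma <= 0) stop("gamma must be positive")
  structure(list(brightness = brightness, contrast = contrast,
                 gamma = gamma, invert = isTRUE(invert)),
            class = "preproc_settings")
}

#' Postprocessing settings (map threshold and morphology)
#'
#' @param threshold Probability cutoff in `[0, 1]` applied to the pupil map.
#' @param morphology Apply morphological refinement ([morph_refine()]).
#' @return An object of class `postproc_settings`.
#' @export
postproc_settings <- function(threshold = 0.5, morphology = TRUE) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  structure(list(threshold = threshold, morphology = isTRUE(morphology)),
            class = "postproc_settings")
}

#' Species presets for offline video analysis
#'
#' Thresholds 0.25, 0.15 and 0.5, with morphology off, on and on, for
#' `"human"`, `"mouse"` and `"2P-mouse"` recordings respectively.
#'
#' @param preset One of `"human"`, `"mouse"`, `"2P-mouse"`.
#' @return A [postproc_settings()] object.
#' @export
pipeline_preset <- function(preset = c("human", "mouse", "2P-mouse")) {
  preset <- match.arg(preset)
  switch(preset,
         "human" = postproc_settings(0.25, morphology = FALSE),
         "mouse" = postproc_settings(0.15, morphology = TRUE),
         "2P-mouse" = postproc_settings(0.5, morphology = TRUE))
}

#' Apply tunable preprocessing to a gray image
#'
#' @param image Gray matrix in `[0, 1]`.
#' @param settings A [preproc_settings()].
#' @return Preprocessed image, clipped to `[0, 1]`.
#' @export
apply_preprocess <- function(image, settings) {
  stopifnot(inherits(settings, "preproc_settings"))
  x <- image
  if (settings$invert) x <- 1 - x
  x <- clip01(x * settings$contrast + settings$brightness)
  clip01(x^settings$gamma)
}

#' Threshold a probability map
#'
#' @param map Matrix of probabilities in `[0, 1]`.
#' @param threshold Cutoff; a pixel is foreground when `map >= threshold`
#'   (closed at the cutoff, so threshold 0 yields the all-ones mask).
#' @return Binary 0/1 matrix.
#' @export
threshold_map <- function(map, threshold) {
  (map >= threshold) * 1
}

#' Morphological refinement of a binary mask
#'
#' Binary opening with the 3x3 cross structuring element followed by
#' retention of the largest 8-connected component. Removes speckle and
#' enforces a single pupil blob; never adds pixels outside the input mask.
#'
#' @param mask Binary 0/1 matrix.
#' @param enabled If `FALSE`, the mask is returned unchanged.
#' @return Refined binary mask.
#' @export
morph_refine <- function(mask, enabled = TRUE) {
  if (!enabled) return(mask)
  storage.mode(mask) <- "double"
  opened <- morph_open_cross_cpp(mask)
  opened <- opened * (mask > 0) # opening never grows beyond the input
  largest_component_cpp(opened)
}

#' Measure area and centroid of a binary mask within an ROI
#'
#' Area is the foreground pixel count; the centroid is the mean 0-based
#' pixel coordinate mapped back into source-frame coordinates via the ROI
#' origin. An empty mask yields `NA` centroid coordinates.
#'
#' @param mask Binary mask at ROI resolution.
#' @param roi A [roi_state()] locating the mask in the source frame.
#' @return List with `area` (pixels) and `centroid` (`(x, y)` source px,
#'   `NA` when the area is 0).
#' @export
measure_mask <- function(mask, roi) {
  area <- sum(mask > 0)
  if (area == 0)
    return(list(area = 0, centroid = c(NA_real_, NA_real_)))
  ys <- (row(mask) - 1)[mask > 0]
  xs <- (col(mask) - 1)[mask > 0]
  origin <- roi_origin(roi)
  list(area = area,
       centroid = c(mean(xs) + origin[1], mean(ys) + origin[2]))
}

# top-left (x0, y0) of the ROI window, unclamped
roi_origin <- function(roi) round(roi$center - roi$size / 2)

# clamp the ROI window inside a frame of the given size
clamp_roi <- function(roi, frame_dim) {
  origin <- roi_origin(roi)
  x0 <- min(max(origin[1], 0), frame_dim[2] - roi$size)
  y0 <- min(max(origin[2], 0), frame_dim[1] - roi$size)
  roi_state(c(x0 + roi$size / 2, y0 + roi$size / 2), roi$size, roi$follow)
}

#' Process one frame: crop, preprocess, predict, refine, measure
#'
#' Cuts the ROI window from the frame, applies preprocessing, runs the
#' network, thresholds and refines the pupil map, measures area and
#' centroid in source coordinates, and (when `roi$follow` and the area is
#' positive) re-centres the ROI on the measured centroid, clamped to the
#' frame bounds.
#'
#' @param frame Gray matrix (at least ROI-sized).
#' @param model A `segmenter` whose input size equals the ROI size.
#' @param roi A [roi_state()].
#' @param pre A [preproc_settings()].
#' @param post A [postproc_settings()].
#' @param triggers Logical vector of 4 trigger-channel states for this frame.
#' @return List with `measure` (list: `area`, `centroid`, `eye_prob`,
#'   `blink_prob`, `triggers`) and `roi` (updated [roi_state()]).
#' @export
pipeline_step <- function(frame, model, roi, pre = preproc_settings(),
                 post = postproc_settings(), triggers = rep(FALSE, 4)) {
  if (nrow(frame) < roi$size || ncol(frame) < roi$size)
    stop("frame smaller than ROI")
  roi <- clamp_roi(roi, dim(frame))
  origin <- roi_origin(roi)
  crop <- frame[origin[2] + 1:roi$size, origin[1] + 1:roi$size]
  crop <- apply_preprocess(crop, pre)
  pred <- predict_frame(model, crop)
  mask <- threshold_map(pred$pupil_map, post$threshold)
  mask <- morph_refine(mask, post$morphology)
  meas <- measure_mask(mask, roi)
  new_roi <- roi
  if (roi$follow && meas$area > 0) {
    new_roi <- clamp_roi(roi_state(meas$centroid, roi$size, roi$follow),
                         dim(frame))
  }
  list(measure = list(area = meas$area, centroid = meas$centroid,
                      eye_prob = pred$eye_prob, blink_prob = pred$blink_prob,
                      triggers = as.logical(triggers)),
       roi = new_roi)
}

# normalize the various frame-source types to a list of gray matrices
load_frames <- function(source) {
  if (is.list(source)) {
    frames <- lapply(source, function(f) if (inherits(f, "labeled_frame"))
      f$image else f)
  } else if (is.array(source) && length(dim(source)) == 3) {
    frames <- lapply(seq_len(dim(source)[3]), function(i) source[, , i])
  } else if (is.character(source) && length(source) == 1 &&
             dir.exists(source)) {
    files <- sort(list.files(source, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0) stop("no PNG/TIFF frames found in ", source)
    frames <- lapply(files, read_gray_image)
  } else {
    stop("unreadable frame source")
  }
  if (length(frames) == 0) stop("zero frames in source")
  frames
}

#' Run the full pipeline over a frame source
#'
#' Processes every frame of a frame directory (PNG/TIFF), a list of frames
#' (matrices or `labeled_frame`s) or a 3-D array, producing one measurement
#' per frame.
#'
#' @param source Frame directory path, list of frames, or H x W x N array.
#' @param model A `segmenter`.
#' @param post A [postproc_settings()] or a preset name
#'   (`"human"`, `"mouse"`, `"2P-mouse"`).
#' @param pre A [preproc_settings()].
#' @param roi Initial [roi_state()]; default: frame centre, size = model
#'   input.
#' @param follow When `roi` is `NULL`, whether the default ROI follows the
#'   tracked pupil centre.
#' @param fps Frame rate used for the time axis.
#' @param events Optional data frame `(time_s, channel)` of trigger events;
#'   each marks channel 1-4 `TRUE` on the frame containing its timestamp.
#' @return A `pupil_trace`: data frame with columns `frame`, `time_s`,
#'   `area_px`, `pupil_x`, `pupil_y`, `eye_prob`, `blink_prob`,
#'   `trig1`..`trig4`, with the frame rate in `attr(, "fps")`.
#' @export
run_video <- function(source, model, post = postproc_settings(),
                      pre = preproc_settings(), roi = NULL, fps = 30,
                      events = NULL, follow = TRUE) {
  if (is.character(post)) post <- pipeline_preset(post)
  frames <- load_frames(source)
  n <- length(frames)
  d <- dim(frames[[1]])
  if (is.null(roi))
    roi <- roi_state(c(d[2] / 2, d[1] / 2), size = model$config$input_size,
                     follow = follow)
  trig <- matrix(FALSE, n, 4)
  if (!is.null(events) && nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      fr <- floor(events$time_s[i] * fps)
      ch <- events$channel[i]
      if (fr >= 0 && fr < n && ch >= 1 && ch <= 4) trig[fr + 1, ch] <- TRUE
    }
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    res <- pipeline_step(frames[[i]], model, roi, pre, post, triggers = trig[i, ])
    roi <- res$roi
    m <- res$measure
    rows[[i]] <- data.frame(
      frame = i - 1L, time_s = (i - 1) / fps, area_px = m$area,
      pupil_x = m$centroid[1], pupil_y = m$centroid[2],
      eye_prob = m$eye_prob, blink_prob = m$blink_prob,
      trig1 = m$triggers[1], trig2 = m$triggers[2], trig3 = m$triggers[3],
      trig4 = m$triggers[4])
    if (i %% 1000 == 0)
      message(sprintf("processed %d/%d frames", i, n))
  }
  trace <- do.call(rbind, rows)
  as_pupil_trace(trace, fps)
}

#' Construct a pupil trace from a measurement data frame
#'
#' @param df Data frame with the documented trace columns.
#' @param fps Nominal frame rate.
#' @return A `pupil_trace` (data frame with `fps` attribute).
#' @export
as_pupil_trace <- function(df, fps) {
  stopifnot(fps > 0, all(c("frame", "time_s", "area_px") %in% names(df)))
  if (is.unsorted(df$time_s, strictly = TRUE))
    stop("trace times must be strictly increasing")
  structure(df, fps = fps, class = c("pupil_trace", "data.frame"))
}

#' Frame rate of a pupil trace
#' @param trace A `pupil_trace`.
#' @return Frames per second.
#' @export
trace_fps <- function(trace) attr(trace, "fps")

TRACE_COLUMNS <- c("frame", "time_s", "area_px", "pupil_x", "pupil_y",
                   "eye_prob", "blink_prob", "trig1", "trig2", "trig3",
                   "trig4")

fmt6 <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("")
    s <- trimws(formatC(signif(v, 6), format = "fg", digits = 6))
    if (grepl(".", s, fixed = TRUE)) # strip trailing zeros after the point
      s <- sub("\\.$", "", sub("0+$", "", s))
    s
  }, character(1))
}

#' Export / import a pupil trace as CSV
#'
#' The header line is exactly
#' `frame,time_s,area_px,pupil_x,pupil_y,eye_prob,blink_prob,trig1,trig2,trig3,trig4`.
#' Numeric fields are written with 6 significant digits; centroid columns of
#' zero-area frames are written as empty strings, not zeros. The frame rate
#' is not part of the file and must be supplied again on read.
#'
#' @param trace A `pupil_trace`.
#' @param path Output CSV path.
#' @return `read_pupil_csv` returns the restored `pupil_trace`.
#' @export
write_pupil_csv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(TRACE_COLUMNS, collapse = ","), con)
  for (i in seq_len(nrow(trace))) {
    r <- trace[i, ]
    writeLines(paste(c(
      r$frame, fmt6(r$time_s), fmt6(r$area_px), fmt6(r$pupil_x),
      fmt6(r$pupil_y), fmt6(r$eye_prob), fmt6(r$blink_prob),
      as.integer(r$trig1), as.integer(r$trig2), as.integer(r$trig3),
      as.integer(r$trig4)), collapse = ","), con)
  }
  invisible(path)
}

#' @rdname write_pupil_csv
#' @param fps Frame rate of the recorded trace.
#' @export
read_pupil_csv <- function(path, fps = 30) {
  lines <- readLines(path)
  if (length(lines) < 1) stop("malformed trace file: no header at line 1")
  start <- 1
  header <- strsplit(lines[start], ",")[[1]]
  if (!identical(header, TRACE_COLUMNS))
    stop("malformed trace file at line ", start, ": unexpected header")
  body <- lines[-seq_len(start)]
  rows <- lapply(seq_along(body), function(i) {
    parts <- strsplit(body[i], ",", fixed = TRUE)[[1]]
    if (length(parts) != length(TRACE_COLUMNS))
      stop("malformed trace file at line ", start + i, ": expected ",
           length(TRACE_COLUMNS), " fields")
    parts
  })
  num <- function(j) vapply(rows, function(p)
    if (p[j] == "") NA_real_ else as.numeric(p[j]), numeric(1))
  df <- data.frame(
    frame = as.integer(num(1)), time_s = num(2), area_px = num(3),
    pupil_x = num(4), pupil_y = num(5), eye_prob = num(6),
    blink_prob = num(7), trig1 = num(8) > 0, trig2 = num(9) > 0,
    trig3 = num(10) > 0, trig4 = num(11) > 0)
  as_pupil_trace(df, fps)
}

#' Read a grayscale PNG/TIFF image as a matrix in `[0, 1]`
#' @param path Image file path.
#' @return Gray matrix; RGB inputs are averaged over channels.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3])],
                                          c(1, 2), mean)
  img
}
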