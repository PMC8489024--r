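#' Detect blink epochs from the blink-probability channel
#'
#' A blink epoch is a maximal run of frames whose blink probability is at
#' least `cutoff`; runs separated by fewer than `merge_gap` non-blink frames
#' are merged to avoid flickering epochs. Epochs are half-open frame
#' intervals `[start, end)` in the trace's 0-based frame numbering.
#'
#' @param trace A `pupil_trace` with a `blink_prob` column.
#' @param cutoff Blink-probability cutoff.
#' @param merge_gap Runs closer than this many frames are merged.
#' @return Data frame with columns `start`, `end` (0-based, half-open),
#'   sorted and disjoint; zero rows when no frame crosses the cutoff.
#' @export
blink_epochs <- function(trace, cutoff = 0.5, merge_gap = 2) {
  flag <- trace$blink_prob >= cutoff
  if (!any(flag)) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ep <- data.frame(start = starts[r$values] - 1, end = ends[r$values])
  if (nrow(ep) > 1) {
    keep <- list(ep[1, ])
    for (i in 2:nrow(ep)) {
      last <- keep[[length(keep)]]
      if (ep$start[i] - last$end < merge_gap) {
        keep[[length(keep)]]$end <- ep$end[i]
      } else {
        keep[[length(keep) + 1]] <- ep[i, ]
      }
    }
    ep <- do.call(rbind, keep)
  }
  rownames(ep) <- NULL
  ep
}

#' Remove blinks by interpolation and median filtering
#'
#' Area samples inside blink epochs are replaced by linear interpolation
#' between the nearest valid neighbours (epochs touching the trace edges are
#' held at the nearest valid value), then the whole area trace is median
#' filtered with a window of `round(0.5 s * fps)` samples, forced odd by
#' adding one.
#'
#' @param trace A `pupil_trace`.
#' @param epochs Blink epochs as returned by [blink_epochs()] (0-based
#'   half-open frame intervals).
#' @param filter_s Median filter length in seconds.
#' @return The trace with `area_px` deblinked; the filled frames are marked
#'   in a logical `interpolated` column.
#' @export
deblink <- function(trace, epochs, filter_s = 0.5) {
  n <- nrow(trace)
  bad <- rep(FALSE, n)
  for (i in seq_len(nrow(epochs))) {
    if (epochs$start[i] < 0 || epochs$end[i] > n ||
        epochs$start[i] >= epochs$end[i])
      stop("blink epoch outside trace")
    bad[(epochs$start[i] + 1):epochs$end[i]] <- TRUE
  }
  if (all(bad)) stop("all samples fall in blink epochs")
  area <- trace$area_px
  if (any(bad)) {
    good <- which(!bad)
    area[bad] <- approx(x = good, y = area[good], xout = which(bad),
                        method = "linear", rule = 2)$y
  }
  k <- round(filter_s * trace_fps(trace))
  if (k %% 2 == 0) k <- k + 1
  if (k >= 3 && k <= n) area <- as.numeric(runmed(area, k, endrule = "median"))
  out <- trace
  out$area_px <- area
  out$interpolated <- bad
  out
}

#' Event-aligned trial matrix
#'
#' Holds trials x timepoints values on the trace's frame grid, a relative
#' time axis, and the baseline window used for z-scoring and significance.
#'
#' @param values Trials x timepoints numeric matrix.
#' @param time Relative time axis in seconds (length = columns).
#' @param baseline `(t0, t1)` half-open baseline window in relative seconds,
#'   preceding the event onset at 0.
#' @return An object of class `trial_matrix`.
#' @export
trial_matrix <- function(values, time, baseline) {
  values <- as.matrix(values)
  stopifnot(ncol(values) == length(time), length(baseline) == 2,
            baseline[1] < baseline[2], baseline[2] <= 0)
  if (!any(time >= baseline[1] & time < baseline[2]))
    stop("baseline window contains no samples")
  structure(list(values = values, time = time,
                 baseline = as.numeric(baseline)), class = "trial_matrix")
}

baseline_cols <- function(m) which(m$time >= m$baseline[1] &
                                     m$time < m$baseline[2])

#' Align a trace on event onsets
#'
#' Cuts one row per event from the area trace, spanning `window[1]` seconds
#' before to `window[2]` seconds after the onset on the trace's frame grid.
#' Events whose window exceeds the trace are dropped with a warning.
#'
#' @param trace A `pupil_trace` (typically deblinked).
#' @param events Event onset times in seconds.
#' @param window `(pre, post)` extents in seconds; a 15 s window centred on
#'   the event is `c(7.5, 7.5)`.
#' @param baseline Baseline window relative to onset; default the full
#'   pre-onset half of the window.
#' @param column Trace column to align (default `area_px`).
#' @return A [trial_matrix()].
#' @export
event_align <- function(trace, events, window = c(7.5, 7.5),
                        baseline = c(-window[1], 0), column = "area_px") {
  fps <- trace_fps(trace)
  ncols <- round(sum(window) * fps)
  rel_time <- (seq_len(ncols) - 1) / fps - window[1]
  n <- nrow(trace)
  rows <- list(); kept <- c()
  for (e in events) {
    i0 <- round((e - window[1]) * fps) # 0-based first frame
    if (i0 < 0 || i0 + ncols > n) {
      warning(sprintf("event at %.3f s: window exceeds trace; dropped", e))
      next
    }
    rows[[length(rows) + 1]] <- trace[[column]][(i0 + 1):(i0 + ncols)]
    kept <- c(kept, e)
  }
  if (length(rows) == 0) stop("no event window fits inside the trace")
  m <- trial_matrix(do.call(rbind, rows), rel_time, baseline)
  attr(m, "events") <- kept
  m
}

#' Z-score each trial by its own baseline
#'
#' Applies `z = (x - mean(baseline)) / sd(baseline)` per trial. Trials with
#' zero baseline SD are excluded with a warning.
#'
#' @param m A [trial_matrix()].
#' @return A `trial_matrix` of z values (possibly fewer rows).
#' @export
zscore_trials <- function(m) {
  stopifnot(inherits(m, "trial_matrix"))
  bl <- baseline_cols(m)
  mu <- rowMeans(m$values[, bl, drop = FALSE])
  sdev <- apply(m$values[, bl, drop = FALSE], 1, sd)
  bad <- sdev == 0 | !is.finite(sdev)
  if (any(bad)) {
    warning(sprintf("%d trial(s) with zero baseline SD excluded", sum(bad)))
    if (all(bad)) stop("no trial has positive baseline SD")
  }
  z <- (m$values[!bad, , drop = FALSE] - mu[!bad]) / sdev[!bad]
  trial_matrix(z, m$time, m$baseline)
}

#' Tag locomotion state from a velocity trace
#'
#' A sample is "moving" when its speed is at least 10% of the maximal speed
#' over the recording; otherwise "stationary". An all-zero (or nonpositive)
#' velocity trace is entirely stationary.
#'
#' @param v Nonnegative per-sample speeds.
#' @param fraction Moving threshold as a fraction of the maximum.
#' @return Logical vector, `TRUE` = moving.
#' @export
locomotion_state <- function(v, fraction = 0.10) {
  if (length(v) == 0) stop("empty velocity trace")
  vmax <- max(v)
  if (vmax <= 0) return(rep(FALSE, length(v)))
  v >= fraction * vmax
}

#' Pointwise comparison of post-onset samples against baseline
#'
#' For every timepoint after the event onset, the trial values are compared
#' with each trial's own baseline mean using a paired t statistic, and the
#' resulting p values are adjusted across timepoints with the
#' Benjamini-Hochberg FDR procedure.
#'
#' @param m A [trial_matrix()] with at least 3 trials.
#' @param alpha Significance level applied to the adjusted p values.
#' @return Data frame with `time`, `p`, `p_adj`, `significant` for each
#'   post-onset timepoint (`time >= 0`).
#' @export
pointwise_significance <- function(m, alpha = 0.05) {
  stopifnot(inherits(m, "trial_matrix"))
  nt <- nrow(m$values)
  if (nt < 3) stop("at least 3 trials are required")
  bl <- baseline_cols(m)
  base_mean <- rowMeans(m$values[, bl, drop = FALSE])
  post <- which(m$time >= 0)
  d <- m$values[, post, drop = FALSE] - base_mean # paired differences
  dbar <- colMeans(d)
  dsd <- sqrt(colSums((d - rep(dbar, each = nt))^2) / (nt - 1))
  tstat <- dbar / (dsd / sqrt(nt))
  p <- 2 * pt(-abs(tstat), df = nt - 1)
  p[dsd == 0 & dbar == 0] <- 1 # no difference at all
  p_adj <- p.adjust(p, method = "BH")
  data.frame(time = m$time[post], p = p, p_adj = p_adj,
             significant = p_adj < alpha)
}

#' Mean absolute error between traces from two devices
#'
#' Both traces are min-max normalized to `[-1, 1]`; the lower-rate trace is
#' linearly interpolated onto the higher-rate grid (e.g. 15 fps eye-camera
#' data upsampled to a 1000 Hz tracker grid); the MAE is taken over the
#' common time support.
#'
#' @param a,b Numeric traces (or `pupil_trace`s, whose `area_px` is used).
#' @param fps_a,fps_b Sampling rates; taken from the traces when omitted.
#' @return Scalar mean absolute error.
#' @export
trace_mae <- function(a, b, fps_a = NULL, fps_b = NULL) {
  get_vals <- function(x, f) {
    if (inherits(x, "pupil_trace")) list(v = x$area_px, fps = trace_fps(x))
    else list(v = as.numeric(x), fps = f)
  }
  A <- get_vals(a, fps_a); B <- get_vals(b, fps_b)
  if (is.null(A$fps) || is.null(B$fps)) stop("sampling rates are required")
  norm11 <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) stop("constant trace cannot be normalized to [-1, 1]")
    2 * (v - r[1]) / (r[2] - r[1]) - 1
  }
  va <- norm11(A$v); vb <- norm11(B$v)
  ta <- (seq_along(va) - 1) / A$fps
  tb <- (seq_along(vb) - 1) / B$fps
  tmax <- min(max(ta), max(tb))
  if (tmax <= 0) stop("traces have no overlapping time support")
  if (A$fps >= B$fps) {
    grid <- ta[ta <= tmax]
    hi <- va[ta <= tmax]
    lo <- approx(tb, vb, xout = grid, method = "linear", rule = 2)$y
  } else {
    grid <- tb[tb <= tmax]
    hi <- vb[tb <= tmax]
    lo <- approx(ta, va, xout = grid, method = "linear", rule = 2)$y
  }
  mean(abs(hi - lo))
}

#' Summarize pupil area by locomotion state
#'
#' @param trace A `pupil_trace`.
#' @param moving Logical per-frame moving tag ([locomotion_state()]).
#' @return Data frame with mean area and sample count per state.
#' @export
state_summary <- function(trace, moving) {
  stopifnot(nrow(trace) == length(moving))
  data.frame(state = c("moving", "stationary"),
             mean_area = c(mean(trace$area_px[moving]),
                           mean(trace$area_px[!moving])),
             n = c(sum(moving), sum(!moving)))
}
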