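test_that("blink epochs are maximal half-open runs with gap merging", {
  expect_equal(nrow(blink_epochs(mk_trace(rep(10, 5)))), 0)

  tr <- mk_trace(rep(10, 5), blink_prob = c(0, 0, 0.9, 0.9, 0))
  ep <- blink_epochs(tr, cutoff = 0.5)
  expect_equal(ep$start, 2)
  expect_equal(ep$end, 4)

  # runs [2,4) and [5,7) separated by one frame merge at merge_gap = 2
  tr2 <- mk_trace(rep(10, 8),
                  blink_prob = c(0, 0, 0.9, 0.9, 0, 0.9, 0.9, 0))
  ep2 <- blink_epochs(tr2, cutoff = 0.5, merge_gap = 2)
  expect_equal(nrow(ep2), 1)
  expect_equal(c(ep2$start, ep2$end), c(2, 7))
  # without merging they stay separate
  ep3 <- blink_epochs(tr2, cutoff = 0.5, merge_gap = 1)
  expect_equal(nrow(ep3), 2)
})

test_that("deblinking interpolates linearly and median-filters at 0.5 s", {
  tr <- mk_trace(c(10, 10, 99, 99, 10), fps = 4) # window round(2) -> 3
  ep <- data.frame(start = 2, end = 4)
  db <- deblink(tr, ep)
  expect_equal(db$area_px, rep(10, 5))

  # linear fill between unequal neighbours, checked before filtering
  tr2 <- mk_trace(c(0, 99, 99, 30), fps = 1) # window 1: no filtering
  db2 <- deblink(tr2, data.frame(start = 1, end = 3))
  expect_equal(db2$area_px, c(0, 10, 20, 30))

  # fps 30: round(0.5 * 30) = 15, already odd
  set.seed(5)
  tr3 <- mk_trace(100 + rnorm(90), fps = 30)
  db3 <- deblink(tr3, data.frame(start = integer(0), end = integer(0)))
  expect_equal(db3$area_px, as.numeric(runmed(tr3$area_px, 15,
                                              endrule = "median")))

  # epochs at the trace edge hold the nearest valid value
  tr4 <- mk_trace(c(99, 99, 7, 8), fps = 1)
  db4 <- deblink(tr4, data.frame(start = 0, end = 2))
  expect_equal(db4$area_px, c(7, 7, 7, 8))

  expect_error(deblink(mk_trace(c(1, 2)), data.frame(start = 0, end = 2)),
               "all samples")
})

test_that("z-scoring matches the formula and the two-pass oracle", {
  # baseline samples (90, 100, 110): mean 100, SD 10; a sample of 120 -> z 2
  vals <- rbind(c(90, 100, 110, 120, 95))
  m <- trial_matrix(vals, time = c(-3, -2, -1, 0, 1), baseline = c(-3, 0))
  z <- zscore_trials(m)
  expect_equal(z$values[1, 4], 2.0)

  # constant trial at its baseline mean maps to zero everywhere
  m2 <- trial_matrix(rbind(c(90, 110, 100, 100)), time = c(-2, -1, 0, 1),
                     baseline = c(-2, 0))
  expect_equal(zscore_trials(m2)$values[1, 3:4], c(0, 0))

  set.seed(6)
  vals3 <- matrix(rnorm(5 * 40, 100, 12), 5, 40)
  time3 <- seq(-1, 2.9, by = 0.1)
  m3 <- trial_matrix(vals3, time3, baseline = c(-1, 0))
  z3 <- zscore_trials(m3)
  bl <- which(time3 >= -1 & time3 < 0)
  expect_equal(z3$values, oracle_zscore(vals3, bl), tolerance = 1e-12)
  # baseline of the output: mean 0, SD 1 per trial
  expect_lt(max(abs(rowMeans(z3$values[, bl]))), 1e-10)
  expect_lt(max(abs(apply(z3$values[, bl], 1, sd) - 1)), 1e-10)

  # zero-SD trials are excluded with a warning
  vals4 <- rbind(c(1, 1, 1, 5), c(1, 2, 3, 4))
  m4 <- trial_matrix(vals4, c(-2, -1.5, -1, 0), baseline = c(-2, -0.5))
  expect_warning(z4 <- zscore_trials(m4), "zero baseline SD")
  expect_equal(nrow(z4$values), 1)
})

test_that("event alignment samples the frame grid and drops bad events", {
  tr <- mk_trace(rep(100, 40 * 30), fps = 30)
  m <- event_align(tr, c(10, 25), window = c(7.5, 7.5))
  expect_equal(ncol(m$values), 450) # 15 s at 30 fps
  expect_equal(nrow(m$values), 2)
  expect_warning(m2 <- event_align(tr, c(1, 20), window = c(7.5, 7.5)),
                 "dropped")
  expect_equal(nrow(m2$values), 1)
  expect_error(suppressWarnings(event_align(tr, c(1), window = c(7.5, 7.5))),
               "no event")
})

test_that("locomotion tagging thresholds at exactly 10% of maximal speed", {
  v <- c(2.0, 1.99, 20, 0.5)
  expect_equal(locomotion_state(v), c(TRUE, FALSE, TRUE, FALSE))
  expect_true(all(locomotion_state(rep(3, 5)))) # constant: v = max
  expect_false(any(locomotion_state(rep(0, 5)))) # no movement at all
  # invariant under positive rescaling
  set.seed(7)
  v2 <- runif(50, 0, 10)
  expect_identical(locomotion_state(v2), locomotion_state(3.7 * v2))
})

test_that("BH adjustment reproduces the hand-computed worked example", {
  # sorted p (0.01, 0.02, 0.03, 0.04, 0.20): p * 5 / rank gives
  # (0.05, 0.05, 0.05, 0.05, 0.20); the step-up minimum changes nothing
  p <- c(0.02, 0.2, 0.01, 0.04, 0.03)
  expect_equal(p.adjust(p, method = "BH"),
               c(0.05, 0.20, 0.05, 0.05, 0.05))
})

test_that("pointwise significance is paired-t plus BH across timepoints", {
  set.seed(8)
  vals <- matrix(rnorm(6 * 30), 6, 30)
  vals[, 25] <- vals[, 25] + 5 # strong effect at one timepoint
  time <- seq(-1, 1.9, by = 0.1)
  m <- trial_matrix(vals, time, baseline = c(-1, 0))
  res <- pointwise_significance(m)
  expect_equal(nrow(res), sum(time >= 0))
  expect_true(res$significant[which.min(abs(res$time - 1.4))])

  # per-timepoint p agrees with stats::t.test on the paired differences
  bl <- which(time >= -1 & time < 0)
  bmean <- rowMeans(vals[, bl])
  j <- which(time >= 0)[3]
  ref <- t.test(vals[, j] - bmean)$p.value
  expect_equal(res$p[3], ref, tolerance = 1e-12)

  # single post-onset timepoint: BH is the identity on one p value
  m1 <- trial_matrix(vals[, c(bl, which(time >= 0)[1])],
                     c(time[bl], 0), baseline = c(-1, 0))
  r1 <- pointwise_significance(m1)
  expect_equal(r1$p, r1$p_adj)

  expect_error(pointwise_significance(
    trial_matrix(vals[1:2, ], time, baseline = c(-1, 0))), "3 trials")
})

test_that("trace MAE normalizes, upsamples and averages as defined", {
  expect_equal(trace_mae(sin(1:100), sin(1:100), 10, 10), 0)

  set.seed(9)
  a <- runif(50)
  b <- max(a) + min(a) - a # mirrored: normalized b = -normalized a
  ahat <- 2 * (a - min(a)) / (max(a) - min(a)) - 1
  expect_equal(trace_mae(a, b, 10, 10), mean(abs(2 * ahat)),
               tolerance = 1e-12)

  # 15 fps samples of a slow sinusoid upsampled onto a 1000 fps grid
  t_hi <- seq(0, 10, by = 1 / 1000)
  hi <- sin(2 * pi * 0.1 * t_hi)
  lo <- sin(2 * pi * 0.1 * seq(0, 10, by = 1 / 15))
  expect_lte(trace_mae(lo, hi, 15, 1000), 0.01)

  expect_error(trace_mae(rep(1, 10), 1:10, 5, 5), "constant")
})

test_that("state summary splits mean area by locomotion state", {
  tr <- mk_trace(c(10, 20, 30, 40), fps = 1)
  s <- state_summary(tr, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(s$mean_area, c(15, 35))
  expect_equal(s$n, c(2, 2))
})
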