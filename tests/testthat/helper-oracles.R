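# Independent oracles used across the suite. These deliberately use naive
# algorithms (double loops, flood fill, closed forms) so they share no code
# with the implementation paths they check.

# count pixel centres inside a rotated ellipse by brute-force double loop
oracle_ellipse_pixel_count <- function(n, center, semi_axes, angle = 0) {
  count <- 0
  for (x in 0:(n - 1)) for (y in 0:(n - 1)) {
    dx <- x - center[1]; dy <- y - center[2]
    u <- (dx * cos(angle) + dy * sin(angle)) / semi_axes[1]
    v <- (-dx * sin(angle) + dy * cos(angle)) / semi_axes[2]
    if (u^2 + v^2 <= 1) count <- count + 1
  }
  count
}

# naive area + centroid by double loop (0-based coordinates)
oracle_measure <- function(mask) {
  area <- 0L; sx <- 0; sy <- 0
  for (x in seq_len(ncol(mask))) for (y in seq_len(nrow(mask))) {
    if (mask[y, x] > 0) {
      area <- area + 1L
      sx <- sx + (x - 1); sy <- sy + (y - 1)
    }
  }
  if (area == 0) list(area = 0, centroid = c(NA, NA))
  else list(area = area, centroid = c(sx / area, sy / area))
}

# largest 8-connected component by recursive flood fill over an R matrix
oracle_largest_component <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (x0 in seq_len(w)) for (y0 in seq_len(h)) {
    if (mask[y0, x0] > 0 && lab[y0, x0] == 0L) {
      cur <- cur + 1L
      queue <- list(c(y0, x0))
      lab[y0, x0] <- cur
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (dy in -1:1) for (dx in -1:1) {
          yy <- p[1] + dy; xx <- p[2] + dx
          if (yy >= 1 && yy <= h && xx >= 1 && xx <= w &&
              mask[yy, xx] > 0 && lab[yy, xx] == 0L) {
            lab[yy, xx] <- cur
            queue[[length(queue) + 1]] <- c(yy, xx)
          }
        }
      }
    }
  }
  if (cur == 0L) return(mask * 0)
  sizes <- tabulate(lab[lab > 0], nbins = cur)
  (lab == which.max(sizes)) * 1
}

# element-wise binary cross-entropy with explicit clipping
oracle_bce_sum <- function(map_p, map_y, eye_p, eye_y, blink_p, blink_y,
                           eps = 1e-7) {
  clip <- function(p) pmin(pmax(p, eps), 1 - eps)
  f <- function(p, y) -(y * log(clip(p)) + (1 - y) * log(1 - clip(p)))
  mean(f(map_p, map_y)) + f(eye_p, eye_y) + f(blink_p, blink_y)
}

# two-pass z-score: explicit per-trial mean/SD, then transform
oracle_zscore <- function(values, bl_cols) {
  out <- values
  for (i in seq_len(nrow(values))) {
    mu <- mean(values[i, bl_cols])
    sdev <- sd(values[i, bl_cols])
    out[i, ] <- (values[i, ] - mu) / sdev
  }
  out
}

# reference forward pass + summed BCE loss for a tiny network, in double
# precision with direct convolution loops (independent of the C++ path)
oracle_net_loss <- function(params, cfg, image, mask, eye, blink) {
  conv3 <- function(X, W, b, relu = TRUE) {
    # X: H x W x Cin array; W: (9*Cin) x Cout; column k = c*9+(dx+1)*3+(dy+1)
    h <- dim(X)[1]; w <- dim(X)[2]; cin <- dim(X)[3]
    cout <- ncol(W)
    Y <- array(0, c(h, w, cout))
    for (o in seq_len(cout)) {
      acc <- matrix(b[o], h, w)
      for (ci in seq_len(cin)) for (dx in -1:1) for (dy in -1:1) {
        k <- (ci - 1) * 9 + (dx + 1) * 3 + (dy + 1) + 1
        for (x in seq_len(w)) for (y in seq_len(h)) {
          ys <- y + dy; xs <- x + dx
          if (ys >= 1 && ys <= h && xs >= 1 && xs <= w)
            acc[y, x] <- acc[y, x] + X[ys, xs, ci] * W[k, o]
        }
      }
      Y[, , o] <- if (relu) pmax(acc, 0) else acc
    }
    Y
  }
  pool2 <- function(X) {
    h <- dim(X)[1] / 2
    Y <- array(0, c(h, h, dim(X)[3]))
    for (o in seq_len(dim(X)[3]))
      for (x in seq_len(h)) for (y in seq_len(h))
        Y[y, x, o] <- max(X[2 * y - 1:0, 2 * x - 1:0, o])
    Y
  }
  up2 <- function(X) {
    h <- dim(X)[1] * 2
    Y <- array(0, c(h, h, dim(X)[3]))
    for (o in seq_len(dim(X)[3]))
      for (x in seq_len(h)) for (y in seq_len(h))
        Y[y, x, o] <- X[ceiling(y / 2), ceiling(x / 2), o]
    Y
  }
  d <- cfg$depth; k <- cfg$convs_per_level
  X <- array(image, c(nrow(image), ncol(image), 1))
  skips <- list()
  for (l in seq_len(d)) {
    for (j in seq_len(k)) {
      key <- sprintf("enc%d_%d", l, j)
      X <- conv3(X, params[[paste0(key, ".W")]], params[[paste0(key, ".b")]])
    }
    skips[[l]] <- X
    if (l < d) X <- pool2(X)
  }
  g <- apply(X, 3, mean)
  cls <- as.numeric(t(params[["fc.W"]]) %*% g + params[["fc.b"]])
  for (l in (d - 1):1) {
    U <- up2(X)
    X <- array(c(U, skips[[l]]), c(dim(U)[1], dim(U)[2],
                                   dim(U)[3] + dim(skips[[l]])[3]))
    for (j in seq_len(k)) {
      key <- sprintf("dec%d_%d", l, j)
      X <- conv3(X, params[[paste0(key, ".W")]], params[[paste0(key, ".b")]])
    }
  }
  logit_map <- matrix(0, dim(X)[1], dim(X)[2])
  for (ci in seq_len(dim(X)[3]))
    logit_map <- logit_map + X[, , ci] * params[["head.W"]][ci, 1]
  logit_map <- logit_map + params[["head.b"]][1]
  bce_z <- function(z, y) pmax(z, 0) - z * y + log1p(exp(-abs(z)))
  mean(bce_z(logit_map, mask)) + bce_z(cls[1], eye) + bce_z(cls[2], blink)
}
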