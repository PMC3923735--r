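# Independent brute-force oracles, written as plain nested loops so they
# share no code path with the package implementation.

# --- stepwise mask geometry ------------------------------------------------

# Intersections of the infinite line through p, q with the border of the
# rectangle x in [0, W-1], y in [0, H-1]; same-border pairs return themselves.
oracle_line_rect <- function(p, q, H, W) {
  xmax <- W - 1; ymax <- H - 1; eps <- 1e-9
  same <- function(a, b, v) abs(a - v) < eps && abs(b - v) < eps
  if (same(p[1], q[1], 0) || same(p[1], q[1], xmax) ||
      same(p[2], q[2], 0) || same(p[2], q[2], ymax)) {
    return(list(p, q))
  }
  dx <- q[1] - p[1]; dy <- q[2] - p[2]
  hits <- list()
  if (abs(dx) > eps) {
    for (X in c(0, xmax)) {
      yy <- p[2] + (X - p[1]) / dx * dy
      if (yy >= -eps && yy <= ymax + eps) {
        hits[[length(hits) + 1]] <- c(X, min(max(yy, 0), ymax))
      }
    }
  }
  if (abs(dy) > eps) {
    for (Y in c(0, ymax)) {
      xx <- p[1] + (Y - p[2]) / dy * dx
      if (xx >= -eps && xx <= xmax + eps) {
        hits[[length(hits) + 1]] <- c(min(max(xx, 0), xmax), Y)
      }
    }
  }
  uniq <- list()
  for (h in hits) {
    dup <- FALSE
    for (u in uniq) {
      if (abs(h[1] - u[1]) < 1e-7 && abs(h[2] - u[2]) < 1e-7) dup <- TRUE
    }
    if (!dup) uniq[[length(uniq) + 1]] <- h
  }
  stopifnot(length(uniq) == 2)
  uniq
}

# Full stepwise mask: pairwise boundary extrapolation, per-border pairwise
# mean profiles (least-squares plane fallback), then the mean of the two
# directional interpolations at each pixel.
oracle_build_mask <- function(x, y, lstar, reference, H, W) {
  m <- reference - lstar
  xmax <- W - 1; ymax <- H - 1; eps <- 1e-9
  bp <- list(top = list(), bottom = list(), left = list(), right = list())
  for (i in 1:3) for (j in (i + 1):4) {
    p <- c(x[i], y[i]); q <- c(x[j], y[j])
    for (b in oracle_line_rect(p, q, H, W)) {
      dxy <- q - p
      t <- sum((b - p) * dxy) / sum(dxy^2)
      val <- m[i] + t * (m[j] - m[i])
      if (abs(b[2]) < eps)        bp$top[[length(bp$top) + 1]] <- c(b[1], val)
      if (abs(b[2] - ymax) < eps) bp$bottom[[length(bp$bottom) + 1]] <- c(b[1], val)
      if (abs(b[1]) < eps)        bp$left[[length(bp$left) + 1]] <- c(b[2], val)
      if (abs(b[1] - xmax) < eps) bp$right[[length(bp$right) + 1]] <- c(b[2], val)
    }
  }
  plane_coef <- NULL
  plane_at <- function(px, py) {
    if (is.null(plane_coef)) {
      A <- cbind(1, x, y)
      plane_coef <<- qr.solve(A, m)
    }
    plane_coef[1] + plane_coef[2] * px + plane_coef[3] * py
  }
  profile <- function(pts, positions, fallback_xy) {
    vals <- numeric(length(positions))
    for (si in seq_along(positions)) {
      s <- positions[si]
      acc <- 0; np <- 0
      if (length(pts) >= 2) {
        for (i in seq_len(length(pts) - 1)) for (j in (i + 1):length(pts)) {
          dp <- pts[[j]][1] - pts[[i]][1]
          if (abs(dp) < eps) next
          acc <- acc + pts[[i]][2] +
            (s - pts[[i]][1]) / dp * (pts[[j]][2] - pts[[i]][2])
          np <- np + 1
        }
      }
      vals[si] <- if (np == 0) plane_at(fallback_xy(s)[1], fallback_xy(s)[2]) else acc / np
    }
    vals
  }
  top <- profile(bp$top, 0:xmax, function(s) c(s, 0))
  bottom <- profile(bp$bottom, 0:xmax, function(s) c(s, ymax))
  left <- profile(bp$left, 0:ymax, function(s) c(0, s))
  right <- profile(bp$right, 0:ymax, function(s) c(xmax, s))
  mask <- matrix(0, H, W)
  for (py in 0:ymax) for (px in 0:xmax) {
    v1 <- top[px + 1] + (bottom[px + 1] - top[px + 1]) * py / ymax
    v2 <- left[py + 1] + (right[py + 1] - left[py + 1]) * px / xmax
    mask[py + 1, px + 1] <- (v1 + v2) / 2
  }
  mask
}

# Random valid integer point set on an H x W grid (no duplicates, no three
# colinear), with L* values drawn in [lo, hi].
random_point_set <- function(H, W, lo = 85, hi = 100) {
  repeat {
    x <- sample(0:(W - 1), 4, replace = TRUE)
    y <- sample(0:(H - 1), 4, replace = TRUE)
    ok <- TRUE
    for (i in 1:3) for (j in (i + 1):4) {
      if (x[i] == x[j] && y[i] == y[j]) ok <- FALSE
    }
    if (ok) {
      for (tr in list(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))) {
        a <- abs((x[tr[2]] - x[tr[1]]) * (y[tr[3]] - y[tr[1]]) -
                 (x[tr[3]] - x[tr[1]]) * (y[tr[2]] - y[tr[1]])) / 2
        if (a < 1e-9) ok <- FALSE
      }
    }
    if (ok) return(list(x = x, y = y, lstar = runif(4, lo, hi)))
  }
}

# --- convolution -----------------------------------------------------------

# Nested-loop 2-D convolution with replicate-edge padding.
oracle_convolve <- function(plane, kern) {
  H <- nrow(plane); W <- ncol(plane)
  k <- (nrow(kern) - 1) / 2
  out <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    acc <- 0
    for (di in -k:k) for (dj in -k:k) {
      ii <- min(max(i + di, 1), H)
      jj <- min(max(j + dj, 1), W)
      acc <- acc + plane[ii, jj] * kern[di + k + 1, dj + k + 1]
    }
    out[i, j] <- acc
  }
  out
}

# --- F distribution --------------------------------------------------------

# CDF of the F distribution by numerical integration of its density.
oracle_f_cdf <- function(fval, d1, d2) {
  dens <- function(u) {
    exp(lgamma((d1 + d2) / 2) - lgamma(d1 / 2) - lgamma(d2 / 2) +
        (d1 / 2) * log(d1 / d2) + (d1 / 2 - 1) * log(u) -
        ((d1 + d2) / 2) * log(1 + d1 * u / d2))
  }
  stats::integrate(dens, 0, fval, rel.tol = 1e-12)$value
}

# --- misc ------------------------------------------------------------------

# Two-pass mean / unbiased variance.
oracle_mean_var <- function(v) {
  m <- sum(v) / length(v)
  list(mean = m, var = sum((v - m)^2) / (length(v) - 1))
}

# A random LAB image whose planes stay in realistic ranges.
random_lab_image <- function(H, W) {
  out <- array(0, c(H, W, 3))
  out[, , 1] <- matrix(runif(H * W, 0, 100), H)
  out[, , 2] <- matrix(runif(H * W, -60, 60), H)
  out[, , 3] <- matrix(runif(H * W, -60, 60), H)
  out
}
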