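make_pts <- function(x, y, lstar, reference = 100) {
  source_points(x, y, lstar, reference = reference)
}

test_that("validate_points enforces bounds, distinctness and non-colinearity", {
  shape <- c(10, 10)
  corners <- make_pts(c(0, 9, 0, 9), c(0, 0, 9, 9), rep(95, 4))
  expect_silent(validate_points(corners, shape))
  row3 <- make_pts(c(1, 4, 7, 5), c(2, 2, 2, 8), rep(95, 4))
  expect_error(validate_points(row3, shape),
               class = "heshade_error_colinear_points")
  oob <- make_pts(c(-1, 4, 7, 5), c(0, 2, 3, 8), rep(95, 4))
  expect_error(validate_points(oob, shape),
               class = "heshade_error_out_of_bounds")
  dup <- make_pts(c(2, 2, 7, 5), c(3, 3, 2, 8), rep(95, 4))
  expect_error(validate_points(dup, shape),
               class = "heshade_error_duplicate_point")
})

test_that("line/rectangle intersections handle interior, diagonal and same-border lines", {
  shape <- c(10, 10)
  h <- line_rectangle_intersections(c(3, 5), c(7, 5), shape)
  expect_equal(h[order(h[, 1]), ], matrix(c(0, 5, 9, 5), 2, byrow = TRUE),
               ignore_attr = TRUE)
  d <- line_rectangle_intersections(c(2, 2), c(4, 4), shape)
  expect_equal(d[order(d[, 1]), ], matrix(c(0, 0, 9, 9), 2, byrow = TRUE),
               ignore_attr = TRUE)
  # both points on the left border: the intersections are the points themselves
  s <- line_rectangle_intersections(c(0, 2), c(0, 8), shape)
  expect_equal(s, matrix(c(0, 2, 0, 8), 2, byrow = TRUE), ignore_attr = TRUE)
  expect_error(line_rectangle_intersections(c(3, 3), c(3, 3), shape),
               class = "heshade_error_validation")
})

test_that("boundary extrapolation is linear in signed distance along the line", {
  # constant deficit field stays constant
  expect_equal(extrapolate_mask_to_boundary(c(1, 1), c(5, 5), 100, 100, c(9, 9)), 0)
  # deficits 2 at t=0 and 4 at t=1 extrapolate to 6 at t=2
  expect_equal(
    extrapolate_mask_to_boundary(c(0, 0), c(1, 0), 98, 96, c(2, 0)), 6)
  # deficits sampled from the plane m = 0.05 x + 0.1 y stay on the plane
  p <- c(2, 3); q <- c(7, 5); b <- c(12, 7)  # b on the line p + 2 (q - p)
  plane <- function(pt) 0.05 * pt[1] + 0.1 * pt[2]
  got <- extrapolate_mask_to_boundary(p, q, 100 - plane(p), 100 - plane(q), b)
  expect_lt(abs(got - plane(b)), 1e-9)
})

test_that("a single pair on a border extrapolates linearly across it", {
  prof <- heshade:::.pairwise_profile(rbind(c(2, 1), c(6, 3)), c(0, 9))
  expect_equal(prof, c(0, 4.5))
})

test_that("border profiles restrict to the plane for planar deficits", {
  H <- 12; W <- 15
  x <- c(2, 11, 3, 12); y <- c(2, 3, 9, 8)
  plane <- function(px, py) 0.2 + 0.05 * px + 0.1 * py
  pts <- make_pts(x, y, 100 - plane(x, y))
  prof <- border_profiles(pts, c(H, W))
  expect_equal(prof$top, plane(0:(W - 1), 0), tolerance = 1e-9)
  expect_equal(prof$bottom, plane(0:(W - 1), H - 1), tolerance = 1e-9)
  expect_equal(prof$left, plane(0, 0:(H - 1)), tolerance = 1e-9)
  expect_equal(prof$right, plane(W - 1, 0:(H - 1)), tolerance = 1e-9)
})

test_that("build_mask is zero for reference-white points and exact on planes", {
  shape <- c(20, 24)
  flat <- make_pts(c(2, 20, 3, 21), c(2, 3, 16, 17), rep(100, 4))
  expect_lt(max(abs(build_mask(flat, shape))), 1e-9)

  x <- c(2, 20, 3, 21); y <- c(2, 3, 16, 17)
  pts <- make_pts(x, y, 100 - 0.05 * x - 0.1 * y)
  mask <- build_mask(pts, shape)
  gx <- matrix(rep(0:(shape[2] - 1), each = shape[1]), shape[1])
  gy <- matrix(rep(0:(shape[1] - 1), shape[2]), shape[1])
  expect_lt(max(abs(mask - (0.05 * gx + 0.1 * gy))), 1e-6)
})

test_that("build_mask reproduces the deficit at source points for planar-consistent sets", {
  set.seed(41)
  for (rep in 1:20) {
    a <- runif(1, 0, 0.1); b <- runif(1, 0, 0.1); c0 <- runif(1, 0, 2)
    ps <- random_point_set(18, 22)
    lstar <- 100 - (c0 + a * ps$x + b * ps$y)
    pts <- make_pts(ps$x, ps$y, lstar)
    mask <- build_mask(pts, c(18, 22))
    for (i in 1:4) {
      expect_lt(abs(mask[ps$y[i] + 1, ps$x[i] + 1] - (100 - lstar[i])), 1e-6)
    }
  }
})

test_that("build_mask agrees with the brute-force stepwise oracle", {
  # the worked 10x10 instance (planar-consistent corners-in set)
  pts <- make_pts(c(1, 8, 1, 8), c(1, 1, 8, 8), c(96, 94, 90, 88))
  mask <- build_mask(pts, c(10, 10))
  orc <- oracle_build_mask(c(1, 8, 1, 8), c(1, 1, 8, 8), c(96, 94, 90, 88),
                           100, 10, 10)
  expect_lt(max(abs(mask - orc)), 1e-9)
  expect_equal(mask[5, 5], 4 + (2 / 7) * 3 + (6 / 7) * 3, tolerance = 1e-9)

  set.seed(42)
  for (rep in 1:15) {
    ps <- random_point_set(16, 16)
    pts <- make_pts(ps$x, ps$y, ps$lstar)
    expect_lt(max(abs(build_mask(pts, c(16, 16)) -
                      oracle_build_mask(ps$x, ps$y, ps$lstar, 100, 16, 16))),
              1e-9)
  }
})

test_that("apply_correction restores deficits, scales with factor, and preserves chromaticity", {
  set.seed(43)
  lab <- random_lab_image(12, 14)
  zero <- matrix(0, 12, 14)
  expect_identical(apply_correction(lab, zero), lab)

  # full factor restores the reference at a source point of a planar field
  x <- c(1, 11, 2, 12); y <- c(1, 2, 9, 10)
  pts <- make_pts(x, y, 100 - 0.1 * x - 0.2 * y)
  mask <- build_mask(pts, c(12, 14))
  lab2 <- lab
  lab2[, , 1] <- clamp(100 - 0.1 *
    matrix(rep(0:13, each = 12), 12) - 0.2 * matrix(rep(0:11, 14), 12), 0, 100)
  out <- apply_correction(lab2, mask, factor = 5)
  for (i in 1:4) expect_equal(out[y[i] + 1, x[i] + 1, 1], 100, tolerance = 1e-6)

  # pointwise monotone in factor wherever the mask is non-negative
  prev <- apply_correction(lab2, mask, factor = 1)[, , 1]
  for (f in 2:5) {
    cur <- apply_correction(lab2, mask, factor = f)[, , 1]
    expect_true(all(cur[mask >= 0] >= prev[mask >= 0]))
    prev <- cur
  }

  # a*/b* bitwise unchanged
  out2 <- apply_correction(lab, mask, factor = 3)
  expect_identical(out2[, , 2], lab[, , 2])
  expect_identical(out2[, , 3], lab[, , 3])

  expect_error(apply_correction(lab, matrix(0, 5, 5)),
               class = "heshade_error_shape")
  expect_error(apply_correction(lab, zero, factor = 6),
               class = "heshade_error_validation")
  expect_error(apply_correction(lab, zero, factor = 0),
               class = "heshade_error_validation")
})

test_that("auto selection picks the white pixel in each populated quadrant", {
  H <- 20; W <- 20
  lab <- array(0, c(H, W, 3))
  lab[, , 1] <- 50
  whites <- list(c(3, 4), c(15, 2), c(2, 16), c(17, 18))  # (x, y), one per quadrant
  for (w in whites) lab[w[2] + 1, w[1] + 1, 1] <- 97
  pts <- auto_select_points(lab, white_threshold = 90)
  got <- pts[order(pts$y, pts$x), c("x", "y")]
  want <- do.call(rbind, whites)
  want <- data.frame(x = want[, 1], y = want[, 2])
  want <- want[order(want$y, want$x), ]
  expect_equal(got$x, want$x)
  expect_equal(got$y, want$y)
  expect_equal(sort(pts$lstar), rep(97, 4))
})

test_that("an empty quadrant falls back to the mirrored centroid with the mean deficit", {
  H <- 20; W <- 20
  lab <- array(0, c(H, W, 3))
  lab[, , 1] <- 50
  # candidates only in TL, TR, BL
  lab[4 + 1, 3 + 1, 1] <- 96     # TL (x=3,  y=4)
  lab[3 + 1, 15 + 1, 1] <- 94    # TR (x=15, y=3)
  lab[16 + 1, 2 + 1, 1] <- 92    # BL (x=2,  y=16)
  pts <- auto_select_points(lab, white_threshold = 90)
  br <- pts[pts$x >= 10 & pts$y >= 10, ]
  expect_equal(nrow(br), 1L)
  # mirrors into BR: (3,4) -> (16,15); (15,3) -> (15,16); (2,16) -> (17,16)
  expect_equal(br$x, round(mean(c(16, 15, 17))))
  expect_equal(br$y, round(mean(c(15, 16, 16))))
  expect_equal(br$lstar, 100 - mean(100 - c(96, 94, 92)))
})

test_that("auto selection errors without white pixels; uniform white yields a zero mask", {
  lab <- array(0, c(8, 8, 3)); lab[, , 1] <- 40
  expect_error(auto_select_points(lab), class = "heshade_error_no_white_area")

  lab[, , 1] <- 100
  pts <- auto_select_points(lab)
  expect_lt(max(abs(build_mask(pts, c(8, 8)))), 1e-9)
})
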