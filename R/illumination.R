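# Estimation of the uneven-lighting mask from four white background points,
# and its application to the L* channel.
#
# Coordinates are 0-based throughout this module: x is the column index
# (0 .. W-1, left to right), y the row index (0 .. H-1, top to bottom), to
# match the plain-text points-file format and the boundary geometry, which
# lives on the rectangle x in [0, W-1], y in [0, H-1]. `mask[row, col]` in R
# (1-based) corresponds to the point (x = col - 1, y = row - 1).

.GEOM_TOL <- 1e-9

#' Construct a set of four background source points
#'
#' The four points anchor the illumination-mask estimate; they should sit on
#' unstained (white) background, where the lightness deficit
#' `reference - L*` reveals the lighting field.
#'
#' @param x,y Numeric length-4 vectors of 0-based column / row coordinates.
#' @param lstar Length-4 vector of observed L* values at the points, in
#'   `[0,100]`.
#' @param reference Reference lightness the background should reach after
#'   correction; 100 (diffuse white) in almost all cases.
#' @return A data frame of class `source_points` with columns `x`, `y`,
#'   `lstar` and attribute `reference`.
#' @export
source_points <- function(x, y, lstar, reference = 100) {
  if (length(x) != 4L || length(y) != 4L || length(lstar) != 4L) {
    stop_validation("exactly four source points are required")
  }
  if (!all(is.finite(c(x, y, lstar, reference)))) {
    stop_validation("source point coordinates and L* values must be finite")
  }
  structure(
    data.frame(x = as.numeric(x), y = as.numeric(y), lstar = as.numeric(lstar)),
    reference = reference,
    class = c("source_points", "data.frame")
  )
}

point_reference <- function(pts) {
  r <- attr(pts, "reference")
  if (is.null(r)) 100 else r
}

# Twice the signed triangle area of points (in squared-pixel units).
.triangle_area <- function(x1, y1, x2, y2, x3, y3) {
  abs((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
}

#' Validate a source-point set against an image shape
#'
#' Checks that all four points are inside the image, pairwise distinct, and
#' that no three are colinear (triangle area above a 1e-9 squared-pixel
#' tolerance) -- the geometric preconditions of the mask estimation.
#'
#' @param pts A [source_points()] set.
#' @param image_shape Integer vector `c(H, W)`.
#' @return `pts`, invisibly unchanged, if valid; otherwise a classed error
#'   (`heshade_error_out_of_bounds`, `heshade_error_duplicate_point` or
#'   `heshade_error_colinear_points`).
#' @export
validate_points <- function(pts, image_shape) {
  H <- image_shape[1]; W <- image_shape[2]
  if (nrow(pts) != 4L) stop_validation("exactly four source points are required")
  if (any(pts$x < 0 | pts$x > W - 1 | pts$y < 0 | pts$y > H - 1)) {
    stop_out_of_bounds(sprintf(
      "source points must lie within x in [0,%d], y in [0,%d]", W - 1, H - 1))
  }
  for (i in 1:3) for (j in (i + 1):4) {
    if (abs(pts$x[i] - pts$x[j]) < .GEOM_TOL && abs(pts$y[i] - pts$y[j]) < .GEOM_TOL) {
      stop_duplicate(sprintf("source points %d and %d coincide", i, j))
    }
  }
  triples <- utils::combn(4L, 3L)
  for (k in seq_len(ncol(triples))) {
    i <- triples[, k]
    a <- .triangle_area(pts$x[i[1]], pts$y[i[1]], pts$x[i[2]], pts$y[i[2]],
                        pts$x[i[3]], pts$y[i[3]])
    if (a < .GEOM_TOL) {
      stop_colinear(sprintf("source points %d, %d, %d are colinear",
                            i[1], i[2], i[3]))
    }
  }
  pts
}

#' Intersect the line through two points with the image boundary
#'
#' Returns the two points where the infinite line through `p` and `q` meets
#' the border of the rectangle spanning x in `[0, W-1]`, y in `[0, H-1]`.
#' When both points already lie on the same border, the intersection points
#' are the points themselves.
#'
#' @param p,q Numeric length-2 vectors `c(x, y)` (0-based), `p != q`.
#' @param image_shape Integer vector `c(H, W)`.
#' @return 2 x 2 matrix, one intersection point per row, columns `x`, `y`.
#' @export
line_rectangle_intersections <- function(p, q, image_shape) {
  H <- image_shape[1]; W <- image_shape[2]
  xmax <- W - 1; ymax <- H - 1
  if (abs(p[1] - q[1]) < .GEOM_TOL && abs(p[2] - q[2]) < .GEOM_TOL) {
    stop_validation("degenerate line: the two points coincide")
  }
  on_border <- function(a, b, v) abs(a - v) < .GEOM_TOL && abs(b - v) < .GEOM_TOL
  # Same-border rule: the points themselves are the intersections.
  if (on_border(p[1], q[1], 0) || on_border(p[1], q[1], xmax) ||
      on_border(p[2], q[2], 0) || on_border(p[2], q[2], ymax)) {
    return(matrix(c(p, q), nrow = 2, byrow = TRUE,
                  dimnames = list(NULL, c("x", "y"))))
  }
  d <- q - p
  cand <- matrix(numeric(0), ncol = 2)
  if (abs(d[1]) > .GEOM_TOL) {
    for (X in c(0, xmax)) {
      t <- (X - p[1]) / d[1]
      yy <- p[2] + t * d[2]
      if (yy >= -.GEOM_TOL && yy <= ymax + .GEOM_TOL) {
        cand <- rbind(cand, c(X, clamp(yy, 0, ymax)))
      }
    }
  }
  if (abs(d[2]) > .GEOM_TOL) {
    for (Y in c(0, ymax)) {
      t <- (Y - p[2]) / d[2]
      xx <- p[1] + t * d[1]
      if (xx >= -.GEOM_TOL && xx <= xmax + .GEOM_TOL) {
        cand <- rbind(cand, c(clamp(xx, 0, xmax), Y))
      }
    }
  }
  # Deduplicate corner hits.
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(cand))) {
      if (j > i && keep[j] &&
          abs(cand[i, 1] - cand[j, 1]) < 1e-7 &&
          abs(cand[i, 2] - cand[j, 2]) < 1e-7) keep[j] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) != 2L) {
    stop_validation("line does not intersect the image boundary in two points")
  }
  dimnames(cand) <- list(NULL, c("x", "y"))
  cand
}

#' Extrapolate a lightness deficit along a line to a boundary point
#'
#' With deficits `m(p) = reference - L*(p)` and `m(q) = reference - L*(q)`,
#' the deficit at a point on the line through `p` and `q` is the 1-D linear
#' inter/extrapolation of `m`, parameterized by signed distance from `p`.
#'
#' @param p,q Numeric length-2 `c(x, y)` positions of the source points.
#' @param lstar_p,lstar_q Observed L* values at `p` and `q`.
#' @param boundary_pt Numeric length-2 point on the line through `p`, `q`.
#' @param reference Reference lightness (default 100).
#' @return The extrapolated deficit at `boundary_pt` (scalar).
#' @export
extrapolate_mask_to_boundary <- function(p, q, lstar_p, lstar_q, boundary_pt,
                                         reference = 100) {
  d <- q - p
  len2 <- sum(d^2)
  if (len2 < .GEOM_TOL^2) stop_validation("degenerate line: p equals q")
  t <- sum((boundary_pt - p) * d) / len2
  mp <- reference - lstar_p
  mq <- reference - lstar_q
  mp + t * (mq - mp)
}

# Collect boundary intersection points with their extrapolated deficits for
# every pair of source points; returns a list of data frames (pos, value),
# one per border, positions measured along the border (x for top/bottom,
# y for left/right). A point sitting on a corner contributes to both borders.
.collect_border_points <- function(pts, image_shape, reference) {
  H <- image_shape[1]; W <- image_shape[2]
  xmax <- W - 1; ymax <- H - 1
  borders <- list(top = NULL, bottom = NULL, left = NULL, right = NULL)
  add <- function(border, pos, value) {
    borders[[border]] <<- rbind(borders[[border]], c(pos, value))
  }
  for (i in 1:3) for (j in (i + 1):4) {
    p <- c(pts$x[i], pts$y[i]); q <- c(pts$x[j], pts$y[j])
    ipts <- line_rectangle_intersections(p, q, image_shape)
    for (k in 1:2) {
      b <- ipts[k, ]
      v <- extrapolate_mask_to_boundary(p, q, pts$lstar[i], pts$lstar[j], b,
                                        reference)
      if (abs(b[2] - 0) < .GEOM_TOL)    add("top", b[1], v)
      if (abs(b[2] - ymax) < .GEOM_TOL) add("bottom", b[1], v)
      if (abs(b[1] - 0) < .GEOM_TOL)    add("left", b[2], v)
      if (abs(b[1] - xmax) < .GEOM_TOL) add("right", b[2], v)
    }
  }
  borders
}

# Least-squares plane m = a + b x + c y through the four source deficits;
# used for borders that end up with fewer than two distinct intersection
# points. Exact whenever the four deficits are planar-consistent.
.deficit_plane <- function(pts, reference) {
  A <- cbind(1, pts$x, pts$y)
  m <- reference - pts$lstar
  coef <- qr.solve(A, m)
  function(x, y) coef[1] + coef[2] * x + coef[3] * y
}

# Mean over all pairwise linear inter/extrapolations of (pos, value) points,
# evaluated at positions s (vectorized). Pairs at coincident positions are
# skipped; with no usable pair, returns NULL.
.pairwise_profile <- function(mat, s) {
  if (is.null(mat) || nrow(mat) < 2L) return(NULL)
  acc <- rep(0, length(s)); npair <- 0L
  n <- nrow(mat)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dp <- mat[j, 1] - mat[i, 1]
    if (abs(dp) < .GEOM_TOL) next
    acc <- acc + mat[i, 2] + (s - mat[i, 1]) / dp * (mat[j, 2] - mat[i, 2])
    npair <- npair + 1L
  }
  if (npair == 0L) return(NULL)
  acc / npair
}

#' Border deficit profiles from boundary intersection points
#'
#' For each of the four image borders, every unordered pair of intersection
#' points on that border (at distinct positions) contributes one linear
#' inter/extrapolation; the profile value at each border position is the
#' arithmetic mean over all pairs. A border carrying fewer than two distinct
#' intersection points falls back to a least-squares plane fitted to the four
#' source deficits, evaluated along that border (exact for planar fields).
#'
#' @param pts Validated [source_points()].
#' @param image_shape Integer `c(H, W)`.
#' @return List with numeric vectors `top`, `bottom` (length W, indexed by
#'   column) and `left`, `right` (length H, indexed by row).
#' @export
border_profiles <- function(pts, image_shape) {
  H <- image_shape[1]; W <- image_shape[2]
  reference <- point_reference(pts)
  bp <- .collect_border_points(pts, image_shape, reference)
  xs <- 0:(W - 1); ys <- 0:(H - 1)
  plane <- NULL
  get_plane <- function() {
    if (is.null(plane)) plane <<- .deficit_plane(pts, reference)
    plane
  }
  prof <- list()
  prof$top <- .pairwise_profile(bp$top, xs)
  if (is.null(prof$top)) prof$top <- get_plane()(xs, 0)
  prof$bottom <- .pairwise_profile(bp$bottom, xs)
  if (is.null(prof$bottom)) prof$bottom <- get_plane()(xs, H - 1)
  prof$left <- .pairwise_profile(bp$left, ys)
  if (is.null(prof$left)) prof$left <- get_plane()(0, ys)
  prof$right <- .pairwise_profile(bp$right, ys)
  if (is.null(prof$right)) prof$right <- get_plane()(W - 1, ys)
  prof
}

#' Build the illumination mask from four background points
#'
#' Stepwise geometry: (1) for every pair of source points, the line through
#' them is intersected with the image boundary and the lightness deficit
#' `reference - L*` is linearly extrapolated to the intersection points;
#' (2) each border position gets the mean over all pairwise linear
#' extensions of the intersection values on that border; (3) the value at an
#' interior pixel (x, y) is the mean of the linear interpolation in y between
#' `top(x)` and `bottom(x)` and the linear interpolation in x between
#' `left(y)` and `right(y)`. Each step is linear in the sampled values, but
#' the composite estimate is quadratic in pixel position. The mask is exact
#' on planar deficit fields.
#'
#' @param pts A [source_points()] set (validated here).
#' @param image_shape Integer `c(H, W)`.
#' @return H x W numeric matrix of per-pixel deficits;
#'   `mask[y + 1, x + 1]` is the deficit at 0-based `(x, y)`.
#' @export
build_mask <- function(pts, image_shape) {
  pts <- validate_points(pts, image_shape)
  H <- image_shape[1]; W <- image_shape[2]
  prof <- border_profiles(pts, image_shape)
  wy <- if (H > 1) (0:(H - 1)) / (H - 1) else 0
  wx <- if (W > 1) (0:(W - 1)) / (W - 1) else 0
  # vertical pass: rows vary with wy between top(x) and bottom(x)
  vert <- outer(1 - wy, prof$top) + outer(wy, prof$bottom)
  # horizontal pass: columns vary with wx between left(y) and right(y)
  horiz <- outer(prof$left, 1 - wx) + outer(prof$right, wx)
  (vert + horiz) / 2
}

#' Apply an illumination mask to the L* channel
#'
#' Restores the estimated lightness deficit: `L*out = clamp(L*in +
#' (factor/5) * mask, 0, 100)`. Factor 5 restores the full deficit (the
#' background reaches the reference); smaller factors restore proportionally
#' less, giving a dimmer result. The a* and b* planes are returned
#' bit-identical -- chromaticity, which carries the stain information, is
#' never touched.
#'
#' @param img H x W x 3 LAB array.
#' @param mask H x W deficit matrix from [build_mask()].
#' @param factor Integer 1..5 (default 5).
#' @return LAB array with corrected L*.
#' @export
apply_correction <- function(img, mask, factor = 5) {
  .assert_image3(img, "LAB image")
  if (!isTRUE(all.equal(dim(img)[1:2], dim(mask), check.attributes = FALSE))) {
    stop_shape("mask shape must equal image shape")
  }
  if (length(factor) != 1L || !is.finite(factor) ||
      factor != round(factor) || factor < 1 || factor > 5) {
    stop_validation("correction factor must be an integer between 1 and 5")
  }
  out <- img
  out[, , 1] <- clamp(img[, , 1] + (factor / 5) * mask, 0, 100)
  out
}

#' Automatically select four white background points
#'
#' Pixels with `L* >= white_threshold` are candidate white background. The
#' image is divided into four quadrants (splits at column `floor(W/2)` and
#' row `floor(H/2)`, boundary pixels assigned right/bottom); in each
#' populated quadrant the candidate closest (Euclidean) to the centroid of
#' that quadrant's candidates is chosen (ties broken by row-major scan
#' order). For a quadrant with no candidate, the point is the centroid of
#' the found points mirrored across the image's vertical and horizontal
#' center lines into that quadrant, and its deficit is set to the mean
#' deficit of the found points.
#'
#' @param img H x W x 3 LAB array.
#' @param white_threshold Minimum L* for a pixel to count as white
#'   background (default 90).
#' @param reference Reference lightness for deficits (default 100).
#' @return A [source_points()] set passing [validate_points()].
#' @export
auto_select_points <- function(img, white_threshold = 90, reference = 100) {
  .assert_image3(img, "LAB image")
  H <- dim(img)[1]; W <- dim(img)[2]
  L <- img[, , 1]
  idx <- which(L >= white_threshold, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    stop_no_white_area(sprintf(
      "no pixel reaches the white threshold L* >= %g", white_threshold))
  }
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  lv <- L[idx]
  xsplit <- floor(W / 2); ysplit <- floor(H / 2)
  qx <- as.integer(x >= xsplit)   # 0 = left half, 1 = right half
  qy <- as.integer(y >= ysplit)   # 0 = top half, 1 = bottom half
  quads <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  found <- list()
  for (k in seq_along(quads)) {
    sel <- qx == quads[[k]][1] & qy == quads[[k]][2]
    if (!any(sel)) next
    cx <- x[sel]; cy <- y[sel]; cl <- lv[sel]
    # row-major order makes the tie-break deterministic
    ord <- order(cy, cx)
    cx <- cx[ord]; cy <- cy[ord]; cl <- cl[ord]
    d2 <- (cx - mean(cx))^2 + (cy - mean(cy))^2
    i <- which.min(d2)
    found[[length(found) + 1L]] <- list(quad = quads[[k]], x = cx[i], y = cy[i],
                                        lstar = cl[i])
  }
  pts_x <- numeric(0); pts_y <- numeric(0); pts_l <- numeric(0)
  found_quads <- vapply(found, function(f) paste(f$quad, collapse = ","), "")
  mean_deficit <- mean(vapply(found, function(f) reference - f$lstar, 0))
  for (k in seq_along(quads)) {
    key <- paste(quads[[k]], collapse = ",")
    hit <- match(key, found_quads)
    if (!is.na(hit)) {
      f <- found[[hit]]
      pts_x <- c(pts_x, f$x); pts_y <- c(pts_y, f$y); pts_l <- c(pts_l, f$lstar)
    } else {
      # mirror each found point across the center lines into this quadrant
      mx <- my <- numeric(0)
      for (f in found) {
        px <- f$x; py <- f$y
        if (f$quad[1] != quads[[k]][1]) px <- (W - 1) - px
        if (f$quad[2] != quads[[k]][2]) py <- (H - 1) - py
        mx <- c(mx, px); my <- c(my, py)
      }
      pts_x <- c(pts_x, clamp(round(mean(mx)), 0, W - 1))
      pts_y <- c(pts_y, clamp(round(mean(my)), 0, H - 1))
      pts_l <- c(pts_l, reference - mean_deficit)
    }
  }
  pts <- source_points(pts_x, pts_y, pts_l, reference = reference)
  validate_points(pts, c(H, W))
}

#' Correct uneven illumination in an H&E RGB image
#'
#' Convenience pipeline: RGB to LAB, source points (supplied or
#' auto-selected), mask estimation, L*-channel correction, LAB back to RGB.
#'
#' @param img H x W x 3 RGB array in `[0,1]`.
#' @param points Optional [source_points()] with `x`, `y` set; their `lstar`
#'   values are read from the image. `NULL` (default) auto-selects.
#' @param factor Correction factor, integer 1..5.
#' @param reference Reference lightness (default 100).
#' @param white_threshold Threshold for auto-selection (default 90).
#' @return List with `rgb` (corrected, clamped to `[0,1]`), `mask`,
#'   `points` (the set actually used) and `lab` (corrected LAB).
#' @export
correct_illumination <- function(img, points = NULL, factor = 5,
                                 reference = 100, white_threshold = 90) {
  .assert_image3(img, "RGB image")
  lab <- rgb_to_lab(img)
  if (is.null(points)) {
    pts <- auto_select_points(lab, white_threshold = white_threshold,
                              reference = reference)
  } else {
    L <- lab[, , 1]
    lstar <- L[cbind(round(points$y) + 1, round(points$x) + 1)]
    pts <- source_points(points$x, points$y, lstar, reference = reference)
    pts <- validate_points(pts, dim(img)[1:2])
  }
  mask <- build_mask(pts, dim(img)[1:2])
  lab_out <- apply_correction(lab, mask, factor = factor)
  list(rgb = clamp(lab_to_rgb(lab_out), 0, 1), mask = mask, points = pts,
       lab = lab_out)
}
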