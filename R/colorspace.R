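# RGB <-> XYZ <-> CIE LAB conversions.
#
# Images are plain numeric arrays of dimension H x W x 3 (rows = image rows,
# top to bottom; columns = image columns, left to right), the layout returned
# by png::readPNG / tiff::readTIFF. RGB channels live in [0,1] (8-bit counts
# scaled by 1/255); LAB planes are L* in [0,100] and signed a*, b*.
#
# The RGB <-> XYZ maps are purely linear (no gamma companding): 8-bit values
# divided by 255 enter the matrix directly. This deviates from sRGB on
# purpose; the lightness pipeline is self-consistent under the row-sum
# reference white below, which maps RGB white exactly to L* = 100, a* = b* = 0.

# 3x3 linear map, rows X,Y,Z.
.M_RGB2XYZ <- matrix(c(
  0.412453, 0.357580, 0.180423,
  0.212671, 0.715160, 0.072169,
  0.019334, 0.119193, 0.950227
), nrow = 3, byrow = TRUE)

# Printed inverse (rounded, so round trips are exact only to ~1e-4).
.M_XYZ2RGB <- matrix(c(
   3.240479, -1.537150, -0.498535,
  -0.969256,  1.875992,  0.041556,
   0.055648, -0.204043,  1.057311
), nrow = 3, byrow = TRUE)

#' Reference white and LAB companding constants
#'
#' The reference white (Xn, Yn, Zn) is defined as the row sums of the
#' RGB-to-XYZ matrix, so that RGB white (1,1,1) maps exactly to
#' L* = 100, a* = b* = 0. The piecewise lightness function f(t) switches from
#' the cube root to a linear segment below `t0 = delta^3` with
#' `delta = 6/29`; `slope = 1/(3 delta^2)` and `intercept = 16/116` make the
#' two branches meet in value and slope at `t0`.
#'
#' @return A list of class `white_reference` with elements `Xn`, `Yn`, `Zn`,
#'   `delta`, `t0`, `slope`, `intercept`.
#' @examples
#' ref <- white_reference()
#' ref$t0     # ~0.008856
#' ref$slope  # ~7.787037
#' @export
white_reference <- function() {
  delta <- 6 / 29
  structure(list(
    Xn = sum(.M_RGB2XYZ[1, ]),
    Yn = sum(.M_RGB2XYZ[2, ]),
    Zn = sum(.M_RGB2XYZ[3, ]),
    delta = delta,
    t0 = delta^3,
    slope = 1 / (3 * delta^2),
    intercept = 16 / 116
  ), class = "white_reference")
}

#' Piecewise lightness companding function f(t)
#'
#' Cube root for `t > t0`, the tangent line `slope * t + 16/116` below; the
#' split avoids the infinite slope of the cube root at zero while keeping f
#' continuous with continuous slope at `t0`.
#'
#' @param t Non-negative numeric vector (ratios to the reference white).
#' @param ref A [white_reference()].
#' @return Numeric vector, same length as `t`.
#' @export
f_forward <- function(t, ref = white_reference()) {
  if (any(!is.finite(t)) || any(t < 0)) {
    stop_domain("f_forward requires finite, non-negative t")
  }
  ifelse(t > ref$t0, t^(1 / 3), ref$slope * t + ref$intercept)
}

#' Inverse of the lightness companding function
#'
#' Cubes values above `delta`, applies the linear inverse
#' `(f - 16/116) * 3 delta^2` below, so that `f_inverse(f_forward(t)) == t`
#' over the attainable range.
#'
#' @param fval Finite numeric vector.
#' @param ref A [white_reference()].
#' @return Numeric vector.
#' @export
f_inverse <- function(fval, ref = white_reference()) {
  if (any(!is.finite(fval))) stop_domain("f_inverse requires finite input")
  ifelse(fval > ref$delta, fval^3, (fval - ref$intercept) * 3 * ref$delta^2)
}

.assert_image3 <- function(img, what) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stop_shape(sprintf("%s must be an H x W x 3 numeric array", what))
  }
  if (dim(img)[1] < 2L || dim(img)[2] < 2L) {
    stop_shape(sprintf("%s must be at least 2 x 2 pixels", what))
  }
  invisible(img)
}

# Apply a 3x3 channel matrix per pixel: out_c = sum_k M[c,k] * in_k.
.apply_channel_matrix <- function(img, M) {
  d <- dim(img)
  flat <- matrix(img, ncol = 3L)   # N x 3, channels in columns
  out <- flat %*% t(M)
  array(out, dim = d)
}

#' Convert RGB to CIE XYZ
#'
#' Per-pixel linear map by the fixed 3x3 matrix; no gamma companding is
#' applied (8-bit inputs are simply scaled by 1/255 upstream).
#'
#' @param img H x W x 3 array, RGB in `[0,1]`.
#' @return H x W x 3 array of X, Y, Z tristimulus values.
#' @export
rgb_to_xyz <- function(img) {
  .assert_image3(img, "RGB image")
  .apply_channel_matrix(img, .M_RGB2XYZ)
}

#' Convert CIE XYZ to RGB
#'
#' Linear map by the printed inverse matrix. Outputs are *not* clamped here:
#' clamping to `[0,1]` happens only at image write-out, to avoid compounding
#' clamp errors across pipeline stages.
#'
#' @param img H x W x 3 array of X, Y, Z.
#' @return H x W x 3 array of (possibly out-of-range) RGB values.
#' @export
xyz_to_rgb <- function(img) {
  .assert_image3(img, "XYZ image")
  .apply_channel_matrix(img, .M_XYZ2RGB)
}

#' Convert CIE XYZ to CIE LAB
#'
#' `L* = 116 f(Y/Yn) - 16`, `a* = 500 (f(X/Xn) - f(Y/Yn))`,
#' `b* = 200 (f(Y/Yn) - f(Z/Zn))`.
#'
#' @param img H x W x 3 array of non-negative X, Y, Z.
#' @param ref A [white_reference()].
#' @return H x W x 3 array with planes L*, a*, b*.
#' @export
xyz_to_lab <- function(img, ref = white_reference()) {
  .assert_image3(img, "XYZ image")
  fx <- f_forward(img[, , 1] / ref$Xn, ref)
  fy <- f_forward(img[, , 2] / ref$Yn, ref)
  fz <- f_forward(img[, , 3] / ref$Zn, ref)
  out <- array(0, dim = dim(img))
  out[, , 1] <- 116 * fy - 16
  out[, , 2] <- 500 * (fx - fy)
  out[, , 3] <- 200 * (fy - fz)
  out
}

#' Convert CIE LAB to CIE XYZ
#'
#' Reverse rules: `fy = (L* + 16)/116`, `fx = fy + a*/500`,
#' `fz = fy - b*/200`, then each coordinate through [f_inverse()]. Note
#' `fz` is derived from `fy` (not `fx`), which is the only reading that makes
#' this the exact inverse of the forward `b* = 200 (fy - fz)` definition.
#'
#' @param img H x W x 3 array with planes L*, a*, b*.
#' @param ref A [white_reference()].
#' @return H x W x 3 array of X, Y, Z.
#' @export
lab_to_xyz <- function(img, ref = white_reference()) {
  .assert_image3(img, "LAB image")
  fy <- (img[, , 1] + 16) / 116
  fx <- fy + img[, , 2] / 500
  fz <- fy - img[, , 3] / 200
  out <- array(0, dim = dim(img))
  out[, , 1] <- ref$Xn * f_inverse(fx, ref)
  out[, , 2] <- ref$Yn * f_inverse(fy, ref)
  out[, , 3] <- ref$Zn * f_inverse(fz, ref)
  out
}

#' @rdname rgb_to_lab
#' @export
lab_to_rgb <- function(img, ref = white_reference()) {
  xyz_to_rgb(lab_to_xyz(img, ref))
}

#' Convert between RGB and CIE LAB through XYZ
#'
#' Compositions of the matrix maps and the LAB formulas, XYZ as intermediate.
#' An 8-bit image survives the round trip with at most 1 count of error per
#' channel (the printed matrices are rounded to 6 decimals).
#'
#' @param img H x W x 3 array (RGB in `[0,1]`, or L*, a*, b*).
#' @param ref A [white_reference()].
#' @return H x W x 3 array in the target space.
#' @export
rgb_to_lab <- function(img, ref = white_reference()) {
  xyz_to_lab(rgb_to_xyz(img), ref)
}

#' Clamp values into a range
#'
#' @param x Numeric.
#' @param lo,hi Range limits.
#' @return `x` with values pinned to `[lo, hi]`.
#' @export
clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# Quantize an RGB array to the 8-bit grid (clamp, then round to 255 levels).
quantize_rgb <- function(img) round(clamp(img, 0, 1) * 255) / 255
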