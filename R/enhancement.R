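# Nuclei-selective unsharp masking: sharpen the L* channel only where the
# pixel is bluish (b* < 0), i.e. over hematoxylin-stained structures.

#' Sampled, normalized Gaussian kernel
#'
#' Weights are the 2-D Gaussian `exp(-(x^2 + y^2) / (2 sigma^2))` sampled at
#' integer offsets centered on 0, then normalized to sum to one (the
#' `1/(2 pi sigma^2)` factor cancels in the normalization).
#'
#' @param size Odd kernel side length, >= 3 (default 3).
#' @param sigma Positive standard deviation in pixels (default 3).
#' @return `size` x `size` matrix of non-negative weights summing to 1.
#' @export
gaussian_kernel <- function(size = 3, sigma = 3) {
  if (length(size) != 1L || size != round(size) || size < 3 || size %% 2 == 0) {
    stop_validation("kernel size must be an odd integer >= 3")
  }
  if (!is.finite(sigma) || sigma <= 0) {
    stop_validation("sigma must be a positive real")
  }
  k <- (size - 1) / 2
  off <- -k:k
  w <- exp(-outer(off^2, off^2, "+") / (2 * sigma^2))
  w / sum(w)
}

.validate_enhancement <- function(factor, sigma, kernel_size, threshold) {
  if (length(factor) != 1L || !is.finite(factor) || factor != round(factor) ||
      factor < 1 || factor > 12) {
    stop_validation("enhancement factor must be an integer between 1 and 12")
  }
  if (!is.finite(threshold) || threshold < 0) {
    stop_validation("threshold must be a non-negative real")
  }
  gaussian_kernel(kernel_size, sigma)  # validates size and sigma
}

#' Low-pass filter the L* plane
#'
#' Convolves L* with a sampled Gaussian kernel (border handling by edge
#' replication, which avoids rim artifacts), then clamps the result into
#' `[0,100]`.
#'
#' @param img H x W x 3 LAB array.
#' @param sigma Gaussian standard deviation (default 3).
#' @param kernel_size Odd kernel side (default 3).
#' @return H x W matrix, the blurred L* plane in `[0,100]`.
#' @export
blur_lightness <- function(img, sigma = 3, kernel_size = 3) {
  .assert_image3(img, "LAB image")
  kern <- gaussian_kernel(kernel_size, sigma)
  blurred <- EBImage::filter2(img[, , 1], kern, boundary = "replicate")
  matrix(clamp(as.numeric(blurred), 0, 100), nrow = dim(img)[1])
}

#' Enhance nuclei detail by a b*-gated unsharp mask
#'
#' The detail plane is `L* - blur(L*)`. Where the pixel is bluish
#' (`b* < 0`, hematoxylin-stained nuclei) and `|detail| > threshold`,
#' the output lightness is `clamp(L* + factor * detail, 0, 100)`; everywhere
#' else L* is left untouched. a* and b* are returned bit-identical, so the
#' stain chromaticity is never altered.
#'
#' @param img H x W x 3 LAB array (typically the output of
#'   [apply_correction()], though prior correction is not required).
#' @param factor Integer 1..12; how strongly detail is amplified.
#' @param sigma,kernel_size Gaussian blur parameters (defaults 3 and 3).
#' @param threshold Minimum `|detail|` for a pixel to be sharpened
#'   (default 0: include all minor details).
#' @return LAB array with sharpened L*.
#' @export
enhance_nuclei <- function(img, factor, sigma = 3, kernel_size = 3,
                           threshold = 0) {
  .assert_image3(img, "LAB image")
  .validate_enhancement(factor, sigma, kernel_size, threshold)
  L <- img[, , 1]
  detail <- L - blur_lightness(img, sigma = sigma, kernel_size = kernel_size)
  gate <- img[, , 3] < 0 & abs(detail) > threshold
  out <- img
  Lout <- L
  Lout[gate] <- clamp(L[gate] + factor * detail[gate], 0, 100)
  out[, , 1] <- Lout
  out
}

#' Sharpen nuclei in an H&E RGB image
#'
#' Convenience wrapper: RGB to LAB, [enhance_nuclei()], LAB back to RGB.
#'
#' @inheritParams enhance_nuclei
#' @param img H x W x 3 RGB array in `[0,1]`.
#' @return Corrected RGB array, clamped to `[0,1]`.
#' @export
sharpen_nuclei <- function(img, factor, sigma = 3, kernel_size = 3,
                           threshold = 0) {
  .assert_image3(img, "RGB image")
  lab <- enhance_nuclei(rgb_to_lab(img), factor = factor, sigma = sigma,
                        kernel_size = kernel_size, threshold = threshold)
  clamp(lab_to_rgb(lab), 0, 1)
}
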