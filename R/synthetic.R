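# Synthetic H&E phantoms: white background, pinkish elliptical cytoplasm
# patches (b* > 0) containing bluish elliptical nuclei (b* < 0), degraded by
# a known additive L* illumination field. The ground-truth clean image,
# field and white-pixel map make every pipeline stage testable without real
# slides.

#' Describe an additive L* illumination field
#'
#' The field is the lightness shift added to the clean image's L* plane
#' (negative values darken). Supported kinds:
#' \describe{
#'   \item{uniform}{`value` everywhere (an evenly dim lamp).}
#'   \item{planar}{`offset + alpha * x + beta * y` -- the linear gradient
#'     observed under a misaligned filament/condenser.}
#'   \item{quadratic}{`const + x1 * x + y1 * y + x2 * x^2 + y2 * y^2 +
#'     xy * x * y`, a mild curved field beyond the planar assumption.}
#' }
#' Coordinates are 0-based, x = column, y = row.
#'
#' @param kind One of `"uniform"`, `"planar"`, `"quadratic"`.
#' @param value Constant for `uniform`.
#' @param alpha,beta,offset Slopes and offset for `planar`.
#' @param x2,y2,xy,x1,y1,const Coefficients for `quadratic`.
#' @return A list of class `field_spec`.
#' @export
field_spec <- function(kind = c("uniform", "planar", "quadratic"),
                       value = 0, alpha = 0, beta = 0, offset = 0,
                       x2 = 0, y2 = 0, xy = 0, x1 = 0, y1 = 0, const = 0) {
  kind <- match.arg(kind)
  spec <- switch(kind,
    uniform = list(kind = kind, value = value),
    planar = list(kind = kind, alpha = alpha, beta = beta, offset = offset),
    quadratic = list(kind = kind, x2 = x2, y2 = y2, xy = xy,
                     x1 = x1, y1 = y1, const = const)
  )
  if (!all(vapply(spec[-1], is.finite, TRUE))) {
    stop_validation("field coefficients must be finite")
  }
  structure(spec, class = "field_spec")
}

#' Evaluate an illumination field on an image grid
#'
#' @param spec A [field_spec()].
#' @param image_shape Integer `c(H, W)`.
#' @return H x W matrix of L* shifts.
#' @export
evaluate_field <- function(spec, image_shape) {
  H <- image_shape[1]; W <- image_shape[2]
  x <- matrix(rep(0:(W - 1), each = H), nrow = H)
  y <- matrix(rep(0:(H - 1), times = W), nrow = H)
  switch(spec$kind,
    uniform = matrix(spec$value, H, W),
    planar = spec$offset + spec$alpha * x + spec$beta * y,
    quadratic = spec$const + spec$x1 * x + spec$y1 * y +
      spec$x2 * x^2 + spec$y2 * y^2 + spec$xy * x * y
  )
}

# Paint a filled rotated ellipse onto a logical mask.
.ellipse_mask <- function(H, W, cx, cy, a, b, theta) {
  x <- matrix(rep(0:(W - 1), each = H), nrow = H) - cx
  y <- matrix(rep(0:(H - 1), times = W), nrow = H) - cy
  u <- (x * cos(theta) + y * sin(theta)) / a
  v <- (-x * sin(theta) + y * cos(theta)) / b
  u^2 + v^2 <= 1
}

# Base dye colors in 8-bit RGB; jittered per object to emulate the batch
# variability of real hematoxylin / eosin dyes. Chosen so that nuclei map to
# b* < 0 and cytoplasm to b* > 0 under the package's LAB conversion, while
# cytoplasm stays below the L* >= 90 white-selection band.
.CYTO_RGB <- c(230, 150, 140) / 255
.NUC_RGB <- c(70, 85, 160) / 255
.COLOR_JITTER <- 10 / 255

#' Generate a synthetic H&E phantom
#'
#' Builds a clean phantom (white unstained background, pink/red elliptical
#' cytoplasm regions each holding a bluish elliptical nucleus), then degrades
#' it by adding `field` to the L* plane in LAB and converting back to 8-bit
#' RGB. Four 3x3 corner patches are kept paint-free so every quadrant always
#' retains truly white pixels, and object sizes are budgeted so at least 5%
#' of pixels stay pure white. Fully deterministic given `seed`; the global
#' RNG state is restored afterwards.
#'
#' @param height,width Image dimensions, >= 16.
#' @param n_nuclei Number of cytoplasm+nucleus objects, >= 0.
#' @param seed Integer seed for the object placement and color jitter.
#' @param field A [field_spec()]; the resulting L* must stay within
#'   `[0,100]`.
#' @return List of class `phantom`: `clean` and `degraded` (H x W x 3 RGB,
#'   8-bit quantized), `field` (H x W matrix), `white_map` (H x W logical),
#'   `seed`, `field_spec`.
#' @export
generate_phantom <- function(height, width, n_nuclei, seed,
                             field = field_spec("uniform", value = 0)) {
  if (height < 16 || width < 16) stop_validation("phantom must be at least 16 x 16")
  if (n_nuclei < 0 || n_nuclei != round(n_nuclei)) {
    stop_validation("n_nuclei must be a non-negative integer")
  }
  H <- height; W <- width
  amax <- 0.10 * min(H, W)
  if (n_nuclei * pi * amax^2 > 0.6 * H * W) {
    stop_infeasible("image too small for the requested number of nuclei")
  }
  # corner patches reserved as guaranteed white background, one per quadrant
  reserved <- matrix(FALSE, H, W)
  reserved[1:3, 1:3] <- TRUE; reserved[1:3, (W - 2):W] <- TRUE
  reserved[(H - 2):H, 1:3] <- TRUE; reserved[(H - 2):H, (W - 2):W] <- TRUE

  img <- array(1, dim = c(H, W, 3))
  painted <- matrix(FALSE, H, W)
  withr::with_seed(seed, {
    for (i in seq_len(n_nuclei)) {
      cx <- stats::runif(1, 0, W - 1)
      cy <- stats::runif(1, 0, H - 1)
      a <- stats::runif(1, 0.05, 0.10) * min(H, W)
      b <- stats::runif(1, 0.05, 0.10) * min(H, W)
      th <- stats::runif(1, 0, pi)
      cyto <- clamp(.CYTO_RGB + stats::runif(3, -.COLOR_JITTER, .COLOR_JITTER), 0, 1)
      nuc <- clamp(.NUC_RGB + stats::runif(3, -.COLOR_JITTER, .COLOR_JITTER), 0, 1)
      m_cyto <- .ellipse_mask(H, W, cx, cy, a, b, th) & !reserved
      off <- stats::runif(2, -0.2, 0.2) * c(a, b)
      m_nuc <- .ellipse_mask(H, W, cx + off[1], cy + off[2],
                             0.45 * a, 0.45 * b, th) & !reserved
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[m_cyto] <- cyto[ch]
        plane[m_nuc] <- nuc[ch]
        img[, , ch] <- plane
      }
      painted <- painted | m_cyto | m_nuc
    }
  })
  white_map <- !painted
  if (mean(white_map) < 0.05) {
    stop_infeasible("less than 5% of pixels remain unstained white")
  }
  clean <- quantize_rgb(img)

  fld <- evaluate_field(field, c(H, W))
  lab <- rgb_to_lab(clean)
  Lshift <- lab[, , 1] + fld
  if (min(Lshift) < -1e-6 || max(Lshift) > 100 + 1e-6) {
    stop_validation("field drives L* outside [0,100]; choose milder coefficients")
  }
  lab[, , 1] <- Lshift
  degraded <- quantize_rgb(lab_to_rgb(lab))

  structure(list(clean = clean, degraded = degraded, field = fld,
                 white_map = white_map, seed = seed, field_spec = field),
            class = "phantom")
}

#' Measure how well a correction recovered a phantom's clean image
#'
#' Compares `corrected` against the phantom's clean image in LAB: root mean
#' square L* error over the truly-white pixels and over the whole image, and
#' the largest absolute a*/b* change relative to the *degraded* image (which
#' must be ~0 under the chromaticity-conservation contract, up to 8-bit
#' write-out rounding).
#'
#' @param phantom A [generate_phantom()] result.
#' @param corrected H x W x 3 RGB array in `[0,1]`.
#' @return List: `rmse_white`, `rmse_overall`, `max_da`, `max_db`.
#' @export
measure_recovery <- function(phantom, corrected) {
  if (!identical(dim(corrected), dim(phantom$clean))) {
    stop_shape("corrected image shape must match the phantom")
  }
  lab_clean <- rgb_to_lab(phantom$clean)
  lab_corr <- rgb_to_lab(clamp(corrected, 0, 1))
  lab_deg <- rgb_to_lab(phantom$degraded)
  dl <- lab_corr[, , 1] - lab_clean[, , 1]
  list(
    rmse_white = sqrt(mean(dl[phantom$white_map]^2)),
    rmse_overall = sqrt(mean(dl^2)),
    max_da = max(abs(lab_corr[, , 2] - lab_deg[, , 2])),
    max_db = max(abs(lab_corr[, , 3] - lab_deg[, , 3]))
  )
}
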