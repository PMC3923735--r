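# Validation metrics: per-channel histogram statistics and the two-sided
# F test for equality of variances, used to check that a correction did not
# shift the chromaticity distribution (the b* channel in particular).

#' Per-channel statistics and 256-bin histogram
#'
#' Computes mean, unbiased variance (n-1 denominator) and a 256-bin
#' histogram of one LAB plane. With `display_scale = TRUE`, values are first
#' affinely mapped to the 0-255 convention used by common image editors
#' (`L* * 255/100` for L; `a* + 128`, `b* + 128` for the chromaticity
#' planes), clamped to `[0,255]`; statistics and histogram are then reported
#' on that display scale, which makes them comparable with editor readouts.
#'
#' @param img H x W x 3 LAB array.
#' @param channel One of `"L"`, `"a"`, `"b"`.
#' @param display_scale Report on the 8-bit display scale? Default `FALSE`.
#' @return List of class `channel_stats`: `mean`, `variance`, `n`,
#'   `histogram` (256 counts), `breaks` (length 257), `channel`,
#'   `display_scale`.
#' @export
channel_stats <- function(img, channel = c("L", "a", "b"),
                          display_scale = FALSE) {
  .assert_image3(img, "LAB image")
  channel <- match.arg(channel)
  plane <- switch(channel, L = 1L, a = 2L, b = 3L)
  v <- as.numeric(img[, , plane])
  if (length(v) < 2L) stop_validation("image must contain at least 2 pixels")
  if (display_scale) {
    v <- if (channel == "L") v * 255 / 100 else v + 128
    v <- clamp(v, 0, 255)
    lo <- 0; hi <- 255
  } else if (channel == "L") {
    lo <- 0; hi <- 100
  } else {
    lo <- -128; hi <- 128
  }
  bin <- pmin(pmax(floor((v - lo) / (hi - lo) * 256), 0), 255)
  structure(list(
    mean = mean(v),
    variance = stats::var(v),
    n = length(v),
    histogram = tabulate(bin + 1L, nbins = 256L),
    breaks = seq(lo, hi, length.out = 257L),
    channel = channel,
    display_scale = display_scale
  ), class = "channel_stats")
}

#' Two-sided F test for equality of variances
#'
#' `F = var(sample1) / var(sample2)` with `n1 - 1` and `n2 - 1` degrees of
#' freedom; the two-sided p-value is `2 * min(P(F <= f), P(F >= f))`, capped
#' at 1. The null hypothesis of equal variances is rejected when
#' `p < alpha`. Pixels fed to this test are treated as independent
#' observations, an optimistic assumption for images documented with the
#' method.
#'
#' @param sample1,sample2 Numeric vectors, each with `n >= 2` and nonzero
#'   variance.
#' @param alpha Significance level (default 0.05).
#' @return List of class `f_test_result`: `f_statistic`, `df1`, `df2`,
#'   `p_value`, `reject_at_alpha`, `alpha`.
#' @export
variance_f_test <- function(sample1, sample2, alpha = 0.05) {
  sample1 <- as.numeric(sample1); sample2 <- as.numeric(sample2)
  if (length(sample1) < 2L || length(sample2) < 2L) {
    stop_validation("both samples need at least two observations")
  }
  v1 <- stats::var(sample1); v2 <- stats::var(sample2)
  if (!is.finite(v1) || !is.finite(v2) || v1 <= 0 || v2 <= 0) {
    stop_validation("both samples need nonzero, finite variance")
  }
  f <- v1 / v2
  df1 <- length(sample1) - 1L
  df2 <- length(sample2) - 1L
  p <- min(1, 2 * min(stats::pf(f, df1, df2),
                      stats::pf(f, df1, df2, lower.tail = FALSE)))
  structure(list(
    f_statistic = f, df1 = df1, df2 = df2, p_value = p,
    reject_at_alpha = p < alpha, alpha = alpha
  ), class = "f_test_result")
}

#' @export
print.f_test_result <- function(x, ...) {
  cat(sprintf("Two-sided F test: F = %.6g (df %d, %d), p = %.4g -> %s at alpha = %g\n",
              x$f_statistic, x$df1, x$df2, x$p_value,
              if (x$reject_at_alpha) "reject equal variances" else "no evidence against equal variances",
              x$alpha))
  invisible(x)
}

#' @export
print.channel_stats <- function(x, ...) {
  cat(sprintf("%s channel%s: n = %d, mean = %.4f, variance = %.4f\n",
              x$channel, if (x$display_scale) " (display scale 0-255)" else "",
              x$n, x$mean, x$variance))
  invisible(x)
}
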