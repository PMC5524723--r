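#' Image contrast (grey-value variance)
#'
#' Population variance of the grey values,
#' \eqn{\frac{1}{NM}\sum f^2 - (\frac{1}{NM}\sum f)^2} — the quantity reported
#' as "Contrast" and used unchanged as the PSO fitness: a larger value means a
#' wider, more uniform grey distribution.
#'
#' @param image `gray_image` or numeric matrix.
#' @return Nonnegative real.
#' @export
img_contrast <- function(image) {
  x <- as.vector(px(image))
  if (length(x) == 0L) stop("image is empty", call. = FALSE)
  mean(x^2) - mean(x)^2
}

# Contrast of a discrete grey-level distribution: levels y with counts w.
# Used by the pipeline's histogram fitness shortcut; agrees with img_contrast
# on the expanded image exactly (same population-variance formula).
contrast_weighted <- function(y, w) {
  n <- sum(w)
  m1 <- sum(w * y) / n
  sum(w * y^2) / n - m1^2
}

#' Mean squared error between two images
#'
#' \eqn{MSE = \frac{1}{MN} \sum_{x,y} [I(x,y) - \hat I(x,y)]^2}.
#'
#' @param original,processed Images of identical dimensions.
#' @return Nonnegative real.
#' @export
img_mse <- function(original, processed) {
  stop_dims(original, processed)
  mean((px(original) - px(processed))^2)
}

#' Peak signal-to-noise ratio
#'
#' \eqn{PSNR = 10 \log_{10}(m^2 / MSE)} in dB, with
#' \eqn{m = 2^{bit\_depth} - 1} (255 for 8-bit). Identical images (MSE = 0)
#' yield the degenerate infinite-PSNR signal, returned as `Inf` rather than a
#' finite number.
#'
#' @param original,processed Images of identical dimensions.
#' @param bit_depth Bit depth fixing the peak value m.
#' @return PSNR in dB (`Inf` when MSE is zero).
#' @export
img_psnr <- function(original, processed, bit_depth = NULL) {
  bd <- if (is.null(bit_depth)) bit_depth(original) else as.integer(bit_depth)
  e <- img_mse(original, processed)
  if (e == 0) return(Inf)
  10 * log10((2^bd - 1)^2 / e)
}

#' Shannon entropy of the grey-level histogram
#'
#' \eqn{H = -\sum_i p(x_i) \log_2 p(x_i)} in bits, with \eqn{p} the empirical
#' grey-level frequencies; zero-probability levels contribute nothing. Ranges
#' from 0 (constant image) to `bit_depth` (all levels equally frequent).
#' Requires an integer-quantized image — quantize real-valued pipeline output
#' with [quantize_gray()] first.
#'
#' @param image Integer-valued `gray_image` with levels in
#'   \eqn{[0, 2^{bit\_depth} - 1]}.
#' @return Entropy in bits.
#' @export
img_entropy <- function(image) {
  x <- px(image)
  if (!is_integer_valued(x)) {
    stop("entropy requires an integer-quantized image; apply quantize_gray() first",
         call. = FALSE)
  }
  bd <- bit_depth(image)
  if (min(x) < 0 || max(x) > 2^bd - 1) {
    stop(sprintf("grey levels must lie in [0, %d]", 2^bd - 1), call. = FALSE)
  }
  p <- tabulate(as.vector(x) + 1L, nbins = 2^bd) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Image-quality report for an (original, processed) pair
#'
#' Bundles the four quality measures: contrast and entropy of the processed
#' image, MSE and PSNR between the pair. Contrast, MSE and PSNR are computed
#' on the processed image as given (typically the real-valued, pre-quantization
#' pipeline output); entropy is computed on `processed_quantized`, which
#' defaults to `quantize_gray(processed)`.
#'
#' @param original Display-domain reference image.
#' @param processed Processed image, same dimensions.
#' @param processed_quantized Optional integer-quantized copy of `processed`
#'   used for the entropy histogram.
#' @return A `quality_report` list: `contrast`, `mse`, `psnr`, `entropy`,
#'   `bit_depth`.
#' @export
quality_report <- function(original, processed, processed_quantized = NULL) {
  stop_dims(original, processed)
  bd <- bit_depth(original)
  if (is.null(processed_quantized)) {
    processed_quantized <- if (is_integer_valued(processed)) {
      as_gray_image(px(processed), bit_depth = bd)
    } else {
      quantize_gray(as_gray_image(px(processed), bit_depth = bd))
    }
  }
  structure(list(contrast = img_contrast(processed),
                 mse = img_mse(original, processed),
                 psnr = img_psnr(original, processed, bd),
                 entropy = img_entropy(processed_quantized),
                 bit_depth = bd),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report>\n")
  cat(sprintf("  contrast: %.4f\n  MSE:      %.4f\n", x$contrast, x$mse))
  cat(sprintf("  PSNR:     %s\n",
              if (is.infinite(x$psnr)) "Inf dB (identical images)"
              else sprintf("%.4f dB", x$psnr)))
  cat(sprintf("  entropy:  %.4f bits\n", x$entropy))
  invisible(x)
}

#' Write a quality report as flat key-value text
#'
#' One `key value` pair per line (`contrast`, `mse`, `psnr`, `entropy`,
#' `bit_depth`), full precision.
#'
#' @param report A [quality_report()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  keys <- c("contrast", "mse", "psnr", "entropy", "bit_depth")
  lines <- vapply(keys, function(k) {
    sprintf("%s %s", k, format(report[[k]], digits = 17))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
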