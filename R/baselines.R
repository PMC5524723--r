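#' Linear (percentile-stretch) enhancement
#'
#' Classic linear contrast stretch: grey levels at or below the
#' `low_percentile` map to 0, at or above the `high_percentile` to
#' \eqn{2^{bit\_depth} - 1}, linearly in between. The default 1st/99th
#' percentiles avoid a single outlier dominating the stretch. Percentiles use
#' the standard interpolation rule of [stats::quantile()] (type 7).
#'
#' @param image Display-domain `gray_image`.
#' @param low_percentile,high_percentile Percentiles in \eqn{[0, 100]} with
#'   `low_percentile < high_percentile`; defaults 1 and 99.
#' @return A display-domain, real-valued `gray_image` (quantize with
#'   [quantize_gray()] for file output).
#' @export
linear_enhance <- function(image, low_percentile = 1, high_percentile = 99) {
  if (!is.finite(low_percentile) || !is.finite(high_percentile) ||
      low_percentile < 0 || high_percentile > 100 ||
      low_percentile >= high_percentile) {
    stop("need 0 <= low_percentile < high_percentile <= 100", call. = FALSE)
  }
  image <- as_gray_image(image)
  x <- px(image)
  qs <- stats::quantile(x, c(low_percentile, high_percentile) / 100,
                        names = FALSE, type = 7)
  if (qs[1] == qs[2]) {
    stop("degenerate input: percentile range is empty (constant image?)",
         call. = FALSE)
  }
  m <- 2^bit_depth(image) - 1
  y <- (x - qs[1]) / (qs[2] - qs[1])
  y <- pmin(pmax(y, 0), 1) * m
  gray_image(y, bit_depth = bit_depth(image), domain = "display")
}

#' Histogram equalization
#'
#' Classic CDF-mapping equalization: grey level v maps to
#' `round((2^bit_depth - 1) * cdf(v))`, with the empirical CDF including the
#' current level (non-exceedance) and round-half-up rounding. The output
#' always reaches the top grey level; rank order is preserved non-strictly.
#'
#' @param image Integer-quantized display-domain `gray_image`.
#' @return An integer-valued display-domain `gray_image`.
#' @export
hist_equalize <- function(image) {
  image <- as_gray_image(image)
  x <- px(image)
  if (!is_integer_valued(x)) {
    stop("histogram equalization requires an integer-quantized image", call. = FALSE)
  }
  bd <- bit_depth(image)
  m <- 2^bd - 1
  counts <- tabulate(as.vector(x) + 1L, nbins = m + 1L)
  cdf <- cumsum(counts) / length(x)
  mapping <- floor(m * cdf + 0.5)
  y <- matrix(mapping[x + 1L], nrow(x), ncol(x))
  gray_image(y, bit_depth = bd, domain = "display")
}
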