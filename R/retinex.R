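#' Multi-Scale Retinex parameters
#'
#' Surround scales \eqn{c_k} (in pixels) and weights \eqn{\omega_k} for the
#' Multi-Scale Retinex sum. The defaults — three scales 15, 80, 250 with equal
#' weights 1/3 — are the standard choice balancing local detail (small scale)
#' against global tonal consistency (large scale).
#'
#' @param scales Ordered vector of positive surround scales \eqn{c_k}.
#' @param weights Positive weights \eqn{\omega_k}, same length as `scales`,
#'   summing to 1 (within 1e-9).
#' @return A `retinex_params` list.
#' @export
retinex_params <- function(scales = c(15, 80, 250),
                           weights = rep(1 / length(scales), length(scales))) {
  if (length(scales) < 1L || any(!is.finite(scales)) || any(scales <= 0)) {
    stop("`scales` must be positive reals", call. = FALSE)
  }
  if (length(weights) != length(scales)) {
    stop("`weights` must have the same length as `scales`", call. = FALSE)
  }
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("`weights` must be positive reals", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("`weights` must sum to 1 (within 1e-9)", call. = FALSE)
  }
  structure(list(scales = as.numeric(scales), weights = as.numeric(weights)),
            class = "retinex_params")
}

#' Gaussian surround kernel
#'
#' The surround function estimating local illumination at scale `c`:
#' entries are proportional to \eqn{\exp(-(x^2+y^2)/c^2)} on a square support
#' of side `2 * radius + 1`, normalized to sum to 1 (the kernel's leading
#' constant is taken as the unit-sum normalizer).
#'
#' @param scale Positive surround scale \eqn{c} in pixels.
#' @param radius Positive integer truncation radius; the default
#'   `ceiling(3 * scale)` captures >= 99.9\% of the Gaussian mass.
#' @return A `(2 * radius + 1)` square matrix of nonnegative reals summing to 1.
#' @examples
#' k <- gaussian_surround(15, 45)
#' sum(k)  # 1
#' @export
gaussian_surround <- function(scale, radius = ceiling(3 * scale)) {
  if (!is.finite(scale) || scale <= 0) {
    stop("`scale` must be a positive real", call. = FALSE)
  }
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 1L) {
    stop("`radius` must be a positive integer", call. = FALSE)
  }
  k1 <- exp(-((-radius:radius)^2) / scale^2)
  k2 <- outer(k1, k1)
  k2 / sum(k2)
}

# Index folding for symmetric (mirror, edge-duplicating) padding: the signal
# 1..n is extended as ..., 2, 1 | 1, 2, ..., n | n, n-1, ... with period 2n.
reflect_index <- function(i, n) {
  j <- (i - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

# n x n linear operator performing 1-D Gaussian convolution with symmetric
# padding along one axis. The Gaussian factorizes, so the 2-D surround
# convolution is op(nrow) %*% X %*% t(op(ncol)) — exact separable equivalence
# with direct 2-D spatial convolution.
conv_operator_1d <- function(n, scale, radius) {
  k <- exp(-((-radius:radius)^2) / scale^2)
  k <- k / sum(k)
  A <- matrix(0, n, n)
  idx <- seq_len(n)
  for (j in seq_along(k)) {
    src <- reflect_index(idx + (j - radius - 1L), n)
    A[cbind(idx, src)] <- A[cbind(idx, src)] + k[j]
  }
  A
}

# Unit-sum Gaussian surround blur with symmetric boundary padding.
gauss_blur <- function(x, scale, radius) {
  Ar <- conv_operator_1d(nrow(x), scale, radius)
  Ac <- if (ncol(x) == nrow(x)) Ar else conv_operator_1d(ncol(x), scale, radius)
  Ar %*% x %*% t(Ac)
}

#' Single-scale Retinex
#'
#' One summand of the Multi-Scale Retinex: the log-domain difference between
#' the image and its Gaussian-surround estimate of the illumination,
#' \deqn{R_c(x,y) = \log(I(x,y) + \epsilon) - \log((F_c * I)(x,y) + \epsilon),}
#' with a fixed offset \eqn{\epsilon = 1} guarding \eqn{\log 0} (the
#' `log(I + 1)` convention). Convolution uses symmetric (mirror) boundary
#' padding, which avoids the dark halos that zero padding creates at frame
#' edges.
#'
#' @param image `gray_image` (or matrix) with nonnegative pixels.
#' @param scale Positive surround scale.
#' @param radius Kernel truncation radius (default `ceiling(3 * scale)`).
#' @param eps Log offset; default 1.
#' @return A log-domain (`domain = "real"`) `gray_image` of the same size.
#' @export
single_scale_retinex <- function(image, scale, radius = ceiling(3 * scale),
                                 eps = 1) {
  x <- px(image)
  if (min(x) < 0) stop("image pixels must be nonnegative", call. = FALSE)
  if (!is.finite(scale) || scale <= 0) {
    stop("`scale` must be a positive real", call. = FALSE)
  }
  out <- log(x + eps) - log(gauss_blur(x, scale, radius) + eps)
  gray_image(out, bit_depth = bit_depth(image), domain = "real")
}

#' Multi-Scale Retinex illumination correction
#'
#' Weighted sum of single-scale Retinex outputs over the surround scales:
#' \deqn{R(x,y) = \sum_k \omega_k \{\log[I(x,y)] - \log[F(\cdot,c_k) * I](x,y)\}.}
#' Subtracting the log of the Gaussian-smoothed image removes the smoothly
#' varying illumination component, so a constant image maps to identically
#' zero and a global intensity rescale leaves the output (essentially)
#' unchanged.
#'
#' @param image `gray_image` (or matrix) with nonnegative pixels.
#' @param params A [retinex_params()] object.
#' @param eps Log offset passed to [single_scale_retinex()].
#' @return A log-domain (`domain = "real"`) `gray_image` of the same size.
#' @examples
#' img <- synth_scene(scene_config(width = 64, height = 64, seed = 1))$image
#' r <- msr(img)
#' range(r)
#' @export
msr <- function(image, params = retinex_params(), eps = 1) {
  if (!inherits(params, "retinex_params")) {
    params <- do.call(retinex_params, params)
  }
  out <- 0
  for (k in seq_along(params$scales)) {
    out <- out + params$weights[k] *
      px(single_scale_retinex(image, params$scales[k], eps = eps))
  }
  gray_image(out, bit_depth = bit_depth(image), domain = "real")
}
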