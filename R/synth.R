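#' Synthetic tank-scene configuration
#'
#' Parameters of the seeded synthetic fixture generator, which emulates
#' near-infrared imaging of fish in a recirculating-aquaculture tank under a
#' single overhead lamp: dark elliptical "fish" blobs on a lighter tank
#' background (a reflectance field), multiplied by a smooth radial
#' illumination field dimming toward the frame edges, with additive sensor
#' noise and 8-bit quantization. The defaults yield a genuinely low-contrast,
#' histogram-concentrated image, which is the condition the enhancement
#' pipeline targets.
#'
#' @param width,height Image size in pixels (default 256 x 256).
#' @param n_blobs Number of elliptical fish blobs (default 8); `NA` draws a
#'   count uniformly from 4..12 using the scene's own seed.
#' @param blob_intensity_range Blob reflectance interval, darker than the
#'   background (default `c(0.15, 0.35)`).
#' @param background_reflectance Tank background reflectance (default 0.55).
#' @param blob_axes_range Ellipse semi-axis interval in pixels (default
#'   `c(6, 20)`).
#' @param illumination_center Lamp-center offset from the image center, as
#'   fractions of width/height (default `c(0, 0)`).
#' @param illumination_sigma Radial falloff scale as a fraction of the image
#'   diagonal (default 0.6).
#' @param illumination_floor Relative brightness at the dimmest point, in
#'   (0, 1] (default 0.35); the field spans exactly
#'   `[illumination_floor, 1]`.
#' @param noise_sigma Additive Gaussian noise SD in grey levels (default 2).
#' @param seed Integer seed; identical seeds give pixel-identical scenes.
#' @return A `scene_config` list.
#' @export
scene_config <- function(width = 256L, height = 256L, n_blobs = 8L,
                         blob_intensity_range = c(0.15, 0.35),
                         background_reflectance = 0.55,
                         blob_axes_range = c(6, 20),
                         illumination_center = c(0, 0),
                         illumination_sigma = 0.6,
                         illumination_floor = 0.35,
                         noise_sigma = 2, seed = 0L) {
  width <- as.integer(width); height <- as.integer(height)
  if (width < 1L || height < 1L) {
    stop("`width` and `height` must be positive integers", call. = FALSE)
  }
  if (!is.na(n_blobs) && n_blobs < 0) {
    stop("`n_blobs` must be nonnegative (or NA for a random count)", call. = FALSE)
  }
  if (any(blob_intensity_range <= 0) || any(blob_intensity_range > 1) ||
      background_reflectance <= 0 || background_reflectance > 1) {
    stop("reflectances must lie in (0, 1]", call. = FALSE)
  }
  if (blob_axes_range[1] > blob_axes_range[2] || blob_axes_range[1] <= 0) {
    stop("`blob_axes_range` must be a positive increasing interval", call. = FALSE)
  }
  if ((is.na(n_blobs) || n_blobs > 0) &&
      2 * blob_axes_range[2] > min(width, height)) {
    stop("impossible geometry: blob axes exceed the image size", call. = FALSE)
  }
  if (illumination_floor <= 0 || illumination_floor > 1) {
    stop("`illumination_floor` must lie in (0, 1]", call. = FALSE)
  }
  if (noise_sigma < 0) stop("`noise_sigma` must be nonnegative", call. = FALSE)
  structure(list(width = width, height = height, n_blobs = n_blobs,
                 blob_intensity_range = blob_intensity_range,
                 background_reflectance = background_reflectance,
                 blob_axes_range = blob_axes_range,
                 illumination_center = illumination_center,
                 illumination_sigma = illumination_sigma,
                 illumination_floor = illumination_floor,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "scene_config")
}

#' Generate a synthetic tank scene
#'
#' Builds `image = quantize(255 * reflectance * illumination + noise)` from a
#' [scene_config()] and returns the quantized 8-bit image together with the
#' ground-truth reflectance and illumination grids, so illumination-removal
#' claims can be tested against the known field. Noise is added after the
#' illumination product and clipped to \eqn{[0, 255]} before round-half-up
#' quantization. The caller's RNG state is left untouched.
#'
#' @param config A [scene_config()].
#' @return A `synth_scene` list: `image` (integer `gray_image`),
#'   `reflectance`, `illumination` (matrices), `config`.
#' @examples
#' sc <- synth_scene(scene_config(width = 64, height = 64, seed = 42))
#' img_contrast(sc$image)
#' @export
synth_scene <- function(config = scene_config()) {
  if (!inherits(config, "scene_config")) config <- do.call(scene_config, config)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  w <- config$width; h <- config$height
  nb <- config$n_blobs
  if (is.na(nb)) nb <- sample(4:12, 1L)

  refl <- matrix(config$background_reflectance, h, w)
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  for (b in seq_len(nb)) {
    cx <- stats::runif(1, 1, w)
    cy <- stats::runif(1, 1, h)
    a <- stats::runif(1, config$blob_axes_range[1], config$blob_axes_range[2])
    bb <- stats::runif(1, config$blob_axes_range[1], config$blob_axes_range[2])
    th <- stats::runif(1, 0, pi)
    val <- stats::runif(1, config$blob_intensity_range[1],
                        config$blob_intensity_range[2])
    dx <- xs - cx; dy <- ys - cy
    u <- (dx * cos(th) + dy * sin(th)) / a
    v <- (-dx * sin(th) + dy * cos(th)) / bb
    refl[u^2 + v^2 <= 1] <- val
  }

  cx0 <- (w + 1) / 2 + config$illumination_center[1] * w
  cy0 <- (h + 1) / 2 + config$illumination_center[2] * h
  s <- config$illumination_sigma * sqrt(w^2 + h^2)
  g <- exp(-((xs - cx0)^2 + (ys - cy0)^2) / (2 * s^2))
  gr <- range(g)
  ill <- if (gr[1] == gr[2]) {
    matrix(1, h, w)
  } else {
    config$illumination_floor +
      (1 - config$illumination_floor) * (g - gr[1]) / (gr[2] - gr[1])
  }

  clean <- 255 * refl * ill
  noisy <- if (config$noise_sigma > 0) {
    clean + stats::rnorm(length(clean), 0, config$noise_sigma)
  } else clean
  noisy <- pmin(pmax(noisy, 0), 255)
  img <- quantize_gray(gray_image(matrix(noisy, h, w), bit_depth = 8L,
                                  domain = "display"))

  structure(list(image = img, reflectance = refl, illumination = ill,
                 config = config),
            class = "synth_scene")
}

#' Generate a suite of synthetic fixtures
#'
#' `n` scenes seeded `base_seed .. base_seed + n - 1`, each with a randomized
#' blob count (4..12) and blob layout; suites sharing seeds share scenes.
#'
#' @param n Number of scenes (>= 1).
#' @param base_seed Seed of the first scene.
#' @param config Template [scene_config()]; its `seed` and `n_blobs` are
#'   overridden per scene (`n_blobs` set to `NA` = random count).
#' @return List of `synth_scene` objects.
#' @export
synth_suite <- function(n, base_seed = 100L, config = scene_config()) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be a positive integer", call. = FALSE)
  lapply(seq_len(n), function(i) {
    cfg <- config
    cfg$seed <- as.integer(base_seed) + i - 1L
    cfg$n_blobs <- NA_integer_
    synth_scene(cfg)
  })
}
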