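#' Greyscale image objects
#'
#' A `gray_image` is a numeric matrix (rows = image height, columns = image
#' width) carrying a declared bit depth and a *domain* flag:
#'
#' * `"display"` — pixel values lie in the displayable range
#'   \eqn{[0, 2^{bit\_depth} - 1]} (they may be non-integer; quantize with
#'   [quantize_gray()] before writing to file);
#' * `"unit"` — values lie in \eqn{[0, 1]} (normalized images);
#' * `"real"` — any finite real values (log-domain Retinex output and other
#'   intermediates that are not directly displayable).
#'
#' @param pixels Numeric matrix of intensity values.
#' @param bit_depth Positive integer; the displayable range is
#'   \eqn{[0, 2^{bit\_depth} - 1]}. Default 8.
#' @param domain One of `"display"`, `"unit"`, `"real"` (see above).
#' @return A `gray_image` object.
#' @examples
#' img <- gray_image(matrix(0:255, 16, 16), bit_depth = 8)
#' img_contrast(img)
#' @export
gray_image <- function(pixels, bit_depth = 8L, domain = c("display", "unit", "real")) {
  domain <- match.arg(domain)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image must have width >= 1 and height >= 1", call. = FALSE)
  }
  if (!all(is.finite(pixels))) {
    stop("image pixels must all be finite", call. = FALSE)
  }
  bit_depth <- as.integer(bit_depth)
  if (length(bit_depth) != 1L || is.na(bit_depth) || bit_depth < 1L) {
    stop("`bit_depth` must be a positive integer", call. = FALSE)
  }
  m <- 2^bit_depth - 1
  if (domain == "display" && (min(pixels) < 0 || max(pixels) > m)) {
    stop(sprintf("display-domain pixels must lie in [0, %d]", m), call. = FALSE)
  }
  if (domain == "unit" && (min(pixels) < 0 || max(pixels) > 1)) {
    stop("unit-domain pixels must lie in [0, 1]", call. = FALSE)
  }
  structure(unclass(as.matrix(pixels)),
            class = "gray_image", bit_depth = bit_depth, domain = domain)
}

#' @rdname gray_image
#' @param x Object to coerce / query.
#' @export
as_gray_image <- function(x, bit_depth = 8L, domain = "display") {
  if (inherits(x, "gray_image")) return(x)
  gray_image(as.matrix(x), bit_depth = bit_depth, domain = domain)
}

#' @rdname gray_image
#' @export
bit_depth <- function(x) {
  bd <- attr(x, "bit_depth")
  if (is.null(bd)) 8L else bd
}

#' @rdname gray_image
#' @export
img_domain <- function(x) {
  d <- attr(x, "domain")
  if (is.null(d)) "display" else d
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d (width x height), %d-bit, domain: %s\n",
              ncol(x), nrow(x), bit_depth(x), img_domain(x)))
  cat(sprintf("  pixel range: [%.6g, %.6g]\n", min(x), max(x)))
  invisible(x)
}

# Pixel payload as a plain numeric matrix.
px <- function(x) {
  if (inherits(x, "gray_image")) {
    attributes(x) <- list(dim = dim(x))
  }
  as.matrix(x)
}

#' Quantize a display-range image to integer grey levels
#'
#' Rounds half up (`floor(x + 0.5)`) and clips to
#' \eqn{[0, 2^{bit\_depth} - 1]}; this is the rounding rule used for all file
#' output and for the entropy metric's histogram.
#'
#' @param image A display-domain `gray_image` (or matrix in display range).
#' @param bit_depth Target bit depth; defaults to the image's own.
#' @return Integer-valued `gray_image` in the display domain.
#' @export
quantize_gray <- function(image, bit_depth = NULL) {
  bd <- if (is.null(bit_depth)) bit_depth(image) else as.integer(bit_depth)
  m <- 2^bd - 1
  x <- floor(px(image) + 0.5)
  x[x < 0] <- 0
  x[x > m] <- m
  if (bd <= 30L) storage.mode(x) <- "integer"
  gray_image(x, bit_depth = bd, domain = "display")
}

is_integer_valued <- function(x) {
  x <- px(x)
  all(x == floor(x))
}

stop_dims <- function(a, b) {
  if (!identical(dim(px(a)), dim(px(b)))) {
    stop("images must have identical dimensions", call. = FALSE)
  }
  invisible(NULL)
}
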