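# Independent quadrature oracle for the normalized incomplete Beta function:
# adaptive quadrature of the integrand t^(a-1) (1-t)^(b-1), split at 0.5 so
# each piece has at most one (integrable) endpoint singularity.
ibeta_quad <- function(alpha, beta, u) {
  f <- function(t) t^(alpha - 1) * (1 - t)^(beta - 1)
  q <- function(lo, hi) stats::integrate(f, lo, hi, rel.tol = 1e-9,
                                         subdivisions = 400L)$value
  total <- q(0, 0.5) + q(0.5, 1)
  part <- if (u <= 0.5) {
    if (u == 0) 0 else q(0, u)
  } else {
    q(0, 0.5) + q(0.5, u)
  }
  part / total
}

# Direct 2-D spatial convolution with symmetric (edge-duplicating mirror)
# padding — the brute-force reference for the separable blur.
direct_blur <- function(x, scale, radius) {
  k <- gaussian_surround(scale, radius)
  h <- nrow(x); w <- ncol(x)
  refl <- function(i, n) {
    j <- (i - 1L) %% (2L * n)
    ifelse(j < n, j + 1L, 2L * n - j)
  }
  out <- matrix(0, h, w)
  for (r in seq_len(h)) {
    for (cc in seq_len(w)) {
      rows <- refl(r + (-radius:radius), h)
      cols <- refl(cc + (-radius:radius), w)
      out[r, cc] <- sum(k * x[rows, cols])
    }
  }
  out
}

# Strip a gray_image (or matrix) to a bare numeric matrix for comparisons.
px_mat <- function(x) {
  d <- dim(x)
  x <- unclass(x)
  attributes(x) <- list(dim = d)
  x
}

# Small low-contrast tank scene used across tests.
tiny_scene <- function(seed = 42, width = 64, height = 64) {
  synth_scene(scene_config(width = width, height = height, seed = seed))
}
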