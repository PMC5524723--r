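test_that("incomplete beta fixes endpoints, identity and symmetry cases", {
  u <- seq(0, 1, by = 0.05)
  expect_equal(incomplete_beta(beta_params(1, 1), u), u)
  for (a in c(0.3, 1, 2.5, 7)) {
    expect_equal(incomplete_beta(beta_params(a, a), 0.5), 0.5)
    expect_identical(incomplete_beta(beta_params(a, 9.9 - a/2), c(0, 1)), c(0, 1))
  }
})

test_that("incomplete beta is monotone and matches the quadrature oracle", {
  set.seed(21)
  for (i in 1:40) {
    a <- runif(1, 0.1, 9.9); b <- runif(1, 0.1, 9.9); u <- runif(1)
    expect_equal(incomplete_beta(beta_params(a, b), u), ibeta_quad(a, b, u),
                 tolerance = 1e-6)
    grid <- incomplete_beta(beta_params(a, b), seq(0, 1, length.out = 101))
    expect_true(all(diff(grid) >= 0))
  }
  # the worked optimum (alpha = 5.09, beta = 9.97) at u = 0.338:
  # frozen quadrature value 0.523746556477
  expect_equal(incomplete_beta(beta_params(5.09, 9.97), 0.338),
               0.523746556477, tolerance = 1e-6)
  expect_equal(incomplete_beta(beta_params(5.09, 9.97), 0.338),
               ibeta_quad(5.09, 9.97, 0.338), tolerance = 1e-6)
})

test_that("parameter and domain validation is strict", {
  expect_error(beta_params(0, 5), "strictly")
  expect_error(beta_params(10, 5), "strictly")
  expect_error(beta_params(5, -1), "strictly")
  expect_error(incomplete_beta(beta_params(2, 2), 1.2), "\\[0, 1\\]")
  expect_error(incomplete_beta(beta_params(2, 2), -0.1), "\\[0, 1\\]")
})

test_that("transform curve is monotone with correct endpoints and S shape", {
  crv <- transform_curve(beta_params(1, 1), 11)
  expect_equal(crv$F, crv$u)
  expect_error(transform_curve(beta_params(1, 1), 1), ">= 2")

  crv <- transform_curve(beta_params(5.09, 9.97), 101)
  expect_equal(crv$F[1], 0)
  expect_equal(crv$F[101], 1)
  expect_true(all(diff(crv$F) >= 0))
  # mid-stretching curve: flat at both ends, steeper than 1 in between
  slopes <- diff(crv$F) / diff(crv$u)
  expect_lt(slopes[1], 1)
  expect_lt(slopes[100], 1)
  expect_gt(max(slopes), 1)
})

test_that("curve family matches the dark/bright stretching taxonomy", {
  u <- seq(0.02, 0.98, by = 0.02)
  # alpha < 1 < beta stretches dark regions: F(u) > u on (0, 1)
  expect_true(all(incomplete_beta(beta_params(0.5, 2), u) > u))
  # beta < 1 < alpha stretches bright regions: F(u) < u on (0, 1)
  expect_true(all(incomplete_beta(beta_params(2, 0.5), u) < u))
})

test_that("LUT evaluation agrees with direct evaluation for smooth curves", {
  sc <- tiny_scene(seed = 9)
  fn <- img_normalize(msr(sc$image))
  # linear interpolation on a 1/256 grid carries error up to |F''| h^2 / 8,
  # ~6e-5 for these curves; off-grid agreement is therefore checked at 1e-4
  # while grid values (the attainable quantized levels) must match exactly
  for (p in list(beta_params(5.09, 9.97), beta_params(2, 3))) {
    direct <- apply_beta(fn, p, method = "direct")
    lut <- apply_beta(fn, p, method = "lut")
    expect_lt(max(abs(unclass(direct) - unclass(lut))), 1e-4)
  }
  # the table is exact at its own grid values
  g <- gray_image(matrix(seq(0, 1, length.out = 257), 1), domain = "unit")
  p <- beta_params(0.3, 4)
  expect_equal(unclass(apply_beta(g, p, "lut")), unclass(apply_beta(g, p)))
})

test_that("normalization maps min/max to 0/1 and preserves order", {
  img <- gray_image(matrix(c(10, 60, 110, 60), 2, 2))
  got <- img_normalize(img)
  expect_equal(as.vector(unclass(got)), c(0, 0.5, 1, 0.5))
  set.seed(4)
  x <- matrix(rnorm(100), 10, 10)
  n <- unclass(img_normalize(gray_image(x, domain = "real")))
  expect_identical(range(n), c(0, 1))
  expect_identical(order(as.vector(n)), order(as.vector(x)))
  expect_error(img_normalize(gray_image(matrix(77, 5, 5))), "degenerate")
})

test_that("apply_beta respects identity, endpoints and its unit domain", {
  sc <- tiny_scene(seed = 12)
  fn <- img_normalize(msr(sc$image))
  expect_equal(unclass(apply_beta(fn, beta_params(1, 1))), unclass(fn))
  ends <- gray_image(matrix(c(0, 1), 1), domain = "unit")
  for (p in list(c(0.2, 5), c(8, 0.7), c(3, 3))) {
    expect_equal(as.vector(unclass(apply_beta(ends, beta_params(p[1], p[2])))),
                 c(0, 1))
  }
  bad <- gray_image(matrix(c(0, 2), 1), domain = "real")
  expect_error(apply_beta(bad, beta_params(2, 2)), "\\[0, 1\\]")
})

test_that("denormalization inverts normalization on the real-valued path", {
  half <- gray_image(matrix(0.5, 1, 1), domain = "unit")
  expect_equal(as.vector(unclass(img_denormalize(half, 8))), 127.5)
  expect_equal(as.vector(unclass(quantize_gray(img_denormalize(half, 8)))), 128)
  ends <- gray_image(matrix(c(0, 1), 1), domain = "unit")
  expect_equal(as.vector(unclass(img_denormalize(ends, 8))), c(0, 255))
  set.seed(8)
  x <- matrix(runif(64), 8, 8)
  x[1] <- 0; x[64] <- 1
  u <- gray_image(x, domain = "unit")
  back <- img_normalize(img_denormalize(u, 8))
  expect_equal(px_mat(back), x, tolerance = 1e-12)
  expect_error(img_denormalize(gray_image(matrix(c(0, 1.5), 1), domain = "real")),
               "\\[0, 1\\]")
})
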