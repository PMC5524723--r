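test_that("contrast is the population variance of grey values", {
  expect_equal(img_contrast(gray_image(matrix(42, 7, 7))), 0)
  half <- gray_image(matrix(c(0, 255), 16, 16))
  expect_equal(img_contrast(half), 16256.25)
  # variance scaling law: contrast(a * x) = a^2 contrast(x)
  set.seed(2)
  x <- matrix(runif(100, 0, 50), 10, 10)
  for (a in c(0.5, 2, 3)) {
    expect_equal(img_contrast(a * x), a^2 * img_contrast(x), tolerance = 1e-9)
  }
})

test_that("MSE and PSNR follow their closed forms and error cases", {
  a <- gray_image(matrix(100, 10, 10))
  b <- gray_image(matrix(101, 10, 10))
  expect_equal(img_mse(a, a), 0)
  expect_equal(img_mse(a, b), 1)
  one_off <- matrix(100, 10, 10); one_off[5, 5] <- 110
  expect_equal(img_mse(a, gray_image(one_off)), 1)
  expect_equal(img_psnr(a, b, 8), 48.1308, tolerance = 1e-4)
  m2 <- gray_image(matrix(c(0, 255), 10, 10))
  m2b <- gray_image(matrix(c(255, 0), 10, 10))
  expect_equal(img_psnr(m2, m2b, 8), 0)       # MSE = m^2
  expect_identical(img_psnr(a, a), Inf)        # degenerate identical images
  expect_error(img_mse(a, gray_image(matrix(1, 3, 3))), "dimensions")
  # PSNR decreases strictly as MSE grows
  noisy <- function(s) gray_image(pmin(pmax(100 + s * sin(1:100), 0), 255) |> matrix(10, 10))
  expect_gt(img_psnr(a, noisy(2)), img_psnr(a, noisy(10)))
})

test_that("entropy matches its degenerate and uniform cases within [0, bit_depth]", {
  expect_equal(img_entropy(gray_image(matrix(7, 5, 5))), 0)
  expect_equal(img_entropy(gray_image(matrix(c(0, 255), 4, 4))), 1)
  expect_equal(img_entropy(gray_image(matrix(0:255, 16, 16))), 8)
  expect_error(img_entropy(gray_image(matrix(c(0.5, 1), 2, 2))), "quantize")
  set.seed(14)
  for (i in 1:10) {
    img <- gray_image(matrix(sample(0:255, 64, replace = TRUE), 8, 8))
    h <- img_entropy(img)
    expect_gte(h, 0)
    expect_lte(h, 8)
  }
})

test_that("the histogram fitness shortcut equals per-pixel contrast on quantized images", {
  sc <- tiny_scene(seed = 17)
  x <- px_mat(sc$image)
  counts <- tabulate(as.vector(x) + 1L, nbins = 256L)
  expect_equal(msrbeta:::contrast_weighted(0:255, counts), img_contrast(x),
               tolerance = 1e-9)
  # and through an arbitrary monotone level mapping
  y <- 255 * pbeta(0:255 / 255, 5.09, 9.97)
  mapped <- matrix(y[x + 1L], nrow(x), ncol(x))
  expect_equal(msrbeta:::contrast_weighted(y, counts), img_contrast(mapped),
               tolerance = 1e-9)
})

test_that("quality reports bundle the four measures consistently", {
  sc <- tiny_scene(seed = 23)
  img <- sc$image
  rep_self <- quality_report(img, img)
  expect_equal(rep_self$contrast, img_contrast(img))
  expect_equal(rep_self$mse, 0)
  expect_identical(rep_self$psnr, Inf)
  expect_equal(rep_self$entropy, img_entropy(img))

  a <- gray_image(matrix(100, 6, 6)); b <- gray_image(matrix(101, 6, 6))
  rep2 <- quality_report(a, b)
  expect_equal(rep2$mse, 1)
  expect_equal(rep2$psnr, 48.1308, tolerance = 1e-4)
  expect_equal(rep2$entropy, 0)
})

test_that("reports serialize to flat key-value text", {
  sc <- tiny_scene(seed = 29)
  rep <- quality_report(sc$image, hist_equalize(sc$image))
  path <- withr::local_tempfile(fileext = ".txt")
  write_report(rep, path)
  got <- read.table(path, col.names = c("key", "value"))
  expect_setequal(got$key, c("contrast", "mse", "psnr", "entropy", "bit_depth"))
  expect_equal(got$value[got$key == "contrast"], rep$contrast, tolerance = 1e-12)
})
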