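test_that("sRGB to CIELAB maps the anchor colors correctly", {
  w <- rgb_to_lab(uniform_img(c(255, 255, 255), 2, 2))
  expect_equal(as.numeric(w[1, 1, ]), c(100, 0, 0), tolerance = 1e-4)
  k <- rgb_to_lab(uniform_img(c(0, 0, 0), 2, 2))
  expect_equal(as.numeric(k[1, 1, ]), c(0, 0, 0), tolerance = 1e-12)
  g <- rgb_to_lab(uniform_img(c(119, 119, 119), 2, 2))
  expect_equal(g[1, 1, 1], 50, tolerance = 0.1)
  expect_lt(abs(g[1, 1, 2]), 0.5)
  expect_lt(abs(g[1, 1, 3]), 0.5)
})

test_that("CIELAB conversion agrees with grDevices::convertColor", {
  set.seed(11)
  m <- matrix(sample(0:255, 600, replace = TRUE), ncol = 3)
  mine <- tonguecast:::srgb_matrix_to_lab(m)
  ref <- grDevices::convertColor(m / 255, from = "sRGB", to = "Lab")
  # small matrix-precision differences on saturated colors are expected
  expect_lt(max(abs(mine - ref)), 0.5)
  grays <- cbind(0:255, 0:255, 0:255)
  expect_lt(max(abs(tonguecast:::srgb_matrix_to_lab(grays) -
                    grDevices::convertColor(grays / 255, "sRGB", "Lab"))), 1e-4)
})

test_that("lab round trip recovers every channel within one level", {
  set.seed(21)
  img <- rand_img(25, 40)  # 1000 random colors
  back <- lab_to_rgb(rgb_to_lab(img))
  expect_lte(max(abs(unclass(back) - unclass(img))), 1)
})

test_that("delta E summary is zero on identity, symmetric, and ordered", {
  set.seed(31)
  x <- rand_img()
  s <- delta_e_summary(x, x)
  expect_identical(unlist(s[c("mean", "q1", "q2", "q3", "max")]),
                   c(mean = 0, q1 = 0, q2 = 0, q3 = 0, max = 0))
  for (i in 1:5) {
    a <- rand_img(10, 14)
    b <- rand_img(10, 14)
    sab <- delta_e_summary(a, b)
    sba <- delta_e_summary(b, a)
    expect_equal(sab, sba)
    expect_true(sab$q1 <= sab$q2 && sab$q2 <= sab$q3 && sab$q3 <= sab$max)
    expect_gte(sab$mean, 0)
    expect_lte(sab$mean, sab$max)
  }
  expect_error(delta_e_summary(rand_img(4, 4), rand_img(4, 5)), "dimensions")
})

test_that("uniform image pairs collapse all distance levels to one value", {
  a <- uniform_img(c(200, 40, 60))
  b <- uniform_img(c(180, 60, 90))
  expected <- sqrt(sum((oracle_lab(c(200, 40, 60)) - oracle_lab(c(180, 60, 90)))^2))
  s <- delta_e_summary(a, b)
  for (f in c("mean", "q1", "q2", "q3", "max")) {
    expect_equal(s[[f]], expected, tolerance = 1e-9)
  }
})

test_that("cast severity classification follows the 6/15 criteria", {
  expect_identical(classify_cast(5), "same")
  expect_identical(classify_cast(10), "mild_cast")
  expect_identical(classify_cast(20), "cast")
  expect_identical(classify_cast(0), "same")
  expect_identical(classify_cast(6), "mild_cast")
  expect_identical(classify_cast(15), "cast")  # boundary flagged as cast
  expect_error(classify_cast(-1), "non-negative")
})

test_that("quality report identity and scale conventions hold", {
  set.seed(41)
  x <- rand_img()
  q <- quality_report(x, x)
  expect_identical(q$mae, 0)
  expect_identical(q$rmse, 0)
  expect_identical(q$psnr, Inf)
  expect_identical(q$ssim, 1)
  expect_identical(q$delta_e$max, 0)
  expect_identical(q$cast, "same")
  # RMSE of 255 on the 0-255 scale gives 0 dB exactly
  black <- uniform_img(c(0, 0, 0))
  white <- uniform_img(c(255, 255, 255))
  expect_identical(psnr(black, white), 0)
  # fixed uniform pair: direct arithmetic oracle
  a <- uniform_img(c(100, 150, 200))
  b <- uniform_img(c(110, 130, 190))
  expect_equal(mae(a, b), mean(c(10, 20, 10)) / 255, tolerance = 1e-12)
  expect_equal(rmse(a, b), sqrt(mean(c(100, 400, 100))) / 255, tolerance = 1e-12)
})

test_that("metric inequalities and PSNR/RMSE consistency hold on random pairs", {
  set.seed(51)
  for (i in 1:10) {
    a <- rand_img(12, 15)
    b <- rand_img(12, 15)
    expect_lte(mae(a, b), rmse(a, b))  # Jensen
    rmse_255 <- rmse(a, b) * 255
    expect_lt(abs(psnr(a, b) - 20 * log10(255 / rmse_255)), 1e-9)
  }
})

test_that("SSIM is exactly 1 on identity, symmetric, and matches a window-loop oracle", {
  set.seed(61)
  a <- rand_img(14, 16)
  b <- rand_img(14, 16)
  expect_identical(ssim(a, a), 1)
  expect_identical(ssim(a, b), ssim(b, a))
  expect_lte(ssim(a, b), 1)
  expect_equal(ssim(a, b), oracle_ssim(unclass(a), unclass(b)), tolerance = 1e-8)
  expect_error(ssim(rand_img(8, 8), rand_img(8, 8)), "11x11")
})

test_that("quality CSV uses the conventional column order", {
  set.seed(71)
  reports <- list(quality_report(rand_img(12, 12), rand_img(12, 12)))
  path <- tempfile(fileext = ".csv")
  write_quality_csv(reports, path)
  got <- utils::read.csv(path)
  expect_identical(names(got), c("PSNR", "SSIM", "E_mean", "E_Q1", "E_Q2",
                                 "E_Q3", "E_Max", "MAE", "RMSE"))
})

test_that("images with an alpha channel are rejected at read time", {
  path <- tempfile(fileext = ".png")
  png::writePNG(array(runif(8 * 8 * 4), c(8, 8, 4)), path)
  expect_error(read_image(path), "alpha")
  png::writePNG(array(runif(8 * 8 * 3), c(8, 8, 3)), path)
  expect_s3_class(read_image(path), "rgb_image")
})

test_that("rgb_image enforces its invariants", {
  expect_error(rgb_image(array(0, c(4, 4, 4))), "3 channels")
  expect_error(rgb_image(array(-1, c(4, 4, 3))), "\\[0, 255\\]")
  expect_error(rgb_image(array(256, c(4, 4, 3))), "\\[0, 255\\]")
  expect_error(rgb_image(matrix(0, 4, 4)), "3-dimensional")
})
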