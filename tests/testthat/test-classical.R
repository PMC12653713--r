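test_that("gray world equalizes channel means (derived two-pixel example)", {
  g <- uniform_img(c(137, 137, 137))
  expect_identical(unclass(gray_world(g)), unclass(g))
  two <- rgb_image(array(rep(c(100, 50, 150), each = 2), c(2, 1, 3)))
  expect_true(all(gray_world(two) == 100))  # K = 100, scales (1, 2, 2/3)
  expect_error(gray_world(uniform_img(c(0, 10, 10))), "zero")
})

test_that("gray world corrected means agree within half a level absent clamping", {
  set.seed(22)
  for (i in 1:5) {
    base <- array(0, c(20, 20, 3))
    mu <- c(100, 120, 140)
    for (ch in 1:3) base[, , ch] <- mu[ch] + sample(-20:20, 400, replace = TRUE)
    out <- gray_world(rgb_image(base))
    means <- apply(unclass(out), 3, mean)
    expect_lt(max(means) - min(means), 0.5)
  }
})

test_that("perfect reflection maps the brightest pixel to pure white", {
  img <- rand_img(10, 10)
  x <- unclass(img)
  x[4, 7, ] <- c(255, 255, 255)
  out <- perfect_reflection(rgb_image(x))
  expect_identical(unclass(out), x)  # scale factors all 1
  # derived rounding example: brightest (200,100,50), pixel (100,50,25)
  arr <- array(c(200, 100, 100, 50, 50, 25), c(2, 1, 3))
  out2 <- perfect_reflection(rgb_image(arr))
  expect_identical(as.numeric(out2[1, 1, ]), c(255, 255, 255))
  expect_identical(as.numeric(out2[2, 1, ]), c(128, 128, 128))
  expect_error(perfect_reflection(rgb_image(array(c(200, 10, 100, 5, 0, 2),
                                                  c(2, 1, 3)))), "zero")
})

test_that("perfect reflection breaks brightness ties by first occurrence", {
  arr <- array(c(200, 50, 100, 100, 50, 200), c(2, 1, 3))  # equal R+G+B
  out <- perfect_reflection(rgb_image(arr))
  expect_identical(as.numeric(out[1, 1, ]), c(255, 255, 255))
})

test_that("SDW reduces to gray world when all blocks share statistics", {
  u <- uniform_img(c(90, 120, 150), 32, 32)
  expect_identical(unclass(sdw_correct(u)), unclass(gray_world(u)))  # fallback
  set.seed(23)
  block <- array(sample(40:200, 16 * 16 * 3, replace = TRUE), c(16, 16, 3))
  tiled <- array(0, c(64, 64, 3))
  for (i in 0:3) for (j in 0:3) {
    tiled[i * 16 + 1:16, j * 16 + 1:16, ] <- block
  }
  timg <- rgb_image(tiled)
  expect_identical(unclass(sdw_correct(timg)), unclass(gray_world(timg)))
  expect_error(sdw_correct(rand_img(8, 8)), "at least 16")
})

test_that("SDW down-weights a flat saturated region relative to plain gray world", {
  set.seed(24)
  img <- array(0, c(32, 64, 3))
  img[, 1:32, 1] <- 230; img[, 1:32, 2] <- 30; img[, 1:32, 3] <- 30  # flat red
  tex <- sample(90:150, 32 * 32, replace = TRUE)
  for (ch in 1:3) img[, 33:64, ch] <- tex + sample(-10:10, 32 * 32, replace = TRUE)
  img <- rgb_image(img)
  balance <- function(out) {
    m <- apply(unclass(out)[, 33:64, , drop = FALSE], 3, mean)
    max(m) / min(m)  # 1 = perfectly neutral texture region
  }
  expect_lt(balance(sdw_correct(img)), balance(gray_world(img)))
})

test_that("polynomial fit is exact on identity and invertible linear ground truth", {
  chart <- colorchecker_chart()
  pm <- fit_polynomial_map(chart, chart)
  V <- tonguecast:::poly_expand(as.matrix(chart[, c("R", "G", "B")]) / 255, pm$terms)
  resid <- V %*% pm$coefficients * 255 - as.matrix(chart[, c("R", "G", "B")])
  expect_lt(max(abs(resid)), 1e-9)
  # observed = reference * 0.5: the x2 linear transform is in the model class
  obs <- chart
  obs[, c("R", "G", "B")] <- obs[, c("R", "G", "B")] * 0.5
  pm2 <- fit_polynomial_map(obs, chart)
  V2 <- tonguecast:::poly_expand(as.matrix(obs[, c("R", "G", "B")]) / 255, pm2$terms)
  resid2 <- V2 %*% pm2$coefficients * 255 - as.matrix(chart[, c("R", "G", "B")])
  expect_lt(max(abs(resid2)), 1e-6)
})

test_that("a map fitted on a channel swap un-swaps an image", {
  chart <- colorchecker_chart()
  swapped <- chart
  swapped$R <- chart$B
  swapped$B <- chart$R
  pm <- fit_polynomial_map(swapped, chart)
  set.seed(25)
  img <- rand_img(8, 8)
  simg <- unclass(img)[, , c(3, 2, 1)]
  out <- apply_polynomial_map(pm, rgb_image(simg))
  expect_lte(max(abs(unclass(out) - unclass(img))), 1)
})

test_that("polynomial fitting validates its design", {
  chart <- colorchecker_chart()
  expect_error(fit_polynomial_map(chart[1:8, ], chart[1:8, ]), "patches")
  flat <- chart
  flat[, c("R", "G", "B")] <- 128
  expect_error(fit_polynomial_map(flat, chart), "rank-deficient")
  expect_error(fit_polynomial_map(chart[1:20, ], chart), "same number")
  id <- fit_polynomial_map(chart, chart)
  img <- rand_img(6, 6)
  expect_lte(max(abs(unclass(apply_polynomial_map(id, img)) - unclass(img))), 1)
  expect_true(all(apply_polynomial_map(id, img) >= 0) &&
              all(apply_polynomial_map(id, img) <= 255))
})

test_that("chart CSV round trip preserves the embedded chart", {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(colorchecker_chart(), path, row.names = FALSE)
  got <- read_chart_csv(path)
  expect_equal(as.numeric(got$R), as.numeric(colorchecker_chart()$R))
  bad <- data.frame(name = "x", R = 300, G = 0, B = 0)
  path2 <- tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(read_chart_csv(path2), "\\[0, 255\\]")
})
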