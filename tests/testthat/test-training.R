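test_that("mse loss matches its closed forms and a brute-force sum", {
  x <- array(runif(60), c(5, 4, 3))
  expect_identical(mse_loss(x, x), 0)
  expect_equal(mse_loss(x + 0.3, x), 0.3^2, tolerance = 1e-12)
  set.seed(31)
  a <- array(runif(60), c(5, 4, 3))
  b <- array(runif(60), c(5, 4, 3))
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  expect_lt(abs(mse_loss(a, b) - s / length(a)), 1e-12)
  expect_error(mse_loss(a, array(0, c(4, 5, 3))), "shape")
})

test_that("patch extraction follows the sliding-window contract", {
  img <- rand_img(8, 8)
  ps <- extract_patches(img, size = 4, step = 2)
  expect_length(ps, 9)  # ((8-4)/2 + 1)^2
  expect_true(all(vapply(ps, function(p) identical(dim(p), c(4L, 4L, 3L)), logical(1))))
  expect_identical(unclass(ps[[1]]), unclass(img)[1:4, 1:4, ])
  expect_identical(unclass(ps[[2]]), unclass(img)[1:4, 3:6, ])  # row-major
  whole <- extract_patches(img, size = 8, step = 3)
  expect_length(whole, 1)
  expect_identical(unclass(whole[[1]]), unclass(img))
  expect_error(extract_patches(img, size = 9), "exceeds")
})

test_that("patch footprints cover every pixel when step <= size", {
  img <- rand_img(20, 20)
  size <- 8; step <- 6
  cov <- matrix(0, 20, 20)
  offs <- seq.int(1, 20 - size + 1, by = step)
  for (r in offs) for (cc in offs) cov[r:(r + size - 1), cc:(cc + size - 1)] <- 1
  # contract check on the same offsets the extractor uses
  expect_length(extract_patches(img, size, step), length(offs)^2)
  expect_true(all(cov[seq_len(max(offs) + size - 1), ] == 1))
})

test_that("splits are by source image, seeded, and leak-free", {
  info <- data.frame(source = rep(1:100, each = 3))
  s1 <- split_dataset(info, seed = 5)
  s2 <- split_dataset(info, seed = 5)
  expect_identical(s1, s2)
  per_image <- unique(s1[, c("source", "split")])
  expect_identical(as.integer(table(per_image$split)), c(60L, 30L, 10L))
  # no source appears in two splits
  expect_identical(nrow(per_image), 100L)
  expect_error(split_dataset(data.frame(source = c(1, 2))), "at least 3")
  expect_error(split_dataset(info, ratios = c(0.5, 0.5, 0.5)), "summing to 1")
})

test_that("a tiny network masters the identity task", {
  patches <- generate_color_blocks(30, seed = 41, size = 8)
  ds <- toy_dataset(patches, patches, sources = rep(1:6, each = 5), seed = 2)
  m <- build_dccn(dccn_config(filters = 16), seed = 9)
  cfg <- train_config(epochs = 199, batch_size = 20, learning_rate = 3e-3,
                      scheduler_patience = 40, seed = 3)
  r <- train_model(m, ds, cfg)
  h <- r$history
  expect_identical(nrow(h), 199L)
  expect_lt(h$train_loss[199], h$train_loss[1] / 10)
  expect_true(all(diff(h$lr) <= 0))  # learning rate never increases
  expect_true(all(h$lr %in% (cfg$learning_rate * cfg$scheduler_factor^(0:199))))
  # corrected output stays close to the input it was trained to reproduce
  out <- correct_image(r$model, patches[[1]])
  expect_lt(mean(abs(unclass(out) - unclass(patches[[1]]))), 8)
})

test_that("training is reproducible for a fixed seed", {
  set.seed(51)
  patches <- lapply(1:12, function(i) rand_img(8, 8))
  ds <- toy_dataset(patches, patches, sources = rep(1:4, each = 3), seed = 2)
  cfg <- train_config(epochs = 2, batch_size = 4, learning_rate = 1e-3,
                      scheduler_patience = 1, seed = 7)
  r1 <- train_model(build_dccn(dccn_config(filters = 4), seed = 9), ds, cfg)
  r2 <- train_model(build_dccn(dccn_config(filters = 4), seed = 9), ds, cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$model$params, r2$model$params)
})

test_that("train_config validates the scheduler and positivity constraints", {
  expect_error(train_config(scheduler_patience = 200, epochs = 100), "smaller")
  expect_error(train_config(learning_rate = 0), "invalid")
  expect_error(train_config(batch_size = 0), "invalid")
})

test_that("evaluate_corrector reports original and corrected rows", {
  set.seed(61)
  patches <- lapply(1:12, function(i) rand_img(12, 12))
  ds <- toy_dataset(patches, patches, sources = rep(1:4, each = 3), seed = 2)
  tab <- evaluate_corrector(function(im) im, ds, split = "test")
  expect_true(all(c("original", "corrected") %in% tab$state))
  expect_true(all(tab$SSIM == 1))  # unbiased pairs, identity corrector
  expect_true(all(tab$E_mean == 0))
  expect_identical(names(tab)[5:13],
                   c("PSNR", "SSIM", "E_mean", "E_Q1", "E_Q2", "E_Q3",
                     "E_Max", "MAE", "RMSE"))
})

test_that("bootstrap resampling has the right degenerate and CLT behavior", {
  b <- bootstrap_evaluate(rep(4.2, 25), n_boot = 40, seed = 3)
  expect_identical(b$sd, 0)
  expect_identical(b$mean, 4.2)
  expect_length(b$resample_means, 40)
  expect_identical(bootstrap_evaluate(1:10, seed = 9)$resample_means,
                   bootstrap_evaluate(1:10, seed = 9)$resample_means)
  set.seed(71)
  vals <- rnorm(2000, mean = 10, sd = 2)
  b2 <- bootstrap_evaluate(vals, n_boot = 40, seed = 5)
  expect_lt(abs(b2$mean - mean(vals)), 3 * sd(vals) / sqrt(length(vals)))
  expect_error(bootstrap_evaluate(numeric(0)), "non-empty")
})

test_that("paired t-test matches hand arithmetic and handles degeneracies", {
  a <- c(10, 12, 9, 14, 11)
  d <- c(2, 4, 6, 8, 10)
  r <- paired_t_test(a + d, a)
  t_hand <- mean(d) / (sd(d) / sqrt(5))  # textbook formula
  expect_lt(abs(r$t_statistic - t_hand), 1e-9)
  expect_lt(abs(r$p_value - 2 * stats::pt(-abs(t_hand), 4)), 1e-12)
  same <- paired_t_test(a, a)
  expect_identical(same$t_statistic, 0)
  expect_identical(same$p_value, 1)
  expect_false(same$significant)
  set.seed(81)
  x <- rnorm(40)
  big <- paired_t_test(x + 100, x)
  expect_true(big$significant)
  expect_lt(big$p_value, 0.001)
  expect_error(paired_t_test(1:4, 1:5), "equal length")
  expect_error(paired_t_test(1, 1), "at least 2")
})

test_that("the null rejection rate of the paired t-test is calibrated", {
  set.seed(91)
  rejections <- vapply(1:1000, function(i) {
    a <- rnorm(20)
    b <- rnorm(20)
    paired_t_test(a, b, alpha = 0.05)$significant
  }, logical(1))
  expect_gt(mean(rejections), 0.03)
  expect_lt(mean(rejections), 0.07)
})
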