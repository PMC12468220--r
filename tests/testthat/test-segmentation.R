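test_that("grayscale conversion uses BT.601 weights and fixed quantization", {
  expect_equal(to_grayscale(array(1, c(1, 1, 3)))[1, 1], 255)
  expect_equal(to_grayscale(array(0, c(1, 1, 3)))[1, 1], 0)
  red <- array(c(1, 0, 0), c(1, 1, 3))
  expect_equal(to_grayscale(red)[1, 1], 76)  # floor(0.299*255 + 0.5)
  set.seed(12)
  img <- random_rgb(6, 6)
  g <- to_grayscale(img)
  lum <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  expect_equal(g, floor(lum * 255 + 0.5), ignore_attr = TRUE)
})

test_that("histograms normalize and carry the exact mean and variance", {
  const <- quantize_levels(matrix(128 / 255, 5, 5))
  h <- compute_histogram(const)
  expect_equal(h$p[129], 1)
  expect_equal(h$mean, 128)
  expect_equal(h$variance, 0)
  half <- quantize_levels(matrix(c(0, 1), 4, 4))
  h2 <- compute_histogram(half)
  expect_equal(h2$mean, 127.5)
  expect_equal(h2$variance, 127.5^2)
  set.seed(13)
  any_img <- quantize_levels(matrix(runif(100), 10, 10))
  expect_equal(sum(compute_histogram(any_img)$p), 1, tolerance = 1e-12)
})

test_that("class statistics obey the variance decomposition and hand cases", {
  p <- numeric(256); p[c(10, 128, 240) + 1] <- 1 / 3
  h <- histogram_from_p(p)
  cs <- class_stats(h, c(10, 128))
  expect_equal(cs$omega, rep(1 / 3, 3))
  expect_equal(cs$mu, c(10, 128, 240))
  # degenerate single-level histogram: no between-class variance anywhere
  p1 <- numeric(256); p1[100] <- 1
  h1 <- histogram_from_p(p1)
  expect_equal(class_stats(h1, c(50, 150))$sigma_b2, 0)
  # sigma_B^2 + sigma_W^2 = sigma_T^2 on random draws
  set.seed(14)
  for (i in 1:50) {
    hr <- histogram_from_p(runif(256))
    t1 <- sample(0:200, 1); t2 <- sample((t1 + 1):254, 1)
    cs <- class_stats(hr, c(t1, t2))
    expect_equal(cs$sigma_b2 + cs$sigma_w2, hr$variance, tolerance = 1e-9)
    expect_equal(sum(cs$omega), 1, tolerance = 1e-12)
    expect_equal(sum(cs$omega * cs$mu), hr$mean, tolerance = 1e-9)
  }
})

test_that("multi-Otsu matches exhaustive enumeration including tie-breaks", {
  # equal spikes: large tie plateau, lexicographic tie-break
  p <- numeric(256); p[c(10, 128, 240) + 1] <- 1 / 3
  res <- multi_otsu(histogram_from_p(p))
  expect_identical(res$t, c(10L, 128L))
  # fully scalar double-loop oracle on a few random histograms
  set.seed(15)
  for (i in 1:3) {
    p <- runif(256)^3
    h <- histogram_from_p(p)
    got <- multi_otsu(h)
    ref <- o_multi_otsu_scalar(h$p)
    expect_identical(as.integer(got$t), as.integer(ref$t))
    expect_equal(got$sigma_b2, ref$sigma_b2, tolerance = 1e-9)
  }
  # optimum dominates random sampled pairs
  h <- histogram_from_p(runif(256))
  opt <- multi_otsu(h)
  for (i in 1:200) {
    t1 <- sample(0:250, 1); t2 <- sample((t1 + 1):254, 1)
    expect_lte(class_stats(h, c(t1, t2))$sigma_b2, opt$sigma_b2 + 1e-9)
  }
})

test_that("reflecting the histogram reflects the optimal thresholds", {
  set.seed(16)
  p <- runif(256)^2
  p <- (p + rev(p)) / sum(p + rev(p))   # symmetric under i -> 255 - i
  t_fwd <- multi_otsu(histogram_from_p(p))$t
  # enumerate the reflected problem with the same tie-break on reflected order
  ref <- o_multi_otsu(rev(p))
  expect_identical(as.integer(rev(254 - ref$t)), as.integer(t_fwd))
})

test_that("three-Gaussian mixtures threshold between the modes", {
  set.seed(17)
  x <- c(rnorm(30000, 40, 5), rnorm(30000, 130, 5), rnorm(30000, 220, 5))
  lev <- pmin(pmax(round(x), 0), 255)
  p <- tabulate(lev + 1, 256) / length(lev)
  got <- multi_otsu(histogram_from_p(p))
  expect_true(got$t[1] > 40 && got$t[1] < 130)
  expect_true(got$t[2] > 130 && got$t[2] < 220)
  expect_identical(as.integer(o_multi_otsu(p / sum(p))$t), as.integer(got$t))
})

test_that("degenerate histograms are rejected with guidance", {
  p <- numeric(256); p[c(3, 200) + 1] <- 0.5
  expect_error(multi_otsu(histogram_from_p(p)), "fewer than 3 occupied")
})

test_that("class-1 extraction keeps exactly the darkest pixels", {
  z <- quantize_levels(matrix(0, 4, 4))
  expect_true(all(extract_class_mask(z, c(50, 150))))
  lv <- quantize_levels(matrix(c(0, 100 / 255, 200 / 255), 3, 3))
  m <- extract_class_mask(lv, c(50, 150))
  expect_identical(m, lv == 0)
  expect_identical(extract_class_mask(lv, c(50, 150), class_index = 2), lv == 100)
  expect_identical(extract_class_mask(lv, c(50, 150), class_index = 3), lv == 200)
  expect_error(extract_class_mask(lv, c(150, 50)), "t1 < t2")
  # two-population image: all nucleus pixels still land in the mask when the
  # dark mode sits below t1
  img <- matrix(230 / 255, 32, 32)
  nuc <- disk_mask(32, 32, 16, 16, 6)
  img[nuc] <- 20 / 255
  img[1, 1] <- 120 / 255   # token third level to keep three classes occupied
  lev <- quantize_levels(img)
  t <- multi_otsu(compute_histogram(lev))$t
  mask <- extract_class_mask(lev, t)
  expect_true(all(mask[nuc]))
})
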