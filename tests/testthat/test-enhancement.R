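test_that("bilateral filter fixes constants and matches the naive evaluation", {
  const <- matrix(0.37, 12, 15)
  p <- bilateral_params(2, 0.1, 4)
  expect_equal(bilateral_filter(const, p), const)
  set.seed(7)
  img <- matrix(runif(16 * 16), 16, 16)
  got <- bilateral_filter(img, p)
  expect_equal(got, o_bilateral(img, 2, 0.1, 4), tolerance = 1e-12)
  expect_gte(min(got), min(img))
  expect_lte(max(got), max(img))
})

test_that("huge range sigma reduces the bilateral filter to Gaussian smoothing", {
  set.seed(8)
  img <- matrix(runif(20 * 20), 20, 20)
  got <- bilateral_filter(img, bilateral_params(2, 1e6, 4))
  expect_equal(got, o_gaussian_window(img, 2, 4), tolerance = 1e-6)
})

test_that("a sharp step edge survives bilateral smoothing", {
  img <- cbind(matrix(0, 16, 8), matrix(1, 16, 8))
  out <- bilateral_filter(img, bilateral_params(2, 0.05, 4))
  # plateaus barely move; the edge stays where it was
  expect_lt(max(abs(out[, c(1:6, 11:16)] - img[, c(1:6, 11:16)])), 0.01)
  expect_true(all(out[, 8] < 0.5) && all(out[, 9] > 0.5))
})

test_that("invalid bilateral parameters are rejected", {
  expect_error(bilateral_params(-1, 0.1), "positive")
  expect_error(bilateral_params(1, 0), "positive")
})

test_that("mean intensity is the plain pixel average", {
  expect_equal(mean_intensity(matrix(0.3, 4, 4)), 0.3)
  expect_equal(mean_intensity(matrix(c(0, 0.5, 0.5, 1), 2, 2)), 0.5)
  expect_equal(mean_intensity(matrix(0, 3, 3)), 0)
  expect_error(mean_intensity(matrix(numeric(0), 0, 0)), "height")
})

test_that("adaptive gamma follows its two branches and is continuous at 0.5", {
  g <- adaptive_gamma(0.5)
  expect_equal(g$gamma, 1.0)
  expect_equal(adaptive_gamma(0.8)$gamma, 0.7)
  expect_equal(adaptive_gamma(0.8)$branch, "above_half")
  expect_equal(adaptive_gamma(0.25)$gamma, 2.0)
  expect_equal(adaptive_gamma(0.25)$branch, "at_or_below_half")
  # |gamma(0.5-eps) - gamma(0.5+eps)| -> 0 linearly (the two branches meet)
  for (eps in 10^-(3:7)) {
    expect_lt(abs(adaptive_gamma(0.5 - eps)$gamma -
                  adaptive_gamma(0.5 + eps)$gamma), 4 * eps)
  }
  # prose convention swaps the formulas but stays continuous
  expect_equal(adaptive_gamma(0.5, convention = "prose")$gamma, 1.0)
  expect_equal(adaptive_gamma(0.8, convention = "prose")$gamma, 1 / 1.6)
  # divergence clamp near zero mean
  expect_warning(gz <- adaptive_gamma(0), "clamped")
  expect_equal(gz$gamma, 5)
  expect_true(gz$clamped)
  expect_error(adaptive_gamma(1.2), "\\[0, 1\\]")
})

test_that("power-law correction has the expected fixed points and monotonicity", {
  set.seed(9)
  ch <- matrix(runif(64), 8, 8)
  expect_equal(apply_gamma(ch, 1), ch)
  expect_equal(apply_gamma(matrix(0.25, 1, 1), 2)[1, 1], 0.0625)
  expect_equal(apply_gamma(matrix(c(0, 1), 1, 2), 3.7), matrix(c(0, 1), 1, 2))
  for (g in c(0.4, 1, 2.5)) {
    out <- apply_gamma(ch, g)
    expect_equal(order(as.vector(out)), order(as.vector(ch)))
  }
  expect_error(apply_gamma(ch, 0), "positive")
})

test_that("enhance composes the stages and preserves hue and saturation", {
  # achromatic mid-gray: gamma 1, only bilateral smoothing (identity here)
  flat <- array(0.5, c(10, 10, 3))
  res <- enhance(flat, bilateral_params(2, 0.1, 3))
  expect_equal(res$gamma, 1.0)
  expect_equal(res$image, flat, tolerance = 1e-12)
  set.seed(10)
  img <- random_rgb(20, 20)
  res <- enhance(img, bilateral_params(2, 0.1, 3))
  # recompute the forward path: H and S must come through unchanged
  hsv_in <- rgb_to_hsv(img)
  hsv_out <- rgb_to_hsv(res$image)
  sel <- hsv_in[, , 2] > 0.05
  expect_lt(max(abs(hsv_out[, , 1][sel] - hsv_in[, , 1][sel])), 1e-6)
  expect_lt(max(abs(hsv_out[, , 2][sel] - hsv_in[, , 2][sel])), 1e-6)
  # corrected V equals the gamma law applied to the filtered V
  v_filt <- bilateral_filter(hsv_in[, , 3], bilateral_params(2, 0.1, 3))
  expect_equal(hsv_out[, , 3], v_filt^res$gamma, tolerance = 1e-9)
})

test_that("the gamma branch moves the mean in the direction its exponent implies", {
  sc <- generate_scene(scene_spec(seed = 5, nucleus_axes = c(10, 14),
                                  background_intensity = 0.45,
                                  cytoplasm_intensity = 0.35,
                                  cytoplasm_jitter = 0,
                                  nucleus_intensity = 0.12,
                                  nucleus_jitter = 0))
  v_in <- rgb_to_hsv(sc$image)[, , 3]
  stopifnot(mean(v_in) < 0.5)   # a dark scene
  bp <- bilateral_params(2, 0.1, 3)
  res_eq <- enhance(sc$image, bp, gamma_convention = "equations")
  res_pr <- enhance(sc$image, bp, gamma_convention = "prose")
  v_eq <- rgb_to_hsv(res_eq$image)[, , 3]
  expect_equal(res_eq$gamma, 1 / (2 * res_eq$mean_v))   # reciprocal branch
  expect_gt(res_eq$gamma, 1)
  expect_lt(mean(v_eq), res_eq$mean_v)  # gamma > 1 darkens on [0,1]
  # the swapped reading picks the linear formula here; still gamma > 1
  expect_equal(res_pr$gamma, 1 + (0.5 - res_pr$mean_v))
  expect_false(isTRUE(all.equal(res_pr$gamma, res_eq$gamma)))
  # a bright scene gets gamma < 1 and is brightened further toward white
  bright <- generate_scene(scene_spec(seed = 5))
  res_b <- enhance(bright$image, bp)
  stopifnot(res_b$mean_v > 0.5)
  expect_lt(res_b$gamma, 1)
  expect_gt(mean(rgb_to_hsv(res_b$image)[, , 3]), res_b$mean_v)
})
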