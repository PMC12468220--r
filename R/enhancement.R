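#' Bilateral filter parameters
#'
#' @param spatial_sigma Standard deviation of the spatial Gaussian, in pixels.
#' @param range_sigma Standard deviation of the range (intensity) Gaussian, in
#'   normalized intensity units.
#' @param window_radius Half-width of the square window; defaults to
#'   `ceiling(2 * spatial_sigma)` so the spatial kernel is not truncated early.
#' @return A `bilateral_params` list.
#' @export
bilateral_params <- function(spatial_sigma = 3, range_sigma = 0.1,
                             window_radius = NULL) {
  if (spatial_sigma <= 0 || range_sigma <= 0)
    stop("spatial_sigma and range_sigma must be positive", call. = FALSE)
  if (is.null(window_radius)) window_radius <- max(1L, ceiling(2 * spatial_sigma))
  window_radius <- as.integer(window_radius)
  if (window_radius < 1L) stop("window_radius must be >= 1", call. = FALSE)
  structure(list(spatial_sigma = spatial_sigma, range_sigma = range_sigma,
                 window_radius = window_radius),
            class = "bilateral_params")
}

## Edge-inclusive mirror index: 0 -> 1, -1 -> 2, n+1 -> n, ... applied until
## in range (covers radii larger than the image).
reflect_index <- function(idx, n) {
  repeat {
    below <- idx < 1L
    above <- idx > n
    if (!any(below) && !any(above)) return(idx)
    idx[below] <- 1L - idx[below]
    idx[above] <- 2L * n + 1L - idx[above]
  }
}

pad_reflect <- function(channel, r) {
  h <- nrow(channel); w <- ncol(channel)
  channel[reflect_index(seq(1L - r, h + r), h),
          reflect_index(seq(1L - r, w + r), w), drop = FALSE]
}

#' Edge-preserving bilateral filter
#'
#' Each output pixel is the weighted mean of its `(2r+1)^2` window, the weight
#' of a neighbor being the product of an unnormalized spatial Gaussian of its
#' distance and an unnormalized range Gaussian of its intensity difference
#' from the center. Similar-intensity neighbors dominate, so edges survive
#' smoothing. Borders are handled by mirror reflection.
#'
#' @param channel Single-channel matrix in \[0,1\].
#' @param params A [bilateral_params()] object.
#' @return Filtered matrix, same shape; values stay within the input range.
#' @export
bilateral_filter <- function(channel, params = bilateral_params()) {
  assert_channel(channel)
  stopifnot(inherits(params, "bilateral_params"))
  r <- params$window_radius
  h <- nrow(channel); w <- ncol(channel)
  padded <- pad_reflect(channel, r)
  inv2ss <- 1 / (2 * params$spatial_sigma^2)
  inv2rs <- 1 / (2 * params$range_sigma^2)
  num <- matrix(0, h, w)
  den <- matrix(0, h, w)
  for (di in -r:r) {
    for (dj in -r:r) {
      ws <- exp(-(di * di + dj * dj) * inv2ss)
      shifted <- padded[(1L + r + di):(h + r + di),
                        (1L + r + dj):(w + r + dj), drop = FALSE]
      d <- shifted - channel
      wgt <- ws * exp(-(d * d) * inv2rs)
      num <- num + shifted * wgt
      den <- den + wgt
    }
  }
  num / den
}

#' Mean intensity of a channel
#'
#' `(1 / (M N)) * sum(V)`: the overall brightness driving the adaptive gamma
#' choice.
#'
#' @param channel Single-channel matrix in \[0,1\].
#' @return Scalar in \[0,1\].
#' @export
mean_intensity <- function(channel) {
  assert_channel(channel)
  mean(channel)
}

#' Choose a gamma exponent from the mean intensity
#'
#' Two branches meet continuously at a mean of 0.5 (both give gamma 1):
#' for mean above 0.5, `gamma = 1 + (0.5 - mean)`; at or below 0.5,
#' `gamma = 1 / (2 * mean)`. The low-mean branch diverges as the mean
#' approaches 0, so gamma is clamped at `gamma_max` with a warning.
#'
#' The `convention` switch exposes the two possible readings of the rule:
#' `"equations"` (default) assigns the branches as above; `"prose"` swaps
#' which formula serves which side of 0.5. Both are continuous at 0.5.
#'
#' @param mean_intensity Scalar in \[0,1\].
#' @param convention `"equations"` or `"prose"`.
#' @param gamma_max Upper clamp for the divergent branch (default 5).
#' @return List with `mean_intensity`, `gamma`, `branch`
#'   (`"above_half"` / `"at_or_below_half"`), and `clamped`.
#' @export
adaptive_gamma <- function(mean_intensity, convention = c("equations", "prose"),
                           gamma_max = 5) {
  convention <- match.arg(convention)
  if (is.na(mean_intensity) || mean_intensity < 0 || mean_intensity > 1)
    stop("mean_intensity must lie in [0, 1]", call. = FALSE)
  above <- mean_intensity > 0.5
  branch <- if (above) "above_half" else "at_or_below_half"
  use_linear <- if (convention == "equations") above else !above
  if (use_linear) {
    gamma <- 1 + (0.5 - mean_intensity)
  } else {
    gamma <- if (mean_intensity == 0) Inf else 1 / (2 * mean_intensity)
  }
  clamped <- FALSE
  if (!is.finite(gamma) || gamma > gamma_max) {
    warning("gamma ", ifelse(is.finite(gamma), signif(gamma, 4), "Inf"),
            " clamped to ", gamma_max)
    gamma <- gamma_max
    clamped <- TRUE
  }
  list(mean_intensity = mean_intensity, gamma = gamma, branch = branch,
       clamped = clamped)
}

#' Power-law gamma correction
#'
#' `V_out = V_in ^ gamma` on the normalized \[0,1\] scale; gamma below 1
#' brightens, above 1 darkens, 1 is the identity.
#'
#' @param channel Single-channel matrix in \[0,1\].
#' @param gamma Positive exponent.
#' @return Corrected matrix in \[0,1\].
#' @export
apply_gamma <- function(channel, gamma) {
  assert_channel(channel)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("gamma must be a positive scalar", call. = FALSE)
  channel^gamma
}

#' Enhance an RGB cytology image
#'
#' The preprocessing stage of the segmentation pipeline: convert to HSV,
#' bilateral-filter the value channel, measure its mean intensity, pick an
#' adaptive gamma ([adaptive_gamma()]), apply the power law to the filtered
#' value channel, and reassemble RGB from the original hue/saturation and the
#' corrected value.
#'
#' @param img `h x w x 3` RGB array in \[0,1\].
#' @param params [bilateral_params()] for the value-channel smoothing.
#' @param gamma_convention,gamma_max Passed to [adaptive_gamma()].
#' @return List: `image` (enhanced RGB), `mean_v` (mean of the filtered value
#'   channel), `gamma`, `branch`, `clamped`.
#' @export
enhance <- function(img, params = bilateral_params(),
                    gamma_convention = "equations", gamma_max = 5) {
  assert_rgb(img)
  hsv <- rgb_to_hsv(img)
  v_filt <- bilateral_filter(hsv[, , 3L], params)
  mi <- mean_intensity(v_filt)
  gd <- adaptive_gamma(mi, convention = gamma_convention, gamma_max = gamma_max)
  hsv[, , 3L] <- apply_gamma(v_filt, gd$gamma)
  list(image = hsv_to_rgb(hsv), mean_v = mi, gamma = gd$gamma,
       branch = gd$branch, clamped = gd$clamped)
}
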