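#' Integral image (summed-area table)
#'
#' Returns an `(h+1) x (w+1)` cumulative table with a zero first row/column,
#' so any rectangle sum is four lookups. Exact for integer inputs.
#'
#' @param channel Numeric matrix.
#' @return List: `sum` and `sumsq` tables.
#' @export
integral_image <- function(channel) {
  stop_if_empty(channel)
  h <- nrow(channel); w <- ncol(channel)
  pad <- function(x) {
    s <- matrix(x, h, w)
    if (h > 1L) s <- apply(s, 2L, cumsum)
    if (w > 1L) s <- t(apply(s, 1L, cumsum))
    out <- matrix(0, h + 1L, w + 1L)
    out[-1L, -1L] <- s
    out
  }
  list(sum = pad(channel), sumsq = pad(channel * channel))
}

rect_lookup <- function(S, r1, r2, c1, c2) {
  ## vector row/col bounds -> matrix of rectangle sums
  S[r2 + 1L, c2 + 1L, drop = FALSE] - S[r1, c2 + 1L, drop = FALSE] -
    S[r2 + 1L, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
}

#' Sliding-window mean and standard deviation
#'
#' Per-pixel statistics of the `(2r+1)^2` window (cropped at the image
#' borders) computed from integral images of the intensity and its square.
#'
#' @param channel Numeric matrix (any scale).
#' @param window_radius Window half-width in pixels.
#' @return List: `m` (mean), `s` (population standard deviation), `count`.
#' @export
window_stats <- function(channel, window_radius) {
  stop_if_empty(channel)
  r <- as.integer(window_radius)
  h <- nrow(channel); w <- ncol(channel)
  if (2L * r + 1L > h || 2L * r + 1L > w)
    stop("window larger than image", call. = FALSE)
  ii <- integral_image(channel)
  r1 <- pmax(1L, seq_len(h) - r); r2 <- pmin(h, seq_len(h) + r)
  c1 <- pmax(1L, seq_len(w) - r); c2 <- pmin(w, seq_len(w) + r)
  sums <- rect_lookup(ii$sum, r1, r2, c1, c2)
  sq <- rect_lookup(ii$sumsq, r1, r2, c1, c2)
  count <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  m <- sums / count
  s <- sqrt(pmax(sq / count - m * m, 0))
  list(m = m, s = s, count = count, sumsq = sq)
}

## Sliding-window minimum (separable, cropped borders) for Feng's M.
window_min <- function(channel, r) {
  h <- nrow(channel); w <- ncol(channel)
  rowmin <- matrix(Inf, h, w)
  for (d in -r:r) {
    sh <- matrix(Inf, h, w)
    rs <- max(1L, 1L + d):min(h, h + d)
    sh[rs, ] <- channel[rs - d, , drop = FALSE]
    rowmin <- pmin(rowmin, sh)
  }
  out <- matrix(Inf, h, w)
  for (d in -r:r) {
    sh <- matrix(Inf, h, w)
    cs <- max(1L, 1L + d):min(w, w + d)
    sh[, cs] <- rowmin[, cs - d, drop = FALSE]
    out <- pmin(out, sh)
  }
  out
}

#' Parameters for the local-thresholding baselines
#'
#' Defaults follow the published constants of each method: Bradley `k = 12`
#' (percent), Niblack `k = -0.2`, Nick `k = -0.13`, Sauvola `k = 0.1` with
#' `R = 128` gray levels. Feng's coefficients (`alpha1 = 0.12`, `gamma = 2`,
#' `k1 = 0.25`, `k2 = 0.04`) and its secondary-window factor come from the
#' method's original description; they are exposed because the method is
#' sensitive to them.
#'
#' @param method One of `"bradley"`, `"feng"`, `"niblack"`, `"nick"`,
#'   `"sauvola"`.
#' @param window_radius Primary window half-width in pixels (default 15).
#' @param bradley_k,niblack_k,nick_k,sauvola_k,sauvola_R Method constants.
#' @param feng_alpha1,feng_gamma,feng_k1,feng_k2 Feng coefficients.
#' @param feng_secondary_factor Secondary window radius =
#'   `feng_secondary_factor * window_radius` (default 2).
#' @return A `baseline_params` list.
#' @export
baseline_params <- function(method = c("bradley", "feng", "niblack", "nick",
                                       "sauvola"),
                            window_radius = 15L,
                            bradley_k = 12, niblack_k = -0.2, nick_k = -0.13,
                            sauvola_k = 0.1, sauvola_R = 128,
                            feng_alpha1 = 0.12, feng_gamma = 2,
                            feng_k1 = 0.25, feng_k2 = 0.04,
                            feng_secondary_factor = 2L) {
  method <- match.arg(method)
  window_radius <- as.integer(window_radius)
  if (window_radius < 1L)
    stop("window must cover at least 9 pixels (radius >= 1)", call. = FALSE)
  structure(list(method = method, window_radius = window_radius,
                 bradley_k = bradley_k, niblack_k = niblack_k,
                 nick_k = nick_k, sauvola_k = sauvola_k, sauvola_R = sauvola_R,
                 feng_alpha1 = feng_alpha1, feng_gamma = feng_gamma,
                 feng_k1 = feng_k1, feng_k2 = feng_k2,
                 feng_secondary_factor = as.integer(feng_secondary_factor)),
            class = "baseline_params")
}

#' Local adaptive thresholding (Bradley / Feng / Niblack / Nick / Sauvola)
#'
#' One engine, five threshold formulas over the shared sliding-window
#' statistics (intensity scale 0-255, where the published constants live):
#' \describe{
#'   \item{Bradley}{`T = m (1 - k/100)`}
#'   \item{Niblack}{`T = m + k s`}
#'   \item{Nick}{`T = m + k sqrt((sum(I^2) - m^2) / N)` over the window}
#'   \item{Sauvola}{`T = m (1 - k (1 - s/R))`}
#'   \item{Feng}{`T = (1 - a1) m + a2 (s/Rs)(m - M) + a3 M` with
#'     `a2 = k1 (s/Rs)^gamma`, `a3 = k2 (s/Rs)^gamma`, `M` the window
#'     minimum and `Rs` the standard deviation of a larger secondary window}
#' }
#' Foreground follows the dark-object convention: `mask = I < T`, so nuclei
#' (dark on a light background) come out `TRUE`; `invert` flips it.
#'
#' @param channel Single-channel matrix, either \[0,1\] (scaled internally to
#'   0-255) or already on the 0-255 scale.
#' @param params A [baseline_params()] object.
#' @param invert Flip the polarity (default `FALSE`).
#' @return Logical mask.
#' @export
local_threshold <- function(channel, params, invert = FALSE) {
  stopifnot(inherits(params, "baseline_params"))
  stop_if_empty(channel)
  if (!is.matrix(channel)) stop("channel must be a matrix", call. = FALSE)
  I <- if (max(channel) <= 1 && !isTRUE(attr(channel, "levels256")))
    channel * 255 else channel + 0  # +0 drops attributes
  r <- params$window_radius
  ws <- window_stats(I, r)
  T <- switch(params$method,
    bradley = ws$m * (1 - params$bradley_k / 100),
    niblack = ws$m + params$niblack_k * ws$s,
    nick    = ws$m + params$nick_k *
      sqrt(pmax((ws$sumsq - ws$m^2) / ws$count, 0)),
    sauvola = ws$m * (1 - params$sauvola_k * (1 - ws$s / params$sauvola_R)),
    feng = {
      r2 <- params$feng_secondary_factor * r
      r2 <- min(r2, (nrow(I) - 1L) %/% 2L, (ncol(I) - 1L) %/% 2L)  # stay inside image
      ws2 <- window_stats(I, max(r2, r))
      Rs <- ws2$s
      ratio <- ifelse(Rs > 0, ws$s / Rs, 0)
      a2 <- params$feng_k1 * ratio^params$feng_gamma
      a3 <- params$feng_k2 * ratio^params$feng_gamma
      M <- window_min(I, r)
      (1 - params$feng_alpha1) * ws$m + a2 * ratio * (ws$m - M) + a3 * M
    }
  )
  mask <- I < T
  if (invert) !mask else mask
}
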