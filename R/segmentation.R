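#' Convert RGB to 8-bit grayscale levels
#'
#' ITU-R BT.601 luminance `0.299 R + 0.587 G + 0.114 B`, then quantization to
#' the 256 levels used for histogramming: `floor(v * 255 + 0.5)` after
#' clamping to \[0,1\] (bit-exact reproducible histograms).
#'
#' @param img `h x w x 3` RGB array in \[0,1\].
#' @param weights Length-3 channel weights summing to 1.
#' @return Numeric matrix of integer levels 0..255 (attribute `levels256`).
#' @export
to_grayscale <- function(img, weights = c(0.299, 0.587, 0.114)) {
  assert_rgb(img)
  stopifnot(length(weights) == 3L)
  lum <- weights[1L] * slice_ch(img, 1L) + weights[2L] * slice_ch(img, 2L) +
    weights[3L] * slice_ch(img, 3L)
  quantize_levels(lum)
}

## Luminance without quantization (used by PSNR and edge refinement).
luminance <- function(img, weights = c(0.299, 0.587, 0.114)) {
  weights[1L] * slice_ch(img, 1L) + weights[2L] * slice_ch(img, 2L) +
    weights[3L] * slice_ch(img, 3L)
}

#' Quantize a \[0,1\] channel to 256 integer levels
#'
#' `floor(v * 255 + 0.5)` after clamping (round half up, fixed tie direction).
#'
#' @param channel Single-channel matrix in \[0,1\].
#' @return Matrix of levels 0..255 with attribute `levels256 = TRUE`.
#' @export
quantize_levels <- function(channel) {
  assert_channel(channel)
  lev <- floor(pmin(pmax(channel, 0), 1) * 255 + 0.5)
  attr(lev, "levels256") <- TRUE
  lev
}

assert_levels <- function(channel, what = "channel") {
  stop_if_empty(channel, what)
  if (!is.matrix(channel)) stop(what, " must be a matrix", call. = FALSE)
  if (isTRUE(attr(channel, "levels256"))) return(invisible(channel))
  if (any(channel != floor(channel)) || min(channel) < 0 || max(channel) > 255)
    stop(what, " must hold integer levels 0..255 (see quantize_levels)",
         call. = FALSE)
  invisible(channel)
}

#' Normalized 256-bin intensity histogram
#'
#' Returns the probabilities `p(i)` for levels `i = 0..255` together with the
#' global mean `mu_T = sum(i p(i))` and total variance
#' `sigma_T^2 = sum((i - mu_T)^2 p(i))`, the substrate of the multi-Otsu
#' criterion.
#'
#' @param channel Matrix of integer levels 0..255 (see [quantize_levels()]).
#' @return Object of class `intensity_histogram`: list with `p` (length 256),
#'   `mean`, `variance`, `n_pixels`.
#' @export
compute_histogram <- function(channel) {
  assert_levels(channel)
  counts <- tabulate(as.vector(channel) + 1L, nbins = 256L)
  n <- length(channel)
  p <- counts / n
  lv <- 0:255
  mu <- sum(lv * p)
  sigma2 <- sum((lv - mu)^2 * p)
  structure(list(p = p, mean = mu, variance = sigma2, n_pixels = n),
            class = "intensity_histogram")
}

#' Build an `intensity_histogram` from raw probabilities
#'
#' Convenience for testing and for histogram-level work without an image.
#'
#' @param p Length-256 non-negative vector; normalized to sum 1.
#' @return An `intensity_histogram`.
#' @export
histogram_from_p <- function(p) {
  stopifnot(length(p) == 256L, all(p >= 0), sum(p) > 0)
  p <- p / sum(p)
  lv <- 0:255
  mu <- sum(lv * p)
  structure(list(p = p, mean = mu, variance = sum((lv - mu)^2 * p),
                 n_pixels = NA_integer_),
            class = "intensity_histogram")
}

#' Three-class statistics at a threshold pair
#'
#' Classes are `[0, t1]`, `[t1+1, t2]`, `[t2+1, 255]`. Per class k:
#' probability `omega_k = sum p(i)`, mean `mu_k = sum(i p(i)) / omega_k`.
#' The between-class variance is `sigma_B^2 = sum omega_k (mu_k - mu_T)^2`
#' (empty classes contribute 0); the within-class variance
#' `sigma_W^2 = sum omega_k var_k` completes the decomposition
#' `sigma_B^2 + sigma_W^2 = sigma_T^2`.
#'
#' @param h An `intensity_histogram`.
#' @param t Integer vector `c(t1, t2)` with `0 <= t1 < t2 <= 254`.
#' @return List: `omega` (3), `mu` (3, 0 for empty classes), `sigma_b2`,
#'   `sigma_w2`.
#' @export
class_stats <- function(h, t) {
  stopifnot(inherits(h, "intensity_histogram"))
  t <- validate_threshold_pair(t)
  lv <- 0:255
  cls <- list(lv <= t[1L], lv > t[1L] & lv <= t[2L], lv > t[2L])
  omega <- vapply(cls, function(idx) sum(h$p[idx]), numeric(1))
  mu <- numeric(3L)
  var_k <- numeric(3L)
  for (k in 1:3) {
    if (omega[k] > 0) {
      mu[k] <- sum(lv[cls[[k]]] * h$p[cls[[k]]]) / omega[k]
      var_k[k] <- sum((lv[cls[[k]]] - mu[k])^2 * h$p[cls[[k]]]) / omega[k]
    }
  }
  sigma_b2 <- sum(omega * (mu - h$mean)^2 * (omega > 0))
  list(omega = omega, mu = mu, sigma_b2 = sigma_b2,
       sigma_w2 = sum(omega * var_k))
}

validate_threshold_pair <- function(t) {
  if (length(t) != 2L || any(t != floor(t)))
    stop("threshold pair must be two integers", call. = FALSE)
  t <- as.integer(t)
  if (t[1L] < 0L || t[1L] >= t[2L] || t[2L] > 254L)
    stop("threshold pair must satisfy 0 <= t1 < t2 <= 254", call. = FALSE)
  t
}

#' Three-class multi-Otsu threshold search
#'
#' Finds the pair `(t1, t2)` maximizing the between-class variance over all
#' admissible pairs `0 <= t1 < t2 <= 254`, using cumulative zeroth and first
#' moments so the full search is a single vectorized sweep; the result agrees
#' exactly with exhaustive enumeration. Ties are broken by the
#' lexicographically smallest `(t1, t2)`.
#'
#' @param h An `intensity_histogram` with at least 3 occupied levels.
#' @return List: `t` = `c(t1, t2)`, `sigma_b2` at the optimum.
#' @export
multi_otsu <- function(h) {
  stopifnot(inherits(h, "intensity_histogram"))
  if (sum(h$p > 0) < 3L)
    stop("histogram has fewer than 3 occupied levels; ",
         "use two-class Otsu or handle the constant image upstream",
         call. = FALSE)
  p <- h$p
  lv <- 0:255
  P <- cumsum(p)              # P[i+1] = sum p(0..i)
  Mo <- cumsum(lv * p)        # first moment
  muT <- h$mean
  ## omega/mu contributions for class [a, b]: w = P[b+1]-P[a], m = Mo[b+1]-Mo[a]
  ## term(a, b) = (m - w*muT)^2 / w  (0 when w = 0); sigma_B^2 is the sum of
  ## the three class terms since sum_k w_k (mu_k - muT)^2 expands that way.
  term <- function(w, m) ifelse(w > 0, (m - w * muT)^2 / w, 0)
  t1 <- 0:253
  t2 <- 1:254
  w1 <- P[t1 + 1L]; m1 <- Mo[t1 + 1L]
  ## matrix [t2 index, t1 index]: column-major scan = t1 ascending then t2,
  ## matching the lexicographic tie-break.
  W2 <- outer(P[t2 + 1L], w1, "-")
  M2 <- outer(Mo[t2 + 1L], m1, "-")
  w3 <- 1 - P[t2 + 1L]; m3 <- Mo[256L] - Mo[t2 + 1L]
  sig <- matrix(rep(term(w1, m1), each = length(t2)), length(t2)) +
    term(W2, M2) + matrix(rep(term(w3, m3), length(t1)), length(t2))
  sig[outer(t2, t1, "<=")] <- -Inf
  best <- which.max(sig)
  i2 <- (best - 1L) %% length(t2) + 1L
  i1 <- (best - 1L) %/% length(t2) + 1L
  list(t = c(t1[i1], t2[i2]), sigma_b2 = sig[best])
}

#' Extract the darkest-class binary mask
#'
#' Pixels with level at or below `t1` (Class 1, the darkest of the three
#' classes: the stained nuclei) become `TRUE`.
#'
#' @param channel Matrix of integer levels 0..255.
#' @param t Threshold pair `c(t1, t2)` from [multi_otsu()] (as the plain
#'   integer vector or the list returned by it).
#' @param class_index Which class to extract (1 = darkest, default; 2; 3).
#' @return Logical matrix.
#' @export
extract_class_mask <- function(channel, t, class_index = 1L) {
  assert_levels(channel)
  if (is.list(t)) t <- t$t
  t <- validate_threshold_pair(t)
  switch(as.character(class_index),
    "1" = channel <= t[1L],
    "2" = channel > t[1L] & channel <= t[2L],
    "3" = channel > t[2L],
    stop("class_index must be 1, 2 or 3", call. = FALSE)
  )
}
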