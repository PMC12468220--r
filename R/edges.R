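## Separable Gaussian blur with mirror borders (also used by the synthetic
## generator). sigma = 0 is the identity.
gaussian_blur <- function(channel, sigma) {
  if (sigma <= 0) return(channel)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  h <- nrow(channel); w <- ncol(channel)
  padded <- pad_reflect(channel, r)
  tmp <- matrix(0, h, w + 2L * r)
  for (i in seq_along(k))
    tmp <- tmp + k[i] * padded[i:(i + h - 1L), , drop = FALSE]
  out <- matrix(0, h, w)
  for (j in seq_along(k))
    out <- out + k[j] * tmp[, j:(j + w - 1L), drop = FALSE]
  out
}

sobel_gradients <- function(gray) {
  p <- pad_reflect(gray, 1L)
  h <- nrow(gray); w <- ncol(gray)
  sub <- function(dr, dc) p[(2L + dr):(h + 1L + dr), (2L + dc):(w + 1L + dc),
                            drop = FALSE]
  gx <- (sub(-1L, 1L) + 2 * sub(0L, 1L) + sub(1L, 1L)) -
        (sub(-1L, -1L) + 2 * sub(0L, -1L) + sub(1L, -1L))
  gy <- (sub(1L, -1L) + 2 * sub(1L, 0L) + sub(1L, 1L)) -
        (sub(-1L, -1L) + 2 * sub(-1L, 0L) + sub(-1L, 1L))
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

#' Sobel edge map
#'
#' Gradient magnitude from the 3x3 Sobel operators, thresholded at a fixed
#' fraction of its maximum. A constant image yields no edges.
#'
#' @param gray Single-channel matrix in \[0,1\].
#' @param threshold Fraction of the maximum gradient magnitude (default 0.25).
#' @return Logical edge mask.
#' @export
sobel_edges <- function(gray, threshold = 0.25) {
  assert_channel(gray)
  g <- sobel_gradients(gray)
  mx <- max(g$mag)
  if (mx == 0) return(matrix(FALSE, nrow(gray), ncol(gray)))
  g$mag > threshold * mx
}

#' Canny edge map
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction, and two-level hysteresis (weak edges kept
#' only when 8-connected to a strong edge).
#'
#' @param gray Single-channel matrix in \[0,1\].
#' @param sigma Smoothing sigma in pixels (default 1).
#' @param low,high Hysteresis thresholds as fractions of the maximum
#'   suppressed magnitude (defaults 0.08 and 0.2).
#' @return Logical edge mask.
#' @export
canny_edges <- function(gray, sigma = 1, low = 0.08, high = 0.2) {
  assert_channel(gray)
  g <- sobel_gradients(gaussian_blur(gray, sigma))
  mag <- g$mag
  mx <- max(mag)
  if (mx == 0) return(matrix(FALSE, nrow(gray), ncol(gray)))
  ## non-maximum suppression: direction quantized to 0/45/90/135 degrees
  ang <- atan2(g$gy, g$gx) * 180 / pi
  ang <- ang %% 180
  sector <- matrix(0L, nrow(mag), ncol(mag))
  sector[ang >= 22.5 & ang < 67.5] <- 1L
  sector[ang >= 67.5 & ang < 112.5] <- 2L
  sector[ang >= 112.5 & ang < 157.5] <- 3L
  off <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  pm <- pad_reflect(mag, 1L)
  h <- nrow(mag); w <- ncol(mag)
  nms <- matrix(FALSE, h, w)
  for (s in 0:3) {
    dr <- off[[s + 1L]][1L]; dc <- off[[s + 1L]][2L]
    fwd <- pm[(2L + dr):(h + 1L + dr), (2L + dc):(w + 1L + dc), drop = FALSE]
    bck <- pm[(2L - dr):(h + 1L - dr), (2L - dc):(w + 1L - dc), drop = FALSE]
    sel <- sector == s
    nms[sel] <- mag[sel] >= fwd[sel] & mag[sel] >= bck[sel]
  }
  strong <- nms & (mag >= high * mx)
  cand <- nms & (mag >= low * mx)
  if (!any(strong)) return(matrix(FALSE, h, w))
  lab <- label_px(cand, 8L)
  memb_map <- lab$ids
  memb_map[cand] <- lab$membership
  keep <- unique(memb_map[strong])
  matrix(memb_map %in% keep & cand, h, w)
}

#' Edge-guided mask refinement
#'
#' Detects intensity edges in the grayscale image (Canny or Sobel), dilates
#' them by a disk of radius 1, keeps only those within a 2-pixel band around
#' the current mask boundary, and unions them into the mask. Pixels farther
#' than 3 px from the original boundary are never modified.
#'
#' @param mask Logical matrix.
#' @param gray Grayscale image, either \[0,1\] or integer levels 0..255.
#' @param method `"canny"` or `"sobel"`.
#' @return Logical matrix.
#' @export
refine_edges <- function(mask, gray, method = c("canny", "sobel")) {
  method <- match.arg(method)
  assert_mask(mask)
  stop_if_empty(gray, "gray")
  if (!all(dim(gray) == dim(mask)))
    stop("gray and mask must have the same shape", call. = FALSE)
  if (max(gray) > 1) gray <- gray / 255
  edges <- switch(method, canny = canny_edges(gray), sobel = sobel_edges(gray))
  edges <- dilate_mask(edges, structuring_element("disk", 1L))
  ## boundary: mask pixels touching background + background pixels touching mask
  se1 <- structuring_element("disk", 1L)
  boundary <- (mask & !erode_mask(mask, se1)) | (dilate_mask(mask, se1) & !mask)
  band <- dilate_mask(boundary, structuring_element("disk", 2L))
  mask | (edges & band)
}
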