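#' Convert an RGB image to HSV
#'
#' Per pixel, value is the channel maximum `V = max(R, G, B)`, saturation is
#' `(V - min(R, G, B)) / V` (0 where `V = 0`), and hue follows the standard
#' hexcone sector formula, in degrees on \[0, 360). Achromatic pixels get
#' `H = 0` by convention.
#'
#' @param img `h x w x 3` RGB array with values in \[0,1\].
#' @return `h x w x 3` array with slices H (degrees), S, V.
#' @seealso [hsv_to_rgb()] for the exact inverse.
#' @export
rgb_to_hsv <- function(img) {
  assert_rgb(img)
  r <- slice_ch(img, 1L); g <- slice_ch(img, 2L); b <- slice_ch(img, 3L)
  v <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  delta <- v - mn
  s <- ifelse(v > 0, delta / v, 0)
  h <- matrix(0, nrow(v), ncol(v))
  chroma <- delta > 0
  rmax <- chroma & (r >= g) & (r >= b)
  gmax <- chroma & !rmax & (g >= b)
  bmax <- chroma & !rmax & !gmax
  h[rmax] <- ((g[rmax] - b[rmax]) / delta[rmax]) %% 6
  h[gmax] <- (b[gmax] - r[gmax]) / delta[gmax] + 2
  h[bmax] <- (r[bmax] - g[bmax]) / delta[bmax] + 4
  h <- h * 60
  out <- array(0, dim(img))
  out[, , 1L] <- h; out[, , 2L] <- s; out[, , 3L] <- v
  out
}

#' Convert an HSV image to RGB
#'
#' Uses the chroma decomposition: `C = V * S`, intensity adjustment
#' `X = C * (1 - |(H/60 mod 2) - 1|)`, brightness match `m = V - C`, then
#' assigns `(R', G', B')` by the six 60-degree hue sectors and returns
#' `(R' + m, G' + m, B' + m)`. Output stays in normalized \[0,1\]; the
#' scaling to \[0,255\] happens only at 8-bit serialization
#' ([write_image()]).
#'
#' @param img `h x w x 3` array with slices H (degrees), S and V in \[0,1\].
#'   Hue outside \[0,360) is wrapped by modulo with a warning; S or V outside
#'   \[0,1\] is an error.
#' @return `h x w x 3` RGB array in \[0,1\].
#' @export
hsv_to_rgb <- function(img) {
  stop_if_empty(img)
  if (!is_rgb_array(img)) stop("img must be an h x w x 3 HSV array", call. = FALSE)
  h <- slice_ch(img, 1L); s <- slice_ch(img, 2L); v <- slice_ch(img, 3L)
  if (min(s) < -1e-8 || max(s) > 1 + 1e-8 || min(v) < -1e-8 || max(v) > 1 + 1e-8)
    stop("S and V must lie in [0, 1]", call. = FALSE)
  if (min(h) < 0 || max(h) >= 360) {
    warning("hue outside [0, 360) wrapped by modulo")
    h <- h %% 360
  }
  chroma <- v * s
  x <- chroma * (1 - abs(((h / 60) %% 2) - 1))
  m <- v - chroma
  sector <- pmin(floor(h / 60), 5)
  rp <- gp <- bp <- matrix(0, nrow(h), ncol(h))
  s0 <- sector == 0; s1 <- sector == 1; s2 <- sector == 2
  s3 <- sector == 3; s4 <- sector == 4; s5 <- sector == 5
  rp[s0] <- chroma[s0]; gp[s0] <- x[s0]
  rp[s1] <- x[s1];      gp[s1] <- chroma[s1]
  gp[s2] <- chroma[s2]; bp[s2] <- x[s2]
  gp[s3] <- x[s3];      bp[s3] <- chroma[s3]
  rp[s4] <- x[s4];      bp[s4] <- chroma[s4]
  rp[s5] <- chroma[s5]; bp[s5] <- x[s5]
  out <- array(0, dim(img))
  out[, , 1L] <- rp + m; out[, , 2L] <- gp + m; out[, , 3L] <- bp + m
  out
}
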