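# small mask/image builders shared across tests

disk_mask <- function(h, w, cy, cx, r) {
  outer(seq_len(h), seq_len(w), function(i, j) (i - cy)^2 + (j - cx)^2 <= r^2)
}

annulus_mask <- function(h, w, cy, cx, r_out, r_in) {
  disk_mask(h, w, cy, cx, r_out) & !disk_mask(h, w, cy, cx, r_in)
}

plus_mask <- function(n = 21L, arm = 5L) {
  m <- matrix(FALSE, n, n)
  mid <- (n - arm) %/% 2L + seq_len(arm)
  m[mid, ] <- TRUE
  m[, mid] <- TRUE
  m
}

square_mask <- function(h, w, r1, r2, c1, c2) {
  m <- matrix(FALSE, h, w)
  m[r1:r2, c1:c2] <- TRUE
  m
}

random_rgb <- function(h, w) array(runif(h * w * 3), c(h, w, 3))

rgb_from_gray <- function(gray) array(rep(gray, 3L), c(dim(gray), 3L))

random_mask <- function(h, w, p = 0.5) matrix(runif(h * w) < p, h, w)
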