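# Independent reference implementations used as oracles. Deliberately naive:
# explicit loops and direct formula evaluation, sharing no code with the
# package internals.

# mirror (edge-inclusive) coordinate for naive window loops
o_reflect <- function(k, n) {
  while (k < 1 || k > n) {
    if (k < 1) k <- 1 - k
    if (k > n) k <- 2 * n + 1 - k
  }
  k
}

# quadruple-loop bilateral filter (unnormalized Gaussians, mirror borders)
o_bilateral <- function(ch, spatial_sigma, range_sigma, r) {
  h <- nrow(ch); w <- ncol(ch)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    num <- 0; den <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- o_reflect(i + di, h); jj <- o_reflect(j + dj, w)
      gs <- exp(-(di^2 + dj^2) / (2 * spatial_sigma^2))
      gr <- exp(-((ch[ii, jj] - ch[i, j])^2) / (2 * range_sigma^2))
      num <- num + ch[ii, jj] * gs * gr
      den <- den + gs * gr
    }
    out[i, j] <- num / den
  }
  out
}

# truncated spatial-Gaussian smoothing only (the range_sigma -> Inf limit)
o_gaussian_window <- function(ch, spatial_sigma, r) {
  h <- nrow(ch); w <- ncol(ch)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    num <- 0; den <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- o_reflect(i + di, h); jj <- o_reflect(j + dj, w)
      gs <- exp(-(di^2 + dj^2) / (2 * spatial_sigma^2))
      num <- num + ch[ii, jj] * gs
      den <- den + gs
    }
    out[i, j] <- num / den
  }
  out
}

# exhaustive multi-Otsu: enumerate every (t1, t2), class stats from direct
# slice sums, lexicographic tie-break. Grouped by t1 for speed; each pair's
# between-class variance is still evaluated from its own class partition.
o_multi_otsu <- function(p) {
  lv <- 0:255
  best <- c(-1, -1); best_sig <- -Inf
  muT <- sum(lv * p)
  for (t1 in 0:253) {
    w1 <- sum(p[1:(t1 + 1)])
    m1 <- sum(lv[1:(t1 + 1)] * p[1:(t1 + 1)])
    idx <- (t1 + 2):256
    cw <- cumsum(p[idx])
    cm <- cumsum(lv[idx] * p[idx])
    n2 <- length(idx) - 1L          # t2 ranges t1+1 .. 254
    w2 <- cw[1:n2]; m2 <- cm[1:n2]
    w3 <- cw[length(cw)] - w2; m3 <- cm[length(cm)] - m2
    term <- function(w, m) ifelse(w > 0, w * (m / pmax(w, .Machine$double.xmin) - muT)^2, 0)
    sig <- term(w1, m1) + term(w2, m2) + term(w3, m3)
    k <- which.max(sig)             # first max = smallest t2 for this t1
    if (sig[k] > best_sig + 1e-12) {
      best_sig <- sig[k]; best <- c(t1, t1 + k)
    }
  }
  list(t = best, sigma_b2 = best_sig)
}

# fully scalar double-loop variant (slow; used on a few histograms only)
o_multi_otsu_scalar <- function(p) {
  lv <- 0:255
  muT <- sum(lv * p)
  best <- c(-1, -1); best_sig <- -Inf
  for (t1 in 0:253) for (t2 in (t1 + 1):254) {
    sig <- 0
    for (cls in list(0:t1, (t1 + 1):t2, (t2 + 1):255)) {
      w <- sum(p[cls + 1])
      if (w > 0) {
        mu <- sum(cls * p[cls + 1]) / w
        sig <- sig + w * (mu - muT)^2
      }
    }
    if (sig > best_sig + 1e-12) { best_sig <- sig; best <- c(t1, t2) }
  }
  list(t = best, sigma_b2 = best_sig)
}

# DFS flood-fill 4-connected labeling (linear-index stack)
o_label4 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  stack <- integer(h * w)
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      nxt <- nxt + 1L
      top <- 1L
      stack[1L] <- (j - 1L) * h + i
      lab[i, j] <- nxt
      while (top > 0L) {
        pos <- stack[top]; top <- top - 1L
        pi <- (pos - 1L) %% h + 1L; pj <- (pos - 1L) %/% h + 1L
        for (d in 1:4) {
          qi <- pi + c(-1L, 1L, 0L, 0L)[d]
          qj <- pj + c(0L, 0L, -1L, 1L)[d]
          if (qi >= 1L && qi <= h && qj >= 1L && qj <= w &&
              mask[qi, qj] && lab[qi, qj] == 0L) {
            lab[qi, qj] <- nxt
            top <- top + 1L
            stack[top] <- (qj - 1L) * h + qi
          }
        }
      }
    }
  }
  lab
}

# set-operation morphology: dilation/erosion from the definition, with the
# same boundary convention as the package (outside = background for
# dilation, foreground for erosion)
o_se_offsets <- function(r, shape = "disk") {
  g <- expand.grid(dr = -r:r, dc = -r:r)
  if (shape == "disk") g <- g[g$dr^2 + g$dc^2 <= r^2, ]
  as.matrix(g)
}

o_dilate <- function(mask, off) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  fg <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(fg))) for (s in seq_len(nrow(off))) {
    r <- fg[k, 1L] + off[s, 1L]; c <- fg[k, 2L] + off[s, 2L]
    if (r >= 1L && r <= h && c >= 1L && c <= w) out[r, c] <- TRUE
  }
  out
}

o_erode <- function(mask, off) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(TRUE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    keep <- TRUE
    for (s in seq_len(nrow(off))) {
      r <- i + off[s, 1L]; c <- j + off[s, 2L]
      if (r >= 1L && r <= h && c >= 1L && c <= w && !mask[r, c]) {
        keep <- FALSE; break
      }
    }
    out[i, j] <- keep
  }
  out
}

# border flood fill: background reachable from the border (4-connected);
# unreachable background becomes foreground
o_fill_holes <- function(mask) {
  bg_lab <- o_label4(!mask)
  h <- nrow(mask); w <- ncol(mask)
  border <- unique(c(bg_lab[1L, ], bg_lab[h, ], bg_lab[, 1L], bg_lab[, w]))
  border <- border[border > 0L]
  mask | (bg_lab > 0L & !(bg_lab %in% border))
}

# naive sliding-window local thresholding, all five formulas, cropped windows
o_local_threshold <- function(I255, method, r,
                              bradley_k = 12, niblack_k = -0.2,
                              nick_k = -0.13, sauvola_k = 0.1, sauvola_R = 128,
                              feng_alpha1 = 0.12, feng_gamma = 2,
                              feng_k1 = 0.25, feng_k2 = 0.04,
                              feng_factor = 2L) {
  h <- nrow(I255); w <- ncol(I255)
  out <- matrix(FALSE, h, w)
  r2max <- min(feng_factor * r, (h - 1) %/% 2, (w - 1) %/% 2)
  r2max <- max(r2max, r)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    win <- I255[max(1, i - r):min(h, i + r), max(1, j - r):min(w, j + r)]
    n <- length(win)
    m <- sum(win) / n
    s <- sqrt(max(0, sum(win^2) / n - m^2))
    T <- switch(method,
      bradley = m * (1 - bradley_k / 100),
      niblack = m + niblack_k * s,
      nick = m + nick_k * sqrt(max(0, (sum(win^2) - m^2) / n)),
      sauvola = m * (1 - sauvola_k * (1 - s / sauvola_R)),
      feng = {
        win2 <- I255[max(1, i - r2max):min(h, i + r2max),
                     max(1, j - r2max):min(w, j + r2max)]
        n2 <- length(win2)
        m2 <- sum(win2) / n2
        Rs <- sqrt(max(0, sum(win2^2) / n2 - m2^2))
        ratio <- if (Rs > 0) s / Rs else 0
        a2 <- feng_k1 * ratio^feng_gamma
        a3 <- feng_k2 * ratio^feng_gamma
        (1 - feng_alpha1) * m + a2 * ratio * (m - min(win)) + a3 * min(win)
      })
    out[i, j] <- I255[i, j] < T
  }
  out
}
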