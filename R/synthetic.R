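#' Specification of a synthetic Pap-smear-like scene
#'
#' Describes a scene of dark elliptical nuclei wrapped in lighter cytoplasm
#' on a bright background — the three-plateau intensity structure
#' (hematoxylin-stained nuclei darkest) that three-class thresholding
#' assumes. All degradations (illumination gradient, blur, sensor noise)
#' are controllable, and identical spec + seed reproduce the scene bitwise.
#'
#' @param size Image size `c(height, width)` in pixels.
#' @param n_nuclei Number of cells.
#' @param nucleus_axes Range `c(min, max)` of nucleus semi-axes in pixels.
#' @param nucleus_intensity,nucleus_jitter Mean value-channel intensity of
#'   nuclei and its per-cell uniform jitter (defaults 0.15 +/- 0.05).
#' @param cytoplasm_intensity,cytoplasm_jitter As above for cytoplasm
#'   (defaults 0.55 +/- 0.05).
#' @param background_intensity Background value (default 0.85).
#' @param overlap_fraction In \[0,1\]: 0 forces disjoint nuclei (with a
#'   2-px guard gap); larger values let nucleus ellipses approach and
#'   overlap by relaxing the minimum center distance.
#' @param gradient Left-to-right illumination gradient amplitude
#'   (total swing, in intensity units, symmetric about the mean).
#' @param noise_sigma Additive Gaussian noise sigma (intensity units).
#' @param blur_sigma Gaussian blur sigma in pixels.
#' @param stain_hue Stain hue in degrees (default 300, purple-magenta).
#' @param cytoplasm_scale Cytoplasm semi-axes as a multiple of the nucleus
#'   semi-axes (default 2.2).
#' @param seed Integer RNG seed.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(size = c(128L, 128L), n_nuclei = 3L,
                       nucleus_axes = c(7, 14),
                       nucleus_intensity = 0.15, nucleus_jitter = 0.05,
                       cytoplasm_intensity = 0.55, cytoplasm_jitter = 0.05,
                       background_intensity = 0.85,
                       overlap_fraction = 0, gradient = 0,
                       noise_sigma = 0, blur_sigma = 0,
                       stain_hue = 300, cytoplasm_scale = 2.2, seed = 1L) {
  stopifnot(length(size) == 2L, all(size >= 16), n_nuclei >= 1,
            length(nucleus_axes) == 2L, nucleus_axes[1L] >= 2,
            nucleus_axes[2L] >= nucleus_axes[1L],
            overlap_fraction >= 0, overlap_fraction <= 1,
            gradient >= 0, gradient <= 0.3, noise_sigma >= 0, blur_sigma >= 0)
  if (!(nucleus_intensity + nucleus_jitter < cytoplasm_intensity - cytoplasm_jitter &&
        cytoplasm_intensity + cytoplasm_jitter < background_intensity))
    stop("intensities must satisfy nucleus < cytoplasm < background ",
         "(including jitter)", call. = FALSE)
  structure(list(size = as.integer(size), n_nuclei = as.integer(n_nuclei),
                 nucleus_axes = nucleus_axes,
                 nucleus_intensity = nucleus_intensity,
                 nucleus_jitter = nucleus_jitter,
                 cytoplasm_intensity = cytoplasm_intensity,
                 cytoplasm_jitter = cytoplasm_jitter,
                 background_intensity = background_intensity,
                 overlap_fraction = overlap_fraction, gradient = gradient,
                 noise_sigma = noise_sigma, blur_sigma = blur_sigma,
                 stain_hue = stain_hue, cytoplasm_scale = cytoplasm_scale,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

ellipse_mask <- function(h, w, cy, cx, a, b, theta) {
  dy <- matrix(seq_len(h) - cy, h, w)
  dx <- matrix(rep(seq_len(w) - cx, each = h), h, w)
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  (u / a)^2 + (v / b)^2 <= 1
}

#' Render a synthetic cytology scene with its ground-truth mask
#'
#' Places `n_nuclei` random ellipses (rejection sampling on the center
#' distance controls overlap), wraps each in a cytoplasm ellipse, composites
#' the three intensity plateaus, colorizes via the stain hue in HSV, then
#' applies the degradations (gradient, blur, noise) in fixed order. The
#' returned mask is the exact union of the nucleus ellipses before any
#' degradation.
#'
#' @param spec A [scene_spec()].
#' @return List: `image` (`h x w x 3` RGB in \[0,1\]), `mask` (logical),
#'   `value` (pre-colorization intensity plateaus).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_local_seed(spec$seed, {
    h <- spec$size[1L]; w <- spec$size[2L]
    amax <- spec$nucleus_axes[2L]
    margin <- ceiling(amax) + 2   # nuclei stay inside; cytoplasm may clip
    if (2 * margin >= min(h, w))
      stop("nuclei too large for the image: infeasible packing", call. = FALSE)
    cells <- list()
    for (k in seq_len(spec$n_nuclei)) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        a <- runif(1, spec$nucleus_axes[1L], spec$nucleus_axes[2L])
        b <- runif(1, spec$nucleus_axes[1L], a)
        cy <- runif(1, margin, h - margin + 1)
        cx <- runif(1, margin, w - margin + 1)
        ok <- TRUE
        for (cc in cells) {
          dmin <- (1 - spec$overlap_fraction) * (a + cc$a) + 2
          if (sqrt((cy - cc$cy)^2 + (cx - cc$cx)^2) < dmin) { ok <- FALSE; break }
        }
        if (ok) {
          cells[[k]] <- list(cy = cy, cx = cx, a = a, b = b,
                             theta = runif(1, 0, pi),
                             vn = spec$nucleus_intensity +
                               runif(1, -1, 1) * spec$nucleus_jitter,
                             vc = spec$cytoplasm_intensity +
                               runif(1, -1, 1) * spec$cytoplasm_jitter)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("infeasible packing: could not place nucleus ", k,
             " at overlap_fraction ", spec$overlap_fraction, call. = FALSE)
    }
    value <- matrix(spec$background_intensity, h, w)
    sat <- matrix(0.03, h, w)
    mask <- matrix(FALSE, h, w)
    for (cc in cells) {   # cytoplasm first so nuclei always paint on top
      cyt <- ellipse_mask(h, w, cc$cy, cc$cx, cc$a * spec$cytoplasm_scale,
                          cc$b * spec$cytoplasm_scale, cc$theta)
      value[cyt] <- cc$vc
      sat[cyt] <- 0.35
    }
    for (cc in cells) {
      nuc <- ellipse_mask(h, w, cc$cy, cc$cx, cc$a, cc$b, cc$theta)
      value[nuc] <- cc$vn
      sat[nuc] <- 0.55
      mask <- mask | nuc
    }
    hsv <- array(0, c(h, w, 3L))
    hsv[, , 1L] <- spec$stain_hue
    hsv[, , 2L] <- sat
    hsv[, , 3L] <- value
    img <- hsv_to_rgb(hsv)
    img <- degrade_impl(img, spec$gradient, spec$noise_sigma, spec$blur_sigma)
    list(image = img, mask = mask, value = value)
  })
}

degrade_impl <- function(img, gradient, noise_sigma, blur_sigma) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  if (gradient > 0) {
    t <- if (w > 1L) (seq_len(w) - 1) / (w - 1) else 0.5
    ramp <- matrix(rep(gradient * (t - 0.5), each = h), h, w)
    for (ch in 1:3) img[, , ch] <- img[, , ch] + ramp
  }
  if (blur_sigma > 0)
    for (ch in 1:3) img[, , ch] <- gaussian_blur(img[, , ch], blur_sigma)
  if (noise_sigma > 0)
    img <- img + array(rnorm(length(img), 0, noise_sigma), dim(img))
  pmin(pmax(img, 0), 1)
}

#' Degrade an image with illumination gradient, blur and noise
#'
#' Fixed order: additive left-to-right linear gradient (amplitude symmetric
#' about the mean: a constant 0.5 image under gradient 0.2 becomes a ramp
#' from 0.4 to 0.6), Gaussian blur, additive Gaussian noise; the result is
#' clamped to \[0,1\] (8-bit-style saturation). All-zero parameters return
#' the input bitwise.
#'
#' @param img `h x w x 3` RGB array in \[0,1\].
#' @param gradient,noise_sigma,blur_sigma Non-negative degradation strengths.
#' @param seed Optional seed making the noise reproducible.
#' @return Degraded RGB array.
#' @export
degrade <- function(img, gradient = 0, noise_sigma = 0, blur_sigma = 0,
                    seed = NULL) {
  assert_rgb(img)
  stopifnot(gradient >= 0, noise_sigma >= 0, blur_sigma >= 0)
  if (is.null(seed))
    degrade_impl(img, gradient, noise_sigma, blur_sigma)
  else
    with_local_seed(seed, degrade_impl(img, gradient, noise_sigma, blur_sigma))
}

#' Write a suite of synthetic fixtures spanning a difficulty grid
#'
#' Generates `n_images` paired image/mask PNGs whose scenes walk a grid of
#' overlap x noise x gradient difficulty levels, alternating between a
#' "normal" morphology (small, round nuclei) and an "abnormal" one (large,
#' eccentric nuclei), and writes a CSV manifest holding every scene
#' parameter; feeding a manifest row back to [generate_scene()] reproduces
#' its image bitwise.
#'
#' @param out_dir Output directory (created if missing).
#' @param n_images Number of image/mask pairs (`>= 1`).
#' @param seed Base seed; image i uses `seed + i`.
#' @param size Image size passed to [scene_spec()].
#' @param overlap_levels,noise_levels,gradient_levels Difficulty grid axes.
#' @return The manifest as a data frame (also written to
#'   `file.path(out_dir, "manifest.csv")`).
#' @export
make_fixture_suite <- function(out_dir, n_images, seed = 1L,
                               size = c(128L, 128L),
                               overlap_levels = c(0, 0.3),
                               noise_levels = c(0, 0.03),
                               gradient_levels = c(0, 0.15)) {
  stopifnot(n_images >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  grid <- expand.grid(overlap = overlap_levels, noise = noise_levels,
                      gradient = gradient_levels)
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    g <- grid[((i - 1L) %% nrow(grid)) + 1L, ]
    group <- if (i %% 2L == 1L) "normal" else "abnormal"
    axes <- if (group == "normal") c(6, 9) else c(10, 16)
    spec <- scene_spec(size = size, n_nuclei = 3L, nucleus_axes = axes,
                       overlap_fraction = g$overlap, noise_sigma = g$noise,
                       gradient = g$gradient, blur_sigma = 0.8,
                       seed = seed + i)
    sc <- generate_scene(spec)
    img_file <- sprintf("image_%03d.png", i)
    mask_file <- sprintf("mask_%03d.png", i)
    write_image(sc$image, file.path(out_dir, img_file))
    write_mask(sc$mask, file.path(out_dir, mask_file))
    rows[[i]] <- data.frame(
      image = img_file, mask = mask_file, group = group,
      height = spec$size[1L], width = spec$size[2L],
      n_nuclei = spec$n_nuclei,
      axis_min = axes[1L], axis_max = axes[2L],
      nucleus_intensity = spec$nucleus_intensity,
      nucleus_jitter = spec$nucleus_jitter,
      cytoplasm_intensity = spec$cytoplasm_intensity,
      cytoplasm_jitter = spec$cytoplasm_jitter,
      background_intensity = spec$background_intensity,
      overlap_fraction = spec$overlap_fraction,
      gradient = spec$gradient, noise_sigma = spec$noise_sigma,
      blur_sigma = spec$blur_sigma, stain_hue = spec$stain_hue,
      cytoplasm_scale = spec$cytoplasm_scale, seed = spec$seed,
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Rebuild a [scene_spec()] from a manifest row
#'
#' @param row One-row data frame from the manifest written by
#'   [make_fixture_suite()].
#' @return A `scene_spec`.
#' @export
spec_from_manifest <- function(row) {
  scene_spec(size = c(row$height, row$width), n_nuclei = row$n_nuclei,
             nucleus_axes = c(row$axis_min, row$axis_max),
             nucleus_intensity = row$nucleus_intensity,
             nucleus_jitter = row$nucleus_jitter,
             cytoplasm_intensity = row$cytoplasm_intensity,
             cytoplasm_jitter = row$cytoplasm_jitter,
             background_intensity = row$background_intensity,
             overlap_fraction = row$overlap_fraction, gradient = row$gradient,
             noise_sigma = row$noise_sigma, blur_sigma = row$blur_sigma,
             stain_hue = row$stain_hue, cytoplasm_scale = row$cytoplasm_scale,
             seed = row$seed)
}
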