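#' Structuring element
#'
#' A `disk` of radius r contains every integer offset with Euclidean norm
#' `<= r`; a `square` contains the full `(2r+1)^2` block.
#'
#' @param shape `"disk"` or `"square"`.
#' @param radius Integer radius `>= 1`.
#' @return A `structuring_element` with an `offsets` matrix (columns dr, dc).
#' @export
structuring_element <- function(shape = c("disk", "square"), radius = 1L) {
  shape <- match.arg(shape)
  radius <- as.integer(radius)
  if (radius < 1L) stop("radius must be >= 1", call. = FALSE)
  g <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  if (shape == "disk") g <- g[g$dr^2 + g$dc^2 <= radius^2, ]
  structure(list(shape = shape, radius = radius,
                 offsets = as.matrix(g)),
            class = "structuring_element")
}

## Shift-accumulate morphology. Dilation treats outside the image as
## background; erosion treats it as foreground, so the image border does not
## erode objects by itself and opening/closing keep their anti-extensive /
## extensive algebra on the finite domain.
shift_mask <- function(mask, dr, dc, fill) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(fill, h, w)
  rs <- max(1L, 1L + dr):min(h, h + dr)
  cs <- max(1L, 1L + dc):min(w, w + dc)
  if (length(rs) > 0L && length(cs) > 0L)
    out[rs, cs] <- mask[rs - dr, cs - dc, drop = FALSE]
  out
}

dilate_mask <- function(mask, se) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(se$offsets)))
    out <- out | shift_mask(mask, se$offsets[i, 1L], se$offsets[i, 2L], FALSE)
  out
}

erode_mask <- function(mask, se) {
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(se$offsets)))
    out <- out & shift_mask(mask, -se$offsets[i, 1L], -se$offsets[i, 2L], TRUE)
  out
}

#' Morphological opening (erosion then dilation)
#'
#' Removes objects smaller than the structuring element; anti-extensive
#' (`open(x)` is a subset of `x`) and idempotent.
#'
#' @param mask Logical matrix.
#' @param se A [structuring_element()].
#' @return Logical matrix.
#' @export
morphological_open <- function(mask, se = structuring_element("disk", 2L)) {
  assert_mask(mask)
  dilate_mask(erode_mask(mask, se), se)
}

#' Morphological closing (dilation then erosion)
#'
#' Bridges gaps narrower than the structuring element and smooths boundaries;
#' extensive (`x` is a subset of `close(x)`) and idempotent.
#'
#' @inheritParams morphological_open
#' @return Logical matrix.
#' @export
morphological_close <- function(mask, se = structuring_element("disk", 3L)) {
  assert_mask(mask)
  erode_mask(dilate_mask(mask, se), se)
}

## Pixel adjacency edge list for igraph labeling. ids: integer matrix with
## 0 for excluded pixels, 1..n consecutive over included ones.
adjacency_edges <- function(ids, connectivity = 4L) {
  h <- nrow(ids); w <- ncol(ids)
  pair <- function(a, b) {
    keep <- a > 0L & b > 0L
    cbind(a[keep], b[keep])
  }
  e <- rbind(
    pair(ids[-h, , drop = FALSE], ids[-1L, , drop = FALSE]),   # vertical
    pair(ids[, -w, drop = FALSE], ids[, -1L, drop = FALSE])    # horizontal
  )
  if (connectivity == 8L) {
    e <- rbind(e,
      pair(ids[-h, -w, drop = FALSE], ids[-1L, -1L, drop = FALSE]),
      pair(ids[-h, -1L, drop = FALSE], ids[-1L, -w, drop = FALSE]))
  }
  e
}

label_px <- function(include, connectivity = 4L) {
  n <- sum(include)
  ids <- matrix(0L, nrow(include), ncol(include))
  ids[include] <- seq_len(n)
  if (n == 0L) return(list(ids = ids, membership = integer(0), n = 0L))
  edges <- adjacency_edges(ids, connectivity)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges) > 0L) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  memb <- match(memb, unique(memb))   # deterministic: order of first pixel
  list(ids = ids, membership = memb, n = max(memb))
}

#' Label 4-connected components of a mask
#'
#' Every maximal 4-connected foreground region receives a unique label in
#' order of first appearance (column-major scan). Region areas and bounding
#' boxes are reported for noise screening.
#'
#' @param mask Logical matrix.
#' @return Object of class `component_set`: `label_map` (integer matrix, 0 =
#'   background), `areas` (pixels per label), `bbox` (n x 4 matrix rmin,
#'   rmax, cmin, cmax), `n`.
#' @export
label_components <- function(mask) {
  assert_mask(mask)
  lab <- label_px(mask, 4L)
  label_map <- lab$ids
  label_map[mask] <- lab$membership
  n <- lab$n
  areas <- if (n > 0L) tabulate(lab$membership, nbins = n) else integer(0)
  bbox <- matrix(NA_integer_, n, 4L,
                 dimnames = list(NULL, c("rmin", "rmax", "cmin", "cmax")))
  if (n > 0L) {
    rc <- which(mask, arr.ind = TRUE)
    m <- lab$membership
    bbox[, 1L] <- tapply(rc[, 1L], m, min)
    bbox[, 2L] <- tapply(rc[, 1L], m, max)
    bbox[, 3L] <- tapply(rc[, 2L], m, min)
    bbox[, 4L] <- tapply(rc[, 2L], m, max)
  }
  structure(list(label_map = label_map, areas = areas, bbox = bbox, n = n),
            class = "component_set")
}

#' Fill interior holes of a mask
#'
#' Background regions not connected to the image border become foreground;
#' existing foreground is never removed. Background connectivity defaults to
#' 4 to mirror the 4-connected foreground convention (an 8-connected variant
#' is available).
#'
#' @param mask Logical matrix.
#' @param connectivity 4 (default) or 8, for the background regions.
#' @return Logical matrix containing the input.
#' @export
fill_holes <- function(mask, connectivity = 4L) {
  assert_mask(mask)
  holes <- interior_holes(mask, connectivity)
  mask | holes$hole_mask
}

## Background components not touching the border; returns hole mask + areas.
interior_holes <- function(mask, connectivity = 4L) {
  bg <- !mask
  lab <- label_px(bg, as.integer(connectivity))
  if (lab$n == 0L)
    return(list(hole_mask = bg, areas = integer(0)))
  memb_map <- lab$ids
  memb_map[bg] <- lab$membership
  h <- nrow(mask); w <- ncol(mask)
  border_labels <- unique(c(memb_map[1L, ], memb_map[h, ],
                            memb_map[, 1L], memb_map[, w]))
  border_labels <- border_labels[border_labels > 0L]
  hole_labels <- setdiff(seq_len(lab$n), border_labels)
  hole_mask <- matrix(FALSE, h, w)
  if (length(hole_labels) > 0L)
    hole_mask[bg] <- lab$membership %in% hole_labels
  areas <- tabulate(lab$membership, nbins = lab$n)[hole_labels]
  list(hole_mask = hole_mask, areas = areas)
}

## Moore boundary tracing through pixel centers; diagonal steps count sqrt(2).
## Returns the ordered contour points (matrix r, c) of one component mask.
trace_boundary <- function(comp) {
  rc <- which(comp, arr.ind = TRUE)
  if (nrow(rc) == 1L) return(rc)
  ## start: first foreground pixel in row-major order (its west neighbor is bg)
  ord <- order(rc[, 1L], rc[, 2L])
  start <- rc[ord[1L], ]
  nb <- matrix(c(-1L, 0L, -1L, 1L, 0L, 1L, 1L, 1L,
                 1L, 0L, 1L, -1L, 0L, -1L, -1L, -1L),
               ncol = 2L, byrow = TRUE)  # N NE E SE S SW W NW (clockwise)
  inside <- function(r, c) r >= 1L && c >= 1L && r <= nrow(comp) && c <= ncol(comp)
  fg <- function(r, c) inside(r, c) && comp[r, c]
  p <- start
  back0 <- c(start[1L], start[2L] - 1L)  # west neighbor, known background
  back <- back0
  contour <- list()
  guard <- 8L * nrow(rc) + 8L
  repeat {
    contour[[length(contour) + 1L]] <- p
    ## scan the 8 neighbors clockwise, starting just after the backtrack
    d <- c(back[1L] - p[1L], back[2L] - p[2L])
    bi <- which(nb[, 1L] == d[1L] & nb[, 2L] == d[2L])
    moved <- FALSE
    for (s in 1:8) {
      k <- ((bi - 1L + s) %% 8L) + 1L
      q <- c(p[1L] + nb[k, 1L], p[2L] + nb[k, 2L])
      if (fg(q[1L], q[2L])) {
        prev_k <- ((bi - 1L + s - 1L) %% 8L) + 1L
        back <- c(p[1L] + nb[prev_k, 1L], p[2L] + nb[prev_k, 2L])
        p <- q
        moved <- TRUE
        break
      }
    }
    if (!moved) break
    ## Jacob's stopping criterion: start re-entered from the same direction
    if (all(p == start) && all(back == back0)) break
    if (length(contour) > guard) break
  }
  do.call(rbind, contour)
}

polygon_length <- function(pts, closed = TRUE) {
  if (nrow(pts) < 2L) return(0)
  d <- diff(pts)
  len <- sum(sqrt(rowSums(d^2)))
  if (closed) len <- len + sqrt(sum((pts[1L, ] - pts[nrow(pts), ])^2))
  len
}

hull_perimeter <- function(pts) {
  pts <- unique(pts)
  if (nrow(pts) < 2L) return(0)
  if (nrow(pts) == 2L) return(2 * sqrt(sum((pts[1L, ] - pts[2L, ])^2)))
  hi <- grDevices::chull(pts[, 2L], pts[, 1L])
  if (length(hi) < 3L) {   # collinear
    dmax <- max(stats::dist(pts))
    return(2 * dmax)
  }
  polygon_length(pts[hi, , drop = FALSE], closed = TRUE)
}

#' Boundary jaggedness of a mask
#'
#' Area-weighted mean, over 4-connected components, of the ratio between the
#' traced boundary length (Moore contour through pixel centers, diagonals
#' counting `sqrt(2)`) and the perimeter of the convex hull of the same
#' contour. Smooth convex shapes score near 1; ragged or branched shapes
#' score higher. The hull is the shortest enclosing curve, so the ratio never
#' drops below 1 (up to degenerate 1-2 pixel components, scored 1).
#'
#' @param mask Logical matrix with at least one foreground pixel.
#' @return Scalar `>= 1` (up to discretization).
#' @export
jaggedness <- function(mask) {
  assert_mask(mask)
  if (!any(mask)) stop("jaggedness of an empty mask is undefined", call. = FALSE)
  comps <- label_components(mask)
  ratios <- numeric(comps$n)
  for (k in seq_len(comps$n)) {
    comp <- comps$label_map == k
    contour <- trace_boundary(comp)
    per <- polygon_length(contour, closed = TRUE)
    hull <- hull_perimeter(contour)
    ratios[k] <- if (hull <= 0 || per <= 0) 1 else max(1, per / hull)
  }
  sum(ratios * comps$areas) / sum(comps$areas)
}

#' Remove components smaller than an area threshold
#'
#' Keeps exactly the 4-connected components with at least `a_min` pixels.
#'
#' @param mask Logical matrix.
#' @param a_min Minimum area in pixels (`>= 1`).
#' @return Logical matrix.
#' @export
filter_by_area <- function(mask, a_min) {
  assert_mask(mask)
  if (a_min < 1) stop("a_min must be >= 1", call. = FALSE)
  comps <- label_components(mask)
  if (comps$n == 0L) return(mask)
  keep <- which(comps$areas >= a_min)
  matrix(comps$label_map %in% keep, nrow(mask), ncol(mask))
}

#' Refinement configuration
#'
#' Decision thresholds and structuring elements for the conditional
#' post-processing pipeline.
#'
#' @param a_min Minimum component area in pixels.
#' @param se_open,se_close Structuring elements for opening / closing
#'   (defaults: disk 2 and disk 3).
#' @param jaggedness_threshold Boundary-irregularity trigger for closing
#'   (default 1.15; see [jaggedness()]).
#' @param hole_area_threshold Minimum interior-hole area (pixels) that
#'   triggers hole filling (default 10).
#' @param edge_refinement `"off"` (default), `"canny"` or `"sobel"`.
#' @param hole_connectivity Background connectivity for hole detection
#'   (4, default, or 8).
#' @return A `refinement_config` list.
#' @export
refinement_config <- function(a_min = 20L,
                              se_open = structuring_element("disk", 2L),
                              se_close = structuring_element("disk", 3L),
                              jaggedness_threshold = 1.15,
                              hole_area_threshold = 10L,
                              edge_refinement = c("off", "canny", "sobel"),
                              hole_connectivity = 4L) {
  edge_refinement <- match.arg(edge_refinement)
  if (a_min < 1) stop("a_min must be >= 1", call. = FALSE)
  structure(list(a_min = as.integer(a_min), se_open = se_open,
                 se_close = se_close,
                 jaggedness_threshold = jaggedness_threshold,
                 hole_area_threshold = as.integer(hole_area_threshold),
                 edge_refinement = edge_refinement,
                 hole_connectivity = as.integer(hole_connectivity)),
            class = "refinement_config")
}

#' Conditional morphological post-processing
#'
#' The adaptive refinement flowchart applied to a raw multi-Otsu mask:
#' \enumerate{
#'   \item if any component is smaller than `a_min`, apply morphological
#'     opening (speckle noise present);
#'   \item if any interior hole of at least `hole_area_threshold` pixels
#'     exists, fill all holes;
#'   \item if the boundary [jaggedness()] exceeds its threshold, apply
#'     morphological closing, plus optional edge refinement against the
#'     grayscale image;
#'   \item always filter components by area.
#' }
#'
#' @param mask Logical matrix (raw segmentation).
#' @param gray Grayscale image (levels 0..255 or \[0,1\]) for edge
#'   refinement; may be `NULL` when `edge_refinement = "off"`.
#' @param cfg A [refinement_config()].
#' @return List: `mask` (refined), `log` (branches fired, component counts
#'   before/after).
#' @export
postprocess <- function(mask, gray = NULL, cfg = refinement_config()) {
  assert_mask(mask)
  stopifnot(inherits(cfg, "refinement_config"))
  comps0 <- label_components(mask)
  log <- list(n_components_before = comps0$n,
              opened = FALSE, filled = FALSE, closed = FALSE,
              edge_refined = FALSE, jaggedness = NA_real_)
  out <- mask
  if (comps0$n > 0L && any(comps0$areas < cfg$a_min)) {
    out <- morphological_open(out, cfg$se_open)
    log$opened <- TRUE
  }
  holes <- interior_holes(out, cfg$hole_connectivity)
  if (length(holes$areas) > 0L && any(holes$areas >= cfg$hole_area_threshold)) {
    out <- fill_holes(out, cfg$hole_connectivity)
    log$filled <- TRUE
  }
  if (any(out)) {
    jag <- jaggedness(out)
    log$jaggedness <- jag
    if (jag > cfg$jaggedness_threshold) {
      out <- morphological_close(out, cfg$se_close)
      log$closed <- TRUE
      if (cfg$edge_refinement != "off") {
        if (is.null(gray))
          stop("edge refinement requested but no grayscale image supplied",
               call. = FALSE)
        out <- refine_edges(out, gray, cfg$edge_refinement)
        log$edge_refined <- TRUE
      }
    }
  }
  out <- if (any(out)) filter_by_area(out, cfg$a_min) else out
  if (!any(out)) warning("post-processing produced an empty mask")
  log$n_components_after <- label_components(out)$n
  list(mask = out, log = log)
}
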