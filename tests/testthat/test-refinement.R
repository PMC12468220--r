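# helper: pixels within r (chebyshev-ish disk) of the mask (tests only)
dilate_far <- function(mask, r) {
  morphological_close(mask, structuring_element("disk", r)) |
    nucleoseg:::dilate_mask(mask, structuring_element("disk", r))
}

test_that("4-connected labeling matches hand counts and the flood-fill oracle", {
  m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_equal(label_components(m)$n, 2L)   # diagonal touch does not connect
  plus <- matrix(FALSE, 3, 3); plus[2, ] <- TRUE; plus[, 2] <- TRUE
  cc <- label_components(plus)
  expect_equal(cc$n, 1L)
  expect_equal(cc$areas, 5L)
  expect_equal(label_components(matrix(FALSE, 5, 5))$n, 0L)
  set.seed(22)
  for (i in 1:20) {
    mask <- random_mask(64, 64, p = runif(1, 0.2, 0.7))
    got <- label_components(mask)
    ref <- o_label4(mask)
    expect_equal(max(ref), got$n)
    # same partition up to label names
    expect_true(all(tapply(ref[mask], got$label_map[mask],
                           function(v) length(unique(v))) == 1))
    expect_equal(sort(got$areas), sort(as.integer(tabulate(ref[ref > 0]))))
  }
})

test_that("bounding boxes frame each component", {
  m <- matrix(FALSE, 10, 10)
  m[2:4, 3:5] <- TRUE
  m[8:9, 8] <- TRUE
  cc <- label_components(m)
  expect_equal(cc$n, 2L)
  expect_equal(unname(cc$bbox[1, ]), c(2L, 4L, 3L, 5L))
  expect_equal(unname(cc$bbox[2, ]), c(8L, 9L, 8L, 8L))
})

test_that("opening and closing behave as set operations", {
  se <- structuring_element("disk", 1)
  single <- matrix(FALSE, 9, 9); single[5, 5] <- TRUE
  expect_false(any(morphological_open(single, se)))
  # a solid square survives opening by the square SE (erode 1, dilate back);
  # the disk (cross) SE clips exactly the four corners
  sq <- square_mask(13, 13, 3, 11, 3, 11)
  expect_identical(morphological_open(sq, structuring_element("square", 1)), sq)
  clipped <- morphological_open(sq, se)
  expect_identical(sq & !clipped,
                   `[<-`(matrix(FALSE, 13, 13),
                         cbind(c(3, 3, 11, 11), c(3, 11, 3, 11)), TRUE))
  # two 3-px-thick bars with a 1-px gap: closing bridges the gap
  gap <- matrix(FALSE, 7, 9)
  gap[3:5, 2:4] <- TRUE; gap[3:5, 6:8] <- TRUE
  closed <- morphological_close(gap, se)
  expect_true(closed[4, 5])
  expect_false(any(morphological_close(matrix(FALSE, 5, 5), se)))
  # against the definitional oracle on random masks
  set.seed(23)
  off <- o_se_offsets(2)
  se2 <- structuring_element("disk", 2)
  for (i in 1:5) {
    m <- random_mask(24, 24, 0.5)
    expect_identical(morphological_open(m, se2), o_dilate(o_erode(m, off), off))
    expect_identical(morphological_close(m, se2), o_erode(o_dilate(m, off), off))
  }
})

test_that("morphology is idempotent, anti-extensive/extensive, and ordered", {
  set.seed(24)
  se <- structuring_element("disk", 2)
  for (i in 1:10) {
    m <- random_mask(32, 32, runif(1, 0.3, 0.7))
    op <- morphological_open(m, se)
    cl <- morphological_close(m, se)
    expect_identical(morphological_open(op, se), op)
    expect_identical(morphological_close(cl, se), cl)
    expect_true(all(op <= m))
    expect_true(all(m <= cl))
    expect_true(all(m <= fill_holes(m)))
  }
})

test_that("hole filling solidifies interior holes only", {
  ring <- annulus_mask(21, 21, 11, 11, 8, 4)
  expect_identical(fill_holes(ring), disk_mask(21, 21, 11, 11, 8))
  sq <- square_mask(9, 9, 3, 7, 3, 7)
  expect_identical(fill_holes(sq), sq)
  # C-shape whose cavity opens to the border stays open
  cshape <- matrix(FALSE, 9, 9)
  cshape[2:8, 2:3] <- TRUE; cshape[2:3, 2:8] <- TRUE; cshape[7:8, 2:8] <- TRUE
  expect_identical(fill_holes(cshape), cshape)
  set.seed(25)
  for (i in 1:10) {
    m <- random_mask(32, 32, 0.55)
    expect_identical(fill_holes(m), o_fill_holes(m))
  }
})

test_that("hole-filling connectivity convention matters on diagonal pinches", {
  # a diagonally-pinched cavity: sealed for 4-connected background,
  # leaking for 8-connected background
  m <- matrix(FALSE, 7, 7)
  m[2, 2:5] <- TRUE; m[2:5, 2] <- TRUE; m[5, 2:4] <- TRUE; m[2:4, 5] <- TRUE
  expect_true(fill_holes(m, connectivity = 4)[3, 3] ||
              fill_holes(m, connectivity = 4)[4, 4])
  expect_identical(fill_holes(m, connectivity = 8), m)
})

test_that("jaggedness separates smooth from ragged boundaries", {
  sq <- square_mask(40, 40, 6, 35, 6, 35)
  expect_equal(jaggedness(sq), 1, tolerance = 0.02)
  disk <- matrix(FALSE, 41, 41) | disk_mask(41, 41, 21, 21, 15)
  expect_lt(jaggedness(disk), 1.12)
  expect_gt(jaggedness(plus_mask(21, 5)), 1.15)
  set.seed(26)
  for (i in 1:10) {
    m <- random_mask(20, 20, 0.5)
    if (any(m)) expect_gte(jaggedness(m), 1 - 1e-9)
  }
  expect_error(jaggedness(matrix(FALSE, 3, 3)), "empty")
})

test_that("area filtering keeps exactly the large components", {
  m <- matrix(FALSE, 20, 40)
  m[3:7, 3:12] <- TRUE               # area 50
  m[15, 20:24] <- TRUE               # area 5
  kept <- filter_by_area(m, 10)
  expect_identical(kept, square_mask(20, 40, 3, 7, 3, 12))
  expect_identical(filter_by_area(m, 1), m)
  expect_false(any(filter_by_area(m, 1000)))
  # monotone in a_min
  set.seed(27)
  r <- random_mask(30, 30, 0.5)
  prev <- filter_by_area(r, 1)
  for (a in c(3, 6, 12, 24)) {
    cur <- filter_by_area(r, a)
    expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("edge refinement is local and inert on flat images", {
  mask <- matrix(FALSE, 24, 24) | disk_mask(24, 24, 12, 12, 6)
  flat <- matrix(0.5, 24, 24)
  expect_identical(refine_edges(mask, flat, "canny"), mask)
  expect_identical(refine_edges(mask, flat, "sobel"), mask)
  # sharp dark disk in the intensity image: additions hug the boundary
  gray <- matrix(0.9, 24, 24); gray[disk_mask(24, 24, 12, 12, 6)] <- 0.1
  for (method in c("canny", "sobel")) {
    out <- refine_edges(mask, gray, method)
    far <- !dilate_far(mask, 3)
    expect_identical(out[far], mask[far])
    expect_true(all(mask <= out))
  }
  expect_error(refine_edges(mask, flat, "laplace"), "arg")
})

test_that("the conditional post-processing flowchart fires the right branches", {
  cfg <- refinement_config(a_min = 20, hole_area_threshold = 5)
  # clean mask: nothing fires, area filter is a no-op
  clean <- matrix(FALSE, 40, 40) | disk_mask(40, 40, 20, 20, 10)
  res <- postprocess(clean, NULL, cfg)
  expect_identical(res$mask, clean)
  expect_false(res$log$opened || res$log$filled || res$log$closed)
  # disk plus speckles: opening + area filter remove the speckles
  speck <- clean
  speck[2, 2] <- TRUE; speck[5, 36:37] <- TRUE; speck[36, 5] <- TRUE
  res <- postprocess(speck, NULL, cfg)
  expect_true(res$log$opened)
  expect_identical(res$mask, clean)
  # annulus with speckles: opening and filling both fire, result is solid
  ann <- annulus_mask(41, 41, 21, 21, 13, 7)
  ann[2, 2] <- TRUE
  res <- postprocess(ann, NULL, cfg)
  expect_true(res$log$opened && res$log$filled)
  expect_identical(res$mask, fill_holes(morphological_open(ann, cfg$se_open)))
  expect_equal(res$log$n_components_after, 1)
})

test_that("post-processing never reaches far from the original mask", {
  set.seed(28)
  cfg <- refinement_config(a_min = 5)
  for (i in 1:5) {
    m <- matrix(FALSE, 48, 48)
    m <- m | disk_mask(48, 48, runif(1, 15, 30), runif(1, 15, 30), 8)
    m[sample(48 * 48, 30)] <- TRUE     # speckle noise
    out <- postprocess(m, NULL, cfg)$mask
    reach <- dilate_far(m, cfg$se_close$radius + 3)
    expect_false(any(out & !reach))
  }
})

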