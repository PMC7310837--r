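test_that("feret diameters recover enclosing boxes of known shapes", {
  # axis-aligned 10x10 pixel square
  sq <- expand.grid(x = 0:9, y = 0:9)
  edge <- sq[sq$x %in% c(0, 9) | sq$y %in% c(0, 9), ]
  expect_equal(unname(feret_diameters(as.matrix(edge), pixel_grid = TRUE)),
               c(10, 10))

  # 10 x 30 rectangle rotated by 30 degrees (vertex polygon, not pixels)
  rect <- cbind(c(0, 30, 30, 0), c(0, 0, 10, 10))
  th <- 30 * pi / 180
  rot <- rect %*% rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  f <- feret_diameters(rot)
  expect_equal(unname(f), c(10, 30), tolerance = 0.01)

  # 3-pixel horizontal line: unit thickness, extent 3
  line <- cbind(0:2, c(0, 0, 0))
  expect_equal(unname(feret_diameters(line, pixel_grid = TRUE)), c(1, 3))
  expect_equal(unname(feret_diameters(line, pixel_grid = FALSE)), c(1, 2))
})

test_that("feret agrees with the rotating-projection oracle on random polygons", {
  set.seed(421)
  worst <- 0
  for (i in 1:100) {
    pts <- random_polygon(sample(6:20, 1))
    f <- feret_diameters(pts)
    worst <- max(worst, oracle_feret_disagreement(pts, unname(f)))
  }
  expect_lt(worst, 0.01)
})

test_that("feret is invariant under rotation up to discretization", {
  set.seed(7)
  pts <- random_polygon(15)
  f0 <- feret_diameters(pts)
  for (deg in c(17, 61, 133, 240)) {
    th <- deg * pi / 180
    rot <- pts %*% rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
    expect_equal(unname(feret_diameters(rot)), unname(f0), tolerance = 1e-6)
  }
})

test_that("lattice measurement matches the point-in-polygon oracle", {
  sq <- cbind(c(0, 9, 9, 0), c(0, 0, 9, 9))
  m <- measure_contour(sq)
  expect_equal(m$area_px, 100)
  expect_equal(unname(m$centroid), c(4.5, 4.5))

  ell <- cbind(c(0, 12, 12, 5, 5, 0), c(0, 0, 4, 4, 10, 10)) # L-shape
  m <- measure_contour(ell)
  expect_equal(m$area_px, oracle_polygon_lattice_area(ell))

  set.seed(11)
  for (i in 1:5) {
    poly <- random_polygon(10, r_range = c(4, 12))
    expect_equal(measure_contour(poly)$area_px,
                 oracle_polygon_lattice_area(poly))
  }
})

test_that("annulus area counts the hole and has_holes is flagged", {
  ring <- annulus_mask(12, 6)
  m <- measure_mask(ring)
  disc_area <- measure_mask(disc_mask(12))$area_px
  expect_true(m$has_holes)
  expect_equal(m$area_px, disc_area) # hole not subtracted
  expect_gt(m$area_px, sum(ring))
})

test_that("corrected center stays on the centroid for convex objects", {
  d <- disc_mask(10)
  m <- measure_mask(d)
  expect_equal(unname(m$center), unname(m$centroid))
})

test_that("corrected centers lie strictly on object material", {
  shapes <- c(
    lapply(c(3, 7, 15), disc_mask),
    lapply(c(8, 12, 20), function(r) annulus_mask(r, ceiling(r / 2))),
    lapply(c(6, 9, 12), function(o) crescent_mask(15, o)),
    list(s_curve_mask(), s_curve_mask(80, 20, 3), zigzag_mask()),
    lapply(1:40, function(i) {
      set.seed(i)
      sp <- scene_spec(height = 80, width = 80, n_particles = 0, n_fibers = 1,
                       fiber_length_range = c(25, 50),
                       fiber_width_range = c(2, 5), noise_sd = 0, seed = i)
      sc <- generate_scene(sp)
      m <- matrix(0L, 80, 80)
      m[partseg:::xy_to_rc(sc$truth[[1]]$pixels)] <- 1L
      m
    })
  )
  for (mask in shapes) {
    m <- measure_mask(mask)
    rc <- c(round(m$center[2]) + 1, round(m$center[1]) + 1)
    expect_identical(mask[rc[1], rc[2]], 1L)
  }
})

test_that("centroids in holes or outside are moved deeper inside", {
  for (mask in list(annulus_mask(12, 6), crescent_mask(15, 4),
                    crescent_mask(15, 6))) {
    m <- measure_mask(mask)
    h <- nrow(mask); w <- ncol(mask)
    pad <- matrix(0, h + 2, w + 2); pad[2:(h + 1), 2:(w + 1)] <- mask
    dm <- EBImage::distmap(pad)[2:(h + 1), 2:(w + 1)]
    depth_at <- function(xy) {
      r <- round(xy[2]) + 1; cc <- round(xy[1]) + 1
      if (r < 1 || r > h || cc < 1 || cc > w) 0 else dm[r, cc]
    }
    expect_gt(depth_at(m$center), depth_at(m$centroid))
  }
})

test_that("deepest-point tie-break is deterministic (smallest y then x)", {
  m <- matrix(1L, 5, 9) # all depths symmetric along the long axis
  c1 <- partseg:::correct_center_mask(m, centroid = NULL)
  c2 <- partseg:::correct_center_mask(m, centroid = NULL)
  expect_identical(c1, c2)
  # both maxima rows/cols: smallest y (row) then x must win
  dmax <- EBImage::distmap(rbind(0, cbind(0, m, 0), 0)[, ])[2:6, 2:10]
  ties <- which(dmax == max(dmax), arr.ind = TRUE)
  expect_equal(unname(c1), c(min(ties[ties[, 1] == min(ties[, 1]), 2]) - 1,
                             min(ties[, 1]) - 1))
})

test_that("the fiber rule matches its defining inequalities and is scale invariant", {
  expect_equal(classify_shape(10, 30, 290), "fiber")      # ratio 3 > 2
  expect_equal(classify_shape(10, 10, 78.5), "particle")  # disc
  expect_equal(classify_shape(30, 30, 150), "fiber")      # thin ring, box fill 6
  expect_error(classify_shape(5, 10, 0), "unmeasurable")

  set.seed(5)
  for (i in 1:50) {
    fmin <- runif(1, 1, 50); fmax <- fmin * runif(1, 1, 5)
    area <- runif(1, 0.2, 1) * fmin * fmax
    expected <- if (fmax / fmin > 2 || fmin * fmax / area > 4) "fiber" else "particle"
    expect_equal(classify_shape(fmin, fmax, area), expected)
    s <- runif(1, 0.1, 20) # scaling leaves the class unchanged
    expect_equal(classify_shape(fmin * s, fmax * s, area * s^2), expected)
  }
})

test_that("contour-level correct_center matches the documented contract", {
  sq <- cbind(c(0, 9, 9, 0), c(0, 0, 9, 9))
  expect_equal(unname(correct_center(sq)), c(4.5, 4.5))
  expect_error(correct_center(cbind(c(0, 0.2, 0.2), c(0, 0, 0.2)) + 0.4),
               "unmeasurable")
})
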