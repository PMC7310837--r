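# Morphological descriptors: Feret diameters via the minimal enclosing
# rotated box, lattice area and centroid, the corrected measurement
# center, and the particle/fiber classification rule.

#' Feret diameters of a contour
#'
#' The Feret diameters are defined as the side lengths of the smallest
#' (minimum-area) rotated rectangle enclosing the contour: the shorter
#' side is `feret_min`, the longer `feret_max`. The optimal rectangle has
#' a side collinear with an edge of the convex hull, so the search is
#' exact over hull edges. Note this is the enclosing-box definition used
#' for sizing measurement targets, not the classical directional Feret
#' extremes; the classical maximum caliper diameter can exceed the box's
#' long side for some shapes.
#'
#' @param contour Numeric n x 2 matrix of (x, y) vertices of a closed
#'   polygon (closing vertex optional).
#' @param pixel_grid If `TRUE`, each vertex is treated as the center of a
#'   unit pixel and expanded to its four corners before the box is fitted,
#'   so that e.g. a straight line of 3 pixels measures 1 x 3 rather than
#'   0 x 2.
#' @return Numeric vector `c(feret_min, feret_max)` in pixels.
#' @export
feret_diameters <- function(contour, pixel_grid = FALSE) {
  pts <- as.matrix(contour)[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  if (pixel_grid) {
    pts <- rbind(
      pts + rep(c(-0.5, -0.5), each = nrow(pts)),
      pts + rep(c(-0.5, +0.5), each = nrow(pts)),
      pts + rep(c(+0.5, -0.5), each = nrow(pts)),
      pts + rep(c(+0.5, +0.5), each = nrow(pts))
    )
  }
  pts <- unique(pts)
  if (nrow(pts) == 1L) return(c(feret_min = 1, feret_max = 1))
  hull <- tryCatch(grDevices::chull(pts[, 1], pts[, 2]), error = function(e) NULL)
  if (is.null(hull) || length(hull) < 3L) {
    # degenerate (collinear) contour: unit thickness, extent as length
    d <- as.matrix(stats::dist(pts))
    return(c(feret_min = 1, feret_max = max(d)))
  }
  hp <- pts[hull, , drop = FALSE]
  nh <- nrow(hp)
  edges <- hp[c(2:nh, 1), ] - hp
  len <- sqrt(rowSums(edges^2))
  keep <- len > 0
  edges <- edges[keep, , drop = FALSE] / len[keep]
  best <- c(Inf, Inf, Inf) # area, short side, long side
  for (i in seq_len(nrow(edges))) {
    u <- edges[i, ]
    v <- c(-u[2], u[1])
    pu <- hp %*% u
    pv <- hp %*% v
    a <- max(pu) - min(pu)
    b <- max(pv) - min(pv)
    if (a * b < best[1]) best <- c(a * b, min(a, b), max(a, b))
  }
  c(feret_min = best[2], feret_max = best[3])
}

# TRUE for query points lying on the boundary of the polygon (within eps).
points_on_polygon <- function(pts, poly, eps = 1e-9) {
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  on <- rep(FALSE, nrow(pts))
  for (i in seq_len(n)) {
    ex <- b[i, 1] - a[i, 1]; ey <- b[i, 2] - a[i, 2]
    L2 <- ex^2 + ey^2
    if (L2 < eps) next
    px <- pts[, 1] - a[i, 1]; py <- pts[, 2] - a[i, 2]
    t <- (px * ex + py * ey) / L2
    d2 <- (px - t * ex)^2 + (py - t * ey)^2
    on <- on | (t >= -eps & t <= 1 + eps & d2 <= eps)
  }
  on
}

#' Measure a polygonal contour on the pixel lattice
#'
#' Area is the count of lattice pixels inside or on the polygon; the
#' centroid is the arithmetic mean of those pixel coordinates. Holes are
#' not subtracted: a contour is an outer boundary and encloses its full
#' disc.
#'
#' @param contour Numeric n x 2 matrix of (x, y) vertices.
#' @return List with `area_px`, `centroid` (x, y) and `pixels` (m x 2
#'   matrix of enclosed lattice points).
#' @export
measure_contour <- function(contour) {
  poly <- as.matrix(contour)[, 1:2, drop = FALSE]
  storage.mode(poly) <- "double"
  if (nrow(poly) > 1 && all(poly[1, ] == poly[nrow(poly), ]))
    poly <- poly[-nrow(poly), , drop = FALSE]
  xs <- seq(floor(min(poly[, 1])), ceiling(max(poly[, 1])))
  ys <- seq(floor(min(poly[, 2])), ceiling(max(poly[, 2])))
  grid <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  closed <- rbind(poly, poly[1, ])
  inside <- mgcv::in.out(closed, grid)
  inside <- inside | points_on_polygon(grid, poly)
  px <- grid[inside, , drop = FALSE]
  colnames(px) <- c("x", "y")
  list(area_px = nrow(px),
       centroid = c(x = mean(px[, 1]), y = mean(px[, 2])),
       pixels = px)
}

#' Classify an object as particle or fiber
#'
#' An object is a fiber if its Feret aspect ratio exceeds 2.0 or if the
#' product of its Feret diameters exceeds 4.0 times its area (a thin,
#' possibly curved or ring-shaped object fills little of its enclosing
#' box); otherwise it is a particle. Either criterion suffices, so curled
#' fibers whose enclosing box is nearly square are still caught by the
#' box-fill test.
#'
#' @param feret_min,feret_max Feret diameters in pixels.
#' @param area_px Object area in pixels.
#' @param ratio_threshold,boxfill_threshold Decision thresholds; the
#'   defaults (2.0 and 4.0) are the calibrated values and rarely need
#'   changing.
#' @return `"particle"` or `"fiber"`.
#' @export
classify_shape <- function(feret_min, feret_max, area_px,
                           ratio_threshold = 2.0, boxfill_threshold = 4.0) {
  if (is.na(area_px) || area_px <= 0) stop("unmeasurable object", call. = FALSE)
  if (feret_max / feret_min > ratio_threshold ||
      (feret_min * feret_max) / area_px > boxfill_threshold) "fiber"
  else "particle"
}

# Deepest-interior-point correction on a material mask (0/1 matrix whose
# 1-pixels are the object material, i.e. filled minus holes).  Returns
# 0-based (x, y).  The centroid is kept when it sits on material at depth
# >= d_min; otherwise the global maximum of the interior
# distance-to-boundary field is returned, ties broken by smallest (y, x).
correct_center_mask <- function(material, centroid = NULL, d_min = 2) {
  if (sum(material) < 1) stop("unmeasurable object", call. = FALSE)
  h <- nrow(material); w <- ncol(material)
  padded <- matrix(0, h + 2, w + 2)
  padded[2:(h + 1), 2:(w + 1)] <- material
  dm <- EBImage::distmap(padded)[2:(h + 1), 2:(w + 1), drop = FALSE]
  if (!is.null(centroid)) {
    r <- round(centroid[2]) + 1
    cc <- round(centroid[1]) + 1
    if (r >= 1 && r <= h && cc >= 1 && cc <= w &&
        material[r, cc] > 0 && dm[r, cc] >= d_min)
      return(c(x = unname(centroid[1]), y = unname(centroid[2])))
  }
  best <- which(dm == max(dm))
  rows <- ((best - 1) %% h) + 1
  cols <- ((best - 1) %/% h) + 1
  ord <- order(rows, cols)[1] # smallest y, then x
  c(x = cols[ord] - 1, y = rows[ord] - 1)
}

#' Correct a measurement center to lie inside the object
#'
#' The centroid of a contour can fall outside the object (bow-shaped
#' fibers) or inside a hole (ring-shaped objects); a spectroscopy laser
#' aimed there would miss the material. If the centroid lies on material
#' and at depth of at least `d_min` pixels from the boundary it is
#' returned unchanged; otherwise the interior point furthest from the
#' object boundary (the argmax of the interior distance transform) is
#' returned, with ties broken by smallest y then x for determinism.
#'
#' @param contour Numeric n x 2 matrix of (x, y) vertices of the outer
#'   boundary.
#' @param centroid Optional precomputed centroid; computed from the
#'   contour when missing.
#' @param d_min Minimum acceptable depth (pixels) for keeping the
#'   centroid; default 2, a laser-spot-scale safety margin.
#' @return Numeric `c(x, y)`, always strictly inside the filled contour.
#' @export
correct_center <- function(contour, centroid = NULL, d_min = 2) {
  m <- measure_contour(contour)
  if (m$area_px < 1) stop("unmeasurable object", call. = FALSE)
  if (is.null(centroid)) centroid <- m$centroid
  x0 <- min(m$pixels[, 1]); y0 <- min(m$pixels[, 2])
  h <- max(m$pixels[, 2]) - y0 + 1
  w <- max(m$pixels[, 1]) - x0 + 1
  material <- matrix(0L, h, w)
  material[cbind(m$pixels[, 2] - y0 + 1, m$pixels[, 1] - x0 + 1)] <- 1L
  ctr <- correct_center_mask(material,
                             centroid = c(centroid[1] - x0, centroid[2] - y0),
                             d_min = d_min)
  c(x = unname(ctr[1]) + x0, y = unname(ctr[2]) + y0)
}

# Full measurement of one connected component.
#   raw_local : 0/1 matrix of the component's own foreground pixels
#               (holes absent), cropped to its bounding box
#   offset_rc : 1-based (row, col) of the bounding box top-left in the
#               full image
#   h, w      : full image size, for the border flag
# Returns a detection-shaped list (without source_pass).
measure_component <- function(raw_local, offset_rc, h = NULL, w = NULL) {
  filled <- EBImage::fillHull(raw_local)
  area <- sum(filled)
  has_holes <- area > sum(raw_local)
  idx <- which(filled > 0)
  lr <- ((idx - 1) %% nrow(filled)) + 1
  lc <- ((idx - 1) %/% nrow(filled)) + 1
  # global 0-based coordinates
  gx <- lc + offset_rc[2] - 2
  gy <- lr + offset_rc[1] - 2
  pixels <- cbind(x = gx, y = gy)
  centroid <- c(x = mean(gx), y = mean(gy))

  oc <- EBImage::ocontour(filled)[[1]]
  contour <- cbind(x = oc[, 2] + offset_rc[2] - 1, y = oc[, 1] + offset_rc[1] - 1)

  fer <- feret_diameters(contour, pixel_grid = TRUE)
  ctr_local <- correct_center_mask(
    raw_local,
    centroid = c(centroid[1] - (offset_rc[2] - 1), centroid[2] - (offset_rc[1] - 1))
  )
  center <- c(x = unname(ctr_local[1]) + offset_rc[2] - 1,
              y = unname(ctr_local[2]) + offset_rc[1] - 1)
  on_border <- if (is.null(h) || is.null(w)) FALSE else
    min(gy) == 0 || min(gx) == 0 || max(gy) == h - 1 || max(gx) == w - 1

  list(contour = contour,
       pixels = pixels,
       center = center,
       centroid = centroid,
       area_px = area,
       feret_min_px = unname(fer[1]),
       feret_max_px = unname(fer[2]),
       object_class = classify_shape(fer[1], fer[2], area),
       has_holes = has_holes,
       on_border = on_border)
}
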