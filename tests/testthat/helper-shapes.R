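# Shared fixtures and independent oracles. Everything is built in code;
# no binary fixtures are stored.

# ---- independent oracles ---------------------------------------------------

# Rotating-projection brute force for the minimum-area enclosing box:
# scan box orientations on a fine angular grid and keep the side pair of
# the smallest-area box. Independent of the hull-edge search used by
# feret_diameters().
oracle_feret <- function(pts, step_deg = 0.5) {
  angles <- seq(0, 90 - step_deg, by = step_deg) * pi / 180
  best <- c(Inf, NA, NA)
  for (a in angles) {
    u <- c(cos(a), sin(a)); v <- c(-sin(a), cos(a))
    pu <- pts %*% u; pv <- pts %*% v
    wx <- max(pu) - min(pu); wy <- max(pv) - min(pv)
    if (wx * wy < best[1]) best <- c(wx * wy, min(wx, wy), max(wx, wy))
  }
  c(best[2], best[3])
}

# Relative disagreement between a claimed enclosing-box side pair and the
# rotating-projection scan: the claimed box must (a) be no larger in area
# than any scanned box and (b) be realized, within tolerance, at some
# scanned orientation.  (Near-square shapes can have two near-tied
# minima with different aspect, so comparing against the scan's single
# best angle alone is ill-posed.)
oracle_feret_disagreement <- function(pts, sides, step_deg = 0.5) {
  angles <- seq(0, 90 - step_deg, by = step_deg) * pi / 180
  min_area <- Inf
  best_match <- Inf
  for (a in angles) {
    u <- c(cos(a), sin(a)); v <- c(-sin(a), cos(a))
    pu <- pts %*% u; pv <- pts %*% v
    wx <- max(pu) - min(pu); wy <- max(pv) - min(pv)
    min_area <- min(min_area, wx * wy)
    rel <- max(abs(c(min(wx, wy), max(wx, wy)) - sides) / sides)
    best_match <- min(best_match, rel)
  }
  area_excess <- max(0, (prod(sides) - min_area) / min_area)
  max(best_match, area_excess)
}

# Per-point even-odd ray casting, written independently of mgcv::in.out.
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    on_seg <- {
      cross <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
      within <- px >= min(xi, xj) - 1e-9 && px <= max(xi, xj) + 1e-9 &&
        py >= min(yi, yj) - 1e-9 && py <= max(yi, yj) + 1e-9
      abs(cross) < 1e-9 && within
    }
    if (on_seg) return(TRUE)
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) inside <- !inside
    j <- i
  }
  inside
}

oracle_polygon_lattice_area <- function(poly) {
  xs <- seq(floor(min(poly[, 1])), ceiling(max(poly[, 1])))
  ys <- seq(floor(min(poly[, 2])), ceiling(max(poly[, 2])))
  cnt <- 0L
  for (x in xs) for (y in ys)
    if (oracle_point_in_polygon(x, y, poly)) cnt <- cnt + 1L
  cnt
}

# Exhaustive Otsu: try all 256 thresholds, maximize between-class
# variance directly from first principles.
oracle_otsu <- function(gray) {
  g <- floor(as.vector(gray))
  best_t <- 0L; best_v <- -Inf
  for (t in 0:255) {
    lo <- g[g <= t]; hi <- g[g > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(g); w1 <- 1 - w0
    v <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (v > best_v) { best_v <- v; best_t <- t }
  }
  best_t
}

# Per-pixel Gaussian-weighted neighborhood mean with edge replication,
# computed by direct summation (no convolution library).
oracle_local_mean <- function(gray, block) {
  r <- (block - 1) / 2
  sigma <- 0.3 * ((block - 1) * 0.5 - 1) + 0.8
  g1 <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- outer(g1, g1); k <- k / sum(k)
  h <- nrow(gray); w <- ncol(gray)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      ri <- pmin(pmax(i + seq(-r, r), 1), h)
      cj <- pmin(pmax(j + seq(-r, r), 1), w)
      out[i, j] <- sum(k * gray[ri, cj])
    }
  }
  out
}

# ---- shape builders --------------------------------------------------------

disc_mask <- function(r, pad = 2) {
  n <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  m <- outer(seq_len(n), seq_len(n),
             function(i, j) ((i - ctr)^2 + (j - ctr)^2 <= r^2) * 1L)
  m
}

annulus_mask <- function(r_out, r_in, pad = 2) {
  n <- 2 * (r_out + pad) + 1
  ctr <- r_out + pad + 1
  outer(seq_len(n), seq_len(n), function(i, j) {
    d2 <- (i - ctr)^2 + (j - ctr)^2
    (d2 <= r_out^2 & d2 >= r_in^2) * 1L
  })
}

crescent_mask <- function(r = 15, offset = 8, pad = 2) {
  n <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  outer(seq_len(n), seq_len(n), function(i, j) {
    d2 <- (i - ctr)^2 + (j - ctr)^2
    d2b <- (i - ctr)^2 + (j - ctr - offset)^2
    (d2 <= r^2 & d2b > r^2) * 1L
  })
}

s_curve_mask <- function(len = 60, amp = 12, width = 4) {
  h <- 2 * amp + width + 8
  m <- matrix(0L, h, len + 8)
  t <- seq(0, 1, length.out = 400)
  cx <- 4 + t * len
  cy <- amp + width / 2 + 4 + amp * sin(2 * pi * t)
  hw <- width / 2
  for (k in seq_along(t)) {
    ri <- round(cy[k] + seq(-hw, hw))
    ci <- round(cx[k] + seq(-hw, hw))
    ri <- ri[ri >= 1 & ri <= h]; ci <- ci[ci >= 1 & ci <= ncol(m)]
    m[ri, ci] <- 1L
  }
  m
}

zigzag_mask <- function(n_seg = 5, seg = 10) {
  h <- seg + 4; w <- n_seg * seg + 4
  m <- matrix(0L, h, w)
  x <- 2; y <- 2; dy <- 1
  for (s in seq_len(n_seg)) {
    for (k in seq_len(seg)) {
      m[y, x] <- 1L
      x <- x + 1; y <- y + dy
      if (y >= h - 1 || y <= 2) dy <- -dy
    }
  }
  m
}

# Random simple-ish polygon: star-shaped around the origin (radially
# monotone so never self-intersecting), optionally concave.
random_polygon <- function(n_vertices = 12, r_range = c(5, 30)) {
  ang <- sort(runif(n_vertices, 0, 2 * pi))
  rad <- runif(n_vertices, r_range[1], r_range[2])
  cbind(rad * cos(ang), rad * sin(ang))
}

# Detection-shaped object for a filled axis-aligned square, for match
# bookkeeping tests that need no image pipeline.
square_object <- function(x0, y0, side, source_pass = "large") {
  xs <- x0 + seq_len(side) - 1
  ys <- y0 + seq_len(side) - 1
  px <- cbind(x = rep(xs, times = side), y = rep(ys, each = side))
  list(contour = cbind(x = c(xs[1], xs[side], xs[side], xs[1]),
                       y = c(ys[1], ys[1], ys[side], ys[side])),
       pixels = px,
       center = c(x = mean(xs), y = mean(ys)),
       centroid = c(x = mean(xs), y = mean(ys)),
       area_px = side^2,
       feret_min_px = side, feret_max_px = side,
       object_class = "particle", source_pass = source_pass,
       has_holes = FALSE, on_border = FALSE)
}

# Measure a binary mask through the package's component measurement.
measure_mask <- function(mask) {
  partseg:::measure_component(mask, c(1L, 1L), h = nrow(mask), w = ncol(mask))
}

# Gray image (0..255) from a mask: objects bright on dark background.
mask_to_gray <- function(mask, fg = 200, bg = 30) {
  m <- mask * (fg - bg) + bg
  storage.mode(m) <- "double"
  m
}

gray_to_color <- function(gray) {
  array(rep(gray, 3), dim = c(nrow(gray), ncol(gray), 3))
}
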