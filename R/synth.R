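# Seeded synthetic microscopy-like scenes with exact ground truth:
# bright convex blobs (particles) and curved constant-width strokes
# (fibers) on a dark background with a smooth illumination gradient and
# pixel noise. Used to exercise and test every other module without
# external image data.

#' Specify a synthetic scene
#'
#' The generator emulates the geometry and radiometry that make particle
#' detection hard in practice: a dark background whose brightness drifts
#' smoothly across the field of view (inhomogeneous illumination), pixel
#' noise, and bright objects of both compact and elongated shape. Object
#' intensities are drawn from `object_intensity_range` but always raised
#' to at least `min_contrast` above the local background at the object's
#' position, so every object is locally detectable by construction.
#'
#' @param height,width Canvas size in pixels.
#' @param n_particles,n_fibers Object counts.
#' @param particle_radius_range Semi-major axis range in pixels; the
#'   minor axis is 0.6-1.0 of the major.
#' @param fiber_length_range,fiber_width_range Fiber chord length and
#'   stroke width ranges in pixels. Fibers are constant-width quadratic
#'   Bezier strokes (the simplest family producing bow shapes).
#' @param object_intensity_range Intensity range for objects, in
#'   \[0, 255\].
#' @param background_base Dark background level.
#' @param gradient_amplitude Peak-to-base amplitude of the illumination
#'   ramp added to the background.
#' @param gradient_type `"linear"` (random direction) or `"radial"`
#'   (bright spot at a random center).
#' @param noise_sd Standard deviation of additive Gaussian pixel noise
#'   (clipped to \[0, 255\]).
#' @param min_contrast Minimum intensity excess of an object over the
#'   local background.
#' @param object_color `"white"` renders objects in all channels
#'   (darkfield/SEM-like); `"red"`, `"green"` or `"blue"` renders them in
#'   one channel only (fluorescence-like).
#' @param overlap_allowed If `FALSE` (default), objects are separated by
#'   at least 3 px; if `TRUE`, objects may touch or overlap, producing
#'   agglomerate scenes for negative tests.
#' @param seed Integer seed; the same spec is always rendered
#'   bit-identically.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(height = 320, width = 320,
                       n_particles = 8, n_fibers = 3,
                       particle_radius_range = c(5, 15),
                       fiber_length_range = c(40, 90),
                       fiber_width_range = c(4, 7),
                       object_intensity_range = c(150, 220),
                       background_base = 40,
                       gradient_amplitude = 60,
                       gradient_type = "linear",
                       noise_sd = 6,
                       min_contrast = 40,
                       object_color = "white",
                       overlap_allowed = FALSE,
                       seed = 1L) {
  spec <- list(height = height, width = width,
               n_particles = n_particles, n_fibers = n_fibers,
               particle_radius_range = particle_radius_range,
               fiber_length_range = fiber_length_range,
               fiber_width_range = fiber_width_range,
               object_intensity_range = object_intensity_range,
               background_base = background_base,
               gradient_amplitude = gradient_amplitude,
               gradient_type = match.arg(gradient_type, c("linear", "radial")),
               noise_sd = noise_sd,
               min_contrast = min_contrast,
               object_color = match.arg(object_color,
                                        c("white", "red", "green", "blue")),
               overlap_allowed = isTRUE(overlap_allowed),
               seed = as.integer(seed))
  with(spec, {
    stopifnot(height >= 16, width >= 16, n_particles >= 0, n_fibers >= 0,
              noise_sd >= 0, gradient_amplitude >= 0, min_contrast > 0)
    if (object_intensity_range[1] < 0 || object_intensity_range[2] > 255 ||
        background_base < 0 ||
        background_base + gradient_amplitude > 255)
      stop("intensity settings must stay within [0, 255]", call. = FALSE)
    if ((n_particles > 0 && 2 * particle_radius_range[2] > min(height, width)) ||
        (n_fibers > 0 && fiber_length_range[2] > min(height, width)))
      stop("objects too large for the canvas", call. = FALSE)
  })
  class(spec) <- "scene_spec"
  spec
}

# Pixel mask (local matrix + 1-based global bbox offset) of one ellipse.
ellipse_mask <- function(cx, cy, a, b, theta) {
  r <- ceiling(max(a, b)) + 1L
  xs <- seq(floor(cx) - r, ceiling(cx) + r)
  ys <- seq(floor(cy) - r, ceiling(cy) + r)
  dx <- outer(rep(1, length(ys)), xs) - cx
  dy <- outer(ys, rep(1, length(xs))) - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  m <- ((u / a)^2 + (v / b)^2 <= 1) * 1L
  list(mask = m, row0 = ys[1] + 1L, col0 = xs[1] + 1L) # 1-based offsets
}

# Pixel mask of a constant-width quadratic Bezier stroke.
bezier_mask <- function(p0, p1, p2, width_px) {
  t <- seq(0, 1, length.out = 200)
  bx <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1]
  by <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2]
  hw <- width_px / 2
  xs <- seq(floor(min(bx) - hw) - 1, ceiling(max(bx) + hw) + 1)
  ys <- seq(floor(min(by) - hw) - 1, ceiling(max(by) + hw) + 1)
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  d2 <- matrix(Inf, length(gx), 1)
  for (k in seq_along(t)) # min distance to the sampled centerline
    d2 <- pmin(d2, (gx - bx[k])^2 + (gy - by[k])^2)
  m <- matrix(as.integer(d2 <= hw^2), nrow = length(ys), ncol = length(xs),
              byrow = TRUE)
  list(mask = m, row0 = ys[1] + 1L, col0 = xs[1] + 1L)
}

#' Render a synthetic scene with exact ground truth
#'
#' Draws the scene described by a [scene_spec()] and measures every
#' rendered object mask with the same morphology definitions used for
#' detections (filled area, enclosing-box Feret diameters, corrected
#' center, particle/fiber class). Also produces a red-annotated copy
#' (objects overdrawn in saturated red) for exercising
#' [extract_ground_truth()].
#'
#' @param spec A `scene_spec` object.
#' @return List with `image` (color array), `truth` (list of
#'   ground-truth objects), `annotated` (color array) and `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$height; w <- spec$width
  with_seed(spec$seed, {
    xg <- outer(rep(1, h), seq_len(w) - 1) / max(1, w - 1)
    yg <- outer(seq_len(h) - 1, rep(1, w)) / max(1, h - 1)
    if (spec$gradient_type == "linear") {
      phi <- runif(1, 0, 2 * pi)
      proj <- cos(phi) * xg + sin(phi) * yg
      proj <- (proj - min(proj)) / max(1e-12, diff(range(proj)))
      bg <- spec$background_base + spec$gradient_amplitude * proj
    } else {
      cx <- runif(1); cy <- runif(1)
      rr <- sqrt((xg - cx)^2 + (yg - cy)^2)
      bg <- spec$background_base +
        spec$gradient_amplitude * (1 - rr / max(rr))
    }

    occupancy <- matrix(FALSE, h, w)
    sep_brush <- EBImage::makeBrush(7, shape = "disc") # >= 3 px separation
    masks <- list()
    place <- function(make_candidate) {
      for (try in 1:200) {
        cand <- make_candidate()
        m <- cand$mask
        rows <- cand$row0 + seq_len(nrow(m)) - 1L
        cols <- cand$col0 + seq_len(ncol(m)) - 1L
        if (min(rows) < 3 || min(cols) < 3 || max(rows) > h - 2 ||
            max(cols) > w - 2 || sum(m) < 1) next
        if (!spec$overlap_allowed) {
          pad <- matrix(0L, nrow(m) + 6L, ncol(m) + 6L)
          pad[4:(nrow(m) + 3L), 4:(ncol(m) + 3L)] <- m
          grown <- EBImage::dilate(pad, sep_brush)
          pr <- (cand$row0 - 3L):(cand$row0 + nrow(m) + 2L)
          pc <- (cand$col0 - 3L):(cand$col0 + ncol(m) + 2L)
          kr <- pr >= 1 & pr <= h
          kc <- pc >= 1 & pc <= w
          if (any(occupancy[pr[kr], pc[kc]] & (grown[kr, kc] > 0))) next
        }
        occupancy[rows, cols] <<- occupancy[rows, cols] | (m > 0)
        return(cand)
      }
      stop("cannot place objects", call. = FALSE)
    }

    for (i in seq_len(spec$n_particles)) {
      masks[[length(masks) + 1L]] <- place(function() {
        a <- runif(1, spec$particle_radius_range[1], spec$particle_radius_range[2])
        b <- a * runif(1, 0.6, 1)
        ellipse_mask(runif(1, 2, w - 3), runif(1, 2, h - 3), a, b,
                     runif(1, 0, pi))
      })
    }
    for (i in seq_len(spec$n_fibers)) {
      masks[[length(masks) + 1L]] <- place(function() {
        L <- runif(1, spec$fiber_length_range[1], spec$fiber_length_range[2])
        wid <- runif(1, spec$fiber_width_range[1], spec$fiber_width_range[2])
        ang <- runif(1, 0, 2 * pi)
        p0 <- c(runif(1, 2, w - 3), runif(1, 2, h - 3))
        p2 <- p0 + L * c(cos(ang), sin(ang))
        perp <- c(-sin(ang), cos(ang))
        p1 <- (p0 + p2) / 2 + perp * L * runif(1, 0.1, 0.35) *
          sample(c(-1, 1), 1)
        bezier_mask(p0, p1, p2, wid)
      })
    }

    gray <- bg
    for (cand in masks) {
      ix <- which(cand$mask > 0)
      rows <- cand$row0 + ((ix - 1L) %% nrow(cand$mask))
      cols <- cand$col0 + ((ix - 1L) %/% nrow(cand$mask))
      ctr_r <- round(mean(rows)); ctr_c <- round(mean(cols))
      inten <- runif(1, spec$object_intensity_range[1],
                     spec$object_intensity_range[2])
      inten <- min(255, max(inten, bg[ctr_r, ctr_c] + spec$min_contrast))
      gray[cbind(rows, cols)] <- inten
    }
    if (spec$noise_sd > 0)
      gray <- gray + matrix(rnorm(h * w, 0, spec$noise_sd), h, w)
    gray <- clip255(gray)

    image <- array(0, dim = c(h, w, 3))
    if (spec$object_color == "white") {
      image[, , 1] <- gray; image[, , 2] <- gray; image[, , 3] <- gray
    } else {
      ch <- match(spec$object_color, c("red", "green", "blue"))
      dimmed <- clip255(bg * 0.3 +
                          matrix(rnorm(h * w, 0, spec$noise_sd), h, w))
      for (i in 1:3) image[, , i] <- dimmed
      image[, , ch] <- gray
    }

    truth <- lapply(masks, function(cand)
      measure_component(cand$mask, c(cand$row0, cand$col0), h = h, w = w))
    names(truth) <- NULL

    annotated <- image
    for (cand in masks) {
      ix <- which(cand$mask > 0)
      rows <- cand$row0 + ((ix - 1L) %% nrow(cand$mask))
      cols <- cand$col0 + ((ix - 1L) %/% nrow(cand$mask))
      annotated[cbind(rows, cols, 1)] <- 255
      annotated[cbind(rows, cols, 2)] <- 0
      annotated[cbind(rows, cols, 3)] <- 0
    }

    list(image = image, truth = truth, annotated = annotated, spec = spec)
  })
}
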