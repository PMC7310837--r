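# Mode-specific preprocessing and the two-pass adaptive Gaussian-window
# thresholding that turns a microscopy image into a list of detections.

DETECTION_MODES <- c("optical", "sem", "sem_dark",
                     "fluor_red", "fluor_green", "fluor_blue")

# Reference defaults at 0.5 pixel/um.  Block sizes and areas scale with
# resolution (lengths by k = resolution / 0.5, areas by k^2), since an
# object occupies k times more pixels per um at k times the resolution.
REFERENCE_RESOLUTION <- 0.5
REFERENCE_DEFAULTS <- list(
  block_large = 51, block_small = 11,
  c_large = -8, c_small = -8,
  size_boundary = 300, min_pixels = 20, min_feret = 5, blur_kernel = 3
)

round_odd <- function(x) {
  r <- 2 * floor(x / 2) + 1
  pmax(1, r)
}

#' Construct and validate detection parameters
#'
#' Bundles the five trainable hyperparameters of the two-pass adaptive
#' threshold (neighborhood sizes `block_large`/`block_small`, offsets
#' `c_large`/`c_small`, and the `size_boundary` deciding which pass claims
#' an object) together with the user filters (`min_pixels`, `min_feret`),
#' the image `resolution`, the blur kernel width and the analysis `mode`.
#'
#' Defaults are defined at the reference resolution of 0.5 pixel/um
#' (`block_large` 51, `block_small` 11, `c_large` = `c_small` = -8,
#' `size_boundary` 300 px, `min_pixels` 20 px, `min_feret` 5 px,
#' `blur_kernel` 3) and scale with `resolution`: lengths by
#' `k = resolution / 0.5` (rounded to odd where oddness is required),
#' areas by `k^2`. Explicitly supplied values are never rescaled.
#'
#' The threshold at a pixel is the Gaussian-weighted neighborhood mean
#' minus C, so a more negative C demands more local contrast and a larger
#' (more positive) C makes detection more permissive.
#'
#' @param mode One of `"optical"`, `"sem"`, `"sem_dark"`, `"fluor_red"`,
#'   `"fluor_green"`, `"fluor_blue"`.
#' @param resolution Pixels per micrometer (> 0).
#' @param block_large,block_small Odd neighborhood sizes in pixels,
#'   `block_large > block_small >= 3`.
#' @param c_large,c_small Threshold offsets in intensity units, each in
#'   \[-10, 10\].
#' @param size_boundary Area in pixels separating the two passes.
#' @param min_pixels Minimum object area in pixels.
#' @param min_feret Minimum Feret max in pixels.
#' @param blur_kernel Odd width of the Gaussian pre-blur (1 disables).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(mode = "optical", resolution = 0.5,
                             block_large = NULL, block_small = NULL,
                             c_large = NULL, c_small = NULL,
                             size_boundary = NULL, min_pixels = NULL,
                             min_feret = NULL, blur_kernel = NULL) {
  mode <- match.arg(mode, DETECTION_MODES)
  if (!is.numeric(resolution) || resolution <= 0)
    stop("resolution must be > 0", call. = FALSE)
  k <- resolution / REFERENCE_RESOLUTION
  d <- REFERENCE_DEFAULTS
  p <- list(
    block_large = block_large %||% round_odd(d$block_large * k),
    block_small = block_small %||% round_odd(d$block_small * k),
    c_large = c_large %||% d$c_large,
    c_small = c_small %||% d$c_small,
    size_boundary = size_boundary %||% max(1, round(d$size_boundary * k^2)),
    min_pixels = min_pixels %||% max(1, round(d$min_pixels * k^2)),
    min_feret = min_feret %||% (d$min_feret * k),
    resolution = resolution,
    blur_kernel = blur_kernel %||% round_odd(d$blur_kernel * k),
    mode = mode
  )
  class(p) <- "detection_params"
  validate_params(p)
}

validate_params <- function(p) {
  with(p, {
    if (!is_odd(block_large) || !is_odd(block_small))
      stop("block size must be odd", call. = FALSE)
    if (!(block_large > block_small && block_small >= 3))
      stop("need block_large > block_small >= 3", call. = FALSE)
    if (c_large < -10 || c_large > 10 || c_small < -10 || c_small > 10)
      stop("C values must lie in [-10, 10]", call. = FALSE)
    if (min_pixels < 1 || size_boundary < min_pixels)
      stop("need size_boundary >= min_pixels >= 1", call. = FALSE)
    if (min_feret < 0) stop("min_feret must be >= 0", call. = FALSE)
    if (blur_kernel < 1 || !is_odd(blur_kernel))
      stop("blur_kernel must be odd >= 1", call. = FALSE)
  })
  p
}

#' @export
print.detection_params <- function(x, ...) {
  cat("Detection parameters (mode:", x$mode, ")\n")
  cat(sprintf("  blocks %d/%d  C %+g/%+g  size boundary %d px\n",
              x$block_large, x$block_small, x$c_large, x$c_small,
              as.integer(x$size_boundary)))
  cat(sprintf("  filters: min_pixels %d px, min_feret %g px; resolution %g px/um; blur %d\n",
              as.integer(x$min_pixels), x$min_feret, x$resolution,
              as.integer(x$blur_kernel)))
  invisible(x)
}

#' Read detection parameters from a key = value config file
#'
#' Lines have the form `key = value`; `#` starts a comment. Keys match the
#' arguments of [detection_params()]; unknown keys are an error. Values
#' given in `overrides` (e.g. from command-line flags) take precedence
#' over the file.
#'
#' @param path Path to the config file.
#' @param overrides Named list of values overriding the file.
#' @return A `detection_params` object.
#' @export
read_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.+)$", lines))
  bad <- lines[vapply(kv, length, 1L) != 3L]
  if (length(bad)) stop("malformed config line: ", bad[1], call. = FALSE)
  vals <- stats::setNames(
    lapply(kv, function(m) {
      v <- trimws(m[3])
      num <- suppressWarnings(as.numeric(v))
      if (is.na(num)) v else num
    }),
    vapply(kv, `[`, "", 2)
  )
  vals[names(overrides)] <- overrides
  known <- names(formals(detection_params))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key: ", paste(unknown, collapse = ", "), call. = FALSE)
  do.call(detection_params, vals)
}

#' Mode-specific preprocessing to a blurred gray image
#'
#' Optical and SEM images are converted to luminance grayscale; `sem_dark`
#' additionally inverts intensities (v -> 255 - v) so that dark objects on
#' a bright background become bright. Fluorescence modes keep only the
#' selected RGB channel (the other two are zeroed) and stretch it linearly
#' to \[0, 255\] before grayscale conversion, so that stained particles
#' appear white against the black background. Finally a normalized
#' Gaussian blur of width `blur_kernel` suppresses pixel noise that would
#' otherwise be detected as objects (`blur_kernel = 1` disables).
#'
#' @param image Color image array (see [load_image()]).
#' @param params A `detection_params` object.
#' @return Gray matrix with values in \[0, 255\].
#' @export
preprocess <- function(image, params) {
  assert_color_image(image)
  mode <- params$mode
  if (startsWith(mode, "fluor_")) {
    ch <- match(sub("fluor_", "", mode), c("red", "green", "blue"))
    sel <- image[, , ch]
    rng <- range(sel)
    if (rng[2] > rng[1]) sel <- (sel - rng[1]) / (rng[2] - rng[1]) * 255
    iso <- array(0, dim = dim(image))
    iso[, , ch] <- sel
    gray <- luminance(iso)
    # renormalize so the kept channel spans the full gray range
    if (max(gray) > 0) gray <- gray / max(gray) * 255
  } else {
    gray <- luminance(image)
    if (mode == "sem_dark") gray <- 255 - gray
  }
  if (params$blur_kernel > 1L)
    gray <- clip255(local_gaussian_mean(gray, params$blur_kernel))
  gray
}

#' Adaptive threshold with a Gaussian window
#'
#' A pixel is foreground iff its gray value exceeds the Gaussian-weighted
#' mean of its `block` x `block` neighborhood minus `c`. Border
#' neighborhoods use edge replication. Because the threshold tracks the
#' local background, objects remain detectable under inhomogeneous
#' illumination where any single global threshold fails.
#'
#' @param gray Gray matrix in \[0, 255\].
#' @param block Odd neighborhood size (>= 3).
#' @param c Offset subtracted from the local mean; larger values require
#'   less local contrast for detection.
#' @return Integer 0/1 matrix.
#' @export
adaptive_threshold <- function(gray, block, c = 0) {
  assert_gray_image(gray)
  if (!is_odd(block)) stop("block size must be odd", call. = FALSE)
  thr <- local_gaussian_mean(gray, block) - c
  out <- (gray > thr) * 1L
  dim(out) <- dim(gray)
  out
}

#' Global Otsu threshold
#'
#' Chooses the single threshold `t` maximizing the between-class variance
#' of the 256-bin gray histogram; foreground is every pixel strictly above
#' `t`. Used for fluorescence images (near-black background, no
#' illumination gradient) and as the global-thresholding baseline the
#' adaptive method is compared against.
#'
#' @param gray Gray matrix in \[0, 255\].
#' @return Integer 0/1 matrix; for a constant image an all-background
#'   result with a warning (there is no variance to split).
#' @export
otsu_threshold <- function(gray) {
  assert_gray_image(gray)
  g <- floor(gray)
  if (length(unique(as.vector(g))) < 2L) {
    warning("constant image: no threshold separates it; returning all background")
    return(matrix(0L, nrow(gray), ncol(gray)))
  }
  h <- tabulate(as.vector(g) + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  t <- which.max(sigma_b) - 1L # threshold level; foreground strictly above
  out <- (g > t) * 1L
  dim(out) <- dim(gray)
  attr(out, "threshold") <- t
  out
}

# Extract measured components from a binary image.  Returns a list of
# detection-shaped lists (measure_component output).  `min_area` is an
# optional lower bound on the *filled* area of components worth
# measuring: a component of p raw pixels can enclose at most about
# (p/4 + 1)^2 interior pixels (isoperimetric bound for a closed pixel
# curve), so raw components provably below the bound are skipped before
# the expensive per-component measurement.
extract_components <- function(bw, min_area = 0) {
  lab <- EBImage::bwlabel(bw)
  n <- max(lab)
  if (n == 0) return(list())
  idx <- which(lab > 0)
  comps <- split(idx, lab[idx])
  if (min_area > 0) {
    p <- lengths(comps)
    comps <- comps[p + (p / 4 + 1)^2 >= min_area]
    if (length(comps) == 0) return(list())
  }
  h <- nrow(bw); w <- ncol(bw)
  lapply(comps, function(ix) {
    rows <- ((ix - 1L) %% h) + 1L
    cols <- ((ix - 1L) %/% h) + 1L
    r0 <- min(rows); c0 <- min(cols)
    local <- matrix(0L, max(rows) - r0 + 1L, max(cols) - c0 + 1L)
    local[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- 1L
    measure_component(local, c(r0, c0), h = h, w = w)
  })
}

#' Detect objects by two-pass adaptive thresholding
#'
#' The gray image is thresholded twice: a first pass with the large
#' Gaussian window keeps objects of filled area at least `size_boundary`
#' (large objects are detected well only with a large neighborhood), and a
#' second pass with the small window keeps objects with area in
#' `[min_pixels, size_boundary)`. A second-pass object whose corrected
#' center falls inside a first-pass object is suppressed so nothing is
#' counted twice; first-pass detections take precedence. Any object whose
#' Feret max is below `min_feret` is dropped. In the fluorescence modes
#' the global Otsu threshold replaces the adaptive threshold in both
#' passes.
#'
#' Contours are outer boundaries: interior holes set `has_holes` but their
#' area is not subtracted. Objects touching the image border are kept and
#' flagged `on_border`.
#'
#' @param gray Preprocessed gray matrix (see [preprocess()]).
#' @param params A `detection_params` object.
#' @return List of detections; each has `contour` (n x 2, 0-based x/y),
#'   `pixels` (filled interior), `center` (corrected), `centroid`,
#'   `area_px`, `feret_min_px`, `feret_max_px`, `object_class`,
#'   `source_pass`, `has_holes`, `on_border`.
#' @export
detect_objects <- function(gray, params) {
  validate_params(params)
  fluor <- startsWith(params$mode, "fluor_")
  if (fluor) {
    bw <- otsu_threshold(gray)
    bw_large <- bw_small <- bw
  } else {
    bw_large <- adaptive_threshold(gray, params$block_large, params$c_large)
    bw_small <- adaptive_threshold(gray, params$block_small, params$c_small)
  }
  merge_passes(extract_components(bw_large, min_area = params$min_pixels),
               extract_components(bw_small, min_area = params$min_pixels),
               params, width = ncol(gray))
}

# Pass merging and filtering, shared with the grid search fast path.
merge_passes <- function(comps_large, comps_small, params, width) {
  large <- Filter(function(d) d$area_px >= params$size_boundary, comps_large)
  small <- Filter(function(d) d$area_px >= params$min_pixels &&
                    d$area_px < params$size_boundary, comps_small)
  large <- lapply(large, function(d) { d$source_pass <- "large"; d })
  small <- lapply(small, function(d) { d$source_pass <- "small"; d })
  if (length(large) && length(small)) {
    keys <- unlist(lapply(large, function(d) pixel_keys(d$pixels, width)))
    inside <- vapply(small, function(d) {
      pixel_keys(rbind(round(d$center)), width) %in% keys
    }, TRUE)
    small <- small[!inside]
  }
  out <- c(large, small)
  out <- Filter(function(d) d$feret_max_px >= params$min_feret, out)
  names(out) <- NULL
  out
}

#' Run the full detection pipeline on a color image
#'
#' Convenience wrapper: [preprocess()] then [detect_objects()].
#'
#' @inheritParams preprocess
#' @return See [detect_objects()].
#' @export
detect_particles <- function(image, params = detection_params()) {
  detect_objects(preprocess(image, params), params)
}
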