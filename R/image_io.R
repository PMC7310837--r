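#' Load a raster image as an H x W x 3 array
#'
#' Reads a PNG, TIFF or JPEG file and returns a color image array with
#' values in \[0, 255\]. Single-channel rasters are replicated to three
#' identical channels; an alpha channel, if present, is dropped. 16-bit
#' inputs are linearly rescaled to \[0, 255\], since all thresholding
#' parameters (in particular the C offsets) are defined on the 8-bit
#' intensity scale.
#'
#' @param path Path to an image file.
#' @return Numeric array of dimension `c(height, width, 3)`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- tryCatch(
    suppressWarnings(EBImage::readImage(path)),
    error = function(e) stop("invalid image: ", path, call. = FALSE)
  )
  arr <- EBImage::imageData(img)
  if (length(arr) == 0) stop("invalid image: ", path, call. = FALSE)
  if (length(dim(arr)) == 2L) {
    arr <- array(rep(arr, 3L), dim = c(dim(arr), 3L))
  } else if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3]
    if (nch == 1L) {
      arr <- array(rep(arr[, , 1], 3L), dim = c(dim(arr)[1:2], 3L))
    } else if (nch == 2L) { # gray + alpha
      arr <- array(rep(arr[, , 1], 3L), dim = c(dim(arr)[1:2], 3L))
    } else {
      arr <- arr[, , 1:3, drop = FALSE] # drop alpha and extra channels
    }
  } else stop("invalid image: ", path, call. = FALSE)
  # EBImage stores (x, y, channel); internal convention is (row, col, channel)
  arr <- aperm(arr, c(2L, 1L, 3L))
  clip255(round(arr * 255))
}

#' Stitch a row-major grid of equally sized tiles into one image
#'
#' Tiles are placed without blending: tile (r, c) occupies the block whose
#' top-left corner is at row `r * tile_height`, column `c * tile_width`
#' (0-based). Overlapping-tile registration is out of scope; tiles are
#' assumed contiguous and non-overlapping.
#'
#' @param tiles List of color image arrays (see [load_image()]), row-major.
#' @param n_rows,n_cols Grid shape.
#' @return A single color image array.
#' @export
stitch_tiles <- function(tiles, n_rows, n_cols) {
  if (length(tiles) != n_rows * n_cols)
    stop("grid mismatch: ", length(tiles), " tiles for a ",
         n_rows, " x ", n_cols, " grid", call. = FALSE)
  dims <- lapply(tiles, dim)
  d0 <- dims[[1]]
  for (d in dims) {
    if (length(d) != 3L || !all(d == d0))
      stop("inconsistent tiles: all tiles must share one height and width",
           call. = FALSE)
  }
  th <- d0[1]; tw <- d0[2]
  out <- array(0, dim = c(n_rows * th, n_cols * tw, 3L))
  for (r in seq_len(n_rows)) {
    for (cc in seq_len(n_cols)) {
      tile <- tiles[[(r - 1L) * n_cols + cc]]
      out[(r - 1L) * th + seq_len(th), (cc - 1L) * tw + seq_len(tw), ] <- tile
    }
  }
  out
}

#' Down-scale an image by integer block averaging
#'
#' Each `factor` x `factor` pixel block is replaced by its mean, emulating
#' acquisition of the same field of view at a lower resolution. The image
#' is cropped to a multiple of `factor` first.
#'
#' @param image Color image array or gray matrix.
#' @param factor Integer down-scaling factor (2 halves the resolution).
#' @return Image of the same kind with both pixel dimensions divided by
#'   `factor`.
#' @export
downscale_image <- function(image, factor = 2L) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  if (factor == 1L) return(image)
  block_mean <- function(m) {
    h <- (nrow(m) %/% factor) * factor
    w <- (ncol(m) %/% factor) * factor
    m <- m[seq_len(h), seq_len(w), drop = FALSE]
    # average rows then columns within each block
    rsum <- rowsum(m, rep(seq_len(h %/% factor), each = factor)) / factor
    out <- t(rowsum(t(rsum), rep(seq_len(w %/% factor), each = factor)) / factor)
    dimnames(out) <- NULL
    out
  }
  if (is.matrix(image)) return(block_mean(image))
  assert_color_image(image)
  ch <- lapply(1:3, function(i) block_mean(image[, , i]))
  array(unlist(ch), dim = c(dim(ch[[1]]), 3L))
}

# Rec. 601 luminance on [0, 255] channels.
luminance <- function(image) {
  assert_color_image(image)
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

#' Convert a detection list to the export table
#'
#' One row per detection with pixel and micrometer coordinates, area,
#' Feret diameters, class, pass of origin, and the subsampling flag.
#' Micrometer values use `x_um = x_px / resolution` (and analogously for
#' lengths; areas divide by `resolution^2`); a stage offset in um may be
#' added so coordinates can be imported by stage-control software.
#'
#' @param detections List of detections from [detect_objects()].
#' @param resolution Pixels per micrometer (> 0).
#' @param offset_um Optional `c(x0, y0)` stage offset in micrometers.
#' @return A `data.frame` with columns `id, x_px, y_px, x_um, y_um,
#'   area_px, area_um2, feret_min_um, feret_max_um, feret_min_px,
#'   feret_max_px, class, pass, selected`.
#' @export
detections_to_df <- function(detections, resolution, offset_um = c(0, 0)) {
  stopifnot(resolution > 0, length(offset_um) == 2)
  n <- length(detections)
  get <- function(field, default = NA) {
    if (n == 0) return(vector(mode = mode(default), length = 0))
    vapply(detections, function(d) d[[field]] %||% default, default)
  }
  x_px <- if (n) vapply(detections, function(d) d$center[1], 0) else numeric()
  y_px <- if (n) vapply(detections, function(d) d$center[2], 0) else numeric()
  df <- data.frame(
    id = seq_len(n),
    x_px = x_px,
    y_px = y_px,
    x_um = x_px / resolution + offset_um[1],
    y_um = y_px / resolution + offset_um[2],
    area_px = get("area_px", 0),
    area_um2 = get("area_px", 0) / resolution^2,
    feret_min_um = get("feret_min_px", 0) / resolution,
    feret_max_um = get("feret_max_px", 0) / resolution,
    feret_min_px = get("feret_min_px", 0),
    feret_max_px = get("feret_max_px", 0),
    class = get("object_class", ""),
    pass = get("source_pass", ""),
    selected = as.integer(get("selected", 0)),
    stringsAsFactors = FALSE
  )
  df
}

#' Write the three output artifacts of an analysis
#'
#' Produces (a) an overlay: the grayscale rendering of the input with
#' contours drawn in green (particles from the large-window pass), yellow
#' (particles from the small-window pass) or blue (fibers), plus a 3-px
#' cross at each corrected measurement center; (b) a black-and-white mask
#' with detected object interiors white; and (c) a csv table of the
#' detections (see [detections_to_df()]).
#'
#' @inheritParams detections_to_df
#' @param image Color image array the detections came from.
#' @param out_prefix Output path prefix; files are written as
#'   `<prefix>_overlay.png`, `<prefix>_mask.png` and `<prefix>.csv`.
#' @return Invisibly, a named character vector of the three paths.
#' @export
write_outputs <- function(image, detections, resolution, out_prefix,
                          offset_um = c(0, 0)) {
  assert_color_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  gray <- clip255(luminance(image))
  overlay <- array(gray / 255, dim = c(h, w, 3L))
  mask <- matrix(0L, h, w)

  colors <- list(particle_large = c(0, 1, 0), particle_small = c(1, 1, 0),
                 fiber = c(0, 0, 1))
  paint <- function(ov, rc, col) {
    ok <- rc[, 1] >= 1 & rc[, 1] <= h & rc[, 2] >= 1 & rc[, 2] <= w
    rc <- rc[ok, , drop = FALSE]
    for (i in 1:3) ov[cbind(rc, i)] <- col[i]
    ov
  }
  for (d in detections) {
    col <- if (d$object_class == "fiber") colors$fiber
           else if (d$source_pass == "large") colors$particle_large
           else colors$particle_small
    overlay <- paint(overlay, xy_to_rc(d$contour), col)
    cx <- round(d$center[1]) + 1; cy <- round(d$center[2]) + 1
    cross <- cbind(c(cy - 1, cy, cy, cy, cy + 1), c(cx, cx - 1, cx, cx + 1, cx))
    overlay <- paint(overlay, cross, col)
    prc <- xy_to_rc(d$pixels)
    mask[prc] <- 1L
  }

  paths <- c(overlay = paste0(out_prefix, "_overlay.png"),
             mask = paste0(out_prefix, "_mask.png"),
             csv = paste0(out_prefix, ".csv"))
  ok <- tryCatch({
    EBImage::writeImage(EBImage::Image(aperm(overlay, c(2L, 1L, 3L)),
                                       colormode = "Color"), paths[["overlay"]])
    EBImage::writeImage(t(mask), paths[["mask"]])
    utils::write.csv(detections_to_df(detections, resolution, offset_um),
                     paths[["csv"]], row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("write failed: ", out_prefix, call. = FALSE)
  invisible(paths)
}
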