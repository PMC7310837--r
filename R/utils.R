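# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_color_image <- function(img, arg = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(sprintf("`%s` must be an H x W x 3 array", arg), call. = FALSE)
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop(sprintf("`%s` must have values in [0, 255]", arg), call. = FALSE)
  invisible(img)
}

assert_gray_image <- function(img, arg = "gray") {
  if (!is.matrix(img))
    stop(sprintf("`%s` must be an H x W matrix", arg), call. = FALSE)
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop(sprintf("`%s` must have values in [0, 255]", arg), call. = FALSE)
  invisible(img)
}

is_odd <- function(x) x %% 2 == 1

# 2-D Gaussian window of odd side `block`, normalized to sum 1.  The
# standard deviation follows the usual kernel-size convention
# sigma = 0.3 * ((block - 1) * 0.5 - 1) + 0.8 so that the window widens
# with the neighborhood size.
gaussian_window <- function(block) {
  if (block < 1 || !is_odd(block))
    stop("block size must be odd", call. = FALSE)
  if (block == 1L) return(matrix(1, 1, 1))
  sigma <- 0.3 * ((block - 1) * 0.5 - 1) + 0.8
  r <- (block - 1) / 2
  g1 <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- outer(g1, g1)
  k / sum(k)
}

# Gaussian-weighted local mean with edge replication at the borders.
local_gaussian_mean <- function(gray, block) {
  k <- gaussian_window(block)
  if (nrow(k) == 1L) return(gray)
  EBImage::filter2(gray, k, boundary = "replicate")
}

# Convert between 0-based (x, y) = (col, row) coordinates and 1-based
# matrix indices.
xy_to_rc <- function(xy) cbind(row = xy[, 2] + 1, col = xy[, 1] + 1)
rc_to_xy <- function(rc) cbind(x = rc[, 2] - 1, y = rc[, 1] - 1)

# Membership keys for 0-based pixel coordinate sets.
pixel_keys <- function(xy, width) xy[, 1] + as.numeric(xy[, 2]) * width

clip255 <- function(x) {
  y <- pmin(pmax(x, 0), 255)
  dim(y) <- dim(x)
  y
}

# Seed-scoped RNG: run `expr` under `seed` and restore the global RNG
# state afterwards, so library calls never perturb user randomness.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
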