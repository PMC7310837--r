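# Grid-search calibration of the five threshold hyperparameters against
# an expert consensus, scored by the mean of four relative errors.

#' Summarize a set of objects for grid-search scoring
#'
#' @param objects List of detections or ground-truth objects.
#' @return List with `n_objects`, `total_area_px`, `sum_feret_min_px`,
#'   `sum_feret_max_px`.
#' @export
summarize_objects <- function(objects) {
  list(
    n_objects = length(objects),
    total_area_px = sum(vapply(objects, `[[`, 0, "area_px")),
    sum_feret_min_px = sum(vapply(objects, `[[`, 0, "feret_min_px")),
    sum_feret_max_px = sum(vapply(objects, `[[`, 0, "feret_max_px"))
  )
}

#' Four-term relative-error score of an analysis against a consensus
#'
#' The score is the mean of the relative errors of the object count, the
#' total area, and the summed minimum and maximum Feret diameters. A
#' smaller value indicates a more accurate parametrization; 0 means all
#' four summaries match exactly.
#'
#' @param analysis,consensus Summaries from [summarize_objects()].
#' @return Non-negative scalar.
#' @export
error_score <- function(analysis, consensus) {
  if (consensus$n_objects <= 0) stop("no consensus value", call. = FALSE)
  keys <- c("n_objects", "total_area_px", "sum_feret_min_px", "sum_feret_max_px")
  a <- unlist(analysis[keys]); cns <- unlist(consensus[keys])
  mean(abs(a - cns) / cns)
}

expand_axis <- function(v, name) {
  if (!is.numeric(v) || length(v) != 3 || v[3] <= 0 || v[1] > v[2])
    stop("grid axis `", name, "` must be c(min, max, step) with step > 0",
         call. = FALSE)
  s <- seq(v[1], v[2], by = v[3])
  if (name %in% c("block_small", "block_large") && any(!is_odd(s)))
    stop("grid axis `", name, "` must contain odd values only", call. = FALSE)
  s
}

#' Exhaustive grid search over the five threshold hyperparameters
#'
#' Every combination of `block_small`, `block_large`, `c_small`,
#' `c_large` and `size_boundary` on the grid is run on every image; each
#' run is scored by [error_score()] against that image's consensus
#' summary and scores are averaged unweighted over images. Combinations
#' violating the parameter invariants (e.g. `block_small >= block_large`)
#' are skipped. Results are identical to evaluating [detect_objects()]
#' independently per combination; internally, threshold maps and
#' connected components are cached per `(block, C)` pair since the size
#' boundary only re-partitions already-measured components.
#'
#' @param images List of `list(gray = , truth = )` pairs: a preprocessed
#'   gray image and its nonempty consensus object list.
#' @param grid Named list with entries `block_small`, `block_large`,
#'   `c_small`, `c_large`, `size_boundary`, each `c(min, max, step)`.
#'   Block axes must contain odd values only.
#' @param fixed A `detection_params` object supplying the non-searched
#'   fields (`min_pixels`, `min_feret`, `resolution`, `mode`, ...).
#' @return A `data.frame` of scored combinations sorted by ascending
#'   score, ties broken lexicographically by (`block_large`,
#'   `block_small`, `c_large`, `c_small`, `size_boundary`). Per-image
#'   scores are attached as attribute `"per_image"` (rows align with the
#'   data frame).
#' @export
grid_search <- function(images, grid, fixed = detection_params()) {
  axes <- c("block_small", "block_large", "c_small", "c_large", "size_boundary")
  if (!all(axes %in% names(grid))) stop("empty grid", call. = FALSE)
  seqs <- lapply(axes, function(a) expand_axis(grid[[a]], a))
  names(seqs) <- axes
  if (any(vapply(seqs, length, 1L) == 0)) stop("empty grid", call. = FALSE)
  combos <- expand.grid(seqs, KEEP.OUT.ATTRS = FALSE)
  valid <- combos$block_small < combos$block_large &
    combos$block_small >= 3 &
    combos$size_boundary >= fixed$min_pixels
  if (any(!valid))
    message(sum(!valid), " invalid parameter combinations skipped")
  combos <- combos[valid, , drop = FALSE]
  if (nrow(combos) == 0) stop("empty grid", call. = FALSE)

  consensus <- lapply(images, function(im) {
    if (length(im$truth) == 0) stop("no consensus value", call. = FALSE)
    summarize_objects(im$truth)
  })

  # component cache per image x (block, C): the expensive part of a run
  comp_cache <- lapply(images, function(im) new.env(parent = emptyenv()))
  get_comps <- function(img_i, block, cval) {
    key <- paste(block, cval, sep = "_")
    env <- comp_cache[[img_i]]
    if (is.null(env[[key]])) {
      bw <- adaptive_threshold(images[[img_i]]$gray, block, cval)
      env[[key]] <- extract_components(bw, min_area = fixed$min_pixels)
    }
    env[[key]]
  }

  per_image <- matrix(NA_real_, nrow(combos), length(images))
  for (r in seq_len(nrow(combos))) {
    p <- fixed
    p$block_small <- combos$block_small[r]
    p$block_large <- combos$block_large[r]
    p$c_small <- combos$c_small[r]
    p$c_large <- combos$c_large[r]
    p$size_boundary <- combos$size_boundary[r]
    validate_params(p)
    for (i in seq_along(images)) {
      det <- merge_passes(get_comps(i, p$block_large, p$c_large),
                          get_comps(i, p$block_small, p$c_small),
                          p, width = ncol(images[[i]]$gray))
      per_image[r, i] <- error_score(summarize_objects(det), consensus[[i]])
    }
  }
  score <- rowMeans(per_image)
  ord <- order(score, combos$block_large, combos$block_small,
               combos$c_large, combos$c_small, combos$size_boundary)
  out <- data.frame(
    block_large = combos$block_large[ord],
    block_small = combos$block_small[ord],
    c_large = combos$c_large[ord],
    c_small = combos$c_small[ord],
    size_boundary = combos$size_boundary[ord],
    score = score[ord]
  )
  rownames(out) <- NULL
  attr(out, "per_image") <- per_image[ord, , drop = FALSE]
  out
}
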