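# Ground-truth extraction from expert red annotations and the TP/FP/FN
# scoring protocol (with incorrect-separation bookkeeping for merged
# detections of agglomerates).

#' Extract expert ground truth from red annotations
#'
#' Experts mark every object in saturated red on a copy of the image (the
#' consensus value). A pixel is counted as annotation when its red
#' channel is at least 150 and at least twice the larger of green and
#' blue, which tolerates compression bleed. Red connected components are
#' filled (so outline-only marks become full objects) and measured like
#' detections; components below `min_pixels` are discarded.
#'
#' @param annotated Color image array with red markings.
#' @param min_pixels Minimum filled area in pixels.
#' @return List of ground-truth objects (same structure as detections,
#'   without a `source_pass`). Empty, with a warning, if no red pixels are
#'   found.
#' @export
extract_ground_truth <- function(annotated, min_pixels = 20) {
  assert_color_image(annotated)
  r <- annotated[, , 1]; g <- annotated[, , 2]; b <- annotated[, , 3]
  red <- (r >= 150 & r >= 2 * pmax(g, b)) * 1L
  dim(red) <- dim(r)
  if (sum(red) == 0) {
    warning("no red annotation pixels found")
    return(list())
  }
  objs <- Filter(function(d) d$area_px >= min_pixels, extract_components(red))
  names(objs) <- NULL
  objs
}

#' Match detections against ground truth and compute error rates
#'
#' A detection corresponds to a truth object when the detection's
#' corrected center lies inside the truth object or the truth center lies
#' inside the detection (a containment test is resolution-independent and
#' mirrors how an expert judges an overlay). Correspondences are resolved
#' one-to-one greedily by increasing center distance. Unmatched truths are
#' false negatives, unmatched detections false positives. A matched
#' detection that additionally contains the centers of k - 1 further
#' unmatched truths counts as one true positive plus an incorrect
#' separation of k truths in one instance (an agglomerate detected as a
#' single object); those k - 1 truths are not counted as false negatives.
#'
#' Rates are normalized by the truth count, so `tp_rate + fn_rate = 1`
#' whenever no incorrect separation occurs, and `fp_rate` can exceed 1 on
#' pathological inputs.
#'
#' @param detections List of detections from [detect_objects()].
#' @param truth List of ground-truth objects from
#'   [extract_ground_truth()] (or a scene generator).
#' @return List with `match` (`tp`, `fp`, `fn`, `incorrect_separation` =
#'   `c(n_truths, n_instances)`, `pairs`) and `rates` (`tp_rate`,
#'   `fp_rate`, `fn_rate`).
#' @export
match_and_rate <- function(detections, truth) {
  if (length(truth) == 0) stop("no consensus value", call. = FALSE)
  nd <- length(detections); nt <- length(truth)
  all_x <- c(unlist(lapply(detections, function(d) d$pixels[, 1])),
             unlist(lapply(truth, function(d) d$pixels[, 1])))
  width <- max(all_x, 0) + 1
  det_keys <- lapply(detections, function(d) pixel_keys(d$pixels, width))
  tru_keys <- lapply(truth, function(d) pixel_keys(d$pixels, width))
  ckey <- function(ctr) round(ctr[1]) + round(ctr[2]) * width

  cand <- list()
  for (i in seq_len(nd)) {
    for (j in seq_len(nt)) {
      if (ckey(detections[[i]]$center) %in% tru_keys[[j]] ||
          ckey(truth[[j]]$center) %in% det_keys[[i]]) {
        d2 <- sum((detections[[i]]$center - truth[[j]]$center)^2)
        cand[[length(cand) + 1L]] <- c(i, j, d2)
      }
    }
  }
  det_match <- rep(NA_integer_, nd)
  tru_match <- rep(NA_integer_, nt)
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (is.na(det_match[i]) && is.na(tru_match[j])) {
        det_match[i] <- j
        tru_match[j] <- i
      }
    }
  }

  # merged detections: matched detection containing further unmatched
  # truth centers absorbs them as incorrect separation
  absorbed <- rep(FALSE, nt)
  sep_truths <- 0L; sep_instances <- 0L
  for (i in which(!is.na(det_match))) {
    extra <- which(is.na(tru_match) & !absorbed &
                     vapply(seq_len(nt), function(j)
                       ckey(truth[[j]]$center) %in% det_keys[[i]], TRUE))
    if (length(extra)) {
      absorbed[extra] <- TRUE
      sep_truths <- sep_truths + length(extra) + 1L
      sep_instances <- sep_instances + 1L
    }
  }

  tp <- sum(!is.na(det_match))
  fp <- sum(is.na(det_match))
  fn <- sum(is.na(tru_match) & !absorbed)
  pairs <- cbind(detection = which(!is.na(det_match)),
                 truth = det_match[!is.na(det_match)])
  list(
    match = list(tp = tp, fp = fp, fn = fn,
                 incorrect_separation = c(n_truths = sep_truths,
                                          n_instances = sep_instances),
                 pairs = pairs),
    rates = list(tp_rate = tp / nt, fp_rate = fp / nt, fn_rate = fn / nt)
  )
}

#' Average per-image rates with equal weight per image
#'
#' Each image contributes equally regardless of how many objects it
#' holds: the aggregate is the unweighted mean of the per-image rates.
#'
#' @param rate_list List of `rates` elements from [match_and_rate()].
#' @return List with mean `tp_rate`, `fp_rate`, `fn_rate`.
#' @export
average_rates <- function(rate_list) {
  if (length(rate_list) == 0) stop("no rates to average", call. = FALSE)
  list(
    tp_rate = mean(vapply(rate_list, `[[`, 0, "tp_rate")),
    fp_rate = mean(vapply(rate_list, `[[`, 0, "fp_rate")),
    fn_rate = mean(vapply(rate_list, `[[`, 0, "fn_rate"))
  )
}

#' Validate a detection run against an expert-annotated image
#'
#' Runs the full pipeline on `image`, extracts ground truth from the
#' red-annotated copy, and scores TP/FP/FN.
#'
#' @param image Original color image array.
#' @param annotated Red-annotated copy of the same frame.
#' @param params A `detection_params` object.
#' @return As [match_and_rate()], plus `n_detections` and `n_truth`.
#' @export
validate_against_annotation <- function(image, annotated,
                                        params = detection_params()) {
  det <- detect_particles(image, params)
  truth <- extract_ground_truth(annotated, min_pixels = params$min_pixels)
  res <- match_and_rate(det, truth)
  res$n_detections <- length(det)
  res$n_truth <- length(truth)
  res
}
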