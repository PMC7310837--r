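# Statistical subsampling of detections: minimum representative sample
# size and seeded uniform selection of measurement targets.

#' Minimum number of objects to measure for representativeness
#'
#' Normal-approximation sample size for estimating a proportion, with
#' finite-population correction:
#' \deqn{n_0 = z^2 \, p (1 - p) / m^2, \qquad
#'       n = \lceil n_0 / (1 + (n_0 - 1)/N) \rceil}
#' where `z` is the two-sided standard-normal quantile for the stated
#' confidence, `p` the estimated fraction of the analyte (e.g.
#' microplastic content), `m` the margin of error and `N` the number of
#' detected objects. The result is clamped to `N`. The formula is printed
#' here so users can audit it; whether a finite-population correction is
#' applied, and how rounding is done, varies between texts — this
#' implementation corrects and rounds up.
#'
#' @param population Number of detected objects N (>= 1).
#' @param confidence Two-sided confidence level in (0, 1), e.g. 0.95.
#' @param margin Margin of error in (0, 1), e.g. 0.05.
#' @param p_est Estimated analyte fraction in (0, 1); 0.5 is the
#'   conservative maximum.
#' @return Integer sample size n, `1 <= n <= population`.
#' @export
required_sample_size <- function(population, confidence = 0.95,
                                 margin = 0.05, p_est = 0.5) {
  ok <- is.numeric(population) && population >= 1 &&
    is.numeric(confidence) && confidence > 0 && confidence < 1 &&
    is.numeric(margin) && margin > 0 && margin < 1 &&
    is.numeric(p_est) && p_est > 0 && p_est < 1
  if (!ok) stop("invalid sampling spec", call. = FALSE)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  n0 <- z^2 * p_est * (1 - p_est) / margin^2
  n <- n0 / (1 + (n0 - 1) / population)
  min(as.integer(ceiling(n)), as.integer(population))
}

#' Select a seeded random subset of detections for measurement
#'
#' Draws `required_sample_size()` detections uniformly without
#' replacement (unweighted: every object is equally likely regardless of
#' size), flags them with `selected = 1`, and optionally writes the
#' selection to a separate csv with the same schema as the full export.
#'
#' @param detections Nonempty list of detections.
#' @param confidence,margin,p_est See [required_sample_size()].
#' @param seed Integer seed driving the selection; the same seed always
#'   reproduces the same subset. The global RNG state is left untouched.
#' @param out_csv Optional path for the subset csv.
#' @param resolution Pixels per micrometer, required when `out_csv` is
#'   given.
#' @param offset_um Stage offset passed to [detections_to_df()].
#' @return The detection list with `selected` set on every element (1 for
#'   sampled, 0 otherwise); the sampled indices are attached as attribute
#'   `"selected_idx"`.
#' @export
random_subset <- function(detections, confidence = 0.95, margin = 0.05,
                          p_est = 0.5, seed = 1L, out_csv = NULL,
                          resolution = NULL, offset_um = c(0, 0)) {
  if (length(detections) == 0) stop("nothing to sample", call. = FALSE)
  n <- required_sample_size(length(detections), confidence, margin, p_est)
  idx <- sort(with_seed(seed, sample.int(length(detections), n)))
  detections <- lapply(seq_along(detections), function(i) {
    d <- detections[[i]]
    d$selected <- as.integer(i %in% idx)
    d
  })
  if (!is.null(out_csv)) {
    if (is.null(resolution)) stop("resolution required to write csv", call. = FALSE)
    df <- detections_to_df(detections[idx], resolution, offset_um)
    df$id <- idx
    df$selected <- 1L
    utils::write.csv(df, out_csv, row.names = FALSE, quote = FALSE)
  }
  attr(detections, "selected_idx") <- idx
  detections
}
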