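# PCKh evaluation: percentage of correct keypoints at a threshold that is
# a fraction of the ground-truth head-neck length, plus the normalised
# area under the PCKh(t) curve over t in [0, 0.5].

#' PCKh at a threshold
#'
#' A predicted keypoint counts as correct when its Euclidean error is at
#' most `t * l`, where `l` is the ground-truth head-top-to-neck distance of
#' that image ("within" is read inclusively).  By default all visible
#' keypoints are pooled across images; `per_image = TRUE` instead averages
#' per-image percentages.
#'
#' @param predictions List of predicted 14 x 2 pose matrices (NA rows are
#'   treated as missed keypoints).
#' @param ground_truth List of ground-truth 14 x 2 pose matrices, aligned
#'   with `predictions`.
#' @param t Threshold as a fraction of head-neck length.
#' @param visible Optional list of logical 14-vectors marking which
#'   ground-truth keypoints are evaluated (default: all).
#' @param per_image Average per-image percentages instead of pooling.
#' @return Percentage in `[0, 100]`.
#' @export
pckh_at <- function(predictions, ground_truth, t, visible = NULL,
                    per_image = FALSE) {
  if (length(predictions) == 0 || length(predictions) != length(ground_truth))
    stop("predictions and ground truth must be aligned, non-empty lists")
  correct <- 0; total <- 0; per <- numeric(0)
  for (i in seq_along(predictions)) {
    gt <- ground_truth[[i]]
    pr <- predictions[[i]]
    check_pose(gt)
    l <- sqrt(sum((gt[14, ] - gt[13, ])^2))
    if (l == 0) stop("image ", i, ": head-neck length is zero")
    vis <- if (is.null(visible)) rep(TRUE, 14) else visible[[i]]
    err <- sqrt(rowSums((pr - gt)^2))
    ok <- !is.na(err) & err <= t * l
    correct <- correct + sum(ok[vis])
    total <- total + sum(vis)
    per <- c(per, 100 * sum(ok[vis]) / max(1, sum(vis)))
  }
  if (total == 0) stop("no visible keypoints to evaluate")
  if (per_image) mean(per) else 100 * correct / total
}

#' Sample the PCKh curve over a threshold grid
#'
#' @inheritParams pckh_at
#' @param thresholds Increasing grid over `[0, 0.5]`; the default 51-point
#'   grid makes trapezoid integration error negligible for step-like
#'   curves at the dataset sizes in play.
#' @return A list of class `pckh_curve` with `thresholds` and `values`
#'   (percentages).
#' @export
pckh_curve <- function(predictions, ground_truth,
                       thresholds = seq(0, 0.5, by = 0.01),
                       visible = NULL, per_image = FALSE) {
  values <- vapply(thresholds, function(t)
    pckh_at(predictions, ground_truth, t, visible, per_image), numeric(1))
  structure(list(thresholds = thresholds, values = values),
            class = "pckh_curve")
}

#' Normalised area under a PCKh curve
#'
#' `AUC = (1 / 0.5) * integral of pckh(t) dt over [0, 0.5]`, with pckh as a
#' fraction, evaluated by the trapezoid rule; the result lies in `[0, 1]`.
#'
#' @param curve A `pckh_curve` (or list with `thresholds` and `values`).
#' @return Scalar in `[0, 1]`.
#' @export
auc_pckh <- function(curve) {
  t <- curve$thresholds
  v <- curve$values / 100
  if (length(t) < 2 || length(t) != length(v))
    stop("curve needs aligned thresholds and values of length >= 2")
  if (is.unsorted(t, strictly = TRUE)) stop("thresholds must be increasing")
  area <- sum(diff(t) * (head(v, -1) + tail(v, -1)) / 2)
  area / (max(t) - min(t))
}

#' @rdname auc_pckh
#' @return `auc_percent()`: percentage in `[0, 100]`.
#' @export
auc_percent <- function(curve) 100 * auc_pckh(curve)

#' Standard evaluation report
#'
#' Computes the three headline numbers used throughout: PCKh@0.5, PCKh@0.2
#' and AUC%.
#'
#' @inheritParams pckh_at
#' @return A one-row data frame with columns `pckh_05`, `pckh_02`,
#'   `auc_percent`.
#' @export
evaluate_poses <- function(predictions, ground_truth, visible = NULL,
                           per_image = FALSE) {
  curve <- pckh_curve(predictions, ground_truth, visible = visible,
                      per_image = per_image)
  data.frame(
    pckh_05 = pckh_at(predictions, ground_truth, 0.5, visible, per_image),
    pckh_02 = pckh_at(predictions, ground_truth, 0.2, visible, per_image),
    auc_percent = auc_percent(curve))
}
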