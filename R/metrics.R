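# Pixel-level segmentation scoring: confusion counts, overlap metrics,
# mean(SD) aggregation, and the Welch unequal-variance comparison.

#' Pixel-wise confusion counts between two binary masks
#'
#' @param gt ground-truth binary mask.
#' @param pr_mask predicted binary mask, same shape.
#' @return A list of class \code{"confusion_counts"} with integer fields
#'   \code{tp}, \code{fp}, \code{fn}, \code{tn}; the four always sum to the
#'   pixel count.
#' @export
confusion <- function(gt, pr_mask) {
  validate_mask(gt, arg = "gt")
  validate_mask(pr_mask, arg = "pr_mask")
  if (!identical(dim(gt), dim(pr_mask)))
    stop("image/mask shape mismatch", call. = FALSE)
  structure(list(
    tp = sum(gt == 1 & pr_mask == 1),
    fp = sum(gt == 0 & pr_mask == 1),
    fn = sum(gt == 1 & pr_mask == 0),
    tn = sum(gt == 0 & pr_mask == 0)),
    class = "confusion_counts")
}

#' Intersection over union (Jaccard index)
#'
#' \eqn{tp / (tp + fp + fn)}. When both masks are empty the union is empty
#' and the score is 1 by convention, making the metric a total function.
#'
#' @param c a \code{"confusion_counts"} object.
#' @return Number in \code{[0,1]}.
#' @export
iou <- function(c) {
  denom <- c$tp + c$fp + c$fn
  if (denom == 0) return(1)
  c$tp / denom
}

#' Dice coefficient (F1 score)
#'
#' \eqn{2tp / (2tp + fp + fn)}: the harmonic mean of precision and recall on
#' pixel sets, and equivalently \eqn{2J/(1+J)} for Jaccard index \eqn{J}.
#' Returns 1 when both masks are empty.
#'
#' @param c a \code{"confusion_counts"} object.
#' @return Number in \code{[0,1]}.
#' @export
dice <- function(c) {
  denom <- 2 * c$tp + c$fp + c$fn
  if (denom == 0) return(1)
  2 * c$tp / denom
}

#' Precision, recall, and pixel accuracy
#'
#' \code{precision = tp/(tp+fp)}, \code{recall = tp/(tp+fn)},
#' \code{accuracy = (tp+tn)/total}. Empty denominators return 1, consistent
#' with [iou()] and [dice()].
#'
#' @param c a \code{"confusion_counts"} object.
#' @return Number in \code{[0,1]}.
#' @export
precision <- function(c) {
  if (c$tp + c$fp == 0) return(1)
  c$tp / (c$tp + c$fp)
}

#' @rdname precision
#' @export
recall <- function(c) {
  if (c$tp + c$fn == 0) return(1)
  c$tp / (c$tp + c$fn)
}

#' @rdname precision
#' @export
accuracy <- function(c) {
  total <- c$tp + c$fp + c$fn + c$tn
  if (total == 0) return(1)
  (c$tp + c$tn) / total
}

#' All five evaluation metrics for one mask pair
#'
#' @param gt ground-truth binary mask.
#' @param pr_mask predicted binary mask.
#' @return Named numeric vector with \code{iou}, \code{dice},
#'   \code{precision}, \code{recall}, \code{accuracy}.
#' @export
evaluate_masks <- function(gt, pr_mask) {
  cc <- confusion(gt, pr_mask)
  c(iou = iou(cc), dice = dice(cc), precision = precision(cc),
    recall = recall(cc), accuracy = accuracy(cc))
}

#' Aggregate per-image metrics into a mean(SD) report
#'
#' One row per metric with its mean, sample standard deviation (\eqn{n-1}
#' denominator) and the number of images. A single image reports SD 0 with
#' \code{n = 1}. Rows are ordered by region, method, then metric name.
#'
#' @param per_image data frame with one row per image and one numeric column
#'   per metric (e.g. the output of [evaluate_masks()] row-bound).
#' @param region_label region the metrics describe.
#' @param method_label enhancement method the metrics describe.
#' @return Data frame with columns \code{region}, \code{method},
#'   \code{metric}, \code{mean}, \code{sd}, \code{n}.
#' @export
aggregate_report <- function(per_image, region_label, method_label) {
  per_image <- as.data.frame(per_image)
  num <- vapply(per_image, is.numeric, logical(1))
  per_image <- per_image[, num, drop = FALSE]
  if (nrow(per_image) == 0L || ncol(per_image) == 0L)
    stop("no per-image metrics to aggregate", call. = FALSE)
  n <- nrow(per_image)
  metrics <- sort(names(per_image))
  out <- data.frame(
    region = region_label,
    method = method_label,
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_image[[m]]), numeric(1)),
    sd = vapply(metrics, function(m)
      if (n > 1L) stats::sd(per_image[[m]]) else 0, numeric(1)),
    n = n,
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$region, out$method, out$metric), , drop = FALSE]
}

#' Welch's unequal-variance two-sample t-test
#'
#' The comparison used to contrast per-image Dice distributions between two
#' preprocessing methods: an independent-samples t-test that does not assume
#' equal variances, with Welch--Satterthwaite degrees of freedom and a
#' two-sided p-value.
#'
#' @param a,b numeric vectors, each of length >= 2 with positive variance.
#' @return List with elements \code{t}, \code{df}, \code{p}.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L ||
      !isTRUE(stats::var(a) > 0) || !isTRUE(stats::var(b) > 0))
    stop("degenerate sample", call. = FALSE)
  res <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Write a metric report as CSV
#'
#' @param report data frame from [aggregate_report()] (rows may be bound
#'   across regions/methods).
#' @param path destination CSV path.
#' @return The path, invisibly.
#' @export
write_metric_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
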