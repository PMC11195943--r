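# Soft segmentation losses on probability maps: the training objectives a
# segmenter would minimize (binary cross entropy, Jaccard loss, their sum,
# and Dice loss). All accept a binary ground-truth mask and a per-pixel
# foreground-probability map of the same shape.

check_loss_inputs <- function(gt, pr) {
  validate_mask(gt, arg = "gt")
  if (!is.matrix(pr) || !is.numeric(pr) || anyNA(pr) ||
      any(pr < 0) || any(pr > 1))
    stop("pr must be a probability map with values in [0,1]", call. = FALSE)
  if (!identical(dim(gt), dim(pr)))
    stop("image/mask shape mismatch", call. = FALSE)
}

#' Binary cross entropy loss
#'
#' Mean over pixels of \eqn{-gt \log pr - (1-gt)\log(1-pr)}, with
#' probabilities clipped to \code{[1e-7, 1 - 1e-7]} so the logarithms stay
#' finite at hard 0/1 predictions.
#'
#' @param gt binary ground-truth mask.
#' @param pr probability map in \code{[0,1]}, same shape.
#' @return Non-negative number.
#' @export
bce_loss <- function(gt, pr) {
  check_loss_inputs(gt, pr)
  eps <- 1e-7
  p <- pmin(pmax(pr, eps), 1 - eps)
  mean(-gt * log(p) - (1 - gt) * log(1 - p))
}

#' Jaccard (soft IoU) loss
#'
#' \eqn{1 - } soft IoU, where soft IoU is
#' \eqn{\sum gt\,pr / (\sum gt + \sum pr - \sum gt\,pr)} with a smoothing
#' constant of 1e-7 added to numerator and denominator.
#'
#' @inheritParams bce_loss
#' @return Number in \code{[0,1]}.
#' @export
jaccard_loss <- function(gt, pr) {
  check_loss_inputs(gt, pr)
  eps <- 1e-7
  inter <- sum(gt * pr)
  union <- sum(gt) + sum(pr) - inter
  1 - (inter + eps) / (union + eps)
}

#' Combined BCE + Jaccard loss
#'
#' The sum [bce_loss()] + [jaccard_loss()]: pixel-wise log loss plus an
#' overlap-maximizing term.
#'
#' @inheritParams bce_loss
#' @return Non-negative number.
#' @export
bce_jcd_loss <- function(gt, pr) {
  bce_loss(gt, pr) + jaccard_loss(gt, pr)
}

#' Dice loss
#'
#' \eqn{1 - } soft Dice, where soft Dice is
#' \eqn{2\sum gt\,pr / (\sum gt + \sum pr)} with 1e-7 smoothing.
#'
#' @inheritParams bce_loss
#' @return Number in \code{[0,1]}.
#' @export
dice_loss <- function(gt, pr) {
  check_loss_inputs(gt, pr)
  eps <- 1e-7
  inter <- sum(gt * pr)
  1 - (2 * inter + eps) / (sum(gt) + sum(pr) + eps)
}
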