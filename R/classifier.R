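# Desk-scale reference segmenter: a per-pixel Gaussian naive Bayes
# classifier on intensity. It exists to exercise the enhancement methods and
# the metric/loss machinery end to end; it is intentionally the simplest
# probabilistic segmenter whose output is a per-pixel foreground-probability
# map.

#' Train a per-pixel Gaussian intensity classifier
#'
#' Fits class-conditional normal distributions to the foreground
#' (mask = 1) and background (mask = 0) pixel intensities pooled over the
#' training images; the class prior is the foreground pixel fraction.
#' Standard deviations are floored at 1e-6 to keep the likelihoods proper
#' on constant regions.
#'
#' @param images list of grayscale image matrices (or a single matrix).
#' @param masks list of binary masks paired with \code{images}.
#' @return A list of class \code{"pixel_classifier"} with \code{fg_mean},
#'   \code{fg_sd}, \code{bg_mean}, \code{bg_sd}, \code{prior}.
#' @export
train_pixel_classifier <- function(images, masks) {
  if (is.matrix(images)) images <- list(images)
  if (is.matrix(masks)) masks <- list(masks)
  if (length(images) == 0L || length(images) != length(masks))
    stop("images and masks must be non-empty lists of equal length", call. = FALSE)
  fg <- unlist(lapply(seq_along(images), function(i) {
    validate_gray_image(images[[i]])
    validate_mask(masks[[i]], images[[i]])
    images[[i]][masks[[i]] == 1]
  }), use.names = FALSE)
  bg <- unlist(lapply(seq_along(images), function(i)
    images[[i]][masks[[i]] == 0]), use.names = FALSE)
  if (length(fg) == 0L || length(bg) == 0L)
    stop("degenerate training labels", call. = FALSE)
  sd_floor <- function(x) {
    s <- if (length(x) > 1L) stats::sd(x) else 0
    max(s, 1e-6)
  }
  structure(list(
    fg_mean = mean(fg), fg_sd = sd_floor(fg),
    bg_mean = mean(bg), bg_sd = sd_floor(bg),
    prior = length(fg) / (length(fg) + length(bg))),
    class = "pixel_classifier")
}

#' Per-pixel foreground probability map
#'
#' Posterior foreground probability by Bayes' rule on the two fitted
#' Gaussians. Pixels where both likelihoods underflow to zero get 0.5.
#'
#' @param image grayscale image matrix.
#' @param clf a \code{"pixel_classifier"}.
#' @return Matrix of probabilities in \code{[0,1]}, same shape as
#'   \code{image}.
#' @export
predict_probability <- function(image, clf) {
  validate_gray_image(image)
  stopifnot(inherits(clf, "pixel_classifier"))
  lf <- clf$prior * stats::dnorm(image, clf$fg_mean, clf$fg_sd)
  lb <- (1 - clf$prior) * stats::dnorm(image, clf$bg_mean, clf$bg_sd)
  tot <- lf + lb
  p <- ifelse(tot > 0, lf / tot, 0.5)
  matrix(pmin(pmax(p, 0), 1), nrow(image), ncol(image))
}
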