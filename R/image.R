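# Images are plain numeric matrices with intensities in [0,1]; masks are
# numeric/integer matrices with values in {0,1}. Validators below enforce
# the contracts at every public entry point.

#' Validate a grayscale image
#'
#' A grayscale image is a numeric matrix whose entries are finite and lie in
#' \code{[0,1]}. All enhancement operators in the package consume and produce
#' images in this form.
#'
#' @param image numeric matrix to check.
#' @param arg name used in error messages.
#' @return The image, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_gray_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    stop(sprintf("%s must be a numeric matrix", arg), call. = FALSE)
  if (nrow(image) < 1L || ncol(image) < 1L)
    stop(sprintf("%s must have positive dimensions", arg), call. = FALSE)
  if (anyNA(image) || any(!is.finite(image)))
    stop(sprintf("%s contains non-finite values", arg), call. = FALSE)
  if (any(image < 0) || any(image > 1))
    stop(sprintf("%s has intensities outside [0,1]", arg), call. = FALSE)
  invisible(image)
}

#' Validate a binary region mask
#'
#' @param mask matrix with values in \{0,1\}.
#' @param image optional paired image; shapes must agree when supplied.
#' @param arg name used in error messages.
#' @return The mask, invisibly, if valid.
#' @export
validate_mask <- function(mask, image = NULL, arg = "mask") {
  if (!is.matrix(mask) || !is.numeric(mask))
    stop(sprintf("%s must be a numeric matrix", arg), call. = FALSE)
  if (anyNA(mask) || !all(mask == 0 | mask == 1))
    stop(sprintf("%s must be strictly binary", arg), call. = FALSE)
  if (!is.null(image) && !identical(dim(mask), dim(image)))
    stop("image/mask shape mismatch", call. = FALSE)
  invisible(mask)
}

#' Read a grayscale PNG image
#'
#' 8-bit files map \code{\{0..255\}} to \code{value/255} exactly. Color PNGs
#' are reduced to grayscale by averaging the color channels.
#'
#' @param path file path.
#' @return Numeric matrix with intensities in \code{[0,1]}.
#' @export
read_gray_png <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) {
    nch <- dim(px)[3L]
    # average color channels, ignore alpha
    px <- apply(px[, , seq_len(min(nch, 3L)), drop = FALSE], c(1L, 2L), mean)
  }
  validate_gray_image(px, arg = path)
  px
}

#' Write a grayscale image as 8-bit PNG
#'
#' Intensities are quantized to \code{round(value * 255)} before writing, so
#' a write/read round trip reproduces the quantized matrix exactly.
#'
#' @param image numeric matrix in \code{[0,1]}.
#' @param path destination file path.
#' @return The path, invisibly.
#' @export
write_gray_png <- function(image, path) {
  validate_gray_image(image)
  q <- round(image * 255) / 255
  png::writePNG(q, target = path)
  invisible(path)
}

#' Read a binary mask PNG
#'
#' Any nonzero on-disk value reads as foreground (1).
#'
#' @param path file path.
#' @return Numeric matrix with values in \code{\{0,1\}}.
#' @export
read_mask_png <- function(path) {
  px <- read_gray_png(path)
  (px > 0) * 1
}

#' Write a binary mask as 8-bit PNG
#'
#' Foreground is stored as 255, background as 0.
#'
#' @param mask binary matrix.
#' @param path destination file path.
#' @return The path, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  validate_mask(mask)
  png::writePNG(mask * 1, target = path)
  invisible(path)
}

#' Anatomical regions of the chest-radiograph mask convention
#'
#' The five structures delineated per radiograph: heart, left and right lung,
#' left and right clavicle.
#'
#' @return Character vector of region labels.
#' @export
chest_regions <- function() {
  c("heart", "left_lung", "right_lung", "left_clavicle", "right_clavicle")
}
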