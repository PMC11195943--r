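# Paired image/mask geometric augmentation: random rotation, flips and
# isotropic zoom about the image center, then resize to a common output
# size. The same geometric transform is applied to the image (bilinear
# interpolation) and its mask (nearest neighbor, so binarity is preserved
# and the mask keeps delineating the same structure on the augmented image).

#' Augmentation configuration
#'
#' @param rotation_range maximum rotation in degrees either way; angles are
#'   drawn uniformly from \code{[-rotation_range, rotation_range]}.
#' @param h_flip_p,v_flip_p probabilities of horizontal / vertical flips.
#' @param zoom_range \code{c(low, high)} for the uniform isotropic zoom
#'   factor; values below 1 shrink the content (zoom out).
#' @param out_size output \code{c(height, width)} every augmented pair is
#'   resized to.
#' @param fill_value intensity used for image areas exposed by the
#'   transform; exposed mask areas are always background (0).
#' @param seed integer seed used by [expand_dataset()] for reproducible
#'   expansion.
#' @return A list of class \code{"augment_config"}.
#' @export
augment_config <- function(rotation_range = 90, h_flip_p = 0.5, v_flip_p = 0.5,
                           zoom_range = c(0.5, 1.5), out_size = c(256L, 256L),
                           fill_value = 0, seed = NULL) {
  if (rotation_range < 0) stop("rotation_range must be >= 0", call. = FALSE)
  if (h_flip_p < 0 || h_flip_p > 1 || v_flip_p < 0 || v_flip_p > 1)
    stop("flip probabilities must lie in [0,1]", call. = FALSE)
  if (length(zoom_range) != 2L || zoom_range[1] > zoom_range[2] ||
      any(zoom_range <= 0))
    stop("zoom_range must be 0 < low <= high", call. = FALSE)
  out_size <- as.integer(out_size)
  if (length(out_size) != 2L || anyNA(out_size) || any(out_size < 1L))
    stop("out_size must be two positive integers", call. = FALSE)
  if (fill_value < 0 || fill_value > 1)
    stop("fill_value must lie in [0,1]", call. = FALSE)
  structure(list(rotation_range = rotation_range, h_flip_p = h_flip_p,
                 v_flip_p = v_flip_p, zoom_range = as.numeric(zoom_range),
                 out_size = out_size, fill_value = fill_value, seed = seed),
            class = "augment_config")
}

#' Sample a random transform specification
#'
#' Draws angle ~ Uniform(-rotation_range, rotation_range), flips ~
#' Bernoulli(p) and zoom ~ Uniform(zoom_range) from R's current random
#' number stream, so results are reproducible under \code{set.seed()}.
#'
#' @param config an [augment_config()].
#' @return A list of class \code{"transform_spec"} with \code{angle} (deg),
#'   \code{h_flip}, \code{v_flip} (logicals) and \code{zoom}.
#' @export
sample_transform <- function(config) {
  stopifnot(inherits(config, "augment_config"))
  structure(list(
    angle = stats::runif(1, -config$rotation_range, config$rotation_range),
    h_flip = stats::runif(1) < config$h_flip_p,
    v_flip = stats::runif(1) < config$v_flip_p,
    zoom = stats::runif(1, config$zoom_range[1], config$zoom_range[2])),
    class = "transform_spec")
}

#' The identity transform specification
#'
#' @return A \code{"transform_spec"} that leaves geometry unchanged (the
#'   output is still resized to \code{out_size}).
#' @export
identity_transform <- function() {
  structure(list(angle = 0, h_flip = FALSE, v_flip = FALSE, zoom = 1),
            class = "transform_spec")
}

#' Apply one transform to an image/mask pair
#'
#' Rotation and zoom act about the image center; flips mirror the axes. The
#' image is resampled bilinearly, the mask by nearest neighbor so it stays
#' strictly binary. Both are produced directly at \code{config$out_size};
#' areas mapping outside the source are filled with \code{fill_value}
#' (image) and 0 (mask). Output intensities remain in \code{[0,1]}.
#'
#' Pure flips (and the identity) at unchanged size reproduce pixel values
#' exactly, because pixel centers map onto pixel centers; rotations by
#' multiples of 90 degrees likewise reduce to index permutations.
#'
#' @param image grayscale image matrix.
#' @param mask binary mask matrix, same shape.
#' @param spec a \code{"transform_spec"} from [sample_transform()].
#' @param config an [augment_config()].
#' @return List with elements \code{image} and \code{mask}.
#' @export
apply_pair <- function(image, mask, spec, config) {
  validate_gray_image(image)
  validate_mask(mask, image)
  stopifnot(inherits(spec, "transform_spec"), inherits(config, "augment_config"))

  src <- source_coords(dim(image), config$out_size, spec)
  img <- sample_bilinear(image, src$y, src$x, config$fill_value)
  msk <- sample_nearest(mask, src$y, src$x)
  list(image = pmin(pmax(img, 0), 1), mask = msk)
}

# Inverse mapping: for every output pixel center, the source coordinate in
# the input image (1-based row/col, fractional). cospi/sinpi keep multiples
# of 90 degrees exact.
source_coords <- function(in_dim, out_size, spec) {
  h_in <- in_dim[1L]; w_in <- in_dim[2L]
  h_out <- out_size[1L]; w_out <- out_size[2L]
  cy_in <- (h_in + 1) / 2; cx_in <- (w_in + 1) / 2
  cy_out <- (h_out + 1) / 2; cx_out <- (w_out + 1) / 2
  sy <- h_in / h_out; sx <- w_in / w_out

  yc <- (seq_len(h_out) - cy_out) * sy
  xc <- (seq_len(w_out) - cx_out) * sx
  yg <- matrix(yc, h_out, w_out)
  xg <- matrix(xc, h_out, w_out, byrow = TRUE)

  # inverse zoom, then inverse rotation, then flips
  yg <- yg / spec$zoom
  xg <- xg / spec$zoom
  co <- cospi(spec$angle / 180); si <- sinpi(spec$angle / 180)
  ys <- co * yg - si * xg
  xs <- si * yg + co * xg
  if (spec$h_flip) xs <- -xs
  if (spec$v_flip) ys <- -ys
  list(y = ys + cy_in, x = xs + cx_in)
}

sample_bilinear <- function(m, y, x, fill) {
  h <- nrow(m); w <- ncol(m)
  y0 <- floor(y); x0 <- floor(x)
  fy <- y - y0; fx <- x - x0
  get <- function(r, c) {
    inside <- r >= 1 & r <= h & c >= 1 & c <= w
    v <- matrix(fill, nrow(r), ncol(r))
    v[inside] <- m[cbind(r[inside], c[inside])]
    v
  }
  v00 <- get(y0, x0); v01 <- get(y0, x0 + 1)
  v10 <- get(y0 + 1, x0); v11 <- get(y0 + 1, x0 + 1)
  (1 - fy) * (1 - fx) * v00 + (1 - fy) * fx * v01 +
    fy * (1 - fx) * v10 + fy * fx * v11
}

sample_nearest <- function(m, y, x) {
  h <- nrow(m); w <- ncol(m)
  r <- round(y); c <- round(x)
  inside <- r >= 1 & r <= h & c >= 1 & c <= w
  v <- matrix(0, nrow(r), ncol(r))
  v[inside] <- m[cbind(r[inside], c[inside])]
  v
}

#' Expand a dataset k-fold by random augmentation
#'
#' Draws \code{k} independent transform specifications per input pair and
#' applies each, yielding exactly \code{k * length(images)} augmented pairs
#' (124 inputs with the default \code{k = 5} give 620). Reproducible given
#' \code{config$seed}.
#'
#' @param images list of grayscale image matrices.
#' @param masks list of binary masks, paired with \code{images}. Each element
#'   may also be a named list of masks (one per region); the same transform
#'   is then applied to the image and every mask.
#' @param config an [augment_config()]; \code{config$seed} seeds the draw.
#' @param k augmented copies per input, default 5.
#' @return List of \code{k * n} lists with elements \code{image},
#'   \code{mask} and \code{source} (index of the originating input).
#' @export
expand_dataset <- function(images, masks, config, k = 5L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be >= 1", call. = FALSE)
  if (length(images) == 0L || length(images) != length(masks))
    stop("images and masks must be non-empty lists of equal length", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  out <- vector("list", k * length(images))
  pos <- 0L
  for (i in seq_along(images)) {
    for (j in seq_len(k)) {
      spec <- sample_transform(config)
      pos <- pos + 1L
      if (is.list(masks[[i]])) {
        pair <- apply_pair(images[[i]], masks[[i]][[1L]], spec, config)
        ms <- lapply(masks[[i]], function(m)
          apply_pair(images[[i]], m, spec, config)$mask)
        out[[pos]] <- list(image = pair$image, mask = ms, source = i)
      } else {
        pair <- apply_pair(images[[i]], masks[[i]], spec, config)
        out[[pos]] <- list(image = pair$image, mask = pair$mask, source = i)
      }
    }
  }
  out
}
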