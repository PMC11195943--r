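# ps-KDE core: fit a per-region intensity density on training pixels, then
# substitute every pixel of an image with the (max-normalized) density of its
# intensity.

#' Fit a region-specific intensity density model
#'
#' Pools the intensities of all mask-foreground pixels across the training
#' images and fits a Gaussian kernel density estimate on a uniform grid over
#' \code{[0,1]}. The density is truncated to \code{[0,1]} and renormalized so
#' its trapezoidal integral over the grid is exactly 1; this is the "prior
#' knowledge" that [ps_kde_transform()] applies to new images.
#'
#' Duplicate intensity values are collapsed to a weighted sample before the
#' kernel sums are evaluated, which is algebraically identical to using the
#' raw pixel multiset but makes fitting on 8-bit images (at most 256 distinct
#' values) cheap regardless of image size.
#'
#' @param images a grayscale image matrix or list of them.
#' @param masks a binary mask matrix or list of them, shape-matched to
#'   \code{images}; foreground pixels (value 1) contribute to the fit.
#' @param bandwidth \code{"scott"} (default) for Scott's rule
#'   \eqn{h = \hat\sigma n^{-1/5}} on the pooled sample, or a positive number.
#'   A degenerate sample (single pixel, or zero spread) falls back to
#'   \code{1/255}, one 8-bit quantization step.
#' @param grid_size number of grid points over \code{[0,1]} inclusive;
#'   default 256, matching 8-bit quantization.
#' @param region_label label stored in the model (e.g. \code{"heart"}).
#' @return An object of class \code{"density_model"}: a list with elements
#'   \code{region_label}, \code{grid}, \code{density}, \code{bandwidth},
#'   \code{n_pixels} and \code{max_density}.
#' @seealso [density_at()], [ps_kde_transform()], [save_density_model()]
#' @examples
#' img <- matrix(runif(64), 8, 8)
#' msk <- matrix(rbinom(64, 1, 0.5), 8, 8)
#' m <- fit_density(img, msk, region_label = "demo")
#' m$bandwidth
#' @export
fit_density <- function(images, masks, bandwidth = "scott", grid_size = 256L,
                        region_label = "region") {
  if (is.matrix(images)) images <- list(images)
  if (is.matrix(masks)) masks <- list(masks)
  if (length(images) == 0L || length(images) != length(masks))
    stop("images and masks must be non-empty lists of equal length", call. = FALSE)
  grid_size <- as.integer(grid_size)
  if (is.na(grid_size) || grid_size < 2L)
    stop("grid_size must be an integer >= 2", call. = FALSE)

  xs <- unlist(lapply(seq_along(images), function(i) {
    validate_gray_image(images[[i]])
    validate_mask(masks[[i]], images[[i]])
    images[[i]][masks[[i]] == 1]
  }), use.names = FALSE)
  if (length(xs) == 0L)
    stop("no training pixels for region", call. = FALSE)

  n <- length(xs)
  if (is.character(bandwidth)) {
    if (!identical(bandwidth, "scott"))
      stop("invalid bandwidth", call. = FALSE)
    h <- if (n >= 2L) stats::sd(xs) * n^(-1 / 5) else 0
    if (!is.finite(h) || h <= 0) h <- 1 / 255   # degenerate sample fallback
  } else {
    h <- as.numeric(bandwidth)
    if (length(h) != 1L || !is.finite(h) || h <= 0)
      stop("invalid bandwidth", call. = FALSE)
  }

  # collapse duplicates to weights: exact, and O(distinct values) per grid point
  o <- order(xs)
  r <- rle(xs[o])
  u <- r$values
  w <- as.numeric(r$lengths)

  grid <- seq(0, 1, length.out = grid_size)
  raw <- vapply(grid, function(g) sum(w * stats::dnorm((g - u) / h)), numeric(1))
  raw <- raw / (n * h)

  z <- trapz(grid, raw)
  if (!is.finite(z) || z <= 0)
    stop("degenerate density fit: zero mass on [0,1]", call. = FALSE)
  density <- raw / z

  model <- structure(
    list(region_label = as.character(region_label),
         grid = grid,
         density = density,
         bandwidth = h,
         n_pixels = n,
         max_density = max(density)),
    class = "density_model")
  validate_density_model(model)
  model
}

# trapezoidal rule on an ordered grid
trapz <- function(x, y) {
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

#' Validate a density model's invariants
#'
#' Checks grid shape, non-negativity, unit trapezoidal mass (within 1e-9) and
#' consistency of \code{max_density}.
#'
#' @param model a \code{"density_model"} object.
#' @return The model, invisibly, if valid.
#' @export
validate_density_model <- function(model) {
  need <- c("region_label", "grid", "density", "bandwidth", "n_pixels",
            "max_density")
  if (!is.list(model) || !all(need %in% names(model)))
    stop("invalid density model file", call. = FALSE)
  g <- model$grid; d <- model$density
  if (length(g) < 2L || length(g) != length(d))
    stop("invalid density model file", call. = FALSE)
  if (g[1] != 0 || g[length(g)] != 1 || is.unsorted(g, strictly = TRUE))
    stop("density model grid must span [0,1]", call. = FALSE)
  if (any(!is.finite(d)) || any(d < 0))
    stop("density values must be finite and non-negative", call. = FALSE)
  if (abs(trapz(g, d) - 1) > 1e-9)
    stop("density does not integrate to 1", call. = FALSE)
  if (model$max_density != max(d) || model$max_density <= 0)
    stop("max_density inconsistent with density", call. = FALSE)
  if (!is.finite(model$bandwidth) || model$bandwidth <= 0)
    stop("invalid bandwidth", call. = FALSE)
  if (model$n_pixels < 1)
    stop("n_pixels must be positive", call. = FALSE)
  invisible(model)
}

#' Evaluate a density model at arbitrary intensities
#'
#' Linear interpolation between the two bracketing grid points; values that
#' hit a grid point return the tabulated density exactly.
#'
#' @param model a \code{"density_model"}.
#' @param v numeric vector of intensities in \code{[0,1]}.
#' @return Non-negative densities, same length as \code{v}.
#' @export
density_at <- function(model, v) {
  validate_density_model(model)
  if (anyNA(v) || any(v < 0) || any(v > 1))
    stop("intensity out of range", call. = FALSE)
  stats::approx(model$grid, model$density, xout = v, method = "linear")$y
}

#' Apply the ps-KDE pixel substitution to an image
#'
#' Every pixel intensity \eqn{v} is replaced by
#' \eqn{\hat f(v) / \max \hat f}, the model density at \eqn{v} divided by the
#' model's global maximum density. The division maps output into
#' \code{[0,1]} with a mapping that depends only on the model, never on the
#' image at hand, so the same intensity is rendered identically across
#' images. Intensities that occur frequently in the model's region come out
#' bright; rare ones come out dark.
#'
#' @param image grayscale image matrix.
#' @param model a \code{"density_model"} fitted with [fit_density()].
#' @return Enhanced image matrix in \code{[0,1]}.
#' @examples
#' img <- matrix(runif(64), 8, 8)
#' msk <- matrix(1, 8, 8)
#' m <- fit_density(img, msk)
#' out <- ps_kde_transform(img, m)
#' range(out)
#' @export
ps_kde_transform <- function(image, model) {
  validate_gray_image(image)
  d <- density_at(model, as.vector(image))
  matrix(d / model$max_density, nrow = nrow(image), ncol = ncol(image))
}

#' Save a density model to JSON
#'
#' Numbers are serialized with 17 significant digits, enough to reproduce
#' IEEE doubles bit-exactly on reload.
#'
#' @param model a \code{"density_model"}.
#' @param path destination file path.
#' @return The path, invisibly.
#' @export
save_density_model <- function(model, path) {
  validate_density_model(model)
  num <- function(x) sprintf("%.17g", x)
  vec <- function(x) paste0("[", paste(num(x), collapse = ","), "]")
  json <- paste0(
    "{\n",
    '  "schema_version": 1,\n',
    '  "region_label": ', jsonlite::toJSON(unbox_chr(model$region_label)), ",\n",
    '  "grid": ', vec(model$grid), ",\n",
    '  "density": ', vec(model$density), ",\n",
    '  "bandwidth": ', num(model$bandwidth), ",\n",
    '  "n_pixels": ', format(model$n_pixels), "\n",
    "}\n")
  writeLines(json, path, sep = "")
  invisible(path)
}

unbox_chr <- function(x) jsonlite::unbox(as.character(x))

#' Load a density model from JSON
#'
#' \code{max_density} is recomputed from the stored density; all model
#' invariants are re-validated on load.
#'
#' @param path file written by [save_density_model()].
#' @return A \code{"density_model"}.
#' @export
load_density_model <- function(path) {
  if (!file.exists(path)) stop("invalid density model file", call. = FALSE)
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stop("invalid density model file", call. = FALSE))
  need <- c("schema_version", "region_label", "grid", "density", "bandwidth",
            "n_pixels")
  if (!is.list(obj) || !all(need %in% names(obj)))
    stop("invalid density model file", call. = FALSE)
  if (!identical(as.numeric(obj$schema_version), 1))
    stop("unsupported model version", call. = FALSE)
  model <- structure(
    list(region_label = as.character(obj$region_label),
         grid = as.numeric(obj$grid),
         density = as.numeric(obj$density),
         bandwidth = as.numeric(obj$bandwidth),
         n_pixels = as.integer(obj$n_pixels),
         max_density = max(as.numeric(obj$density))),
    class = "density_model")
  validate_density_model(model)
  model
}

#' @export
print.density_model <- function(x, ...) {
  cat(sprintf("ps-KDE density model: region '%s'\n", x$region_label))
  cat(sprintf("  grid points: %d over [0,1]\n", length(x$grid)))
  cat(sprintf("  bandwidth:   %.6g\n", x$bandwidth))
  cat(sprintf("  fitted on:   %d pixels\n", x$n_pixels))
  cat(sprintf("  max density: %.6g\n", x$max_density))
  invisible(x)
}
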