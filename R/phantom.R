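# Synthetic chest phantom: one grayscale "radiograph" plus five binary
# structure masks (heart, two lungs, two clavicles), mirroring the layout of
# public chest-radiograph segmentation datasets. Each structure draws its
# pixel intensities from its own normal distribution, so the per-region
# intensity histograms genuinely differ -- the property the ps-KDE transform
# exploits.

#' Phantom configuration
#'
#' Geometry defaults are expressed relative to the image size: two large
#' lung ellipses, a heart ellipse between and below them, and two thin
#' slanted clavicle bars near the top, overlapping the lung apices as on a
#' projection radiograph. Intensity defaults give background 0.20,
#' lungs 0.35, heart 0.65 and clavicles 0.80 (SDs 0.05--0.06), plus global
#' additive noise with SD 0.02; samples are clipped to \code{[0,1]}.
#'
#' @param size image \code{c(height, width)}, default \code{c(256, 256)}.
#' @param intensities named list of \code{c(mean, sd)} per region plus
#'   \code{background}.
#' @param noise_sd global additive Gaussian noise SD.
#' @param geometry optional named list overriding the per-structure geometry;
#'   see the package source for the fields of each element.
#' @param seed integer seed; the same seed reproduces the phantom bit-exactly.
#' @return A list of class \code{"phantom_config"}.
#' @export
phantom_config <- function(size = c(256L, 256L),
                           intensities = list(
                             background = c(0.20, 0.05),
                             left_lung = c(0.35, 0.06),
                             right_lung = c(0.35, 0.06),
                             heart = c(0.65, 0.06),
                             left_clavicle = c(0.80, 0.05),
                             right_clavicle = c(0.80, 0.05)),
                           noise_sd = 0.02,
                           geometry = NULL,
                           seed = 1L) {
  size <- as.integer(size)
  if (length(size) != 2L || anyNA(size) || any(size < 16L))
    stop("size must be two integers >= 16", call. = FALSE)
  need <- c("background", chest_regions())
  if (!all(need %in% names(intensities)))
    stop("intensities must name background and all five regions", call. = FALSE)
  for (nm in need) {
    v <- intensities[[nm]]
    if (length(v) != 2L || v[1] < 0 || v[1] > 1 || v[2] <= 0)
      stop(sprintf("intensity spec for %s must be c(mean in [0,1], sd > 0)", nm),
           call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  h <- size[1L]; w <- size[2L]
  if (is.null(geometry)) {
    geometry <- list(
      # image columns run left to right as displayed; anatomical left/right
      # is not modeled, labels just key the five masks
      left_lung = list(type = "ellipse", center = c(0.53 * h, 0.30 * w),
                       semi_axes = c(0.27 * h, 0.15 * w)),
      right_lung = list(type = "ellipse", center = c(0.53 * h, 0.70 * w),
                        semi_axes = c(0.27 * h, 0.15 * w)),
      heart = list(type = "ellipse", center = c(0.62 * h, 0.50 * w),
                   semi_axes = c(0.18 * h, 0.14 * w)),
      left_clavicle = list(type = "bar", center = c(0.22 * h, 0.28 * w),
                           length = 0.30 * w, thickness = 0.04 * h,
                           angle = -10),
      right_clavicle = list(type = "bar", center = c(0.22 * h, 0.72 * w),
                            length = 0.30 * w, thickness = 0.04 * h,
                            angle = 10))
  }
  cfg <- structure(list(size = size, intensities = intensities,
                        noise_sd = noise_sd, geometry = geometry,
                        seed = seed),
                   class = "phantom_config")
  check_geometry(cfg)
  cfg
}

check_geometry <- function(cfg) {
  h <- cfg$size[1L]; w <- cfg$size[2L]
  for (nm in chest_regions()) {
    g <- cfg$geometry[[nm]]
    if (is.null(g)) stop(sprintf("geometry missing for %s", nm), call. = FALSE)
    bb <- if (g$type == "ellipse") {
      c(g$center[1] - g$semi_axes[1], g$center[1] + g$semi_axes[1],
        g$center[2] - g$semi_axes[2], g$center[2] + g$semi_axes[2])
    } else {
      half <- sqrt((g$length / 2)^2 + (g$thickness / 2)^2)
      c(g$center[1] - half, g$center[1] + half,
        g$center[2] - half, g$center[2] + half)
    }
    if (bb[1] < 0.5 || bb[2] > h + 0.5 || bb[3] < 0.5 || bb[4] > w + 0.5)
      stop("geometry out of bounds", call. = FALSE)
  }
  invisible(cfg)
}

rasterize_shape <- function(g, size) {
  h <- size[1L]; w <- size[2L]
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  if (g$type == "ellipse") {
    d <- ((rows - g$center[1]) / g$semi_axes[1])^2 +
      ((cols - g$center[2]) / g$semi_axes[2])^2
    (d <= 1) * 1
  } else if (g$type == "bar") {
    # rotated rectangle: distance along/across the center line
    co <- cospi(g$angle / 180); si <- sinpi(g$angle / 180)
    dy <- rows - g$center[1]; dx <- cols - g$center[2]
    along <- co * dx + si * dy
    across <- -si * dx + co * dy
    (abs(along) <= g$length / 2 & abs(across) <= g$thickness / 2) * 1
  } else stop(sprintf("unknown shape type '%s'", g$type), call. = FALSE)
}

#' Generate one synthetic chest phantom
#'
#' Rasterizes the five structure masks, assigns each pixel to one generating
#' region with priority clavicles > heart > lungs > background (a clavicle
#' projected over a lung owns its pixels, as on a radiograph), samples the
#' pixel intensity from the owning region's normal distribution, adds global
#' Gaussian noise and clips to \code{[0,1]}. The emitted masks are the full
#' rasterized shapes, including parts occluded by a higher-priority
#' structure, mirroring independent per-structure ground-truth masks.
#'
#' @param config a [phantom_config()].
#' @param seed optional override of \code{config$seed}; \code{NULL} there
#'   (and here) uses the current random stream.
#' @return List with \code{image} (grayscale matrix) and \code{masks}
#'   (named list of five binary matrices).
#' @export
generate_phantom <- function(config = phantom_config(), seed = config$seed) {
  stopifnot(inherits(config, "phantom_config"))
  check_geometry(config)
  if (!is.null(seed)) set.seed(seed)
  h <- config$size[1L]; w <- config$size[2L]

  masks <- lapply(config$geometry[chest_regions()], rasterize_shape,
                  size = config$size)
  names(masks) <- chest_regions()

  # ownership by priority: clavicles > heart > lungs > background
  owner <- matrix("background", h, w)
  for (nm in c("left_lung", "right_lung", "heart",
               "left_clavicle", "right_clavicle"))
    owner[masks[[nm]] == 1] <- nm

  img <- matrix(0, h, w)
  for (nm in unique(as.vector(owner))) {
    sel <- owner == nm
    par <- config$intensities[[nm]]
    img[sel] <- stats::rnorm(sum(sel), par[1], par[2])
  }
  if (config$noise_sd > 0)
    img <- img + stats::rnorm(h * w, 0, config$noise_sd)
  img <- pmin(pmax(img, 0), 1)
  list(image = img, masks = masks)
}

#' Write a phantom dataset to disk
#'
#' Generates \code{n} phantoms and writes them as 8-bit PNGs in the layout
#' \code{images/phantom_###.png} and \code{masks/<region>/phantom_###.png},
#' plus a \code{manifest.csv} listing every file with the seed used.
#' Phantom \code{i} uses seed \code{seed + i}, so runs with the same seed
#' are byte-identical.
#'
#' @param n number of phantoms, >= 1.
#' @param config a [phantom_config()].
#' @param seed base integer seed.
#' @param out_dir output directory (created if needed).
#' @return Path to the manifest CSV, invisibly.
#' @export
generate_dataset <- function(n, config = phantom_config(), seed = 1L,
                             out_dir) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  for (r in chest_regions())
    dir.create(file.path(out_dir, "masks", r), recursive = TRUE,
               showWarnings = FALSE)
  rows <- list()
  for (i in seq_len(n)) {
    ph <- generate_phantom(config, seed = seed + i)
    base <- sprintf("phantom_%03d.png", i)
    write_gray_png(ph$image, file.path(out_dir, "images", base))
    for (r in chest_regions()) {
      mp <- file.path("masks", r, base)
      write_mask_png(ph$masks[[r]], file.path(out_dir, mp))
      rows[[length(rows) + 1L]] <- data.frame(
        filename = file.path("images", base), region = r, mask_path = mp,
        seed = seed + i, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Load a phantom-style dataset from disk
#'
#' Reads the \code{images/} + \code{masks/<region>/} layout written by
#' [generate_dataset()] (or arranged manually from any paired
#' image/mask PNG collection).
#'
#' @param dir dataset directory.
#' @param regions regions to load masks for; defaults to every subdirectory
#'   of \code{masks/}.
#' @return List with \code{files} (basenames), \code{images} (list of
#'   matrices) and \code{masks} (named list of lists, one per region).
#' @export
load_dataset <- function(dir, regions = NULL) {
  img_dir <- file.path(dir, "images")
  if (!dir.exists(img_dir)) stop("no images/ directory found", call. = FALSE)
  files <- sort(list.files(img_dir, pattern = "\\.png$"))
  if (length(files) == 0L) stop("dataset directory is empty", call. = FALSE)
  if (is.null(regions))
    regions <- sort(list.dirs(file.path(dir, "masks"), recursive = FALSE,
                              full.names = FALSE))
  images <- lapply(files, function(f) read_gray_png(file.path(img_dir, f)))
  masks <- lapply(regions, function(r)
    lapply(files, function(f) read_mask_png(file.path(dir, "masks", r, f))))
  names(masks) <- regions
  list(files = files, images = images, masks = masks)
}
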