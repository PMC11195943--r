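# Histogram-based baseline enhancers: global histogram equalization and
# contrast-limited adaptive histogram equalization (CLAHE).

#' Global histogram equalization
#'
#' Bins intensities into \code{n_bins} equal-width bins over \code{[0,1]} and
#' maps each pixel to the normalized cumulative histogram of its bin, so the
#' output distribution is approximately uniform. The mapping is monotone
#' non-decreasing in input intensity.
#'
#' @param image grayscale image matrix in \code{[0,1]}.
#' @param n_bins number of histogram bins, default 256.
#' @return Equalized image matrix in \code{[0,1]}.
#' @export
hist_equalize <- function(image, n_bins = 256L) {
  validate_gray_image(image)
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) stop("n_bins must be >= 2", call. = FALSE)
  b <- bin_index(image, n_bins)
  h <- tabulate(b, nbins = n_bins)
  cdf <- cumsum(h) / length(image)
  matrix(cdf[b], nrow = nrow(image), ncol = ncol(image))
}

# 1-based equal-width bin index over [0,1]; intensity 1 joins the last bin
bin_index <- function(image, n_bins) {
  b <- pmin(floor(image * n_bins) + 1, n_bins)
  storage.mode(b) <- "integer"
  b
}

#' CLAHE configuration
#'
#' @param clip_limit relative clip factor, a dimensionless multiple of the
#'   uniform bin height \code{tile_pixels / n_bins}; must be >= 1.
#'   \code{Inf} disables clipping (plain adaptive equalization).
#' @param tiles integer vector \code{c(rows, cols)} of the tile grid.
#' @param n_bins histogram bins per tile.
#' @return A list of class \code{"clahe_config"}.
#' @export
clahe_config <- function(clip_limit = 2, tiles = c(8L, 8L), n_bins = 256L) {
  tiles <- as.integer(tiles)
  n_bins <- as.integer(n_bins)
  if (length(clip_limit) != 1L || is.na(clip_limit) || clip_limit < 1)
    stop("invalid clip limit", call. = FALSE)
  if (length(tiles) != 2L || anyNA(tiles) || any(tiles < 1L))
    stop("tiles must be two positive integers", call. = FALSE)
  if (is.na(n_bins) || n_bins < 2L)
    stop("n_bins must be >= 2", call. = FALSE)
  structure(list(clip_limit = as.numeric(clip_limit), tiles = tiles,
                 n_bins = n_bins),
            class = "clahe_config")
}

#' Contrast-limited adaptive histogram equalization
#'
#' The image is partitioned into a grid of tiles. Each tile's histogram is
#' clipped at \code{clip_limit} times the uniform bin height; the clipped
#' excess is redistributed uniformly over all bins in a single pass, with the
#' integer remainder added one count per bin starting from bin 1. Each tile's
#' clipped histogram yields a cumulative-distribution mapping, and every
#' output pixel is the bilinear blend of the four nearest tile-center
#' mappings (replicated at the borders), which suppresses tile-seam
#' artifacts while capping local contrast amplification.
#'
#' @param image grayscale image matrix; must be at least as large as the tile
#'   grid in both dimensions.
#' @param config a [clahe_config()].
#' @return Enhanced image matrix in \code{[0,1]}.
#' @export
clahe <- function(image, config = clahe_config()) {
  validate_gray_image(image)
  if (!inherits(config, "clahe_config"))
    config <- do.call(clahe_config, as.list(config))
  tr <- config$tiles[1L]; tc <- config$tiles[2L]
  nb <- config$n_bins
  h_img <- nrow(image); w_img <- ncol(image)
  if (tr > h_img || tc > w_img) stop("tile grid exceeds image", call. = FALSE)

  rb <- floor(seq(0, h_img, length.out = tr + 1L))  # tile row boundaries
  cb <- floor(seq(0, w_img, length.out = tc + 1L))
  b <- bin_index(image, nb)

  # per-tile CDF mappings, M[tile_row, tile_col, bin]
  m <- array(0, dim = c(tr, tc, nb))
  for (i in seq_len(tr)) {
    for (j in seq_len(tc)) {
      tile_b <- b[(rb[i] + 1L):rb[i + 1L], (cb[j] + 1L):cb[j + 1L]]
      hist <- tabulate(tile_b, nbins = nb)
      hist <- clip_redistribute(hist, config$clip_limit)
      m[i, j, ] <- cumsum(hist) / length(tile_b)
    }
  }

  # bilinear blend of the four nearest tile-center mappings
  ctr_r <- (rb[-length(rb)] + rb[-1] + 1) / 2  # tile center row coordinates
  ctr_c <- (cb[-length(cb)] + cb[-1] + 1) / 2
  ry <- blend_coords(seq_len(h_img), ctr_r)
  cx <- blend_coords(seq_len(w_img), ctr_c)

  idx <- function(t_r, t_c) {
    # linear index into m for each pixel at its own bin
    t_r + tr * ((t_c - 1L) + tc * (b - 1L))
  }
  t0r <- matrix(ry$lo, h_img, w_img); t1r <- matrix(ry$hi, h_img, w_img)
  wr <- matrix(ry$w, h_img, w_img)
  t0c <- matrix(cx$lo, h_img, w_img, byrow = TRUE)
  t1c <- matrix(cx$hi, h_img, w_img, byrow = TRUE)
  wc <- matrix(cx$w, h_img, w_img, byrow = TRUE)

  out <- wr * wc * m[idx(t0r, t0c)] +
    wr * (1 - wc) * m[idx(t0r, t1c)] +
    (1 - wr) * wc * m[idx(t1r, t0c)] +
    (1 - wr) * (1 - wc) * m[idx(t1r, t1c)]
  matrix(out, h_img, w_img)
}

# For each pixel coordinate, the two bracketing tile centers and the weight
# on the lower one; clamped replication outside the outermost centers.
blend_coords <- function(pos, centers) {
  k <- length(centers)
  lo <- findInterval(pos, centers)
  hi <- pmin(lo + 1L, k)
  lo <- pmax(lo, 1L)
  w <- rep(1, length(pos))
  inner <- hi > lo
  w[inner] <- (centers[hi[inner]] - pos[inner]) /
    (centers[hi[inner]] - centers[lo[inner]])
  w[pos <= centers[1]] <- 1
  lo[pos <= centers[1]] <- 1L; hi[pos <= centers[1]] <- 1L
  list(lo = lo, hi = hi, w = w)
}

# Clip a tile histogram at clip_limit * uniform height and redistribute the
# excess uniformly in one pass; integer remainder goes one count per bin from
# the first bin upward. Total mass is conserved exactly.
clip_redistribute <- function(hist, clip_limit) {
  nb <- length(hist)
  if (!is.finite(clip_limit)) return(hist)
  clip <- max(1L, as.integer(floor(clip_limit * sum(hist) / nb)))
  clipped <- pmin(hist, clip)
  excess <- sum(hist) - sum(clipped)
  if (excess > 0L) {
    base <- excess %/% nb
    rem <- excess %% nb
    clipped <- clipped + base
    if (rem > 0L) clipped[seq_len(rem)] <- clipped[seq_len(rem)] + 1L
  }
  clipped
}
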