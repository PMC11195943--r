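# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths: plain loops and formula transcriptions.

# Brute-force Gaussian KDE truncated to [0,1]: density at arbitrary points,
# renormalized by the trapezoidal integral over `grid`, then evaluated by
# piecewise-linear interpolation (same contract as the fitted model).
oracle_kde <- function(xs, h, grid = seq(0, 1, length.out = 256)) {
  raw <- vapply(grid, function(g)
    sum(stats::dnorm((g - xs) / h)) / (length(xs) * h), numeric(1))
  z <- sum(diff(grid) * (raw[-length(raw)] + raw[-1]) / 2)
  dens <- raw / z
  list(grid = grid, density = dens,
       at = function(v) stats::approx(grid, dens, xout = v)$y)
}

# Brute-force single-tile clipped histogram equalization on one image.
oracle_clipped_he <- function(image, clip_limit, n_bins) {
  b <- pmin(floor(image * n_bins) + 1, n_bins)
  h <- tabulate(b, nbins = n_bins)
  if (is.finite(clip_limit)) {
    clip <- max(1, floor(clip_limit * length(image) / n_bins))
    excess <- sum(pmax(h - clip, 0))
    h <- pmin(h, clip)
    h <- h + excess %/% n_bins
    rem <- excess %% n_bins
    if (rem > 0) h[1:rem] <- h[1:rem] + 1
  }
  cdf <- cumsum(h) / length(image)
  matrix(cdf[b], nrow(image), ncol(image))
}

random_mask <- function(h, w, p = 0.5) {
  matrix(rbinom(h * w, 1, p), h, w)
}

random_image <- function(h, w) {
  matrix(runif(h * w), h, w)
}

# 8-bit-quantized random image, the form produced by a PNG round trip
random_image_8bit <- function(h, w) {
  matrix(sample(0:255, h * w, replace = TRUE) / 255, h, w)
}
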