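four_pixel_model <- function(h = 0.1, grid_size = 256) {
  img <- matrix(c(0.2, 0.4, 0.4, 0.8), 2, 2)
  fit_density(img, matrix(1, 2, 2), bandwidth = h, grid_size = grid_size)
}

test_that("fitted density matches the brute-force Gaussian-sum oracle", {
  m <- four_pixel_model(h = 0.1)
  o <- oracle_kde(c(0.2, 0.4, 0.4, 0.8), 0.1)
  expect_equal(density_at(m, 0.4), o$at(0.4), tolerance = 1e-9)
  set.seed(21)
  v <- runif(1000)
  expect_equal(density_at(m, v), o$at(v), tolerance = 1e-9)
})

test_that("single-value sample yields a symmetric density peaked at the value", {
  img <- matrix(0.5, 3, 3)
  m <- fit_density(img, matrix(1, 3, 3))          # sd = 0 -> 1/255 fallback
  expect_equal(m$bandwidth, 1 / 255)
  # 0.5 sits midway between two grid points; argmax must be one of them
  expect_lte(abs(m$grid[which.max(m$density)] - 0.5), 1 / 255)
  # symmetry about 0.5 on symmetric query pairs
  d <- 0.3
  expect_equal(density_at(m, 0.5 - d), density_at(m, 0.5 + d),
               tolerance = 1e-9)
})

test_that("fit_density enforces its input contracts", {
  img <- matrix(0.5, 2, 2)
  expect_error(fit_density(img, matrix(0, 2, 2)), "no training pixels")
  expect_error(fit_density(img, matrix(1, 3, 3)), "shape mismatch")
  expect_error(fit_density(img, matrix(1, 2, 2), bandwidth = -0.1),
               "invalid bandwidth")
  expect_error(fit_density(img, matrix(1, 2, 2), bandwidth = 0),
               "invalid bandwidth")
})

test_that("every fitted model integrates to unit mass (trapezoid, 1e-9)", {
  set.seed(22)
  for (i in 1:10) {
    img <- random_image(12, 12)
    msk <- random_mask(12, 12)
    if (sum(msk) == 0) msk[1, 1] <- 1
    m <- fit_density(img, msk)
    g <- m$grid; d <- m$density
    expect_lt(abs(sum(diff(g) * (d[-length(d)] + d[-1]) / 2) - 1), 1e-9)
  }
})

test_that("density_at interpolates linearly and rejects out-of-range input", {
  m <- four_pixel_model()
  k <- 37
  expect_identical(density_at(m, m$grid[k]), m$density[k])
  mid <- (m$grid[k] + m$grid[k + 1]) / 2
  expect_equal(density_at(m, mid), (m$density[k] + m$density[k + 1]) / 2,
               tolerance = 1e-12)
  expect_error(density_at(m, -0.01), "out of range")
  expect_error(density_at(m, 1.01), "out of range")
})

test_that("ps_kde_transform divides by the global max density", {
  m <- four_pixel_model()
  img <- matrix(c(0.2, 0.4, 0.4, 0.8), 2, 2)
  out <- ps_kde_transform(img, m)
  o <- oracle_kde(c(0.2, 0.4, 0.4, 0.8), 0.1)
  expect_equal(as.vector(out), o$at(as.vector(img)) / max(o$density),
               tolerance = 1e-9)
  # argmax-density input maps to exactly 1
  peak <- m$grid[which.max(m$density)]
  expect_identical(ps_kde_transform(matrix(peak, 2, 2), m),
                   matrix(1, 2, 2))
  # equal inputs map to equal outputs
  expect_identical(out[2, 1], out[1, 2])
  expect_true(all(out >= 0 & out <= 1))
})

test_that("density order and transformed order agree (frequency monotonicity)", {
  set.seed(23)
  m <- four_pixel_model()
  a <- runif(500); b <- runif(500)
  da <- density_at(m, a); db <- density_at(m, b)
  oa <- as.vector(ps_kde_transform(matrix(a, 25, 20), m))
  ob <- as.vector(ps_kde_transform(matrix(b, 25, 20), m))
  expect_identical(da > db, oa > ob)
})

test_that("weighted fit on duplicated 8-bit values equals raw multiset fit", {
  set.seed(24)
  img <- random_image_8bit(40, 40)
  msk <- random_mask(40, 40)
  m1 <- fit_density(img, msk)
  # same multiset presented in scrambled order, different image shape
  xs <- img[msk == 1]
  perm <- sample(length(xs))
  img2 <- matrix(xs[perm], nrow = 1)
  m2 <- fit_density(img2, matrix(1, 1, length(xs)))
  expect_equal(m1$density, m2$density, tolerance = 1e-12)
  expect_equal(m1$bandwidth, m2$bandwidth, tolerance = 1e-15)
})

test_that("Scott's rule bandwidth is sd * n^(-1/5) on the pooled sample", {
  set.seed(25)
  img <- random_image(10, 10)
  m <- fit_density(img, matrix(1, 10, 10))
  expect_equal(m$bandwidth, sd(img) * 100^(-1 / 5), tolerance = 1e-12)
})

test_that("model JSON round trip is bit-exact and validates on load", {
  set.seed(26)
  img <- random_image(9, 9)
  m <- fit_density(img, matrix(1, 9, 9), region_label = "heart")
  path <- withr::local_tempfile(fileext = ".json")
  save_density_model(m, path)
  back <- load_density_model(path)
  expect_identical(back$grid, m$grid)
  expect_identical(back$density, m$density)
  expect_identical(back$bandwidth, m$bandwidth)
  expect_identical(as.integer(back$n_pixels), as.integer(m$n_pixels))
  expect_identical(back$region_label, m$region_label)
  expect_identical(back$max_density, m$max_density)
})

test_that("malformed or mismatched model files are rejected", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"schema_version": 1, "region_label": "x"}', path)
  expect_error(load_density_model(path), "invalid density model file")
  writeLines("not json at all {", path)
  expect_error(load_density_model(path), "invalid density model file")
  # version bump
  m <- four_pixel_model()
  save_density_model(m, path)
  txt <- sub('"schema_version": 1', '"schema_version": 2', readLines(path))
  writeLines(txt, path)
  expect_error(load_density_model(path), "unsupported model version")
})

test_that("hand-written minimal model loads; non-normalized variant is rejected", {
  path <- withr::local_tempfile(fileext = ".json")
  # G = 2 uniform density on [0,1]: integrates to 1 exactly
  writeLines(paste0('{"schema_version": 1, "region_label": "tiny",',
                    '"grid": [0, 1], "density": [1, 1],',
                    '"bandwidth": 0.1, "n_pixels": 4}'), path)
  m <- load_density_model(path)
  expect_equal(density_at(m, 0.25), 1)
  writeLines(paste0('{"schema_version": 1, "region_label": "tiny",',
                    '"grid": [0, 1], "density": [2, 2],',
                    '"bandwidth": 0.1, "n_pixels": 4}'), path)
  expect_error(load_density_model(path), "integrate")
})
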