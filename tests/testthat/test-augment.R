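spec_of <- function(angle = 0, h = FALSE, v = FALSE, zoom = 1)
  structure(list(angle = angle, h_flip = h, v_flip = v, zoom = zoom),
            class = "transform_spec")

small_cfg <- function(n = 8L, ...)
  augment_config(out_size = c(n, n), ...)

test_that("sample_transform draws within the configured ranges, deterministically", {
  cfg <- augment_config()
  set.seed(61); s1 <- sample_transform(cfg)
  set.seed(61); s2 <- sample_transform(cfg)
  expect_identical(s1, s2)
  expect_lte(abs(s1$angle), 90)
  expect_true(s1$zoom >= 0.5 && s1$zoom <= 1.5)

  frozen <- augment_config(rotation_range = 0, h_flip_p = 0, v_flip_p = 0,
                           zoom_range = c(1, 1))
  s <- sample_transform(frozen)
  expect_equal(s$angle, 0)
  expect_false(s$h_flip || s$v_flip)
  expect_equal(s$zoom, 1)
})

test_that("horizontal flip frequency is close to its probability", {
  cfg <- augment_config()
  set.seed(42)
  flips <- replicate(10000, sample_transform(cfg)$h_flip)
  expect_lt(abs(mean(flips) - 0.5), 0.02)
})

test_that("identity spec at native size reproduces the input exactly", {
  set.seed(62)
  img <- random_image(8, 8); msk <- random_mask(8, 8)
  out <- apply_pair(img, msk, spec_of(), small_cfg(8L))
  expect_equal(out$image, img, tolerance = 1e-12)
  expect_identical(out$mask, msk * 1)
})

test_that("flips are exact index reflections and involutions", {
  set.seed(63)
  img <- random_image(9, 9); msk <- random_mask(9, 9)
  cfg <- small_cfg(9L)

  hf <- apply_pair(img, msk, spec_of(h = TRUE), cfg)
  expect_equal(hf$image, img[, 9:1], tolerance = 1e-12)
  expect_identical(hf$mask, msk[, 9:1] * 1)

  # single marked pixel at (1,1) moves to (1,9) in image and mask alike
  one <- matrix(0, 9, 9); one[1, 1] <- 1
  m1 <- apply_pair(one, one, spec_of(h = TRUE), cfg)
  expect_identical(which(m1$mask == 1), which(m1$image == 1))
  expect_identical(m1$mask[1, 9], 1)
  expect_equal(sum(m1$mask), 1)

  vf <- apply_pair(img, msk, spec_of(v = TRUE), cfg)
  twice <- apply_pair(vf$image, vf$mask, spec_of(v = TRUE), cfg)
  expect_equal(twice$image, img, tolerance = 0)
  expect_identical(twice$mask, msk * 1)
  # foreground count conserved under pure flips
  expect_equal(sum(vf$mask), sum(msk))
})

test_that("90-degree rotation equals the explicit index permutation", {
  set.seed(64)
  img <- random_image(5, 5); msk <- random_mask(5, 5)
  out <- apply_pair(img, msk, spec_of(angle = 90), small_cfg(5L))
  # positive angle rotates the displayed image clockwise:
  # out[i, j] = in[n + 1 - j, i]
  perm <- function(m) {
    n <- nrow(m)
    o <- m
    for (i in seq_len(n)) for (j in seq_len(n)) o[i, j] <- m[n + 1 - j, i]
    o
  }
  expect_equal(out$image, perm(img), tolerance = 1e-9)
  expect_identical(out$mask, perm(msk) * 1)
})

test_that("masks stay binary through random composite transforms", {
  set.seed(65)
  cfg <- small_cfg(16L)
  img <- random_image(24, 24)
  msk <- random_mask(24, 24)
  for (i in 1:200) {
    out <- apply_pair(img, msk, sample_transform(cfg), cfg)
    expect_true(all(out$mask %in% c(0, 1)))
    expect_true(all(out$image >= 0 & out$image <= 1))
    expect_identical(dim(out$image), c(16L, 16L))
  }
})

test_that("zoom-out exposes borders filled with fill_value and background", {
  img <- matrix(1, 8, 8); msk <- matrix(1, 8, 8)
  out <- apply_pair(img, msk, spec_of(zoom = 0.5),
                    small_cfg(8L, zoom_range = c(0.5, 1.5), fill_value = 0))
  expect_equal(out$image[1, 1], 0)
  expect_identical(out$mask[1, 1], 0)
  expect_identical(out$mask[4, 4], 1)
})

test_that("expand_dataset yields exactly k outputs per input, reproducibly", {
  set.seed(66)
  imgs <- lapply(1:124, function(i) random_image(4, 4))
  msks <- lapply(1:124, function(i) random_mask(4, 4))
  cfg <- augment_config(out_size = c(4L, 4L), seed = 99)
  out <- expand_dataset(imgs, msks, cfg, k = 5)
  expect_length(out, 620L)
  expect_identical(vapply(out, `[[`, integer(1), "source"),
                   rep(1:124, each = 5L))
  out2 <- expand_dataset(imgs, msks, cfg, k = 5)
  expect_identical(out, out2)
  expect_true(all(vapply(out, function(o) all(o$mask %in% c(0, 1)),
                         logical(1))))
})

test_that("expand_dataset with identity config only resizes", {
  img <- random_image(6, 6); msk <- random_mask(6, 6)
  cfg <- augment_config(rotation_range = 0, h_flip_p = 0, v_flip_p = 0,
                        zoom_range = c(1, 1), out_size = c(6L, 6L), seed = 1)
  out <- expand_dataset(list(img), list(msk), cfg, k = 1)
  expect_equal(out[[1]]$image, img, tolerance = 1e-12)
  expect_identical(out[[1]]$mask, msk * 1)
  expect_error(expand_dataset(list(img), list(msk), cfg, k = 0), "k must be")
})
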