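# End-to-end evaluation pipeline: split a dataset, fit the enhancement per
# arm on the training half only, train the reference segmenter, score the
# validation half, and write Table-style mean(SD) reports plus per-image
# metrics and probability-map renderings.

#' Apply an enhancement method to a list of images
#'
#' @param images list of grayscale image matrices.
#' @param method one of \code{"none"}, \code{"he"}, \code{"clahe"},
#'   \code{"pskde"}.
#' @param model a \code{"density_model"}, required for \code{"pskde"}.
#' @param clahe_cfg a [clahe_config()], used for \code{"clahe"}.
#' @return List of enhanced image matrices.
#' @export
enhance_images <- function(images, method, model = NULL,
                           clahe_cfg = clahe_config()) {
  switch(method,
    none = images,
    he = lapply(images, hist_equalize),
    clahe = lapply(images, clahe, config = clahe_cfg),
    pskde = {
      if (is.null(model))
        stop("pskde enhancement needs a fitted density model", call. = FALSE)
      lapply(images, ps_kde_transform, model = model)
    },
    stop(sprintf("unknown method name '%s'", method), call. = FALSE))
}

#' Run a full enhancement-comparison experiment
#'
#' Loads a dataset in the \code{images/} + \code{masks/<region>/} layout,
#' shuffles the file order under \code{seed} and splits it
#' \code{split}/\code{1-split} into training and validation halves. For each
#' method arm and region: the enhancement is fitted on the training half
#' only (ps-KDE density models see no validation pixels), all images are
#' enhanced, a Gaussian naive-Bayes pixel classifier is trained on the
#' enhanced training half, validation probability maps are thresholded at
#' 0.5, and IoU, Dice, precision, recall and accuracy are computed per
#' validation image. Writes, under \code{out_dir}: \code{report_<method>.csv}
#' (mean(SD) per region and metric), \code{per_image_<method>.csv}, and
#' grayscale probability-map PNGs under \code{prob_maps/}.
#'
#' @param data_dir dataset directory (see [generate_dataset()]).
#' @param regions character vector of region labels to evaluate.
#' @param methods character vector of arms, subset of
#'   \code{c("none","he","clahe","pskde")}.
#' @param seed integer seed controlling the split.
#' @param out_dir output directory.
#' @param split training fraction, default 0.5.
#' @param augment_k if > 0, expand the training half \code{augment_k}-fold by
#'   random augmentation (validation images are never augmented).
#' @param augment_cfg an [augment_config()] used when \code{augment_k > 0};
#'   its \code{out_size} must match the dataset image size.
#' @param clahe_cfg a [clahe_config()] for the \code{"clahe"} arm.
#' @param write_prob_maps write probability-map PNGs (default TRUE).
#' @return Invisibly, a list with \code{report} (combined data frame),
#'   \code{per_image} (data frame), \code{split} (train/validation files),
#'   \code{models} (fitted ps-KDE density models, by region) and
#'   \code{paths} of the files written.
#' @export
run_experiment <- function(data_dir, regions, methods, seed, out_dir,
                           split = 0.5, augment_k = 0L,
                           augment_cfg = NULL, clahe_cfg = clahe_config(),
                           write_prob_maps = TRUE) {
  ds <- load_dataset(data_dir, regions)
  n <- length(ds$files)
  if (n < 2L) stop("need at least two images to split", call. = FALSE)
  bad <- setdiff(methods, c("none", "he", "clahe", "pskde"))
  if (length(bad) > 0L)
    stop(sprintf("unknown method name '%s'", bad[1L]), call. = FALSE)

  set.seed(seed)
  perm <- sample.int(n)
  n_train <- max(1L, floor(n * split))
  idx_train <- sort(perm[seq_len(n_train)])
  idx_val <- sort(perm[-seq_len(n_train)])

  train_imgs <- ds$images[idx_train]
  val_imgs <- ds$images[idx_val]
  train_masks <- lapply(ds$masks, function(m) m[idx_train])
  val_masks <- lapply(ds$masks, function(m) m[idx_val])

  if (augment_k > 0L) {
    if (is.null(augment_cfg))
      augment_cfg <- augment_config(out_size = dim(train_imgs[[1L]]),
                                    seed = seed)
    packed <- lapply(seq_along(train_imgs), function(i)
      lapply(train_masks, `[[`, i))
    aug <- expand_dataset(train_imgs, packed, augment_cfg, k = augment_k)
    train_imgs <- lapply(aug, `[[`, "image")
    train_masks <- lapply(regions, function(r)
      lapply(aug, function(a) a$mask[[r]]))
    names(train_masks) <- regions
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  reports <- list(); per_rows <- list(); models <- list()
  for (method in sort(methods)) {
    for (region in sort(regions)) {
      model <- NULL
      if (method == "pskde") {
        model <- fit_density(train_imgs, train_masks[[region]],
                             region_label = region)
        models[[region]] <- model
      }
      tr_enh <- enhance_images(train_imgs, method, model, clahe_cfg)
      va_enh <- enhance_images(val_imgs, method, model, clahe_cfg)
      clf <- train_pixel_classifier(tr_enh, train_masks[[region]])
      for (i in seq_along(va_enh)) {
        prob <- predict_probability(va_enh[[i]], clf)
        if (write_prob_maps) {
          pdir <- file.path(out_dir, "prob_maps", method, region)
          dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
          write_gray_png(prob, file.path(pdir, ds$files[idx_val][i]))
        }
        met <- evaluate_masks(val_masks[[region]][[i]], (prob >= 0.5) * 1)
        per_rows[[length(per_rows) + 1L]] <- data.frame(
          region = region, method = method, file = ds$files[idx_val][i],
          t(met), stringsAsFactors = FALSE)
      }
      pi_df <- do.call(rbind, per_rows[
        vapply(per_rows, function(r)
          r$region[1] == region && r$method[1] == method, logical(1))])
      reports[[length(reports) + 1L]] <-
        aggregate_report(pi_df[, names(evaluate_masks(
          matrix(1, 1, 1), matrix(1, 1, 1)))], region, method)
    }
  }
  report <- do.call(rbind, reports)
  per_image <- do.call(rbind, per_rows)
  row.names(report) <- NULL; row.names(per_image) <- NULL

  paths <- character(0)
  for (method in sort(methods)) {
    rp <- file.path(out_dir, sprintf("report_%s.csv", method))
    write_metric_report(report[report$method == method, , drop = FALSE], rp)
    pp <- file.path(out_dir, sprintf("per_image_%s.csv", method))
    utils::write.csv(per_image[per_image$method == method, , drop = FALSE],
                     pp, row.names = FALSE)
    paths <- c(paths, rp, pp)
  }
  invisible(list(report = report, per_image = per_image,
                 split = list(train = ds$files[idx_train],
                              validation = ds$files[idx_val]),
                 models = models, paths = paths))
}

#' Compare two method arms with Welch's t-test
#'
#' Applies [welch_t_test()] region by region to the per-image Dice scores of
#' two arms and flags significance at p < 0.01 (no multiple-comparison
#' correction).
#'
#' @param per_image_a,per_image_b per-image data frames (or CSV paths) as
#'   written by [run_experiment()], each for a single method.
#' @param out optional CSV path for the comparison table.
#' @param metric metric column to compare, default \code{"dice"}.
#' @param alpha significance level, default 0.01.
#' @return Data frame with columns \code{region}, \code{method_a},
#'   \code{method_b}, \code{metric}, \code{t}, \code{df}, \code{p},
#'   \code{significant}.
#' @export
compare_methods <- function(per_image_a, per_image_b, out = NULL,
                            metric = "dice", alpha = 0.01) {
  a <- if (is.character(per_image_a))
    utils::read.csv(per_image_a, stringsAsFactors = FALSE) else per_image_a
  b <- if (is.character(per_image_b))
    utils::read.csv(per_image_b, stringsAsFactors = FALSE) else per_image_b
  regions <- sort(intersect(unique(a$region), unique(b$region)))
  if (length(regions) == 0L) stop("no common regions to compare", call. = FALSE)
  rows <- lapply(regions, function(r) {
    va <- a[[metric]][a$region == r]
    vb <- b[[metric]][b$region == r]
    wt <- welch_t_test(va, vb)
    data.frame(region = r,
               method_a = a$method[a$region == r][1L],
               method_b = b$method[b$region == r][1L],
               metric = metric, t = wt$t, df = wt$df, p = wt$p,
               significant = wt$p < alpha, stringsAsFactors = FALSE)
  })
  cmp <- do.call(rbind, rows)
  if (!is.null(out)) utils::write.csv(cmp, out, row.names = FALSE)
  cmp
}

#' Region-contrast statistic of an image
#'
#' The absolute difference between the mean intensity inside and outside a
#' region, divided by the pooled standard deviation: a scalar measure of how
#' strongly an enhancement separates a structure from its surroundings.
#'
#' @param image grayscale image matrix.
#' @param mask binary region mask, same shape.
#' @return Non-negative number.
#' @export
region_contrast <- function(image, mask) {
  validate_gray_image(image)
  validate_mask(mask, image)
  inside <- image[mask == 1]; outside <- image[mask == 0]
  if (length(inside) < 2L || length(outside) < 2L)
    stop("degenerate sample", call. = FALSE)
  n1 <- length(inside); n2 <- length(outside)
  pooled <- sqrt(((n1 - 1) * stats::var(inside) + (n2 - 1) * stats::var(outside)) /
                   (n1 + n2 - 2))
  if (pooled == 0) return(0)
  abs(mean(inside) - mean(outside)) / pooled
}
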