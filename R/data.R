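# Data ingestion and synthetic fixtures.
#
# A dataset bundle holds images as a single (3, side, side, N) array of
# doubles in [0, 1] (channels-first, batch-last), 0-based integer labels,
# class names in sorted order, and a split tag.

new_dataset <- function(images, labels, class_names, split_tag = "all") {
  stopifnot(dim(images)[4] == length(labels))
  structure(list(images = images, labels = as.integer(labels),
                 class_names = class_names, split_tag = split_tag),
            class = "weed_dataset")
}

#' @export
print.weed_dataset <- function(x, ...) {
  cat(sprintf("<weed_dataset %s> %d images (%dpx), %d classes\n", x$split_tag,
              length(x$labels), dim(x$images)[2], length(x$class_names)))
  print(table(factor(x$labels, levels = seq_along(x$class_names) - 1L,
                     labels = x$class_names)))
  invisible(x)
}

# EBImage stores (width, height, channel); convert to (C, H, W).
ebimage_to_chw <- function(img) {
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))   # grayscale
  if (dim(a)[3] > 3) a <- a[, , 1:3]                             # drop alpha
  aperm(a, c(3, 2, 1))
}

#' Bilinear-resize one image
#'
#' @param img Array `c(3, H, W)` in `[0, 1]`.
#' @param side Target square side.
#' @return Array `c(3, side, side)`.
#' @export
resize_image <- function(img, side) {
  if (dim(img)[2] == side && dim(img)[3] == side) return(img)
  e <- EBImage::Image(aperm(img, c(3, 2, 1)), colormode = "Color")
  out <- EBImage::resize(e, w = side, h = side, filter = "bilinear",
                         antialias = FALSE)
  pmin(pmax(ebimage_to_chw(out), 0), 1)
}

#' Load a class-labeled image folder
#'
#' Expects one subdirectory per class containing PNG/JPEG files. Images are
#' decoded to RGB, bilinear-resized to `side` x `side` and scaled to `[0, 1]`
#' (8-bit values divided by 255). Class indices follow sorted subdirectory
#' names.
#'
#' @param root Dataset root directory.
#' @param side Target side in pixels (default 224).
#' @return A `weed_dataset`.
#' @export
load_image_folder <- function(root, side = 224) {
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0) stop("no class subdirectories under ", root,
                                 call. = FALSE)
  imgs <- list()
  labels <- integer()
  skipped <- 0L
  for (ci in seq_along(classes)) {
    files <- sort(list.files(file.path(root, classes[ci]),
                             pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0) {
      warning("class folder '", classes[ci], "' is empty", call. = FALSE)
      next
    }
    for (f in files) {
      img <- tryCatch(ebimage_to_chw(EBImage::readImage(f)),
                      error = function(e) NULL)
      if (is.null(img)) { skipped <- skipped + 1L; next }
      imgs[[length(imgs) + 1L]] <- resize_image(img, side)
      labels <- c(labels, ci - 1L)
    }
  }
  if (skipped > 0) message(skipped, " unreadable file(s) skipped")
  arr <- array(0, c(3, side, side, length(imgs)))
  for (i in seq_along(imgs)) arr[, , , i] <- imgs[[i]]
  new_dataset(arr, labels, classes)
}

subset_dataset <- function(bundle, idx, tag) {
  new_dataset(bundle$images[, , , idx, drop = FALSE], bundle$labels[idx],
              bundle$class_names, tag)
}

#' Stratified train/test split
#'
#' Splits per class: `round(train_fraction * n_c)` items to the training set,
#' the remainder to the test set, sampled without replacement under the seed.
#'
#' @param bundle A `weed_dataset`.
#' @param train_fraction Fraction in (0, 1) (default 0.8).
#' @param seed Integer RNG seed (default 42).
#' @return `list(train = , test = )` of `weed_dataset` objects.
#' @export
stratified_split <- function(bundle, train_fraction = 0.8, seed = 42) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  counts <- table(bundle$labels)
  if (any(counts < 2))
    stop("every class needs at least 2 items for a stratified split",
         call. = FALSE)
  with_seed(seed, {
    train_idx <- integer()
    for (cl in sort(unique(bundle$labels))) {
      idx <- which(bundle$labels == cl)
      n_train <- round(train_fraction * length(idx))
      n_train <- min(max(n_train, 1L), length(idx) - 1L)
      train_idx <- c(train_idx, sample(idx, n_train))
    }
    train_idx <- sort(train_idx)
    test_idx <- setdiff(seq_along(bundle$labels), train_idx)
    list(train = subset_dataset(bundle, train_idx, "train"),
         test = subset_dataset(bundle, test_idx, "test"))
  })
}

# Vectorized HSV -> RGB for h, s, v vectors in [0, 1).
hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

render_synthetic_image <- function(side, base_hue, hue_spread, leaf_axis,
                                   texture_freq) {
  # soil-toned background with low-frequency clutter and speckle
  coarse <- matrix(stats::runif(64, -1, 1), 8, 8)
  lowfreq <- EBImage::imageData(EBImage::resize(EBImage::Image(coarse),
                                                w = side, h = side))
  soil <- c(0.36, 0.27, 0.18)
  img <- array(0, c(3, side, side))
  speckle <- matrix(stats::runif(side * side, -0.05, 0.05), side, side)
  for (ch in 1:3) img[ch, , ] <- soil[ch] * (1 + 0.3 * t(lowfreq)) + speckle
  # foliage: elliptical leaf elements at class-dependent hue/scale/texture
  n_leaves <- 6L + stats::rpois(1, 6)
  for (l in seq_len(n_leaves)) {
    cx <- stats::runif(1, 0.1, 0.9) * side
    cy <- stats::runif(1, 0.1, 0.9) * side
    a <- leaf_axis * stats::runif(1, 0.7, 1.3)
    b <- a * stats::runif(1, 0.35, 0.75)
    th <- stats::runif(1, 0, pi)
    hue <- base_hue + stats::rnorm(1, 0, hue_spread)
    sat <- stats::runif(1, 0.65, 0.95)   # foliage clearly more saturated than soil
    val0 <- stats::runif(1, 0.45, 0.8)
    r0 <- max(a, b)
    hs <- max(1L, floor(cy - r0)):min(side, ceiling(cy + r0))
    ws <- max(1L, floor(cx - r0)):min(side, ceiling(cx + r0))
    dy <- (hs - cy)
    dx <- (ws - cx)
    u <- outer(dy, dx, function(y, x) (x * cos(th) + y * sin(th)))
    v <- outer(dy, dx, function(y, x) (-x * sin(th) + y * cos(th)))
    mask <- (u / a)^2 + (v / b)^2 <= 1
    if (!any(mask)) next
    tex <- 1 + 0.18 * sin(2 * pi * texture_freq * u[mask] / (2 * a))
    rgb <- hsv_to_rgb(rep(hue, sum(mask)), sat, pmin(pmax(val0 * tex, 0), 1))
    for (ch in 1:3) {
      plane <- img[ch, hs, ws]
      plane[mask] <- rgb[, ch]
      img[ch, hs, ws] <- plane
    }
  }
  gain <- stats::runif(1, 0.75, 1.25)   # illumination variation
  pmin(pmax(img * gain, 0), 1)
}

#' Generate a synthetic class-labeled image set
#'
#' Procedurally renders square RGB images that emulate the statistical
#' structure of field weed photographs: a soil-toned, cluttered background,
#' elliptical leaf elements whose hue, texture frequency and scale depend on
#' the class, and random global illumination gain. The default settings give
#' strongly separated class-conditional color statistics (an "easy" set), so
#' that small training runs can verify the pipeline end to end. Fully
#' deterministic under `seed`.
#'
#' @param n_per_class Images per class (>= 2).
#' @param num_classes Number of classes (default 9).
#' @param side Image side in pixels (default 256).
#' @param seed Integer RNG seed (default 1).
#' @param hue_spread Intra-class hue standard deviation (default 0.015;
#'   class hue centers are `1/num_classes` apart, so the default is strongly
#'   separable).
#' @return A `weed_dataset` with classes `class_0 ... class_{K-1}`.
#' @export
generate_synthetic_dataset <- function(n_per_class, num_classes = 9,
                                       side = 256, seed = 1,
                                       hue_spread = 0.015) {
  stopifnot(n_per_class >= 2, num_classes >= 2, side >= 16)
  n <- n_per_class * num_classes
  images <- array(0, c(3, side, side, n))
  labels <- integer(n)
  with_seed(seed, {
    i <- 0L
    for (cl in 0:(num_classes - 1)) {
      base_hue <- (cl + 0.5) / num_classes
      leaf_axis <- side * (0.06 + 0.015 * cl)
      texture_freq <- 2 + 1.5 * cl
      for (j in seq_len(n_per_class)) {
        i <- i + 1L
        images[, , , i] <- render_synthetic_image(side, base_hue, hue_spread,
                                                  leaf_axis, texture_freq)
        labels[i] <- cl
      }
    }
  })
  new_dataset(images, labels, paste0("class_", 0:(num_classes - 1)))
}

#' Write a dataset as a PNG folder tree
#'
#' Mirrors the layout expected by [load_image_folder()]: one subdirectory per
#' class, one PNG per image.
#'
#' @param bundle A `weed_dataset`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset_png <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counter <- integer(length(bundle$class_names))
  for (i in seq_along(bundle$labels)) {
    cl <- bundle$labels[i] + 1L
    cdir <- file.path(dir, bundle$class_names[cl])
    dir.create(cdir, showWarnings = FALSE)
    counter[cl] <- counter[cl] + 1L
    png::writePNG(aperm(bundle$images[, , , i], c(2, 3, 1)),
                  file.path(cdir, sprintf("img_%04d.png", counter[cl])))
  }
  invisible(dir)
}

#' Summarize class-conditional color statistics
#'
#' Mean foliage-dominant hue per class and its spread, used to verify that
#' the generator separates classes in color space.
#'
#' @param bundle A `weed_dataset`.
#' @return Data frame with per-class circular mean hue and SD.
#' @export
dataset_hue_stats <- function(bundle) {
  stats_rows <- lapply(sort(unique(bundle$labels)), function(cl) {
    idx <- which(bundle$labels == cl)
    hues <- vapply(idx, function(i) {
      img <- bundle$images[, , , i]
      # green-ish foliage pixels dominate the saturated, non-soil range
      m <- matrix(img, nrow = 3)
      hsvm <- grDevices::rgb2hsv(m[1, ], m[2, ], m[3, ], maxColorValue = 1)
      sel <- hsvm[2, ] > 0.55 & hsvm[3, ] > 0.3
      if (!any(sel)) return(NA_real_)
      ang <- 2 * pi * hsvm[1, sel]
      (atan2(mean(sin(ang)), mean(cos(ang))) / (2 * pi)) %% 1
    }, 0)
    ang <- 2 * pi * hues
    mh <- (atan2(mean(sin(ang)), mean(cos(ang))) / (2 * pi)) %% 1
    dev <- abs(((hues - mh + 0.5) %% 1) - 0.5)
    data.frame(class = cl, mean_hue = mh, hue_sd = sqrt(mean(dev^2)))
  })
  do.call(rbind, stats_rows)
}
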