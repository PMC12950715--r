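# Photometric domain-shift transforms and the robustness-evaluation harness.
#
# Every transform maps a normalized RGB image (any array with values in
# [0, 1]; the channel layout is irrelevant except for white balance and hue,
# which expect (3, H, W)) back into [0, 1]. Exactly one transform is applied
# at a time; labels are never modified.

check_image01 <- function(image) {
  r <- range(image)
  if (r[1] < 0 || r[2] > 1)
    stop("image values must lie in [0, 1]", call. = FALSE)
  invisible(TRUE)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Brightness shift: `clip(I + beta)`
#' @param image Normalized image in `[0, 1]`.
#' @param beta Additive offset (severity grid: 0.10, 0.20, 0.30).
#' @return Perturbed image.
#' @export
apply_brightness <- function(image, beta) {
  check_image01(image)
  if (beta == 0) return(image)
  clip01(image + beta)
}

#' Contrast scaling: `clip(alpha * (I - mu) + mu)`
#'
#' `mu` is the scalar mean over all pixels and channels of the image.
#'
#' @param image Normalized image.
#' @param alpha Contrast factor (severity grid: 0.8, 0.6, 0.4).
#' @return Perturbed image.
#' @export
apply_contrast <- function(image, alpha) {
  check_image01(image)
  if (alpha == 1) return(image)
  mu <- mean(image)
  clip01(alpha * (image - mu) + mu)
}

#' Gamma correction: `I^gamma`
#' @param image Normalized image.
#' @param gamma Exponent (severity grid: 0.8, 1.2, 1.6).
#' @return Perturbed image (range-preserving; no clipping needed).
#' @export
apply_gamma <- function(image, gamma) {
  check_image01(image)
  if (gamma == 1) return(image)
  image^gamma
}

#' White-balance shift: per-channel scaling
#' @param image Image with channels first, `c(3, H, W)` or `c(3, H, W, N)`.
#' @param scales Length-3 multiplier `(sR, sG, sB)` (severity grid:
#'   `(1.1, 1.0, 0.9)`, `(1.2, 1.0, 0.8)`, `(1.3, 1.0, 0.7)`).
#' @return Perturbed image.
#' @export
apply_white_balance <- function(image, scales) {
  check_image01(image)
  stopifnot(length(scales) == 3, dim(image)[1] == 3)
  if (all(scales == 1)) return(image)
  clip01(image * scales)  # channel index is fastest: recycling is per-channel
}

gaussian_kernel_1d <- function(kernel_size) {
  sigma <- 0.3 * ((kernel_size - 1) * 0.5 - 1) + 0.8
  r <- (kernel_size - 1) / 2
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  g / sum(g)
}

#' The normalized 2-D Gaussian kernel used by [apply_gaussian_blur()]
#' @param kernel_size Odd kernel side (3, 5 or 7 on the severity grid);
#'   sigma follows `0.3 * ((k - 1) * 0.5 - 1) + 0.8`.
#' @return A `kernel_size` x `kernel_size` matrix summing to 1.
#' @export
gaussian_kernel <- function(kernel_size) {
  g <- gaussian_kernel_1d(kernel_size)
  outer(g, g)
}

reflect_pad_idx <- function(n, r) {
  # reflect-101 (symmetric around the edge pixel, no repetition)
  c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))
}

blur_plane <- function(m, g) {
  r <- (length(g) - 1) / 2
  mp <- m[reflect_pad_idx(nrow(m), r), reflect_pad_idx(ncol(m), r)]
  # separable convolution: rows then columns
  acc <- matrix(0, nrow(m), ncol(m) + 2 * r)
  for (i in seq_along(g))
    acc <- acc + g[i] * mp[seq_len(nrow(m)) + i - 1L, ]
  out <- matrix(0, nrow(m), ncol(m))
  for (j in seq_along(g))
    out <- out + g[j] * acc[, seq_len(ncol(m)) + j - 1L]
  out
}

#' Gaussian blur with reflective borders
#' @param image Image `c(3, H, W)` (or `c(H, W)`), values in `[0, 1]`.
#' @param kernel_size Odd integer >= 3.
#' @return Blurred image.
#' @export
apply_gaussian_blur <- function(image, kernel_size) {
  check_image01(image)
  if (kernel_size %% 2 != 1 || kernel_size < 3)
    stop("`kernel_size` must be an odd integer >= 3", call. = FALSE)
  g <- gaussian_kernel_1d(kernel_size)
  d <- dim(image)
  if (length(d) == 2) return(blur_plane(image, g))
  out <- image
  for (ch in seq_len(d[1])) out[ch, , ] <- blur_plane(image[ch, , ], g)
  out
}

#' Hue rotation in HSV space
#'
#' Converts to HSV, adds `delta_degrees` to the hue angle modulo 360 degrees,
#' and converts back; saturation and value are untouched.
#'
#' @param image Image `c(3, H, W)` in `[0, 1]`.
#' @param delta_degrees Signed hue shift in degrees (severity grid: +-5,
#'   +-10, +-15).
#' @return Perturbed image.
#' @export
apply_hue_shift <- function(image, delta_degrees) {
  check_image01(image)
  d <- dim(image)
  stopifnot(d[1] == 3)
  m <- matrix(image, nrow = 3)
  hsvm <- grDevices::rgb2hsv(m[1, ], m[2, ], m[3, ], maxColorValue = 1)
  h <- (hsvm[1, ] + delta_degrees / 360) %% 1
  rgb <- hsv_to_rgb(h, hsvm[2, ], hsvm[3, ])
  out <- rbind(rgb[, 1], rgb[, 2], rgb[, 3])
  dim(out) <- d
  clip01(out)
}

#' The full severity grid of perturbations
#'
#' Six corruption families, three severities each (mild / moderate / severe):
#' brightness beta {0.10, 0.20, 0.30}; contrast alpha {0.8, 0.6, 0.4}; gamma
#' {0.8, 1.2, 1.6}; white balance {(1.1,1,0.9), (1.2,1,0.8), (1.3,1,0.7)};
#' Gaussian blur kernel {3, 5, 7}; hue shift {±5, ±10, ±15} degrees.
#'
#' @return A list of 18 `perturbation` objects (family, severity, theta).
#' @export
severity_grid <- function() {
  fam <- list(
    brightness = list(0.10, 0.20, 0.30),
    contrast = list(0.8, 0.6, 0.4),
    gamma = list(0.8, 1.2, 1.6),
    white_balance = list(c(1.1, 1.0, 0.9), c(1.2, 1.0, 0.8), c(1.3, 1.0, 0.7)),
    gaussian_blur = list(3L, 5L, 7L),
    hue_shift = list(5, 10, 15)
  )
  out <- list()
  for (f in names(fam))
    for (sev in 1:3)
      out[[length(out) + 1L]] <- structure(
        list(family = f, severity = sev, theta = fam[[f]][[sev]]),
        class = "perturbation")
  out
}

#' @export
print.perturbation <- function(x, ...) {
  cat(sprintf("<perturbation %s sev%d theta=%s>\n", x$family, x$severity,
              paste(x$theta, collapse = ",")))
  invisible(x)
}

#' Apply one perturbation to one image
#'
#' For the hue family the positive shift is applied; the robustness harness
#' evaluates both signs and averages (see [evaluate_robustness()]).
#'
#' @param image Image `c(3, H, W)` in `[0, 1]`.
#' @param pert A `perturbation` from [severity_grid()].
#' @return Perturbed image.
#' @export
apply_perturbation <- function(image, pert) {
  switch(pert$family,
         brightness = apply_brightness(image, pert$theta),
         contrast = apply_contrast(image, pert$theta),
         gamma = apply_gamma(image, pert$theta),
         white_balance = apply_white_balance(image, pert$theta),
         gaussian_blur = apply_gaussian_blur(image, pert$theta),
         hue_shift = apply_hue_shift(image, pert$theta),
         stop("unknown perturbation family: ", pert$family, call. = FALSE))
}

perturb_dataset <- function(bundle, fn) {
  imgs <- bundle$images
  for (i in seq_len(dim(imgs)[4]))
    imgs[, , , i] <- fn(bundle$images[, , , i])
  new_dataset(imgs, bundle$labels, bundle$class_names, bundle$split_tag)
}

#' Evaluate classification robustness under the perturbation grid
#'
#' Computes the clean macro-F1 (percent) on the dataset, then the macro-F1
#' under every perturbation applied to each test image with labels unchanged.
#' Hue-shift rows evaluate the positive and negative shift separately and
#' report the mean of the two F1 scores. `delta_f1_pct` is exactly
#' `f1_pct - clean`.
#'
#' @param model A `weednet`, or a function mapping an image array
#'   `c(3, side, side, N)` to 0-based predicted labels.
#' @param dataset A `weed_dataset` whose labels match the model's classes.
#' @param grid List of perturbations (default [severity_grid()]).
#' @return A `robustness_report` data frame: family, severity, f1_pct,
#'   delta_f1_pct, with the clean row first.
#' @export
evaluate_robustness <- function(model, dataset, grid = severity_grid()) {
  if (length(dataset$labels) == 0) stop("empty dataset", call. = FALSE)
  predict_fn <- if (inherits(model, "weednet"))
    function(imgs) predict(model, imgs, type = "class") else model
  k <- length(dataset$class_names)
  f1_of <- function(bundle) {
    preds <- predict_fn(bundle$images)
    classification_metrics(preds, bundle$labels, k)$macro_f1_pct
  }
  clean <- f1_of(dataset)
  rows <- data.frame(family = "clean", severity = NA_integer_,
                     f1_pct = clean, delta_f1_pct = 0)
  for (pert in grid) {
    if (pert$family == "hue_shift") {
      f1p <- f1_of(perturb_dataset(dataset, function(im)
        apply_hue_shift(im, pert$theta)))
      f1m <- f1_of(perturb_dataset(dataset, function(im)
        apply_hue_shift(im, -pert$theta)))
      f1 <- (f1p + f1m) / 2
    } else {
      f1 <- f1_of(perturb_dataset(dataset, function(im)
        apply_perturbation(im, pert)))
    }
    rows <- rbind(rows, data.frame(family = pert$family,
                                   severity = pert$severity, f1_pct = f1,
                                   delta_f1_pct = f1 - clean))
  }
  class(rows) <- c("robustness_report", class(rows))
  rows
}

#' Write a corrupted copy of an image folder
#'
#' Mirrors `input_dir` into `output_dir/<family>_s<severity>/<class>/...` for
#' each perturbation in the grid.
#'
#' @param input_dir Class-labeled image folder.
#' @param output_dir Output root.
#' @param side Working resolution (default 224).
#' @param grid Perturbation list (default [severity_grid()]).
#' @return `output_dir`, invisibly.
#' @export
corrupt_image_folder <- function(input_dir, output_dir, side = 224,
                                 grid = severity_grid()) {
  bundle <- load_image_folder(input_dir, side)
  for (pert in grid) {
    pb <- perturb_dataset(bundle, function(im) apply_perturbation(im, pert))
    write_dataset_png(pb, file.path(output_dir,
                                    sprintf("%s_s%d", pert$family,
                                            pert$severity)))
  }
  invisible(output_dir)
}
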