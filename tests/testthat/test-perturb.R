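test_that("parameter-identity settings are exact identities", {
  img <- random_batch(16)[, , , 1]
  expect_identical(apply_brightness(img, 0), img)
  expect_identical(apply_contrast(img, 1), img)
  expect_identical(apply_gamma(img, 1), img)
  expect_identical(apply_white_balance(img, c(1, 1, 1)), img)
  expect_equal(apply_hue_shift(img, 0), img, tolerance = 1e-6)
  expect_equal(apply_hue_shift(img, 360), img, tolerance = 1e-6)
})

test_that("brightness adds and clips", {
  img <- array(0.5, c(3, 4, 4))
  expect_equal(apply_brightness(img, 0.2), array(0.7, c(3, 4, 4)))
  expect_equal(apply_brightness(array(0.95, c(3, 2, 2)), 0.30),
               array(1, c(3, 2, 2)))
})

test_that("contrast rescales around the scalar image mean", {
  img <- array(rep(c(0.2, 0.8), 24), c(3, 4, 4))   # mean 0.5
  out <- apply_contrast(img, 0.5)
  expect_equal(sort(unique(as.vector(out))), c(0.35, 0.65))
  const <- array(0.31, c(3, 4, 4))
  expect_equal(apply_contrast(const, 0.4), const)  # I == mu
})

test_that("gamma is an elementwise power with fixed points 0 and 1", {
  expect_equal(apply_gamma(array(0.25, c(3, 1, 1)), 0.5),
               array(0.5, c(3, 1, 1)))
  img <- array(c(0, 1), c(3, 2, 2))
  for (g in c(0.8, 1.2, 1.6))
    expect_equal(apply_gamma(img, g), img)
})

test_that("white balance scales channels independently", {
  gray <- array(0.5, c(3, 2, 2))
  out <- apply_white_balance(gray, c(1.3, 1.0, 0.7))
  expect_equal(out[1, , ], matrix(0.65, 2, 2))
  expect_equal(out[2, , ], matrix(0.50, 2, 2))
  expect_equal(out[3, , ], matrix(0.35, 2, 2))
})

test_that("hue rotation by 120 degrees maps pure red to pure green", {
  red <- array(c(1, 0, 0), c(3, 1, 1))
  green <- apply_hue_shift(red, 120)
  expect_equal(as.vector(green), c(0, 1, 0), tolerance = 1e-9)
})

test_that("blur of a constant image is the identity and kernels normalize", {
  img <- array(0.42, c(3, 10, 10))
  for (k in c(3, 5, 7)) {
    expect_equal(apply_gaussian_blur(img, k), img, tolerance = 1e-12)
    expect_equal(sum(gaussian_kernel(k)), 1, tolerance = 1e-12)
  }
  expect_error(apply_gaussian_blur(img, 4), "odd")
})

test_that("impulse response of the blur equals the normalized kernel", {
  for (k in c(3, 5, 7)) {
    n <- 15
    img <- matrix(0, n, n)
    img[8, 8] <- 1
    out <- apply_gaussian_blur(img, k)
    r <- (k - 1) / 2
    expect_equal(out[(8 - r):(8 + r), (8 - r):(8 + r)], gaussian_kernel(k),
                 tolerance = 1e-12)
    out[(8 - r):(8 + r), (8 - r):(8 + r)] <- 0
    expect_equal(max(abs(out)), 0)
  }
})

test_that("blur preserves the mean of an interior-padded image", {
  set.seed(3)
  img <- matrix(0.5, 20, 20)
  img[8:13, 8:13] <- runif(36)          # variation away from the borders
  for (k in c(3, 5, 7))
    expect_equal(mean(apply_gaussian_blur(img, k)), mean(img),
                 tolerance = 1e-6)
})

test_that("the severity grid carries the published parameter ladder", {
  grid <- severity_grid()
  expect_length(grid, 18)
  by_key <- function(fam, sev)
    Filter(function(p) p$family == fam && p$severity == sev, grid)[[1]]
  expect_equal(by_key("brightness", 1)$theta, 0.10)
  expect_equal(by_key("brightness", 3)$theta, 0.30)
  expect_equal(by_key("contrast", 2)$theta, 0.6)
  expect_equal(by_key("gamma", 1)$theta, 0.8)
  expect_equal(by_key("white_balance", 3)$theta, c(1.3, 1.0, 0.7))
  expect_identical(by_key("gaussian_blur", 2)$theta, 5L)
  expect_equal(by_key("hue_shift", 2)$theta, 10)
  fams <- vapply(grid, `[[`, "", "family")
  expect_identical(unique(fams), c("brightness", "contrast", "gamma",
                                   "white_balance", "gaussian_blur",
                                   "hue_shift"))
  sevs <- vapply(grid, `[[`, 0L, "severity")
  expect_identical(as.vector(tapply(sevs, fams, paste, collapse = "")),
                   rep("123", 6))
})

test_that("every grid perturbation maps [0,1] images into [0,1]", {
  img <- random_batch(24, seed = 5)[, , , 1]
  for (pert in severity_grid()) {
    out <- apply_perturbation(img, pert)
    expect_gte(min(out), 0)
    expect_lte(max(out), 1)
    expect_identical(dim(out), dim(img))
  }
})

test_that("transforms reject out-of-range inputs", {
  bad <- array(1.5, c(3, 2, 2))
  expect_error(apply_brightness(bad, 0.1), "\\[0, 1\\]")
  expect_error(apply_gamma(bad, 1.2), "\\[0, 1\\]")
})

test_that("robustness harness reports 18 perturbation rows plus clean", {
  ds <- generate_synthetic_dataset(3, num_classes = 3, side = 24, seed = 11)
  constant <- function(imgs) rep(0L, dim(imgs)[4])
  rep_ <- evaluate_robustness(constant, ds)
  expect_identical(nrow(rep_), 19L)
  expect_identical(rep_$family[1], "clean")
  expect_true(all(rep_$f1_pct == rep_$f1_pct[1]))    # prediction invariance
  expect_equal(rep_$delta_f1_pct, rep_$f1_pct - rep_$f1_pct[1])
  expect_identical(rep_$severity[-1],
                   rep(1:3, 6))
})

test_that("an identity perturbation row has a delta of exactly zero", {
  ds <- generate_synthetic_dataset(2, num_classes = 2, side = 24, seed = 12)
  flip <- function(imgs) as.integer(colMeans(matrix(imgs, ncol = dim(imgs)[4])) > 0.4)
  ident <- list(structure(list(family = "brightness", severity = 1, theta = 0),
                          class = "perturbation"))
  rep_ <- evaluate_robustness(flip, ds, grid = ident)
  expect_identical(rep_$delta_f1_pct[2], 0)
})

test_that("the harness rejects an empty dataset", {
  ds <- generate_synthetic_dataset(2, num_classes = 2, side = 24, seed = 1)
  empty <- ds
  empty$labels <- integer(0)
  expect_error(evaluate_robustness(function(i) integer(0), empty), "empty")
})
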