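test_that("synthetic generation is sized, labeled and bitwise reproducible", {
  d1 <- generate_synthetic_dataset(10, num_classes = 9, side = 32, seed = 7)
  expect_identical(dim(d1$images), c(3L, 32L, 32L, 90L))
  expect_identical(as.vector(table(d1$labels)), rep(10L, 9))
  expect_identical(sort(unique(d1$labels)), 0:8)
  expect_gte(min(d1$images), 0)
  expect_lte(max(d1$images), 1)
  d2 <- generate_synthetic_dataset(10, num_classes = 9, side = 32, seed = 7)
  expect_identical(d1$images, d2$images)
  d3 <- generate_synthetic_dataset(10, num_classes = 9, side = 32, seed = 8)
  expect_false(identical(d1$images, d3$images))
})

test_that("class hue centers separate further than intra-class spread", {
  ds <- generate_synthetic_dataset(8, num_classes = 9, side = 48, seed = 3)
  st <- dataset_hue_stats(ds)
  gaps <- diff(sort(st$mean_hue))
  wrap <- 1 - sum(gaps)
  expect_gt(min(c(gaps, wrap)), max(st$hue_sd))
})

test_that("class-conditional hue statistics are stable across seeds", {
  a <- dataset_hue_stats(generate_synthetic_dataset(12, 9, side = 48, seed = 1))
  b <- dataset_hue_stats(generate_synthetic_dataset(12, 9, side = 48, seed = 2))
  dev <- abs(((a$mean_hue - b$mean_hue + 0.5) %% 1) - 0.5)
  expect_lt(max(dev), 0.04)
})

test_that("stratified split is a seeded partition with per-class rounding", {
  ds <- generate_synthetic_dataset(10, num_classes = 9, side = 16, seed = 2)
  sp <- stratified_split(ds, 0.8, seed = 42)
  expect_identical(length(sp$train$labels), 72L)
  expect_identical(length(sp$test$labels), 18L)
  expect_identical(as.vector(table(sp$train$labels)), rep(8L, 9))
  expect_identical(as.vector(table(sp$test$labels)), rep(2L, 9))
  # per-class train share within one item of the requested fraction
  ds7 <- generate_synthetic_dataset(7, num_classes = 3, side = 16, seed = 2)
  sp7 <- stratified_split(ds7, 0.8, seed = 1)
  counts <- table(sp7$train$labels)
  expect_true(all(abs(counts - 0.8 * 7) <= 1))
  # determinism and partition
  sp2 <- stratified_split(ds, 0.8, seed = 42)
  expect_identical(sp$train$labels, sp2$train$labels)
  expect_identical(sp$train$images, sp2$train$images)
  expect_identical(length(sp$train$labels) + length(sp$test$labels),
                   length(ds$labels))
})

test_that("a class with fewer than two items cannot be split", {
  ds <- generate_synthetic_dataset(2, num_classes = 2, side = 16, seed = 5)
  one <- ds
  keep <- c(which(one$labels == 0), which(one$labels == 1)[1])
  one$images <- one$images[, , , keep, drop = FALSE]
  one$labels <- one$labels[keep]
  expect_error(stratified_split(one, 0.8), "at least 2")
})

test_that("image folders load, normalize and resize as specified", {
  root <- withr::local_tempdir()
  # an all-white 8-bit image decodes to exactly 1.0 everywhere
  dir.create(file.path(root, "white"))
  dir.create(file.path(root, "dark"))
  png::writePNG(array(1, c(8, 8, 3)), file.path(root, "white", "w.png"))
  png::writePNG(array(0.2, c(8, 8, 3)), file.path(root, "dark", "d.png"))
  b <- load_image_folder(root, side = 8)
  expect_identical(b$class_names, c("dark", "white"))
  expect_identical(b$labels, c(0L, 1L))
  expect_true(all(b$images[, , , 2] == 1))
  # a 256x256 input comes out at the requested square side
  root2 <- withr::local_tempdir()
  dir.create(file.path(root2, "c0"))
  png::writePNG(array(runif(256 * 256 * 3), c(256, 256, 3)),
                file.path(root2, "c0", "a.png"))
  b2 <- load_image_folder(root2, side = 224)
  expect_identical(dim(b2$images), c(3L, 224L, 224L, 1L))
  expect_warning(
    {
      dir.create(file.path(root2, "empty_class"))
      load_image_folder(root2, side = 32)
    }, "empty")
})

test_that("resize is idempotent on already-conforming inputs", {
  img <- random_batch(32, seed = 20)[, , , 1]
  expect_identical(resize_image(img, 32), img)
  # a smooth image survives an up/down round trip to interpolation tolerance
  g <- outer(seq(0, 1, length.out = 32), seq(0, 1, length.out = 32),
             function(a, b) (a + b) / 2)
  smooth <- array(c(g, g / 2, g / 3), c(32, 32, 3))
  smooth <- aperm(smooth, c(3, 1, 2))
  back <- resize_image(resize_image(smooth, 64), 32)
  expect_lt(mean(abs(back - smooth)), 0.02)
})

test_that("PNG round trip preserves the folder layout", {
  ds <- generate_synthetic_dataset(3, num_classes = 2, side = 16, seed = 9)
  dir <- withr::local_tempdir()
  write_dataset_png(ds, dir)
  back <- load_image_folder(dir, side = 16)
  expect_identical(back$class_names, ds$class_names)
  expect_identical(as.vector(table(back$labels)), rep(3L, 2))
  # 8-bit quantization only
  expect_lt(max(abs(back$images - ds$images)), 1 / 255)
})
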