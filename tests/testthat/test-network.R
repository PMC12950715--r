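test_that("shape schedule of the default network matches the layer table", {
  got <- infer_shapes(arch_config())
  expect_identical(got$stage, c("stem", "msc", paste0("ir", 1:5), "head_conv",
                                "gap", "fc"))
  expect_identical(got$channels, c(24L, 36L, 48L, 72L, 96L, 120L, 120L, 240L,
                                   240L, 9L))
  expect_identical(got$height, c(112L, 112L, 56L, 28L, 14L, 7L, 7L, 7L, 1L, 1L))
  expect_identical(got$height, got$width)
})

test_that("spatial entries scale with the input side, vector lengths do not", {
  base <- infer_shapes(arch_config())
  dbl <- infer_shapes(arch_config(), input = c(3L, 448L, 448L))
  spatial <- base$height > 1
  expect_identical(dbl$height[spatial], 2L * base$height[spatial])
  expect_identical(dbl$channels, base$channels)
  half <- infer_shapes(tiny_config())   # 32 px input
  expect_identical(half$height[1], 16L)
  expect_identical(half$height[7], 1L)
})

test_that("shape inference rejects bad inputs", {
  expect_error(infer_shapes(arch_config(), input = c(3, 224, 112)), "square")
  expect_error(infer_shapes(arch_config(), input = c(3, 16, 16)), "32")
  expect_error(infer_shapes(arch_config(), input = c(1, 224, 224)), "3")
})

test_that("stem halving holds across stem widths", {
  for (s in c(8, 24)) {
    sh <- infer_shapes(arch_config(stem_channels = s))
    expect_identical(sh$channels[1], as.integer(s))
    expect_identical(sh$height[1], 112L)
  }
})

test_that("weight initialization is deterministic under the seed", {
  n1 <- tiny_net(seed = 7)
  n2 <- tiny_net(seed = 7)
  n3 <- tiny_net(seed = 8)
  expect_identical(n1$params, n2$params)
  expect_false(identical(n1$params, n3$params))
})

test_that("the default graph has exactly one residual connection, at IR#5", {
  net <- assemble_network(arch_config(), seed = 0)
  res <- vapply(net$meta$ir, `[[`, TRUE, "residual")
  expect_identical(res, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(sum(net$layers$kind == "add"), 1L)
})

test_that("the projection stage is linear (no activation after its BN)", {
  net <- tiny_net()
  rows <- net$layers
  for (blk in paste0("ir", 1:5)) {
    b <- rows[rows$block == blk & rows$kind != "add", ]
    expect_identical(b$kind[nrow(b)], "batch_norm")
    expect_identical(b$kind[nrow(b) - 1], "conv")
  }
})

test_that("zeroed attention parameters scale every channel by exactly 0.5", {
  ca <- build_channel_attention(6, 2)
  ca$params <- rapply(ca$params, function(v) v * 0, how = "replace")
  x <- random_batch(4, n = 2)[1:3, , , , drop = FALSE]
  x6 <- array(c(x, x), c(6, 4, 4, 2))
  out <- tinyweednet:::ca_f(ca$params, ca$state, x6, training = FALSE)$out
  expect_equal(out, 0.5 * x6, tolerance = 1e-12)
})

test_that("attention bottleneck width uses plain integer division", {
  expect_identical(build_channel_attention(144, 8)$reduced, 18L)
  expect_identical(build_channel_attention(3, 8)$reduced, 1L)  # clamped
})

test_that("spatially constant input gives equal pooled descriptors", {
  x <- array(rep(c(0.2, 0.7, 0.4), 25), c(3, 5, 5, 1))
  qa <- tinyweednet:::gap_fwd(x)
  qm <- tinyweednet:::gmp_fwd(x)$out
  expect_equal(qa, qm, tolerance = 1e-12)
})

test_that("ablated graphs drop the corresponding structures", {
  noatt <- assemble_network(make_ablation_config("no_attention",
                                                 input_side = 32), 0)
  expect_false(any(noatt$layers$stage == "ca"))
  nomsc <- assemble_network(make_ablation_config("no_msc", input_side = 32), 0)
  expect_false(any(nomsc$layers$kind == "concat"))
  nodw <- assemble_network(make_ablation_config("no_depthwise",
                                                input_side = 32), 0)
  expect_false(any(nodw$layers$kind == "depthwise_conv"))
})

test_that("all grid and ablation variants assemble", {
  cfgs <- c(enumerate_grid(input_side = 32),
            lapply(ablation_kinds, make_ablation_config, input_side = 32))
  for (cfg in cfgs) expect_s3_class(assemble_network(cfg, seed = 0), "weednet")
})

test_that("forward returns finite deterministic logits of the right width", {
  net <- tiny_net()
  zero <- array(0, c(3, 32, 32, 1))
  l1 <- forward(net, zero)
  l2 <- forward(net, zero)
  expect_identical(dim(l1), c(1L, 4L))
  expect_true(all(is.finite(l1)))
  expect_identical(l1, l2)
  d9 <- assemble_network(arch_config(input_side = 32), 0)
  expect_identical(ncol(forward(d9, array(0, c(3, 32, 32, 1)))), 9L)
})

test_that("evaluation-mode batching matches per-sample forwards", {
  net <- tiny_net(seed = 4)
  x <- random_batch(32, n = 3)
  lg <- forward(net, x)
  for (i in 1:3)
    expect_equal(lg[i, ], drop(forward(net, x[, , , i, drop = FALSE])),
                 tolerance = 1e-10)
})

test_that("forward validates the batch contract", {
  net <- tiny_net()
  expect_error(forward(net, array(0, c(3, 16, 16, 1))), "batch")
  expect_error(forward(net, array(0, c(1, 32, 32, 1))), "batch")
  expect_error(forward(net, array(2, c(3, 32, 32, 1))), "\\[0, 1\\]")
})

test_that("max pooling of a constant map is the identity", {
  x <- array(0.37, c(2, 6, 6, 1))
  mp <- tinyweednet:::maxpool_fwd(x, 3L, 1L, 1L)
  expect_equal(mp$out, x, tolerance = 0)
})
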