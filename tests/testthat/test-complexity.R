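test_that("default parameter total reproduces the published complexity row", {
  total <- closed_form_parameters(arch_config())$total
  expect_identical(total, 475803)
  expect_identical(sprintf("%.1fK", total / 1000), "475.8K")
  expect_identical(sprintf("%.4fM", total / 1e6), "0.4758M")
  expect_equal(round(4 * total / 2^20, 3), 1.815)
})

test_that("the bias-free conv+BN formula gives the documented stem figure", {
  # 3x3 conv 3->24 without bias plus affine BN: 3*24*9 + 2*24
  expect_equal(3 * 24 * 9 + 2 * 24, 696)
  # the calibrated policy adds a stem bias on top
  per <- closed_form_parameters(arch_config())$per_stage
  expect_identical(per$params[per$stage == "stem"], 696 + 24)
})

test_that("classifier layer parameter and MACC counts are exact", {
  per <- closed_form_parameters(arch_config())$per_stage
  head <- per$params[per$stage == "head"]
  expect_identical(head, 120 * 240 + 240 + 2 * 240 + 240 * 9 + 9)
  net <- assemble_network(arch_config(), 0)
  m <- count_macc(net)
  fc_rows <- m$per_layer[m$per_layer$kind == "fully_connected" &
                         m$per_layer$stage == "head", ]
  expect_identical(fc_rows$macc, 240 * 9)
})

test_that("graph walk and closed form agree exactly on all 31 variants", {
  cfgs <- c(enumerate_grid(), lapply(ablation_kinds, make_ablation_config))
  for (cfg in cfgs) {
    net <- assemble_network(cfg, seed = 0)
    expect_identical(count_parameters(net)$total_params,
                     closed_form_parameters(cfg)$total)
    expect_identical(count_macc(net)$total, closed_form_macc(cfg)$total)
  }
})

test_that("model size is exactly 4 bytes per parameter", {
  net <- tiny_net()
  rep_ <- count_parameters(net)
  expect_identical(rep_$model_size_bytes, 4 * rep_$total_params)
})

test_that("ablation parameter counts behave as the architecture dictates", {
  base <- closed_form_parameters(arch_config())$total
  nfp <- closed_form_parameters(make_ablation_config("no_final_projection"))$total
  expect_identical(nfp, 445203)
  expect_identical(sprintf("%.0fK", nfp / 1000), "445K")
  # single 3x3 branch of equal width has the same count as the 4-branch block
  nomsc <- closed_form_parameters(make_ablation_config("no_msc"))$total
  expect_identical(nomsc, base)
  # removing attention removes parameters (closed-form terms are positive)
  noatt <- closed_form_parameters(make_ablation_config("no_attention"))$total
  expect_lt(noatt, base)
  # standard 3x3 in place of depthwise inflates the count about tenfold
  nodw <- closed_form_parameters(make_ablation_config("no_depthwise"))$total
  expect_gt(nodw / base, 8)
  expect_lt(nodw / base, 13)
})

test_that("parameter counts are monotone in E and S and antitone in R", {
  count_of <- function(E, R, S)
    closed_form_parameters(arch_config(E, R, S))$total
  for (R in c(4, 8, 16)) for (S in c(8, 16, 24)) {
    v <- vapply(c(3, 4, 6), count_of, 0, R = R, S = S)
    expect_true(all(diff(v) > 0))
  }
  for (E in c(3, 4, 6)) for (S in c(8, 16, 24)) {
    v <- vapply(c(4, 8, 16), function(R) count_of(E, R, S), 0)
    expect_true(all(diff(v) < 0))
  }
  for (E in c(3, 4, 6)) for (R in c(4, 8, 16)) {
    v <- vapply(c(8, 16, 24), function(S) count_of(E, R, S), 0)
    expect_true(all(diff(v) > 0))
  }
})

test_that("stem MACC at full resolution matches the closed form", {
  per <- closed_form_macc(arch_config(), 224)$per_stage
  expect_identical(per$macc[per$stage == "stem"], 112 * 112 * 24 * 27)
})

test_that("halving the input side quarters every convolution MACC entry", {
  # sides must stay even through the stride ladder for exact quartering
  net <- assemble_network(arch_config(), 0)
  full <- count_macc(net, 448)$per_layer
  half <- count_macc(net, 224)$per_layer
  conv <- full$kind %in% c("conv", "depthwise_conv")
  expect_equal(full$macc[conv], 4 * half$macc[conv])
})

test_that("grid report is table-shaped, sorted, and carries the default row", {
  rep_ <- grid_report()
  expect_identical(nrow(rep_), 27L)
  expect_identical(rep_$id, sort(rep_$id))
  drow <- rep_[rep_$id == "E4_R8_S24", ]
  expect_equal(drow$model_size_mb, 1.815)
  expect_identical(drow$params, 475803)
  withab <- grid_report(ablations = TRUE)
  expect_identical(nrow(withab), 31L)
})
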