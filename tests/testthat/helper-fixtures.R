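# Shared fixtures: small configurations and images so the unit tests stay
# fast; full-size checks live in test-acceptance.R.

tiny_config <- function(...) {
  arch_config(stem_channels = 8, input_side = 32, num_classes = 4, ...)
}

tiny_net <- function(seed = 1, ...) assemble_network(tiny_config(...), seed)

random_batch <- function(side, n = 1, seed = 99) {
  with_seed_local(seed, array(stats::runif(3 * side * side * n),
                              c(3, side, side, n)))
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

ablation_kinds <- c("no_msc", "no_attention", "no_depthwise",
                    "no_final_projection")
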