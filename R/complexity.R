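# Complexity accounting: exact parameter counts, multiply-accumulate counts
# and serialized-size estimates, via two independent routes -- closed-form
# formulas evaluated on the configuration, and a walk over the assembled
# network. The two must agree exactly; tests enforce it.
#
# Conventions (calibrated against the published complexity tables, see the
# methods vignette): standard conv k^2*Cin*Cout + Cout bias; depthwise 9*C,
# no bias; BN affine 2*C; attention bottleneck 2*C*Cr + Cr + 2*Cr + C
# (two shared layers with biases plus a hidden-layer BN), Cr = floor(C/R);
# classifier in*out + out. Model size assumes float32: 4 bytes/parameter,
# 1 MB = 2^20 bytes.

ca_reduced <- function(channels, reduction_ratio)
  max(1L, channels %/% reduction_ratio)

#' Closed-form parameter count for a configuration
#'
#' Evaluates the per-stage parameter formulas directly on the configuration,
#' without assembling any network. Serves as the independent oracle against
#' [count_parameters()].
#'
#' @param config An [arch_config()].
#' @return A list with `per_stage` (data frame) and `total`.
#' @export
closed_form_parameters <- function(config) {
  validate_arch_config(config)
  sch <- config$schedule
  E <- config$expand_ratio
  R <- config$reduction_ratio
  s <- sch$stem_out
  abl <- config$ablation
  rows <- list()
  rows$stem <- 27 * s + s + 2 * s
  if (abl == "no_msc") {
    rows$msc <- 9 * s * sch$msc_out + sch$msc_out + 2 * sch$msc_out
  } else {
    k2 <- c(1, 9, 25, 1)
    bw <- sch$msc_branch_widths
    rows$msc <- sum(k2 * s * bw + bw + 2 * bw)
  }
  cin <- sch$msc_out
  for (i in 1:5) {
    cout <- sch$ir_out[i]
    ce <- E * cin
    cr <- ca_reduced(ce, R)
    p <- cin * ce + ce + 2 * ce                       # expand + bias + BN
    p <- p + if (abl == "no_depthwise") 9 * ce * ce + ce + 2 * ce else 9 * ce + 2 * ce
    if (abl != "no_attention") p <- p + 2 * ce * cr + cr + 2 * cr + ce
    p <- p + ce * cout + cout + 2 * cout              # project + bias + BN
    rows[[paste0("ir", i)]] <- p
    cin <- cout
  }
  head <- 0
  fc_in <- cin
  if (abl != "no_final_projection") {
    head <- cin * sch$head_out + sch$head_out + 2 * sch$head_out
    fc_in <- sch$head_out
  }
  rows$head <- head + fc_in * config$num_classes + config$num_classes
  per_stage <- data.frame(stage = names(rows),
                          params = unname(unlist(rows)))
  list(per_stage = per_stage, total = sum(per_stage$params))
}

walk_params <- function(x) {
  if (is.list(x)) return(sum(vapply(x, walk_params, 0)))
  if (is.numeric(x)) return(length(x))
  0
}

#' Count trainable parameters by walking an assembled network
#'
#' Sums the lengths of every trainable tensor (weights, biases, BN affine
#' pairs; running statistics excluded) per block and in total, and attaches
#' the float32 serialized-size estimate.
#'
#' @param network A `weednet`.
#' @return A `complexity_report`: list with `per_layer` (block, params),
#'   `total_params`, `model_size_bytes`, `model_size_mb`.
#' @export
count_parameters <- function(network) {
  stopifnot(inherits(network, "weednet"))
  per <- vapply(network$params, walk_params, 0)
  total <- sum(per)
  rep_ <- list(per_layer = data.frame(stage = names(per), params = unname(per)),
               total_params = total,
               model_size_bytes = 4 * total,
               model_size_mb = 4 * total / 2^20)
  class(rep_) <- "complexity_report"
  rep_
}

#' @export
print.complexity_report <- function(x, ...) {
  print(x$per_layer, row.names = FALSE)
  cat(sprintf("total: %s parameters, %.3f MB (float32)\n",
              format(x$total_params, big.mark = ","), x$model_size_mb))
  invisible(x)
}

macc_stages <- function(config, side) {
  sch <- config$schedule
  E <- config$expand_ratio
  R <- config$reduction_ratio
  s <- sch$stem_out
  abl <- config$ablation
  out <- conv_out_side(side, 3, 2, 1)
  rows <- list()
  ext <- list()
  rows$stem <- out^2 * 9 * 3 * s
  ext$stem <- 2 * out^2 * s + out^2 * s                 # BN + ReLU elements
  if (abl == "no_msc") {
    rows$msc <- out^2 * 9 * s * sch$msc_out
    ext$msc <- 3 * out^2 * sch$msc_out
  } else {
    k2 <- c(1, 9, 25, 1)
    bw <- sch$msc_branch_widths
    rows$msc <- sum(out^2 * k2 * s * bw)
    ext$msc <- sum(3 * out^2 * bw) + out^2 * s * 9      # branches + pool windows
  }
  cin <- sch$msc_out
  side_in <- out
  for (i in 1:5) {
    cout <- sch$ir_out[i]
    ce <- E * cin
    cr <- ca_reduced(ce, R)
    side_out <- conv_out_side(side_in, 3, sch$ir_strides[i], 1)
    m <- side_in^2 * cin * ce                           # expand 1x1
    m <- m + if (abl == "no_depthwise") side_out^2 * 9 * ce * ce else side_out^2 * 9 * ce
    if (abl != "no_attention") m <- m + 2 * (ce * cr + cr * ce)  # both pooled paths
    m <- m + side_out^2 * ce * cout                     # project 1x1
    rows[[paste0("ir", i)]] <- m
    e <- 3 * side_in^2 * ce + 3 * side_out^2 * ce + 3 * side_out^2 * cout
    if (abl != "no_attention")
      e <- e + 2 * side_out^2 * ce + side_out^2 * ce    # pooled descriptors + rescale
    ext[[paste0("ir", i)]] <- e
    cin <- cout
    side_in <- side_out
  }
  fc_in <- cin
  m <- 0
  e <- side_in^2 * cin                                  # GAP
  if (abl != "no_final_projection") {
    m <- side_in^2 * cin * sch$head_out
    e <- e + 3 * side_in^2 * sch$head_out
    fc_in <- sch$head_out
  }
  rows$head <- m + fc_in * config$num_classes
  ext$head <- e
  list(macc = rows, extended = ext)
}

#' Closed-form multiply-accumulate count
#'
#' Headline MACC counts convolution and fully connected multiplies only
#' (batch size 1). An approximate `extended_ops` figure additionally counts
#' normalization, activation, pooling and rescaling element operations; it is
#' indicative only, since deployment toolchains use their own accounting.
#'
#' @param config An [arch_config()].
#' @param side Input side in pixels (defaults to the config's).
#' @return List with `per_stage`, `total`, `extended_ops`.
#' @export
closed_form_macc <- function(config, side = config$input_side) {
  st <- macc_stages(config, side)
  per_stage <- data.frame(stage = names(st$macc),
                          macc = unname(unlist(st$macc)))
  list(per_stage = per_stage, total = sum(per_stage$macc),
       extended_ops = sum(per_stage$macc) + sum(unlist(st$extended)))
}

#' Count multiply-accumulates by walking an assembled network's layer table
#'
#' Propagates the activation side through the network's `LayerSpec` rows and
#' accumulates `out^2 * k^2 * Cin/groups * Cout` per convolution and
#' `in * out` per fully connected layer (attention bottleneck layers run once
#' per pooled descriptor path, i.e. twice).
#'
#' @param network A `weednet`.
#' @param side Input side in pixels (defaults to the config's).
#' @return List with `per_layer` data frame and `total`.
#' @export
count_macc <- function(network, side = network$config$input_side) {
  stopifnot(inherits(network, "weednet"))
  rows <- network$layers
  cur <- side
  macc <- numeric(nrow(rows))
  branch_side <- NULL
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    if (r$stage == "msc" && is.null(branch_side)) branch_side <- cur
    if (r$stage == "msc") cur <- branch_side   # parallel branches share input
    if (r$kind %in% c("conv", "depthwise_conv", "max_pool")) {
      out <- conv_out_side(cur, r$kernel, r$stride, r$padding)
      if (r$kind == "conv")
        macc[i] <- out^2 * r$kernel^2 * r$in_channels * r$out_channels
      if (r$kind == "depthwise_conv")
        macc[i] <- out^2 * r$kernel^2 * r$out_channels
      cur <- out
    } else if (r$kind == "fully_connected") {
      mult <- if (r$stage == "ca") 2 else 1    # shared MLP runs on both paths
      macc[i] <- mult * r$in_channels * r$out_channels
    }
    if (r$stage != "msc") branch_side <- NULL
  }
  list(per_layer = cbind(rows[, c("block", "stage", "kind")], macc = macc),
       total = sum(macc))
}

#' Complexity table over a list of configurations
#'
#' One row per configuration: identifier, closed-form parameter count, model
#' size in MB (4 bytes/parameter, 2^20 bytes/MB) and headline MACC, sorted by
#' identifier.
#'
#' @param configs List of [arch_config()] objects (default: the 27-point grid).
#' @param ablations Append the four ablation variants (default FALSE).
#' @param side Input side for the MACC column (default 224).
#' @return A data frame.
#' @export
grid_report <- function(configs = enumerate_grid(), ablations = FALSE,
                        side = 224) {
  if (ablations)
    configs <- c(configs,
                 lapply(ABLATION_KINDS[-1], make_ablation_config))
  rows <- lapply(configs, function(cfg) {
    p <- closed_form_parameters(cfg)$total
    data.frame(id = cfg$id, params = p,
               model_size_mb = round(4 * p / 2^20, 3),
               macc = closed_form_macc(cfg, side)$total)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$id), ]
  rownames(out) <- NULL
  out
}
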