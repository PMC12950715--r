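# Network construction and execution.
#
# A "weednet" object holds:
#   config  - the arch_config design point
#   params  - nested list of trainable tensors (conv weights as
#             (Cin*k*k) x Cout matrices, depthwise as (k,k,C) arrays)
#   state   - running batch-norm statistics, mirroring params
#   layers  - flat LayerSpec table used by the complexity walker and exporter
#
# Bias policy (fixed by calibrating closed-form counts against the published
# complexity tables): standard convolutions carry biases, depthwise
# convolutions do not, batch norms are affine, the attention bottleneck has
# biases on both layers plus a batch norm on its hidden layer, and the
# classifier carries a bias.

rand_w <- function(n, fan_out) stats::rnorm(n, 0, sqrt(2 / fan_out))

init_conv <- function(cin, cout, k, bias = TRUE) {
  w <- matrix(rand_w(cin * k * k * cout, k * k * cout), cin * k * k, cout)
  out <- list(w = w)
  if (bias) out$b <- numeric(cout)
  out
}

init_bn <- function(c) list(gamma = rep(1, c), beta = numeric(c))

init_bn_state <- function(c) list(mean = numeric(c), var = rep(1, c))

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# ---- block builders ---------------------------------------------------------

#' Build the stem block
#'
#' A 3x3 stride-2 convolution (padding 1) from RGB to the stem width,
#' followed by batch norm and ReLU; halves the spatial resolution.
#'
#' @param config An [arch_config()].
#' @return A layer block (parameters, BN state and layer specs).
#' @export
build_stem <- function(config) {
  s <- config$schedule$stem_out
  list(
    params = c(init_conv(3, s, 3), bn = list(init_bn(s))),
    state = list(bn = init_bn_state(s)),
    spec = data.frame(
      stage = "stem",
      kind = c("conv", "batch_norm", "relu"),
      kernel = c(3L, 0L, 0L), stride = c(2L, 1L, 1L), padding = c(1L, 0L, 0L),
      in_channels = c(3L, s, s), out_channels = c(s, s, s),
      has_bias = c(TRUE, NA, NA))
  )
}

#' Build the multi-scale convolution block
#'
#' Four stride-1 branches over the same input -- 1x1, 3x3 (pad 1), 5x5
#' (pad 2), and 3x3 max-pool (stride 1, pad 1) followed by 1x1 -- each with
#' batch norm and ReLU, concatenated on the channel axis.
#'
#' @param in_channels Input channel count.
#' @param schedule A `channel_schedule` providing the branch widths.
#' @return A layer block.
#' @export
build_msc_block <- function(in_channels, schedule) {
  bw <- schedule$msc_branch_widths
  ks <- c(1L, 3L, 5L, 1L)
  params <- list()
  state <- list()
  spec <- NULL
  for (i in 1:4) {
    br <- paste0("b", i)
    params[[br]] <- c(init_conv(in_channels, bw[i], ks[i]),
                      bn = list(init_bn(bw[i])))
    state[[br]] <- list(bn = init_bn_state(bw[i]))
    rows <- data.frame(
      stage = "msc",
      kind = c(if (i == 4) "max_pool", "conv", "batch_norm", "relu"),
      kernel = c(if (i == 4) 3L, ks[i], 0L, 0L),
      stride = c(if (i == 4) 1L, 1L, 1L, 1L),
      padding = c(if (i == 4) 1L, as.integer((ks[i] - 1) / 2), 0L, 0L),
      in_channels = c(if (i == 4) in_channels, in_channels, bw[i], bw[i]),
      out_channels = c(if (i == 4) in_channels, bw[i], bw[i], bw[i]),
      has_bias = c(if (i == 4) NA, TRUE, NA, NA))
    spec <- rbind(spec, rows)
  }
  spec <- rbind(spec, data.frame(
    stage = "msc", kind = "concat", kernel = 0L, stride = 1L, padding = 0L,
    in_channels = schedule$msc_out, out_channels = schedule$msc_out,
    has_bias = NA))
  list(params = params, state = state, spec = spec)
}

# Single 3x3 branch replacing the multi-scale block in the no_msc ablation.
build_single_branch <- function(in_channels, out_channels) {
  list(
    params = c(init_conv(in_channels, out_channels, 3),
               bn = list(init_bn(out_channels))),
    state = list(bn = init_bn_state(out_channels)),
    spec = data.frame(
      stage = "msc",
      kind = c("conv", "batch_norm", "relu"),
      kernel = c(3L, 0L, 0L), stride = 1L, padding = c(1L, 0L, 0L),
      in_channels = c(in_channels, out_channels, out_channels),
      out_channels = out_channels, has_bias = c(TRUE, NA, NA))
  )
}

#' Build a channel-attention gate
#'
#' Global average- and max-pooled channel descriptors pass through a shared
#' two-layer bottleneck (width `max(1, channels %/% reduction_ratio)`, with a
#' batch norm and ReLU on the hidden layer); the two excitations are summed
#' and squashed by a sigmoid, and the input is rescaled channel-wise.
#'
#' @param channels Number of input channels C.
#' @param reduction_ratio Bottleneck compression R.
#' @return A layer block.
#' @export
build_channel_attention <- function(channels, reduction_ratio) {
  cr <- as.integer(max(1, channels %/% reduction_ratio))
  list(
    reduced = cr,
    params = list(
      w1 = matrix(rand_w(channels * cr, cr), channels, cr),
      b1 = numeric(cr),
      bn = init_bn(cr),
      w2 = matrix(rand_w(cr * channels, channels), cr, channels),
      b2 = numeric(channels)),
    state = list(bn = init_bn_state(cr)),
    spec = data.frame(
      stage = "ca",
      kind = c("global_avg_pool", "global_max_pool", "fully_connected",
               "batch_norm", "relu", "fully_connected", "sigmoid",
               "channel_scale"),
      kernel = 0L, stride = 1L, padding = 0L,
      in_channels = c(channels, channels, channels, cr, cr, cr, channels,
                      channels),
      out_channels = c(channels, channels, cr, cr, cr, channels, channels,
                       channels),
      has_bias = c(NA, NA, TRUE, NA, NA, TRUE, NA, NA))
  )
}

#' Build an inverted residual block
#'
#' Expand (1x1 conv to E x input channels, BN, ReLU), depthwise 3x3 (stride
#' `stride`, BN, ReLU), channel attention (unless ablated), then a linear
#' 1x1 projection (BN, no activation). A residual connection is added when
#' `stride == 1` and the channel widths match.
#'
#' @param in_channels,out_channels Block input/output widths.
#' @param stride Depthwise stride, 1 or 2.
#' @param config The parent [arch_config()] (supplies E, R and ablation).
#' @return A layer block.
#' @export
build_ir_block <- function(in_channels, out_channels, stride, config) {
  stopifnot(stride %in% c(1L, 2L))
  ce <- config$expand_ratio * in_channels
  residual <- stride == 1L && in_channels == out_channels
  blk <- list(
    ce = ce, stride = as.integer(stride), residual = residual,
    params = list(
      expand = c(init_conv(in_channels, ce, 1), bn = list(init_bn(ce)))),
    state = list(expand = list(bn = init_bn_state(ce))))
  spec <- data.frame(
    stage = "ir", kind = c("conv", "batch_norm", "relu"),
    kernel = c(1L, 0L, 0L), stride = 1L, padding = 0L,
    in_channels = c(in_channels, ce, ce), out_channels = ce,
    has_bias = c(TRUE, NA, NA))
  if (config$ablation == "no_depthwise") {
    blk$params$spatial <- c(init_conv(ce, ce, 3), bn = list(init_bn(ce)))
    spec <- rbind(spec, data.frame(
      stage = "ir", kind = c("conv", "batch_norm", "relu"),
      kernel = c(3L, 0L, 0L), stride = c(as.integer(stride), 1L, 1L),
      padding = c(1L, 0L, 0L), in_channels = ce, out_channels = ce,
      has_bias = c(TRUE, NA, NA)))
  } else {
    blk$params$spatial <- list(w = array(rand_w(9 * ce, 9), c(3, 3, ce)),
                               bn = init_bn(ce))
    spec <- rbind(spec, data.frame(
      stage = "ir", kind = c("depthwise_conv", "batch_norm", "relu"),
      kernel = c(3L, 0L, 0L), stride = c(as.integer(stride), 1L, 1L),
      padding = c(1L, 0L, 0L), in_channels = ce, out_channels = ce,
      has_bias = c(FALSE, NA, NA)))
  }
  blk$state$spatial <- list(bn = init_bn_state(ce))
  if (config$ablation != "no_attention") {
    ca <- build_channel_attention(ce, config$reduction_ratio)
    blk$params$ca <- ca$params
    blk$state$ca <- ca$state
    spec <- rbind(spec, ca$spec)
  }
  blk$params$project <- c(init_conv(ce, out_channels, 1),
                          bn = list(init_bn(out_channels)))
  blk$state$project <- list(bn = init_bn_state(out_channels))
  spec <- rbind(spec, data.frame(
    stage = "ir", kind = c("conv", "batch_norm"),
    kernel = c(1L, 0L), stride = 1L, padding = 0L,
    in_channels = c(ce, out_channels), out_channels = out_channels,
    has_bias = c(TRUE, NA)))
  if (residual)
    spec <- rbind(spec, data.frame(
      stage = "ir", kind = "add", kernel = 0L, stride = 1L, padding = 0L,
      in_channels = out_channels, out_channels = out_channels, has_bias = NA))
  blk$spec <- spec
  blk
}

#' Build the classification head
#'
#' A 1x1 projection to the head width (BN, ReLU; omitted entirely for the
#' `no_final_projection` ablation), global average pooling, dropout on the
#' pooled vector, and a fully connected classifier.
#'
#' @param in_channels Channels entering the head.
#' @param config The parent [arch_config()].
#' @return A layer block.
#' @export
build_head <- function(in_channels, config) {
  project <- config$ablation != "no_final_projection"
  fc_in <- if (project) config$schedule$head_out else in_channels
  blk <- list(fc_in = fc_in, project = project, params = list(), state = list())
  spec <- NULL
  if (project) {
    blk$params$conv <- c(init_conv(in_channels, fc_in, 1),
                         bn = list(init_bn(fc_in)))
    blk$state$conv <- list(bn = init_bn_state(fc_in))
    spec <- data.frame(
      stage = "head", kind = c("conv", "batch_norm", "relu"),
      kernel = c(1L, 0L, 0L), stride = 1L, padding = 0L,
      in_channels = c(in_channels, fc_in, fc_in), out_channels = fc_in,
      has_bias = c(TRUE, NA, NA))
  }
  blk$params$fc <- list(w = matrix(rand_w(fc_in * config$num_classes,
                                          config$num_classes),
                                   fc_in, config$num_classes),
                        b = numeric(config$num_classes))
  spec <- rbind(spec, data.frame(
    stage = "head",
    kind = c("global_avg_pool", "dropout", "fully_connected"),
    kernel = 0L, stride = 1L, padding = 0L,
    in_channels = fc_in, out_channels = c(fc_in, fc_in, config$num_classes),
    has_bias = c(NA, NA, TRUE)))
  blk$spec <- spec
  blk
}

# ---- assembly ---------------------------------------------------------------

#' Assemble a network from a configuration
#'
#' Builds the full computation graph (stem, multi-scale block, five inverted
#' residual blocks, head) with deterministically seeded Kaiming-style
#' initialization. Ablation flags in the config change the structure as
#' described in [make_ablation_config()].
#'
#' @param config An [arch_config()].
#' @param seed Integer seed for weight initialization (default 0).
#' @return A `weednet` object.
#' @examples
#' net <- assemble_network(arch_config(stem_channels = 8, input_side = 32))
#' @export
assemble_network <- function(config, seed = 0) {
  validate_arch_config(config)
  sch <- config$schedule
  with_seed(seed, {
    stem <- build_stem(config)
    msc <- if (config$ablation == "no_msc")
      build_single_branch(sch$stem_out, sch$msc_out)
    else build_msc_block(sch$stem_out, sch)
    irs <- list()
    cin <- sch$msc_out
    for (i in 1:5) {
      irs[[i]] <- build_ir_block(cin, sch$ir_out[i], sch$ir_strides[i], config)
      cin <- sch$ir_out[i]
    }
    head <- build_head(cin, config)
    blocks <- c(list(stem = stem, msc = msc), stats::setNames(irs, paste0("ir", 1:5)),
                list(head = head))
    spec <- do.call(rbind, lapply(names(blocks), function(nm) {
      s <- blocks[[nm]]$spec
      s$block <- nm
      s
    }))
    net <- list(
      config = config,
      seed = seed,
      params = lapply(blocks, `[[`, "params"),
      state = lapply(blocks, `[[`, "state"),
      meta = list(ir = lapply(irs, function(b) b[c("ce", "stride", "residual")]),
                  head = head[c("fc_in", "project")]),
      layers = spec)
    class(net) <- "weednet"
    net
  })
}

#' @export
print.weednet <- function(x, ...) {
  cat(sprintf("<weednet %s>  %s parameters\n", x$config$id,
              format(count_parameters(x)$total_params, big.mark = ",")))
  print(infer_shapes(x))
  invisible(x)
}

# ---- shape inference --------------------------------------------------------

conv_out_side <- function(side, k, s, p)
  as.integer((side + 2 * p - k) %/% s + 1)

#' Infer the activation-shape schedule
#'
#' Returns the activation spec after each named stage (stem, multi-scale
#' block, the five inverted residual blocks, head projection, global pooling
#' and classifier) for a given square input.
#'
#' @param network A `weednet` or an [arch_config()].
#' @param input Integer vector `c(channels, height, width)`;
#'   defaults to the config's input side.
#' @return A data frame with columns `stage`, `channels`, `height`, `width`.
#' @export
infer_shapes <- function(network, input = NULL) {
  cfg <- if (inherits(network, "weednet")) network$config else network
  validate_arch_config(cfg)
  if (is.null(input)) input <- c(3L, cfg$input_side, cfg$input_side)
  input <- as.integer(input)
  if (length(input) != 3 || input[1] != 3)
    stop("input spec must be c(3, height, width)", call. = FALSE)
  if (input[2] != input[3])
    stop("non-square inputs are not supported", call. = FALSE)
  if (input[2] < 32)
    stop("input side must be at least 32 pixels", call. = FALSE)
  sch <- cfg$schedule
  side <- conv_out_side(input[2], 3, 2, 1)
  shapes <- data.frame(stage = "stem", channels = sch$stem_out,
                       height = side, width = side)
  shapes <- rbind(shapes, data.frame(stage = "msc", channels = sch$msc_out,
                                     height = side, width = side))
  for (i in 1:5) {
    side <- conv_out_side(side, 3, sch$ir_strides[i], 1)
    shapes <- rbind(shapes, data.frame(stage = paste0("ir", i),
                                       channels = sch$ir_out[i],
                                       height = side, width = side))
  }
  fc_in <- if (cfg$ablation == "no_final_projection") sch$ir_out[5] else sch$head_out
  if (cfg$ablation != "no_final_projection")
    shapes <- rbind(shapes, data.frame(stage = "head_conv",
                                       channels = sch$head_out,
                                       height = side, width = side))
  shapes <- rbind(shapes,
                  data.frame(stage = "gap", channels = fc_in, height = 1L,
                             width = 1L),
                  data.frame(stage = "fc", channels = cfg$num_classes,
                             height = 1L, width = 1L))
  shapes
}

# ---- forward / backward -----------------------------------------------------

scale_channels <- function(x, s) {
  d <- dim(x)
  dim(x) <- c(d[1], d[2] * d[3], d[4])
  for (n in seq_len(d[4])) x[, , n] <- x[, , n] * s[, n]
  dim(x) <- d
  x
}

channel_sums <- function(a, b) {
  # sum over H, W of a*b, per (channel, sample)
  d <- dim(a)
  prod_ <- a * b
  dim(prod_) <- c(d[1], d[2] * d[3], d[4])
  out <- matrix(0, d[1], d[4])
  for (n in seq_len(d[4])) out[, n] <- rowSums(prod_[, , n, drop = FALSE])
  out
}

convbn_f <- function(p, st, x, k, s, pad, training) {
  z <- conv_fwd(x, p$w, p$b, k, s, pad)
  bn <- bn_fwd(z, p$bn$gamma, p$bn$beta, st$bn, training)
  r <- relu_fwd(bn$out)
  list(out = r$out, state = list(bn = bn$state),
       cache = list(x = x, bn = bn$cache, mask = r$cache, k = k, s = s,
                    pad = pad))
}

convbn_b <- function(p, cache, dout) {
  dr <- relu_bwd(dout, cache$mask)
  dbn <- bn_bwd(dr, p$bn$gamma, cache$bn)
  dc <- conv_bwd(cache$x, p$w, dbn$dx, cache$k, cache$s, cache$pad, TRUE)
  list(dx = dc$dx,
       grads = list(w = dc$dw, b = dc$db,
                    bn = list(gamma = dbn$dgamma, beta = dbn$dbeta)))
}

ca_f <- function(p, st, x, training) {
  qa <- gap_fwd(x)
  qm_ <- gmp_fwd(x)
  ha <- crossprod(p$w1, qa) + p$b1
  bna <- bn_fwd(ha, p$bn$gamma, p$bn$beta, st$bn, training)
  ra <- relu_fwd(bna$out)
  hm <- crossprod(p$w1, qm_$out) + p$b1
  bnm <- bn_fwd(hm, p$bn$gamma, p$bn$beta, bna$state, training)
  rm_ <- relu_fwd(bnm$out)
  s <- sigmoid_fwd(crossprod(p$w2, ra$out) + p$b2 +
                   crossprod(p$w2, rm_$out) + p$b2)
  list(out = scale_channels(x, s), state = list(bn = bnm$state),
       cache = list(x = x, s = s, qa = qa, qm = qm_$out, qm_idx = qm_$idx,
                    bna = bna$cache, bnm = bnm$cache,
                    ma = ra$cache, mm = rm_$cache,
                    ra = ra$out, rm = rm_$out))
}

ca_b <- function(p, cache, dout) {
  x <- cache$x
  s <- cache$s
  xdim <- dim(x)
  dx <- scale_channels(dout, s)
  ds <- channel_sums(dout, x)
  dpre <- ds * s * (1 - s)
  db2 <- 2 * rowSums(dpre)
  dw2 <- cache$ra %*% t(dpre) + cache$rm %*% t(dpre)
  dra <- p$w2 %*% dpre
  drm <- dra
  dbna_out <- relu_bwd(dra, cache$ma)
  dbnm_out <- relu_bwd(drm, cache$mm)
  ba <- bn_bwd(dbna_out, p$bn$gamma, cache$bna)
  bm <- bn_bwd(dbnm_out, p$bn$gamma, cache$bnm)
  dha <- ba$dx
  dhm <- bm$dx
  db1 <- rowSums(dha) + rowSums(dhm)
  dw1 <- cache$qa %*% t(dha) + cache$qm %*% t(dhm)
  dqa <- p$w1 %*% dha
  dqm <- p$w1 %*% dhm
  dx <- dx + gap_bwd(dqa, xdim) + gmp_bwd(dqm, cache$qm_idx, xdim)
  list(dx = dx,
       grads = list(w1 = dw1, b1 = db1,
                    bn = list(gamma = ba$dgamma + bm$dgamma,
                              beta = ba$dbeta + bm$dbeta),
                    w2 = dw2, b2 = db2))
}

ir_f <- function(p, st, x, meta, training, ablation) {
  ex <- convbn_f(p$expand, st$expand, x, 1, 1, 0, training)
  if (ablation == "no_depthwise") {
    sp <- convbn_f(p$spatial, st$spatial, ex$out, 3, meta$stride, 1, training)
    sp_cache <- sp$cache
  } else {
    z <- dw_fwd(ex$out, p$spatial$w, meta$stride)
    bn <- bn_fwd(z, p$spatial$bn$gamma, p$spatial$bn$beta, st$spatial$bn,
                 training)
    r <- relu_fwd(bn$out)
    sp <- list(out = r$out, state = list(bn = bn$state))
    sp_cache <- list(x = ex$out, bn = bn$cache, mask = r$cache,
                     s = meta$stride)
  }
  cur <- sp$out
  ca_cache <- NULL
  ca_state <- NULL
  if (!is.null(p$ca)) {
    ca <- ca_f(p$ca, st$ca, cur, training)
    cur <- ca$out
    ca_cache <- ca$cache
    ca_state <- ca$state
  }
  z <- conv_fwd(cur, p$project$w, p$project$b, 1, 1, 0)
  bn <- bn_fwd(z, p$project$bn$gamma, p$project$bn$beta, st$project$bn,
               training)
  out <- bn$out
  if (meta$residual) out <- out + x
  list(out = out,
       state = list(expand = ex$state, spatial = sp$state, ca = ca_state,
                    project = list(bn = bn$state)),
       cache = list(expand = ex$cache, spatial = sp_cache, ca = ca_cache,
                    proj_x = cur, proj_bn = bn$cache, residual = meta$residual))
}

ir_b <- function(p, cache, dout, ablation) {
  grads <- list()
  dbn <- bn_bwd(dout, p$project$bn$gamma, cache$proj_bn)
  dc <- conv_bwd(cache$proj_x, p$project$w, dbn$dx, 1, 1, 0, TRUE)
  grads$project <- list(w = dc$dw, b = dc$db,
                        bn = list(gamma = dbn$dgamma, beta = dbn$dbeta))
  cur <- dc$dx
  if (!is.null(cache$ca)) {
    ca <- ca_b(p$ca, cache$ca, cur)
    grads$ca <- ca$grads
    cur <- ca$dx
  }
  if (ablation == "no_depthwise") {
    sp <- convbn_b(p$spatial, cache$spatial, cur)
    grads$spatial <- sp$grads
    cur <- sp$dx
  } else {
    dr <- relu_bwd(cur, cache$spatial$mask)
    dbn2 <- bn_bwd(dr, p$spatial$bn$gamma, cache$spatial$bn)
    dd <- dw_bwd(cache$spatial$x, p$spatial$w, dbn2$dx, cache$spatial$s)
    grads$spatial <- list(w = dd$dw, bn = list(gamma = dbn2$dgamma,
                                               beta = dbn2$dbeta))
    cur <- dd$dx
  }
  ex <- convbn_b(p$expand, cache$expand, cur)
  grads$expand <- ex$grads
  dx <- ex$dx
  if (cache$residual) dx <- dx + dout
  list(dx = dx, grads = grads)
}

msc_f <- function(p, st, x, training, single) {
  if (single) {
    r <- convbn_f(p, st, x, 3, 1, 1, training)
    return(list(out = r$out, state = r$state, cache = r$cache))
  }
  ks <- c(1, 3, 5, 1)
  outs <- vector("list", 4)
  caches <- vector("list", 4)
  states <- vector("list", 4)
  pool_cache <- NULL
  for (i in 1:4) {
    xi <- x
    if (i == 4) {
      mp <- maxpool_fwd(x, 3L, 1L, 1L)
      xi <- mp$out
      pool_cache <- mp$idx
    }
    r <- convbn_f(p[[paste0("b", i)]], st[[paste0("b", i)]], xi, ks[i], 1,
                  (ks[i] - 1) / 2, training)
    outs[[i]] <- r$out
    caches[[i]] <- r$cache
    states[[i]] <- r$state
  }
  widths <- vapply(outs, function(o) dim(o)[1], 0L)
  d <- dim(outs[[1]])
  out <- array(0, c(sum(widths), d[2], d[3], d[4]))
  off <- 0L
  for (i in 1:4) {
    out[off + seq_len(widths[i]), , , ] <- outs[[i]]
    off <- off + widths[i]
  }
  names(states) <- paste0("b", 1:4)
  list(out = out, state = states,
       cache = list(branches = caches, widths = widths, pool_idx = pool_cache,
                    xdim = dim(x)))
}

msc_b <- function(p, cache, dout, single) {
  if (single) {
    r <- convbn_b(p, cache, dout)
    return(list(dx = r$dx, grads = r$grads))
  }
  grads <- list()
  dx <- array(0, cache$xdim)
  off <- 0L
  for (i in 1:4) {
    w <- cache$widths[i]
    di <- dout[off + seq_len(w), , , , drop = FALSE]
    off <- off + w
    r <- convbn_b(p[[paste0("b", i)]], cache$branches[[i]], di)
    grads[[paste0("b", i)]] <- r$grads
    if (i == 4) {
      dx <- dx + maxpool_bwd(r$dx, cache$pool_idx, cache$xdim)
    } else {
      dx <- dx + r$dx
    }
  }
  list(dx = dx, grads = grads)
}

head_f <- function(p, st, x, meta, dropout_p, training) {
  conv_cache <- NULL
  conv_state <- NULL
  cur <- x
  if (meta$project) {
    r <- convbn_f(p$conv, st$conv, x, 1, 1, 0, training)
    cur <- r$out
    conv_cache <- r$cache
    conv_state <- r$state
  }
  pooled <- gap_fwd(cur)
  dr <- dropout_fwd(pooled, dropout_p, training)
  logits <- fc_fwd(dr$out, p$fc$w, p$fc$b)
  list(out = logits, state = list(conv = conv_state),
       cache = list(conv = conv_cache, xdim = dim(cur), fc_x = dr$out,
                    drop_mask = dr$cache))
}

head_b <- function(p, cache, dout, meta) {
  grads <- list()
  fcb <- fc_bwd(cache$fc_x, p$fc$w, dout)
  grads$fc <- list(w = fcb$dw, b = fcb$db)
  dp <- dropout_bwd(fcb$dx, cache$drop_mask)
  dx <- gap_bwd(dp, cache$xdim)
  if (meta$project) {
    r <- convbn_b(p$conv, cache$conv, dx)
    grads$conv <- r$grads
    dx <- r$dx
  }
  list(dx = dx, grads = grads)
}

network_forward <- function(net, x, training = FALSE, keep_cache = training) {
  abl <- net$config$ablation
  caches <- list()
  r <- convbn_f(net$params$stem, net$state$stem, x, 3, 2, 1, training)
  if (training) net$state$stem <- r$state
  if (keep_cache) caches$stem <- r$cache
  cur <- r$out
  r <- msc_f(net$params$msc, net$state$msc, cur, training, abl == "no_msc")
  if (training) net$state$msc <- r$state
  if (keep_cache) caches$msc <- r$cache
  cur <- r$out
  for (i in 1:5) {
    nm <- paste0("ir", i)
    r <- ir_f(net$params[[nm]], net$state[[nm]], cur, net$meta$ir[[i]],
              training, abl)
    if (training) net$state[[nm]] <- r$state
    if (keep_cache) caches[[nm]] <- r$cache
    cur <- r$out
  }
  r <- head_f(net$params$head, net$state$head, cur, net$meta$head,
              net$config$dropout_p, training)
  if (training) net$state$head <- r$state
  if (keep_cache) caches$head <- r$cache
  list(logits = r$out, caches = caches, net = net)
}

network_backward <- function(net, caches, dlogits) {
  abl <- net$config$ablation
  grads <- list()
  r <- head_b(net$params$head, caches$head, dlogits, net$meta$head)
  grads$head <- r$grads
  cur <- r$dx
  for (i in 5:1) {
    nm <- paste0("ir", i)
    r <- ir_b(net$params[[nm]], caches[[nm]], cur, abl)
    grads[[nm]] <- r$grads
    cur <- r$dx
  }
  r <- msc_b(net$params$msc, caches$msc, cur, abl == "no_msc")
  grads$msc <- r$grads
  cur <- r$dx
  r <- convbn_b(net$params$stem, caches$stem, cur)
  grads$stem <- r$grads
  grads
}

check_batch <- function(net, batch) {
  d <- dim(batch)
  side <- net$config$input_side
  if (is.null(d) || length(d) != 4 || d[1] != 3 || d[2] != side || d[3] != side)
    stop(sprintf("batch must be a (3, %d, %d, N) array", side, side),
         call. = FALSE)
  rng <- range(batch)
  if (rng[1] < -1e-8 || rng[2] > 1 + 1e-8)
    stop("batch values must lie in [0, 1]", call. = FALSE)
  invisible(TRUE)
}

#' Run inference
#'
#' Evaluation-mode forward pass (running BN statistics, dropout disabled).
#'
#' @param network A `weednet`.
#' @param batch Array `c(3, side, side, N)` of images in `[0, 1]`.
#' @return An `N x num_classes` matrix of logits.
#' @export
forward <- function(network, batch) {
  check_batch(network, batch)
  t(network_forward(network, batch, training = FALSE, keep_cache = FALSE)$logits)
}

#' Predict class labels
#'
#' @param object A `weednet`.
#' @param batch Image array `c(3, side, side, N)`.
#' @param type `"class"` for 0-based labels, `"logits"`, or `"prob"`.
#' @param batch_size Images per forward chunk (default 32).
#' @param ... Unused.
#' @return Labels, logits or softmax probabilities.
#' @export
predict.weednet <- function(object, batch, type = c("class", "logits", "prob"),
                            batch_size = 32, ...) {
  type <- match.arg(type)
  n <- dim(batch)[4]
  out <- NULL
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    out <- rbind(out, forward(object, batch[, , , idx, drop = FALSE]))
  }
  switch(type,
         logits = out,
         prob = {
           e <- exp(out - apply(out, 1, max))
           e / rowSums(e)
         },
         class = max.col(out, ties.method = "first") - 1L)
}
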