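# Export to a framework-independent exchange graph and operator linting.
#
# The exchange format is a self-describing JSON document modeled on the open
# neural-network exchange schema: a flat list of typed nodes (op_type,
# inputs, outputs, attributes) plus named initializers. Batch norm is
# serialized in inference form (running statistics as initializers); dropout
# is stripped. A reference interpreter (run_exported_graph) re-executes the
# serialized graph node by node so that round-trip equivalence can be
# checked without the originating object.

#' Operators natively supported by the embedded deployment target
#'
#' Standard/pointwise/grouped convolutions, batch normalization, ReLU and
#' sigmoid activations, local and global pooling, fully connected layers,
#' concatenation, element-wise add/multiply, and reshape/flatten.
#'
#' @return Character vector of permitted `op_type` values.
#' @export
operator_whitelist <- function() {
  c("Conv", "BatchNormalization", "Relu", "Sigmoid", "MaxPool", "AveragePool",
    "GlobalAveragePool", "GlobalMaxPool", "Gemm", "MatMul", "Add", "Mul",
    "Concat", "Flatten", "Reshape")
}

exporter <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env$inits <- list()
  env$counter <- 0L
  env
}

ex_name <- function(ex, prefix) {
  ex$counter <- ex$counter + 1L
  sprintf("%s_%d", prefix, ex$counter)
}

ex_init <- function(ex, name, values, dims) {
  ex$inits[[name]] <- list(dims = as.integer(dims), values = as.numeric(values))
  name
}

ex_node <- function(ex, op, inputs, prefix, attrs = NULL) {
  out <- ex_name(ex, prefix)
  node <- list(op_type = op, inputs = as.list(inputs), output = out)
  if (!is.null(attrs)) node$attrs <- attrs
  ex$nodes[[length(ex$nodes) + 1L]] <- node
  out
}

# conv weight matrices are (Cin*k*k) x Cout with row index c + Cin*(ki+k*kj);
# serialize with dims (Cout, Cin, k, k) semantics via explicit dims metadata.
ex_conv <- function(ex, ex_in, p, k, s, pad, group = 1L, prefix) {
  wn <- ex_init(ex, paste0(prefix, "_w"), p$w,
                c(ncol(p$w), nrow(p$w) / (k * k), k, k))
  ins <- c(ex_in, wn)
  if (!is.null(p$b)) ins <- c(ins, ex_init(ex, paste0(prefix, "_b"), p$b,
                                           length(p$b)))
  ex_node(ex, "Conv", ins, prefix,
          attrs = list(kernel_shape = c(k, k), strides = c(s, s),
                       pads = c(pad, pad, pad, pad), group = group))
}

ex_dwconv <- function(ex, ex_in, w, s, prefix) {
  k <- dim(w)[1]
  c_ <- dim(w)[3]
  wn <- ex_init(ex, paste0(prefix, "_w"), w, c(c_, 1L, k, k))
  ex_node(ex, "Conv", c(ex_in, wn), prefix,
          attrs = list(kernel_shape = c(k, k), strides = c(s, s),
                       pads = rep((k - 1) / 2, 4), group = c_))
}

ex_bn <- function(ex, ex_in, bn, st, prefix) {
  n <- length(bn$gamma)
  ins <- c(ex_in,
           ex_init(ex, paste0(prefix, "_gamma"), bn$gamma, n),
           ex_init(ex, paste0(prefix, "_beta"), bn$beta, n),
           ex_init(ex, paste0(prefix, "_mean"), st$mean, n),
           ex_init(ex, paste0(prefix, "_var"), st$var, n))
  ex_node(ex, "BatchNormalization", ins, prefix,
          attrs = list(epsilon = BN_EPS))
}

ex_convbn <- function(ex, ex_in, p, st, k, s, pad, prefix, act = TRUE) {
  cur <- ex_conv(ex, ex_in, p, k, s, pad, 1L, paste0(prefix, "_conv"))
  cur <- ex_bn(ex, cur, p$bn, st$bn, paste0(prefix, "_bn"))
  if (act) cur <- ex_node(ex, "Relu", cur, paste0(prefix, "_relu"))
  cur
}

ex_fc <- function(ex, ex_in, w, b, prefix) {
  wn <- ex_init(ex, paste0(prefix, "_w"), w, dim(w))
  ins <- c(ex_in, wn)
  if (!is.null(b)) ins <- c(ins, ex_init(ex, paste0(prefix, "_b"), b,
                                         length(b)))
  ex_node(ex, "Gemm", ins, prefix)
}

ex_ca <- function(ex, ex_in, p, st, prefix) {
  qa <- ex_node(ex, "GlobalAveragePool", ex_in, paste0(prefix, "_gap"))
  qm <- ex_node(ex, "GlobalMaxPool", ex_in, paste0(prefix, "_gmp"))
  # shared bottleneck weights, serialized once, referenced by both paths
  w1 <- ex_init(ex, paste0(prefix, "_w1"), p$w1, dim(p$w1))
  b1 <- ex_init(ex, paste0(prefix, "_b1"), p$b1, length(p$b1))
  w2 <- ex_init(ex, paste0(prefix, "_w2"), p$w2, dim(p$w2))
  b2 <- ex_init(ex, paste0(prefix, "_b2"), p$b2, length(p$b2))
  bng <- ex_init(ex, paste0(prefix, "_bn_gamma"), p$bn$gamma, length(p$bn$gamma))
  bnb <- ex_init(ex, paste0(prefix, "_bn_beta"), p$bn$beta, length(p$bn$beta))
  bnm <- ex_init(ex, paste0(prefix, "_bn_mean"), st$bn$mean, length(st$bn$mean))
  bnv <- ex_init(ex, paste0(prefix, "_bn_var"), st$bn$var, length(st$bn$var))
  path <- function(q, tag) {
    h <- ex_node(ex, "Gemm", c(q, w1, b1), paste0(prefix, "_fc1", tag))
    h <- ex_node(ex, "BatchNormalization", c(h, bng, bnb, bnm, bnv),
                 paste0(prefix, "_bn", tag), attrs = list(epsilon = BN_EPS))
    h <- ex_node(ex, "Relu", h, paste0(prefix, "_relu", tag))
    ex_node(ex, "Gemm", c(h, w2, b2), paste0(prefix, "_fc2", tag))
  }
  sa <- path(qa, "_avg")
  sm <- path(qm, "_max")
  s <- ex_node(ex, "Add", c(sa, sm), paste0(prefix, "_addpaths"))
  s <- ex_node(ex, "Sigmoid", s, paste0(prefix, "_gate"))
  ex_node(ex, "Mul", c(ex_in, s), paste0(prefix, "_scale"))
}

#' Export a network to the JSON exchange format
#'
#' Serializes the inference graph (batch norm in running-statistics form,
#' dropout stripped) with every weight as a named initializer. The file can
#' be re-executed with [run_exported_graph()] and linted with
#' [check_operator_whitelist()].
#'
#' @param network A `weednet`.
#' @param path Output file (conventionally `.json`).
#' @param digits Significant digits for serialized weights (default 8; the
#'   round-trip tolerance of 1e-4 is met with wide margin).
#' @return `path`, invisibly.
#' @export
export_graph <- function(network, path, digits = 8) {
  stopifnot(inherits(network, "weednet"))
  cfg <- network$config
  abl <- cfg$ablation
  ex <- exporter()
  cur <- "input"
  p <- network$params
  st <- network$state
  cur <- ex_convbn(ex, cur, p$stem, st$stem, 3, 2, 1, "stem")
  if (abl == "no_msc") {
    cur <- ex_convbn(ex, cur, p$msc, st$msc, 3, 1, 1, "msc")
  } else {
    outs <- character(4)
    ks <- c(1, 3, 5, 1)
    for (i in 1:4) {
      brin <- cur
      if (i == 4)
        brin <- ex_node(ex, "MaxPool", cur, "msc_pool",
                        attrs = list(kernel_shape = c(3, 3),
                                     strides = c(1, 1), pads = rep(1, 4)))
      outs[i] <- ex_convbn(ex, brin, p$msc[[paste0("b", i)]],
                           st$msc[[paste0("b", i)]], ks[i], 1,
                           (ks[i] - 1) / 2, paste0("msc_b", i))
    }
    cur <- ex_node(ex, "Concat", outs, "msc_concat", attrs = list(axis = 1))
  }
  for (i in 1:5) {
    nm <- paste0("ir", i)
    meta <- network$meta$ir[[i]]
    block_in <- cur
    cur <- ex_convbn(ex, cur, p[[nm]]$expand, st[[nm]]$expand, 1, 1, 0,
                     paste0(nm, "_expand"))
    if (abl == "no_depthwise") {
      cur <- ex_convbn(ex, cur, p[[nm]]$spatial, st[[nm]]$spatial, 3,
                       meta$stride, 1, paste0(nm, "_spatial"))
    } else {
      cur <- ex_dwconv(ex, cur, p[[nm]]$spatial$w, meta$stride,
                       paste0(nm, "_dw"))
      cur <- ex_bn(ex, cur, p[[nm]]$spatial$bn, st[[nm]]$spatial$bn,
                   paste0(nm, "_dwbn"))
      cur <- ex_node(ex, "Relu", cur, paste0(nm, "_dwrelu"))
    }
    if (abl != "no_attention")
      cur <- ex_ca(ex, cur, p[[nm]]$ca, st[[nm]]$ca, paste0(nm, "_ca"))
    cur <- ex_conv(ex, cur, p[[nm]]$project, 1, 1, 0, 1L,
                   paste0(nm, "_project"))
    cur <- ex_bn(ex, cur, p[[nm]]$project$bn, st[[nm]]$project$bn,
                 paste0(nm, "_projbn"))
    if (meta$residual)
      cur <- ex_node(ex, "Add", c(cur, block_in), paste0(nm, "_residual"))
  }
  if (network$meta$head$project)
    cur <- ex_convbn(ex, cur, p$head$conv, st$head$conv, 1, 1, 0, "head")
  cur <- ex_node(ex, "GlobalAveragePool", cur, "head_gap")
  cur <- ex_node(ex, "Flatten", cur, "head_flatten")
  cur <- ex_fc(ex, cur, p$head$fc$w, p$head$fc$b, "head_fc")
  doc <- list(
    format = "weednet-exchange/1",
    producer = paste0("tinyweednet ",
                      as.character(utils::packageVersion("tinyweednet"))),
    config = list(id = cfg$id, input_side = cfg$input_side,
                  num_classes = cfg$num_classes),
    graph = list(input = list(name = "input",
                              shape = c(3L, cfg$input_side, cfg$input_side)),
                 output = cur,
                 nodes = ex$nodes,
                 initializers = ex$inits))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(digits))
  invisible(path)
}

load_exported_graph <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (is.null(doc$graph) || is.null(doc$graph$nodes))
    stop("not a weednet exchange file: ", path, call. = FALSE)
  doc
}

interp_tensor <- function(init) {
  v <- as.numeric(unlist(init$values))
  dims <- as.integer(unlist(init$dims))
  if (length(dims) > 1) {
    # initializers are serialized from column-major R objects
    if (length(dims) == 4 && dims[2] >= 1) {
      # conv weight (Cout, Cin/g, k, k): stored flat as (Cin*k*k) x Cout
      return(matrix(v, nrow = prod(dims[-1]), ncol = dims[1]))
    }
    return(matrix(v, nrow = dims[1], ncol = dims[2]))
  }
  v
}

#' Execute an exported graph on an input batch
#'
#' Reference interpreter for the exchange format: runs every node in file
#' order against named tensors, reproducing the originating network's
#' inference-mode logits.
#'
#' @param path Exchange file written by [export_graph()].
#' @param batch Image array `c(3, side, side, N)`.
#' @return An `N x num_classes` logits matrix.
#' @export
run_exported_graph <- function(path, batch) {
  doc <- load_exported_graph(path)
  tensors <- new.env(parent = emptyenv())
  assign("input", batch, tensors)
  inits <- doc$graph$initializers
  get_t <- function(nm) {
    if (!is.null(inits[[nm]])) return(interp_tensor(inits[[nm]]))
    get(nm, tensors)
  }
  for (node in doc$graph$nodes) {
    ins <- lapply(unlist(node$inputs), get_t)
    a <- node$attrs
    out <- switch(node$op_type,
      Conv = {
        g <- if (is.null(a$group)) 1L else as.integer(a$group)
        k <- as.integer(a$kernel_shape[[1]])
        s <- as.integer(a$strides[[1]])
        pd <- as.integer(a$pads[[1]])
        if (g > 1) {
          w <- array(as.numeric(ins[[2]]), c(k, k, g))
          cpp_dwconv_forward(ins[[1]], dim(ins[[1]]), w, k, s, pd)
        } else {
          b <- if (length(ins) >= 3) as.numeric(ins[[3]]) else NULL
          cpp_conv_forward(ins[[1]], dim(ins[[1]]), ins[[2]], b, k, s, pd)
        }
      },
      BatchNormalization = {
        x <- ins[[1]]
        gmm <- as.numeric(ins[[2]]); bt <- as.numeric(ins[[3]])
        mu <- as.numeric(ins[[4]]); vr <- as.numeric(ins[[5]])
        d <- if (is.null(dim(x))) c(length(x), 1L) else dim(x)
        m <- matrix(x, nrow = d[1])
        out <- ((m - mu) / sqrt(vr + a$epsilon)) * gmm + bt
        dim(out) <- dim(x)
        out
      },
      Relu = ins[[1]] * (ins[[1]] > 0),
      Sigmoid = 1 / (1 + exp(-ins[[1]])),
      MaxPool = cpp_maxpool_forward(ins[[1]], dim(ins[[1]]),
                                    as.integer(a$kernel_shape[[1]]),
                                    as.integer(a$strides[[1]]),
                                    as.integer(a$pads[[1]]))$out,
      GlobalAveragePool = gap_fwd(ins[[1]]),
      GlobalMaxPool = gmp_fwd(ins[[1]])$out,
      Gemm = {
        b <- if (length(ins) >= 3) as.numeric(ins[[3]]) else 0
        crossprod(ins[[2]], ins[[1]]) + b
      },
      Add = ins[[1]] + ins[[2]],
      Mul = {
        if (is.matrix(ins[[2]]) || is.null(dim(ins[[2]])))
          scale_channels(ins[[1]], as.matrix(ins[[2]]))
        else ins[[1]] * ins[[2]]
      },
      Flatten = as.matrix(ins[[1]]),
      Concat = {
        ds <- lapply(ins, dim)
        tot <- sum(vapply(ds, `[`, 0L, 1))
        out <- array(0, c(tot, ds[[1]][2], ds[[1]][3], ds[[1]][4]))
        off <- 0L
        for (x in ins) {
          out[off + seq_len(dim(x)[1]), , , ] <- x
          off <- off + dim(x)[1]
        }
        out
      },
      stop("unsupported op in exchange file: ", node$op_type, call. = FALSE))
    assign(node$output, out, tensors)
  }
  t(get(doc$graph$output, tensors))
}

#' Lint an exported graph against the embedded-operator whitelist
#'
#' @param path Exchange file, or a parsed exchange document.
#' @param whitelist Permitted op types (default [operator_whitelist()]).
#' @return A `compat_report`: list with `inventory` (named op counts),
#'   `violations` (data frame op/location) and `passed`.
#' @export
check_operator_whitelist <- function(path, whitelist = operator_whitelist()) {
  doc <- if (is.character(path)) load_exported_graph(path) else path
  ops <- vapply(doc$graph$nodes, `[[`, "", "op_type")
  locs <- vapply(doc$graph$nodes, `[[`, "", "output")
  inventory <- if (length(ops)) table(ops) else table(character())
  bad <- !(ops %in% whitelist)
  violations <- data.frame(operator = ops[bad], location = locs[bad])
  rep_ <- list(inventory = inventory, violations = violations,
               passed = nrow(violations) == 0)
  class(rep_) <- "compat_report"
  rep_
}

#' @export
print.compat_report <- function(x, ...) {
  cat(if (x$passed) "PASS" else "FAIL",
      "- operator inventory:\n")
  print(x$inventory)
  if (!x$passed) print(x$violations, row.names = FALSE)
  invisible(x)
}
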