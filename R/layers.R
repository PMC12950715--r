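# Internal layer primitives. All activations use dim = c(C, H, W, N); pooled
# vectors use C x N matrices. Forward functions return list(out, cache);
# backward functions return list(dx, <grads>). BN follows the usual framework
# defaults: eps 1e-5, running-stat momentum 0.1, biased batch variance for
# normalization, unbiased for the running estimate.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

conv_fwd <- function(x, w, b, k, s, p) {
  cpp_conv_forward(x, dim(x), w, b, as.integer(k), as.integer(s), as.integer(p))
}

conv_bwd <- function(x, w, dout, k, s, p, has_bias) {
  cpp_conv_backward(x, dim(x), w, dout, as.integer(k), as.integer(s),
                    as.integer(p), has_bias)
}

dw_fwd <- function(x, w, s) {
  k <- dim(w)[1]
  cpp_dwconv_forward(x, dim(x), w, as.integer(k), as.integer(s), as.integer((k - 1) / 2))
}

dw_bwd <- function(x, w, dout, s) {
  k <- dim(w)[1]
  cpp_dwconv_backward(x, dim(x), w, dout, as.integer(k), as.integer(s),
                      as.integer((k - 1) / 2))
}

maxpool_fwd <- function(x, k, s, p) cpp_maxpool_forward(x, dim(x), k, s, p)

maxpool_bwd <- function(dout, idx, xdim) cpp_maxpool_backward(dout, idx, xdim)

relu_fwd <- function(x) {
  out <- x * (x > 0)
  list(out = out, cache = x > 0)
}

relu_bwd <- function(dout, mask) dout * mask

sigmoid_fwd <- function(x) 1 / (1 + exp(-x))

# Batch norm over channels of a (C, ...) array: statistics across every
# non-channel element. Works for 4-D activations and 2-D (C x N) matrices.
bn_fwd <- function(x, gamma, beta, state, training) {
  d <- dim(x)
  cdim <- d[1]
  m <- matrix(x, nrow = cdim)
  if (training) {
    mu <- rowMeans(m)
    xc <- m - mu
    var_b <- rowMeans(xc * xc)
    nobs <- ncol(m)
    var_u <- if (nobs > 1) var_b * nobs / (nobs - 1) else var_b
    state$mean <- (1 - BN_MOMENTUM) * state$mean + BN_MOMENTUM * mu
    state$var <- (1 - BN_MOMENTUM) * state$var + BN_MOMENTUM * var_u
  } else {
    mu <- state$mean
    xc <- m - mu
    var_b <- state$var
  }
  invstd <- 1 / sqrt(var_b + BN_EPS)
  xhat <- xc * invstd
  out <- xhat * gamma + beta
  dim(out) <- d
  list(out = out, cache = list(xhat = xhat, invstd = invstd, dim = d),
       state = state)
}

bn_bwd <- function(dout, gamma, cache) {
  d <- cache$dim
  dm <- matrix(dout, nrow = d[1])
  xhat <- cache$xhat
  nobs <- ncol(dm)
  dbeta <- rowSums(dm)
  dgamma <- rowSums(dm * xhat)
  dxhat <- dm * gamma
  dx <- (cache$invstd / nobs) *
    (nobs * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Global pooling: (C, H, W, N) -> C x N
gap_fwd <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1], d[2] * d[3], d[4])
  out <- matrix(0, d[1], d[4])
  for (n in seq_len(d[4])) out[, n] <- rowMeans(x[, , n, drop = FALSE])
  out
}

gap_bwd <- function(dout, xdim) {
  hw <- xdim[2] * xdim[3]
  dx <- array(0, xdim)
  for (n in seq_len(xdim[4]))
    dx[, , , n] <- rep(dout[, n] / hw, hw)
  dx
}

gmp_fwd <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1], d[2] * d[3], d[4])
  out <- matrix(0, d[1], d[4])
  idx <- matrix(0L, d[1], d[4])
  for (n in seq_len(d[4])) {
    m <- x[, , n]
    if (is.null(dim(m))) m <- matrix(m, nrow = d[1])
    j <- max.col(m, ties.method = "first")
    out[, n] <- m[cbind(seq_len(d[1]), j)]
    idx[, n] <- j
  }
  list(out = out, idx = idx)
}

gmp_bwd <- function(dout, idx, xdim) {
  dx <- array(0, xdim)
  hw <- xdim[2] * xdim[3]
  dim(dx) <- c(xdim[1], hw, xdim[4])
  for (n in seq_len(xdim[4]))
    dx[cbind(seq_len(xdim[1]), idx[, n], n)] <- dout[, n]
  dim(dx) <- xdim
  dx
}

# Fully connected on C x N columns; w is (in x out), b length out.
fc_fwd <- function(x, w, b) crossprod(w, x) + b

fc_bwd <- function(x, w, dout) {
  list(dx = w %*% dout, dw = x %*% t(dout), db = rowSums(dout))
}

dropout_fwd <- function(x, p, training) {
  if (!training || p <= 0) return(list(out = x, cache = NULL))
  mask <- (matrix(stats::runif(length(x)), nrow(x)) >= p) / (1 - p)
  list(out = x * mask, cache = mask)
}

dropout_bwd <- function(dout, mask) if (is.null(mask)) dout else dout * mask

# Softmax cross-entropy over logits (K x N) with integer labels in 0..K-1.
# Returns mean loss and the gradient wrt logits.
softmax_xent <- function(logits, labels) {
  n <- ncol(logits)
  z <- logits - apply(logits, 2, max)[col(logits)]
  ez <- exp(z)
  probs <- ez / colSums(ez)[col(ez)]
  ii <- cbind(labels + 1L, seq_len(n))
  loss <- -mean(log(pmax(probs[ii], 1e-300)))
  dlogits <- probs
  dlogits[ii] <- dlogits[ii] - 1
  list(loss = loss, probs = probs, dlogits = dlogits / n)
}
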