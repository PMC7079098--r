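# Layer primitives for the registration network. Tensors are R arrays in
# (x, y, z, channel) order. Every forward helper returns the output plus the
# cache its backward pass needs; backward helpers return input gradients and
# parameter gradients. Batch size is one throughout (one image pair per
# iteration), so batch normalization normalizes over the spatial voxels of
# each channel; normalization and ReLU are fused in C++, and the convolution
# keeps its im2col patch matrix for reuse in the backward pass when it fits
# in one chunk.

conv_init <- function(cin, cout, zero = FALSE, kernel = 27L) {
  sd <- sqrt(2 / (kernel * cin))
  list(W = if (zero) matrix(0, kernel * cin, cout)
       else matrix(rnorm(kernel * cin * cout, sd = sd), kernel * cin, cout),
       b = numeric(cout))
}

bn_init <- function(ch) list(gamma = rep(1, ch), beta = numeric(ch))

# conv 3x3x3 -> batch norm -> ReLU
cbr_fwd <- function(x, p, bn_state, training, eps) {
  cv <- .conv3d_fwd(x, dim(x), p$W, p$b, keep_col = training)
  col <- NULL
  if (training) { col <- cv$col; cv <- cv$out }
  bn <- .bn_relu_fwd(cv, dim(cv), p$gamma, p$beta,
                     bn_state$mean %||% numeric(length(p$gamma)),
                     bn_state$var %||% rep(1, length(p$gamma)),
                     training, eps)
  list(out = bn$out,
       cache = if (training)
         list(x = x, col = col, xhat = bn$xhat, invstd = bn$invstd,
              mask = bn$mask, dims = dim(cv)) else NULL,
       batch_stats = if (training)
         list(mean = bn$batch_mean, var = bn$batch_var) else NULL)
}

cbr_bwd <- function(dout, cache, p) {
  bn <- .bn_relu_bwd(dout, cache$dims, cache$xhat, cache$invstd, p$gamma,
                     cache$mask)
  cb <- if (!is.null(cache$col)) {
    .conv3d_bwd_col(cache$col, dim(cache$x), p$W, bn$dx)
  } else {
    .conv3d_bwd(cache$x, dim(cache$x), p$W, bn$dx)
  }
  list(dx = cb$dx,
       grads = list(W = cb$dW, b = cb$db, gamma = bn$dgamma,
                    beta = bn$dbeta))
}

# plain 3x3x3 conv (input heads)
conv_fwd_plain <- function(x, p) .conv3d_fwd(x, dim(x), p$W, p$b)

conv_bwd_plain <- function(dout, x, p) {
  cb <- .conv3d_bwd(x, dim(x), p$W, dout)
  list(dx = cb$dx, grads = list(W = cb$dW, b = cb$db))
}

# 1x1x1 conv (output heads): a channel-mixing matrix multiply
head_fwd <- function(x, p) {
  d <- dim(x)
  v <- prod(d[1:3])
  out <- matrix(x, v, d[4]) %*% p$W
  out <- out + rep(p$b, each = v)
  array(out, c(d[1:3], ncol(p$W)))
}

head_bwd <- function(dout, x, p) {
  d <- dim(x)
  v <- prod(d[1:3])
  dM <- matrix(dout, v, ncol(p$W))
  X <- matrix(x, v, d[4])
  list(dx = array(dM %*% t(p$W), d),
       grads = list(W = t(X) %*% dM, b = colSums(dM)))
}
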