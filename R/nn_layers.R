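# Layer primitives. Every forward has a matching backward; gradients are
# verified against finite differences in the test suite. Tensors are
# (H, W, C) arrays; convolution weights are (kh, kw, cin, cout) arrays.

nn_conv_fw <- function(x, w, b, pad = 0L) {
  cpp_conv2d_fw(x, w, b, as.integer(pad))
}

nn_conv_bw <- function(x, w, gy, pad = 0L) {
  cpp_conv2d_bw(x, w, gy, as.integer(pad))
}

nn_tconv_fw <- function(x, w, b) cpp_tconv2_fw(x, w, b)
nn_tconv_bw <- function(x, w, gy) cpp_tconv2_bw(x, w, gy)

nn_pool_fw <- function(x) cpp_maxpool2_fw(x)
nn_pool_bw <- function(gy, idx, H, W) cpp_maxpool2_bw(gy, idx, as.integer(H), as.integer(W))

nn_relu_fw <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}
nn_relu_bw <- function(x, gy) gy * (x > 0)

# Instance normalization: each channel of each image normalized by its own
# spatial statistics (population variance), then scaled/shifted by the
# per-channel affine parameters. Identical at training and inference.
nn_instnorm_fw <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  np <- d[1] * d[2]
  xm <- matrix(x, np, d[3])
  mu <- colMeans(xm)
  v <- colMeans(xm^2) - mu^2
  inv <- 1 / sqrt(v + eps)
  xhat <- (xm - rep(mu, each = np)) * rep(inv, each = np)
  y <- xhat * rep(gamma, each = np) + rep(beta, each = np)
  dim(y) <- d
  list(y = y, xhat = xhat, inv = inv)
}

nn_instnorm_bw <- function(cache, gamma, gy) {
  d <- dim(gy)
  np <- d[1] * d[2]
  gym <- matrix(gy, np, d[3])
  xhat <- cache$xhat
  ggamma <- colSums(gym * xhat)
  gbeta <- colSums(gym)
  gxhat <- gym * rep(gamma, each = np)
  m1 <- colMeans(gxhat)
  m2 <- colMeans(gxhat * xhat)
  gx <- (gxhat - rep(m1, each = np) - xhat * rep(m2, each = np)) *
    rep(cache$inv, each = np)
  dim(gx) <- d
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

# Global average pooling to a length-C vector
nn_gap_fw <- function(x) {
  d <- dim(x)
  colMeans(matrix(x, d[1] * d[2], d[3]))
}
nn_gap_bw <- function(gv, d) {
  np <- d[1] * d[2]
  array(rep(gv, each = np) / np, dim = d)
}

nn_dense_fw <- function(v, w, b) drop(w %*% v + b)
nn_dense_bw <- function(v, w, gy) {
  list(gx = drop(crossprod(w, gy)), gw = tcrossprod(gy, v), gb = gy)
}

nn_softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# categorical cross-entropy on softmax logits; returns loss and gradient
# with respect to the logits
nn_softmax_ce <- function(z, onehot) {
  p <- nn_softmax(z)
  list(loss = -sum(onehot * log(pmax(p, 1e-12))), grad = p - onehot, prob = p)
}

nn_crop_center <- function(x, margin) {
  d <- dim(x)
  x[(margin + 1):(d[1] - margin), (margin + 1):(d[2] - margin), , drop = FALSE]
}
nn_crop_center_bw <- function(gy, d, margin) {
  gx <- array(0, dim = d)
  gx[(margin + 1):(d[1] - margin), (margin + 1):(d[2] - margin), ] <- gy
  gx
}

# ---- parameter initialization --------------------------------------------

init_conv <- function(kh, kw, cin, cout) {
  w <- array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
             dim = c(kh, kw, cin, cout))
  list(w = w, b = numeric(cout))
}

init_instnorm <- function(c) list(gamma = rep(1, c), beta = rep(0, c))

init_dense <- function(cin, cout) {
  list(w = matrix(stats::rnorm(cout * cin, sd = sqrt(2 / (cin + cout))), cout, cin),
       b = numeric(cout))
}
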