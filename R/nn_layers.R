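# Layer primitives for the artifact-prediction network. Feature maps are
# numeric 4-d arrays (H, W, C, B). Convolutions run through the compiled
# im2col/GEMM kernels; normalization and channel attention are vectorized R.

conv_same_forward <- function(x, w, b) {
  kh <- dim(w)[1]; kw <- dim(w)[2]
  cpp_conv_forward(x, w, b, pt = ceiling((kh - 1) / 2),
                   pl = ceiling((kw - 1) / 2))
}

conv_same_backward <- function(x, w, gy) {
  kh <- dim(w)[1]; kw <- dim(w)[2]
  cpp_conv_backward(x, w, gy, pt = ceiling((kh - 1) / 2),
                    pl = ceiling((kw - 1) / 2))
}

relu_forward <- function(x) cpp_relu_forward(x)
relu_backward <- function(x, gy) cpp_relu_backward(x, gy)

# batch normalization over (H, W, B) per channel; biased batch variance
bn_forward <- function(x, gamma, beta, rm, rv, training,
                       momentum = 0.1, eps = 1e-5) {
  r <- cpp_bn_forward(x, gamma, beta, rm, rv, training, momentum, eps)
  list(y = r$y,
       cache = list(xhat = r$xhat, inv_std = r$inv_std, training = training),
       rm = r$rm, rv = r$rv)
}

bn_backward <- function(gy, gamma, cache) {
  cpp_bn_backward(gy, cache$xhat, gamma, cache$inv_std, cache$training)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# squeeze-and-excitation: global average pool -> bottleneck -> sigmoid gate
se_forward <- function(x, w1, b1, w2, b2) {
  d <- dim(x)
  hw <- d[1] * d[2]
  x2 <- x
  dim(x2) <- c(hw, d[3] * d[4])
  z <- matrix(colMeans(x2), d[3], d[4])          # C x B descriptors
  h <- pmax(w1 %*% z + b1, 0)
  g <- sigmoid(w2 %*% h + b2)                     # C x B gates in (0, 1)
  gfull <- array(rep(g, each = hw), d)
  list(y = x * gfull,
       cache = list(x = x, z = z, h = h, g = g, gfull = gfull, dims = d))
}

se_backward <- function(gy, w1, w2, cache) {
  d <- cache$dims
  hw <- d[1] * d[2]
  prod2 <- cache$x * gy
  dim(prod2) <- c(hw, d[3] * d[4])
  gg <- matrix(colSums(prod2), d[3], d[4])
  gpre2 <- gg * cache$g * (1 - cache$g)
  gw2 <- gpre2 %*% t(cache$h)
  gb2 <- rowSums(gpre2)
  gh <- t(w2) %*% gpre2
  gpre1 <- gh * (cache$h > 0)
  gw1 <- gpre1 %*% t(cache$z)
  gb1 <- rowSums(gpre1)
  gz <- t(w1) %*% gpre1
  gx <- gy * cache$gfull + array(rep(gz / hw, each = hw), d)
  list(gx = gx, gw1 = gw1, gb1 = gb1, gw2 = gw2, gb2 = gb2)
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

split_channels <- function(g, c1) {
  list(g[, , seq_len(c1), , drop = FALSE],
       g[, , -seq_len(c1), , drop = FALSE])
}
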