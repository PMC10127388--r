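# Minimal reverse-mode layer zoo used by the density-regression network.
# Feature maps are H x W x C arrays; the (H*W) x C matrix view used by the
# normalisation layers comes from R's column-major layout, where rows of the
# matrix enumerate spatial positions.

#' Grouped 2-D convolution
#'
#' Same-padding grouped convolution over an `H x W x C` feature array, the
#' primitive behind the pyramidal blocks. Weights have
#' `dim = c(k, k, C_in / groups, C_out)`.
#'
#' @param x Input feature array `H x W x C`.
#' @param w Weight array `k x k x (C_in/groups) x C_out`, `k` odd.
#' @param b Bias vector of length `C_out` (default zeros).
#' @param stride Spatial stride.
#' @param pad Zero padding per side; defaults to `(k - 1) / 2` (same
#'   padding at stride 1).
#' @param groups Channel groups; must divide input and output channels.
#' @return Feature array `H' x W' x C_out`.
#' @export
conv2d <- function(x, w, b = NULL, stride = 1L, pad = (dim(w)[1] - 1L) %/% 2L,
                   groups = 1L) {
  if (is.null(b)) b <- numeric(dim(w)[4])
  if (dim(x)[3] != dim(w)[3] * groups) {
    abort("input channels do not match weight channels x groups",
          class = "rape_config_error")
  }
  if (dim(w)[4] %% groups != 0) {
    abort("output channels must be divisible by groups", class = "rape_config_error")
  }
  cpp_conv2d(x, w, as.numeric(b), as.integer(stride), as.integer(pad),
             as.integer(groups))
}

conv2d_backward <- function(x, w, gy, stride, pad, groups, need_gx = TRUE) {
  cpp_conv2d_backward(x, w, gy, as.integer(stride), as.integer(pad),
                      as.integer(groups), need_gx)
}

he_init <- function(k, cin_g, cout, rng_sd = sqrt(2 / (k * k * cin_g))) {
  array(rnorm(k * k * cin_g * cout, sd = rng_sd), c(k, k, cin_g, cout))
}

# --- channel normalisation (per-channel statistics over spatial positions;
# batch size is 1 throughout, so train-time statistics are per-sample, while
# evaluation uses stored running statistics for determinism).

norm_init <- function(C) list(gamma = rep(1, C), beta = rep(0, C))
norm_buffers <- function(C) list(mean = rep(0, C), var = rep(1, C))

norm_forward <- function(xm, par, buf, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu, "-")
    v <- colMeans(xc * xc)
    buf$mean <- (1 - momentum) * buf$mean + momentum * mu
    buf$var <- (1 - momentum) * buf$var + momentum * v
  } else {
    mu <- buf$mean
    v <- buf$var
    xc <- sweep(xm, 2, mu, "-")
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, istd, "*")
  y <- sweep(sweep(xhat, 2, par$gamma, "*"), 2, par$beta, "+")
  list(y = y, cache = list(xhat = xhat, istd = istd, training = training),
       buf = buf)
}

norm_backward <- function(gy, par, cache) {
  xhat <- cache$xhat
  istd <- cache$istd
  dgamma <- colSums(gy * xhat)
  dbeta <- colSums(gy)
  dxhat <- sweep(gy, 2, par$gamma, "*")
  if (cache$training) {
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * xhat)
    dx <- sweep(dxhat, 2, m1, "-") - sweep(xhat, 2, m2, "*")
    dx <- sweep(dx, 2, istd, "*")
  } else {
    dx <- sweep(dxhat, 2, istd, "*")
  }
  list(gx = dx, ggamma = dgamma, gbeta = dbeta)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

as_channel_matrix <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3])
  x
}

as_feature_array <- function(xm, h, w) {
  dim(xm) <- c(h, w, ncol(xm))
  xm
}
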