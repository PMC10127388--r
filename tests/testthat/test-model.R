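test_that("a single-level pyramid degenerates to a plain convolution", {
  set.seed(3)
  spec <- pyconv_spec(list(list(3L, 16L, 1L)), stride = 1L)
  blk <- init_pyconv_block(spec, in_channels = 4L)
  x <- array(rnorm(10 * 12 * 4), c(10, 12, 4))
  raw <- pyconv_block(x, blk, post = FALSE)
  plain <- conv2d(x, blk$levels[[1]]$w, blk$levels[[1]]$b)
  expect_equal(raw, plain)
})

test_that("pyramid levels concatenate channels and preserve spatial size", {
  set.seed(4)
  spec <- pyconv_spec(list(list(3L, 8L, 1L), list(5L, 8L, 1L), list(7L, 8L, 1L)))
  blk <- init_pyconv_block(spec, in_channels = 6L)
  x <- array(rnorm(9 * 11 * 6), c(9, 11, 6))
  y <- pyconv_block(x, blk, training = TRUE)
  expect_equal(dim(y), c(9L, 11L, 24L))
  expect_error(pyconv_spec(list(list(4L, 8L, 1L))), class = "rape_config_error")
  expect_error(init_pyconv_block(pyconv_spec(list(list(3L, 8L, 3L))), 4L),
               class = "rape_config_error")
})

test_that("grouped and strided convolutions agree with a direct computation", {
  set.seed(5)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  w <- array(rnorm(3 * 3 * 2 * 6), c(3, 3, 2, 6))
  b <- rnorm(6)
  y <- conv2d(x, w, b, stride = 2, groups = 2)
  expect_equal(dim(y), c(4L, 4L, 6L))
  # spot-check one output against the definition (group 2, last channel)
  oh <- 2L; ow <- 3L; co <- 6L
  xp <- array(0, c(10, 10, 4)); xp[2:9, 2:9, ] <- x
  patch <- xp[(oh - 1) * 2 + 1:3, (ow - 1) * 2 + 1:3, 3:4]
  expect_equal(y[oh, ow, co], sum(patch * w[, , , co]) + b[co], tolerance = 1e-12)
})

test_that("coordinate attention reweights without changing shape, gates in (0,1)", {
  set.seed(6)
  par <- init_coordinate_attention(16L, reduction = 4L)
  x <- array(rnorm(7 * 9 * 16), c(7, 9, 16))
  y <- coordinate_attention(x, par, training = TRUE)
  expect_equal(dim(y), dim(x))
  # gates strictly inside (0,1): |out| strictly below |in| wherever in != 0
  expect_true(all(abs(y) < abs(x) + 1e-12))
  expect_true(all(abs(y) > 0 | x == 0))
  expect_error(init_coordinate_attention(16L, reduction = 32L),
               class = "rape_config_error")
})

test_that("zeroed attention parameters halve both gates: output is input / 4", {
  par <- init_coordinate_attention(8L, reduction = 2L)
  par$w1[] <- 0; par$b1[] <- 0
  par$wh[] <- 0; par$bh[] <- 0
  par$ww[] <- 0; par$bw[] <- 0
  x <- array(rnorm(5 * 6 * 8), c(5, 6, 8))
  y <- coordinate_attention(x, par, training = TRUE)
  expect_equal(y, x / 4, tolerance = 1e-12)
})

test_that("the backbone emits a non-negative density map at the configured stride", {
  cfg <- network_config(width_multiplier = 0.125)
  model <- rapenet(cfg, seed = 1)
  img <- array(runif(64 * 96 * 3), c(64, 96, 3))
  D <- predict_density(model, img)
  expect_equal(dim(D), c(8L, 12L))
  expect_true(all(D >= 0))
  expect_equal(attr(D, "stride"), 8L)
  expect_error(predict_density(model, array(0, c(60, 64, 3))),
               class = "rape_argument_error")

  # evaluation mode is bit-deterministic
  expect_identical(unclass(predict_density(model, img)), unclass(D))

  # non-negativity across many random inputs
  set.seed(9)
  for (i in 1:50) {
    im <- array(runif(32 * 32 * 3), c(32, 32, 3))
    expect_true(all(predict_density(model, im) >= 0))
  }
})

test_that("attention-augmented backbone shares contracts and exceeds plain capacity", {
  cfg0 <- network_config(width_multiplier = 0.125)
  cfgp <- network_config(width_multiplier = 0.125, attention_after = c(2, 4),
                         attention_reduction = 2L)
  mp <- rapenet(cfgp, seed = 2)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  D <- predict_density(mp, img)
  expect_equal(dim(D), c(8L, 8L))
  expect_true(all(D >= 0))
  expect_gt(parameter_capacity(cfgp), parameter_capacity(cfg0))
})

test_that("zeroed attention gates compose as a 0.25 feature scaling in the backbone", {
  # with zero biases everywhere and per-sample normalisation (which is
  # scale-invariant), scaling features by 1/4 after blocks 2 and 4 is
  # absorbed: the zero-gated RapeNet+ equals the same network without its
  # attention modules
  cfgp <- network_config(width_multiplier = 0.125, attention_after = c(2, 4),
                         attention_reduction = 2L)
  mp <- rapenet(cfgp, seed = 3)
  for (key in names(mp$attn)) {
    for (f in c("w1", "b1", "wh", "bh", "ww", "bw")) mp$attn[[key]][[f]][] <- 0
  }
  m0 <- mp
  m0$attn <- list()
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  Dp <- rapecount:::forward_rapenet(mp, img, training = TRUE)$D
  D0 <- rapecount:::forward_rapenet(m0, img, training = TRUE)$D
  # agreement up to the normalisation epsilon: scaling the features by 1/16
  # turns each var + eps into var + 16 eps, a ~1e-4 relative perturbation
  expect_equal(unclass(Dp), unclass(D0), tolerance = 1e-3)
})

test_that("parameter capacity counts 32-bit weights and respects the lightweight budget", {
  # one 3x3 convolution, 3 -> 8 channels with bias: 3*3*3*8 + 8 = 224
  lst <- list(array(0, c(3, 3, 3, 8)), numeric(8))
  expect_equal(count_parameters(lst), 224)
  expect_equal(parameter_capacity(lst), 896)
  expect_equal(parameter_capacity(list()), 0)

  cap <- parameter_capacity(network_config())
  cap_plus <- parameter_capacity(network_config(attention_after = c(2, 4)))
  expect_lte(cap, 10 * 2^20)
  expect_gt(cap_plus, cap)
  expect_gt(cap, 0)
  # an order of magnitude under the ~80 MB class of heavyweight backbones
  expect_lte(cap_plus, 8 * 2^20)
})

test_that("network configuration enforces the rise-then-fall pyramid shape", {
  expect_error(network_config(level_counts = c(4, 3, 2, 2, 3, 4)),
               class = "rape_config_error")
  expect_error(network_config(level_counts = c(2, 3, 4, 4, 3)),
               class = "rape_config_error")
  expect_error(network_config(attention_after = 7), class = "rape_config_error")
  cfg <- network_config()
  expect_equal(cfg$output_stride, 8)
})

test_that("shifting the input by one stride shifts interior density cells", {
  cfg <- network_config(width_multiplier = 0.125)
  model <- rapenet(cfg, seed = 4)
  set.seed(10)
  img <- array(runif(256 * 256 * 3), c(256, 256, 3))
  st <- cfg$output_stride
  shifted <- img[c((256 - st + 1):256, 1:(256 - st)), , , drop = FALSE]
  D1 <- unclass(predict_density(model, img))
  D2 <- unclass(predict_density(model, shifted))
  # interior cells whose receptive field (+/- 96 px here) stays inside the
  # image in both the original and the shifted frame
  expect_equal(D2[14:20, 13:20], D1[13:19, 13:20], tolerance = 1e-10)
})

test_that("model gradients match finite differences through every layer family", {
  cfg <- network_config(width_multiplier = 0.125, attention_after = c(2, 4),
                        attention_reduction = 2L)
  model <- rapenet(cfg, seed = 7)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  fw <- rapecount:::forward_rapenet(model, img, training = TRUE, want_cache = TRUE)
  set.seed(8)
  gD <- matrix(rnorm(length(fw$D)), nrow(fw$D))
  gr <- rapecount:::backward_rapenet(fw$model, fw$cache, gD)
  f <- function(m) sum(unclass(rapecount:::forward_rapenet(m, img, training = TRUE)$D) * gD)
  base <- f(model)
  eps <- 1e-6
  probes <- list(
    list(\(m) m$blocks[[1]]$levels[[1]]$w, \(m, i) {m$blocks[[1]]$levels[[1]]$w[i] <- m$blocks[[1]]$levels[[1]]$w[i] + eps; m}, gr$blocks[[1]]$levels[[1]]$w),
    list(\(m) m$blocks[[3]]$levels[[2]]$w, \(m, i) {m$blocks[[3]]$levels[[2]]$w[i] <- m$blocks[[3]]$levels[[2]]$w[i] + eps; m}, gr$blocks[[3]]$levels[[2]]$w),
    list(\(m) m$blocks[[5]]$norm$gamma, \(m, i) {m$blocks[[5]]$norm$gamma[i] <- m$blocks[[5]]$norm$gamma[i] + eps; m}, gr$blocks[[5]]$norm$gamma),
    list(\(m) m$attn[["2"]]$w1, \(m, i) {m$attn[["2"]]$w1[i] <- m$attn[["2"]]$w1[i] + eps; m}, gr$attn[["2"]]$w1),
    list(\(m) m$attn[["4"]]$ww, \(m, i) {m$attn[["4"]]$ww[i] <- m$attn[["4"]]$ww[i] + eps; m}, gr$attn[["4"]]$ww),
    list(\(m) m$head$w2, \(m, i) {m$head$w2[i] <- m$head$w2[i] + eps; m}, gr$head$w2)
  )
  for (p in probes) {
    v <- p[[1]](model)
    for (i in sample(length(v), min(3, length(v)))) {
      num <- (f(p[[2]](model, i)) - base) / eps
      expect_lt(abs(num - p[[3]][i]) / max(1, abs(p[[3]][i])), 1e-4)
    }
  }
})
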