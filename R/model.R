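# RapeNet: a six-block pyramidal-convolution backbone regressing a
# non-negative density map at output stride 8. RapeNet+ adds coordinate
# attention after blocks 2 and 4. The number of pyramid levels rises over
# blocks 1-3 and falls over blocks 4-6; larger kernels use grouped
# convolutions to keep the parameter budget at the few-megabyte scale.

#' Pyramidal-convolution block specification
#'
#' One block runs several same-padded convolutions with different (odd,
#' distinct) kernel sizes in parallel on the same input and concatenates
#' their outputs along channels, followed by channel normalisation and a
#' ReLU.
#'
#' @param levels A list of levels, each `list(kernel, out_channels, groups)`.
#' @param stride Spatial stride shared by all levels.
#' @return A `pyconv_spec` list with `levels`, `stride` and `out_channels`
#'   (the concatenated total).
#' @export
pyconv_spec <- function(levels, stride = 1L) {
  ks <- vapply(levels, function(l) l[[1]], numeric(1))
  if (any(ks %% 2 == 0) || anyDuplicated(ks) > 0) {
    abort("kernel sizes must be odd and distinct", class = "rape_config_error")
  }
  structure(list(levels = levels, stride = as.integer(stride),
                 out_channels = sum(vapply(levels, function(l) l[[2]], numeric(1)))),
            class = "pyconv_spec")
}

#' Initialise a pyramidal-convolution block
#'
#' He-initialised weights for every level plus a channel-normalisation
#' layer over the concatenated output. Draws from the current RNG stream.
#'
#' @param spec A [pyconv_spec()].
#' @param in_channels Input channel count; every level's `groups` must
#'   divide it.
#' @return A list with `spec`, `levels` (weight/bias pairs), `norm`
#'   parameters and `buffers` (running statistics).
#' @export
init_pyconv_block <- function(spec, in_channels) {
  levels <- lapply(spec$levels, function(l) {
    k <- l[[1]]; cout <- l[[2]]; g <- l[[3]]
    if (in_channels %% g != 0 || cout %% g != 0) {
      abort(sprintf("groups %d must divide in (%d) and out (%d) channels",
                    g, in_channels, cout), class = "rape_config_error")
    }
    list(w = he_init(k, in_channels %/% g, cout), b = numeric(cout))
  })
  list(spec = spec, levels = levels, norm = norm_init(spec$out_channels),
       buffers = norm_buffers(spec$out_channels))
}

#' Apply a pyramidal-convolution block
#'
#' @param x Feature array `H x W x C_in`.
#' @param block A block from [init_pyconv_block()].
#' @param training Use per-sample normalisation statistics (and update the
#'   running ones) instead of the stored running statistics.
#' @param post Apply the normalisation + ReLU stage; `FALSE` returns the
#'   raw concatenated convolution outputs (useful for comparing a
#'   single-level block against a plain convolution).
#' @return Feature array `H' x W' x out_channels`.
#' @export
pyconv_block <- function(x, block, training = FALSE, post = TRUE) {
  pyconv_forward(x, block, training = training, post = post)$y
}

pyconv_forward <- function(x, block, training = FALSE, post = TRUE) {
  spec <- block$spec
  outs <- vector("list", length(spec$levels))
  for (i in seq_along(spec$levels)) {
    l <- spec$levels[[i]]
    outs[[i]] <- conv2d(x, block$levels[[i]]$w, block$levels[[i]]$b,
                        stride = spec$stride, pad = (l[[1]] - 1L) %/% 2L,
                        groups = l[[3]])
  }
  y <- cbind_channels(outs)
  if (!post) return(list(y = y, block = block))
  d <- dim(y)
  nf <- norm_forward(as_channel_matrix(y), block$norm, block$buffers, training)
  act <- pmax(nf$y, 0)
  block$buffers <- nf$buf
  list(y = as_feature_array(act, d[1], d[2]), block = block,
       cache = list(x = x, dims = d, norm = nf$cache, relu = nf$y > 0))
}

pyconv_backward <- function(gy, block, cache, need_gx = TRUE) {
  d <- cache$dims
  gm <- as_channel_matrix(gy) * cache$relu
  nb <- norm_backward(gm, block$norm, cache$norm)
  gconcat <- as_feature_array(nb$gx, d[1], d[2])
  spec <- block$spec
  gx <- NULL
  glevels <- vector("list", length(spec$levels))
  at <- 0L
  for (i in seq_along(spec$levels)) {
    l <- spec$levels[[i]]
    nc <- l[[2]]
    gpart <- gconcat[, , at + seq_len(nc), drop = FALSE]
    at <- at + nc
    bw <- conv2d_backward(cache$x, block$levels[[i]]$w, gpart,
                          stride = spec$stride, pad = (l[[1]] - 1L) %/% 2L,
                          groups = l[[3]], need_gx = need_gx)
    glevels[[i]] <- list(w = bw$gw, b = bw$gb)
    if (need_gx) gx <- if (is.null(gx)) bw$gx else gx + bw$gx
  }
  list(gx = gx, levels = glevels,
       norm = list(gamma = nb$ggamma, beta = nb$gbeta))
}

#' Initialise a coordinate-attention module
#'
#' Height-wise and width-wise global average pooling produce two
#' direction-aware descriptors; a shared 1x1 transform (with normalisation
#' and ReLU) encodes them, and two sigmoid-gated 1x1 transforms emit
#' per-row and per-column channel gates in (0, 1) that multiply the input.
#'
#' @param channels Input channel count `C`.
#' @param reduction Bottleneck reduction; must divide `C`.
#' @return Parameter list for [coordinate_attention()].
#' @export
init_coordinate_attention <- function(channels, reduction = 8L) {
  if (reduction > channels || channels %% reduction != 0) {
    abort("reduction must divide the channel count", class = "rape_config_error")
  }
  cr <- channels %/% reduction
  list(
    w1 = matrix(rnorm(channels * cr, sd = sqrt(2 / channels)), channels, cr),
    b1 = numeric(cr),
    norm = norm_init(cr), buffers = norm_buffers(cr),
    wh = matrix(rnorm(cr * channels, sd = sqrt(2 / cr)), cr, channels),
    bh = numeric(channels),
    ww = matrix(rnorm(cr * channels, sd = sqrt(2 / cr)), cr, channels),
    bw = numeric(channels),
    channels = channels, reduction = as.integer(reduction)
  )
}

#' Apply coordinate attention
#'
#' @param x Feature array `H x W x C`.
#' @param par Parameters from [init_coordinate_attention()].
#' @param training Normalisation mode as in [pyconv_block()].
#' @return Reweighted feature array of the same shape.
#' @export
coordinate_attention <- function(x, par, training = FALSE) {
  ca_forward(x, par, training = training)$y
}

ca_forward <- function(x, par, training = FALSE) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]
  hp <- apply(x, 3, rowMeans)            # H x C
  wp <- apply(x, 3, colMeans)            # W x C
  cat2 <- rbind(hp, wp)                  # (H+W) x C
  t1 <- sweep(cat2 %*% par$w1, 2, par$b1, "+")
  nf <- norm_forward(t1, par$norm, par$buffers, training)
  a <- pmax(nf$y, 0)
  ah <- sweep(a[seq_len(H), , drop = FALSE] %*% par$wh, 2, par$bh, "+")
  aw <- sweep(a[H + seq_len(W), , drop = FALSE] %*% par$ww, 2, par$bw, "+")
  gh <- sigmoid(ah)                      # H x C gates
  gw <- sigmoid(aw)                      # W x C gates
  y <- x
  for (ci in seq_len(C)) y[, , ci] <- x[, , ci] * outer(gh[, ci], gw[, ci])
  par$buffers <- nf$buf
  list(y = y, par = par,
       cache = list(x = x, dims = d, cat2 = cat2, norm = nf$cache,
                    relu = nf$y > 0, a = a, gh = gh, gw = gw))
}

ca_backward <- function(gy, par, cache) {
  d <- cache$dims
  H <- d[1]; W <- d[2]; C <- d[3]
  x <- cache$x
  gh <- cache$gh; gw <- cache$gw
  gx <- gy
  ggh <- matrix(0, H, C); ggw <- matrix(0, W, C)
  for (ci in seq_len(C)) {
    P <- gy[, , ci] * x[, , ci]
    gx[, , ci] <- gy[, , ci] * outer(gh[, ci], gw[, ci])
    ggh[, ci] <- P %*% gw[, ci]
    ggw[, ci] <- crossprod(P, gh[, ci])
  }
  gah <- ggh * gh * (1 - gh)
  gaw <- ggw * gw * (1 - gw)
  a <- cache$a
  ga <- matrix(0, H + W, ncol(a))
  ga[seq_len(H), ] <- gah %*% t(par$wh)
  ga[H + seq_len(W), ] <- gaw %*% t(par$ww)
  gwh <- crossprod(a[seq_len(H), , drop = FALSE], gah)
  gbh <- colSums(gah)
  gww <- crossprod(a[H + seq_len(W), , drop = FALSE], gaw)
  gbw <- colSums(gaw)
  gt1 <- ga * cache$relu
  nb <- norm_backward(gt1, par$norm, cache$norm)
  gcat <- nb$gx %*% t(par$w1)
  gw1 <- crossprod(cache$cat2, nb$gx)
  gb1 <- colSums(nb$gx)
  # pooling backward: mean over the pooled axis spreads gradients uniformly
  ghp <- gcat[seq_len(H), , drop = FALSE] / W
  gwp <- gcat[H + seq_len(W), , drop = FALSE] / H
  for (ci in seq_len(C)) {
    gx[, , ci] <- gx[, , ci] + ghp[, ci] + matrix(gwp[, ci], H, W, byrow = TRUE)
  }
  list(gx = gx,
       grads = list(w1 = gw1, b1 = gb1,
                    norm = list(gamma = nb$ggamma, beta = nb$gbeta),
                    wh = gwh, bh = gbh, ww = gww, bw = gbw))
}

#' Network configuration
#'
#' Declares the six-block backbone. Pyramid level counts rise over the
#' first three blocks and fall over the last three; blocks 1-3 downsample
#' by 2 each, giving output stride 8. Channel widths scale with
#' `width_multiplier` so the same topology runs from desk-scale tests to
#' the full model. `attention_after = c(2, 4)` selects the
#' coordinate-attention variant (RapeNet+); an empty set selects the plain
#' backbone.
#'
#' @param width_multiplier Multiplies all block channel widths (default 1;
#'   reduced-width profiles such as 0.25 or 0.125 are used for CPU-scale
#'   training).
#' @param attention_after Integer block indices after which coordinate
#'   attention is inserted.
#' @param attention_reduction Bottleneck reduction of the attention module.
#' @param head_channels Hidden width of the 1x1 regression head.
#' @param kernels Pool of odd kernel sizes; level `l` of a block uses
#'   `kernels[l]`.
#' @param level_counts Pyramid levels per block (must rise then fall).
#' @param base_channels Output channels per block before the width
#'   multiplier.
#' @param block_strides Per-block spatial stride.
#' @param max_groups Desired convolution groups per level index (reduced
#'   automatically when they do not divide the channel counts).
#' @return A `network_config` list; `output_stride` is the product of the
#'   block strides.
#' @export
network_config <- function(width_multiplier = 1,
                           attention_after = integer(0),
                           attention_reduction = 8L,
                           head_channels = 32L,
                           kernels = c(3L, 5L, 7L, 9L),
                           level_counts = c(2L, 3L, 4L, 4L, 3L, 2L),
                           base_channels = c(64L, 128L, 256L, 256L, 128L, 64L),
                           block_strides = c(2L, 2L, 2L, 1L, 1L, 1L),
                           max_groups = c(1L, 2L, 4L, 8L)) {
  if (length(level_counts) != 6L || length(base_channels) != 6L ||
      length(block_strides) != 6L) {
    abort("the backbone has exactly six blocks", class = "rape_config_error")
  }
  if (any(diff(level_counts[1:3]) < 0) || any(diff(level_counts[4:6]) > 0)) {
    abort("pyramid level counts must rise over blocks 1-3 and fall over 4-6",
          class = "rape_config_error")
  }
  if (max(level_counts) > length(kernels)) {
    abort("not enough kernel sizes for the requested pyramid levels",
          class = "rape_config_error")
  }
  if (!all(attention_after %in% 1:6)) {
    abort("attention_after must name blocks 1-6", class = "rape_config_error")
  }
  structure(list(
    width_multiplier = width_multiplier,
    attention_after = as.integer(attention_after),
    attention_reduction = as.integer(attention_reduction),
    head_channels = as.integer(head_channels),
    kernels = as.integer(kernels),
    level_counts = as.integer(level_counts),
    base_channels = as.integer(base_channels),
    block_strides = as.integer(block_strides),
    max_groups = as.integer(max_groups),
    output_stride = prod(block_strides)
  ), class = "network_config")
}

# channel allocation: widths are quantised (granularity 8 at full width,
# proportionally less at reduced widths) so that grouped convolutions get
# divisible channel counts.
config_block_specs <- function(cfg) {
  wm <- cfg$width_multiplier
  gran <- if (wm >= 1) 8L else max(2L, floor(8 * wm))
  cin <- 3L
  specs <- vector("list", 6L)
  for (b in 1:6) {
    L <- cfg$level_counts[b]
    units <- max(L, round(cfg$base_channels[b] * wm / gran))
    per <- rep(units %/% L, L)
    extra <- units %% L
    if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
    chans <- per * gran
    levels <- vector("list", L)
    for (l in seq_len(L)) {
      g <- cfg$max_groups[min(l, length(cfg$max_groups))]
      while (g > 1L && (cin %% g != 0 || chans[l] %% g != 0)) g <- g %/% 2L
      levels[[l]] <- list(cfg$kernels[l], chans[l], g)
    }
    specs[[b]] <- pyconv_spec(levels, stride = cfg$block_strides[b])
    cin <- sum(chans)
  }
  specs
}

#' Build a density-regression network
#'
#' Instantiates the six-block pyramidal backbone described by a
#' [network_config()], with coordinate-attention modules at the configured
#' insertion points and a two-layer 1x1 regression head whose output is
#' clamped to be non-negative (a density map cannot be negative).
#'
#' @param cfg A [network_config()].
#' @param seed Optional seed for weight initialisation.
#' @return An object of class `rapenet`.
#' @export
rapenet <- function(cfg = network_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  specs <- config_block_specs(cfg)
  blocks <- list()
  cin <- 3L
  for (b in 1:6) {
    blocks[[b]] <- init_pyconv_block(specs[[b]], cin)
    cin <- specs[[b]]$out_channels
  }
  attn <- list()
  for (b in cfg$attention_after) {
    attn[[as.character(b)]] <-
      init_coordinate_attention(specs[[b]]$out_channels, cfg$attention_reduction)
  }
  hc <- cfg$head_channels
  head <- list(
    w1 = matrix(rnorm(cin * hc, sd = sqrt(2 / cin)), cin, hc),
    b1 = numeric(hc),
    w2 = matrix(rnorm(hc, sd = sqrt(2 / hc)), hc, 1L),
    b2 = 0.01 # small positive start keeps the clamped head alive
  )
  structure(list(cfg = cfg, blocks = blocks, attn = attn, head = head),
            class = "rapenet")
}

#' @export
print.rapenet <- function(x, ...) {
  cfg <- x$cfg
  kind <- if (length(cfg$attention_after) > 0) "RapeNet+ (coordinate attention)" else "RapeNet"
  cat(sprintf("<%s> 6 pyramidal blocks, output stride %d, width x%g\n",
              kind, cfg$output_stride, cfg$width_multiplier))
  cat(sprintf("  parameters: %s (%.2f MB as 32-bit)\n",
              format(count_parameters(x), big.mark = ","),
              parameter_capacity(x) / 2^20))
  invisible(x)
}

forward_rapenet <- function(model, img, training = FALSE, want_cache = FALSE) {
  d <- dim(img)
  st <- model$cfg$output_stride
  if (d[1] %% st != 0 || d[2] %% st != 0) {
    abort(sprintf("input %dx%d not divisible by output stride %d",
                  d[1], d[2], st), class = "rape_argument_error")
  }
  x <- (img - 0.5) * 2
  caches <- if (want_cache) list(blocks = vector("list", 6L), attn = list())
  for (b in 1:6) {
    fw <- pyconv_forward(x, model$blocks[[b]], training = training)
    model$blocks[[b]] <- fw$block
    x <- fw$y
    if (want_cache) caches$blocks[[b]] <- fw$cache
    key <- as.character(b)
    if (!is.null(model$attn[[key]])) {
      af <- ca_forward(x, model$attn[[key]], training = training)
      model$attn[[key]] <- af$par
      x <- af$y
      if (want_cache) caches$attn[[key]] <- af$cache
    }
  }
  dd <- dim(x)
  xm <- as_channel_matrix(x)
  h1 <- sweep(xm %*% model$head$w1, 2, model$head$b1, "+")
  r1 <- pmax(h1, 0)
  pre <- as.vector(r1 %*% model$head$w2) + model$head$b2
  Dv <- pmax(pre, 0)
  D <- matrix(Dv, dd[1], dd[2])
  if (want_cache) {
    caches$head <- list(xm = xm, r1 = r1, mask1 = h1 > 0, pre = pre,
                        h = dd[1], w = dd[2])
  }
  list(D = density_map(D, stride = st), model = model, cache = caches)
}

backward_rapenet <- function(model, cache, gD) {
  hc <- cache$head
  gpre <- as.vector(gD) * (hc$pre > 0)
  gw2 <- crossprod(hc$r1, gpre)
  gb2 <- sum(gpre)
  gr1 <- tcrossprod(gpre, as.vector(model$head$w2)) * hc$mask1
  gw1 <- crossprod(hc$xm, gr1)
  gb1 <- colSums(gr1)
  gx <- gr1 %*% t(model$head$w1)
  gx <- as_feature_array(gx, hc$h, hc$w)
  grads <- list(blocks = vector("list", 6L), attn = list(),
                head = list(w1 = gw1, b1 = gb1, w2 = gw2, b2 = gb2))
  for (b in 6:1) {
    key <- as.character(b)
    if (!is.null(model$attn[[key]])) {
      ab <- ca_backward(gx, model$attn[[key]], cache$attn[[key]])
      gx <- ab$gx
      grads$attn[[key]] <- ab$grads
    }
    bb <- pyconv_backward(gx, model$blocks[[b]], cache$blocks[[b]],
                          need_gx = b > 1L) # the image needs no gradient
    gx <- bb$gx
    grads$blocks[[b]] <- list(levels = bb$levels, norm = bb$norm)
  }
  grads
}

# SGD over the nested parameter lists; grads mirror the parameter layout.
sgd_step <- function(model, grads, lr) {
  for (b in 1:6) {
    for (i in seq_along(model$blocks[[b]]$levels)) {
      model$blocks[[b]]$levels[[i]]$w <-
        model$blocks[[b]]$levels[[i]]$w - lr * grads$blocks[[b]]$levels[[i]]$w
      model$blocks[[b]]$levels[[i]]$b <-
        model$blocks[[b]]$levels[[i]]$b - lr * grads$blocks[[b]]$levels[[i]]$b
    }
    model$blocks[[b]]$norm$gamma <-
      model$blocks[[b]]$norm$gamma - lr * grads$blocks[[b]]$norm$gamma
    model$blocks[[b]]$norm$beta <-
      model$blocks[[b]]$norm$beta - lr * grads$blocks[[b]]$norm$beta
  }
  for (key in names(model$attn)) {
    pa <- model$attn[[key]]; ga <- grads$attn[[key]]
    pa$w1 <- pa$w1 - lr * ga$w1; pa$b1 <- pa$b1 - lr * ga$b1
    pa$norm$gamma <- pa$norm$gamma - lr * ga$norm$gamma
    pa$norm$beta <- pa$norm$beta - lr * ga$norm$beta
    pa$wh <- pa$wh - lr * ga$wh; pa$bh <- pa$bh - lr * ga$bh
    pa$ww <- pa$ww - lr * ga$ww; pa$bw <- pa$bw - lr * ga$bw
    model$attn[[key]] <- pa
  }
  model$head$w1 <- model$head$w1 - lr * grads$head$w1
  model$head$b1 <- model$head$b1 - lr * grads$head$b1
  model$head$w2 <- model$head$w2 - lr * grads$head$w2
  model$head$b2 <- model$head$b2 - lr * grads$head$b2
  model
}

model_param_list <- function(model) {
  out <- list()
  for (b in 1:6) {
    for (l in model$blocks[[b]]$levels) out <- c(out, list(l$w, l$b))
    out <- c(out, list(model$blocks[[b]]$norm$gamma, model$blocks[[b]]$norm$beta))
  }
  for (pa in model$attn) {
    out <- c(out, list(pa$w1, pa$b1, pa$norm$gamma, pa$norm$beta,
                       pa$wh, pa$bh, pa$ww, pa$bw))
  }
  c(out, list(model$head$w1, model$head$b1, model$head$w2, model$head$b2))
}

#' Number of trainable parameters
#'
#' @param model A `rapenet` model (or a bare list of parameter arrays).
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  pl <- if (inherits(model, "rapenet")) model_param_list(model) else model
  sum(vapply(pl, length, numeric(1)))
}

#' Model capacity in bytes
#'
#' Trainable parameter count times 4 bytes (single-precision deployment
#' format), the convention behind "model capacity" comparisons of counting
#' backbones.
#'
#' @param x A `rapenet` model, a [network_config()] (instantiated with a
#'   fixed seed just to count), or a list of parameter arrays.
#' @return Capacity in bytes.
#' @export
parameter_capacity <- function(x) {
  if (inherits(x, "network_config")) {
    x <- with_preserved_seed(rapenet(x, seed = 0L))
  }
  4 * count_parameters(x)
}

#' Forward pass to a density map
#'
#' Runs the network in evaluation mode (stored normalisation statistics,
#' fully deterministic) on a single image whose sides are divisible by the
#' output stride. For full 512x1024 canvases use [predict_count()], which
#' tiles first.
#'
#' @param model A `rapenet` model.
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param training Use per-sample normalisation statistics.
#' @return A [density_map()].
#' @export
predict_density <- function(model, image, training = FALSE) {
  forward_rapenet(model, image, training = training)$D
}

#' @export
predict.rapenet <- function(object, newdata, ...) {
  predict_density(object, newdata)
}

#' Save / load a model checkpoint
#'
#' Checkpoints are written with R's native serialisation (`saveRDS`), the
#' standard weights container for R model objects.
#'
#' @param model A `rapenet` model.
#' @param path Checkpoint path (`.rds`).
#' @return `path` invisibly, or the restored model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
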