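# Training: deterministic dataset splitting, the SGD loop wiring the
# Bayesian counting loss to the backbone, and end-to-end evaluation.

#' Training configuration
#'
#' Defaults follow the reference training protocol for full-scale plot
#' data: SGD at a fixed learning rate of 1e-5, 1000 epochs, batch size 1,
#' an 85/15 train/test split with the training pool further divided 9:1
#' into train/validation. `sigma` and `background_ratio` sit mid-range of
#' the intervals this loss family is tuned over (0.1-10 and 0-1). Desk
#' scale runs override `epochs`, `lr` and `sigma` (see the package
#' vignette).
#'
#' @param lr Learning rate of plain SGD (no schedule).
#' @param epochs Training epochs.
#' @param batch_size Images per gradient step; only 1 is supported, as in
#'   the reference protocol.
#' @param test_fraction Fraction of all items held out for testing.
#' @param val_fraction_of_pool Fraction of the remaining pool used for
#'   validation.
#' @param sigma Gaussian scale of the loss posterior, in density-grid
#'   units.
#' @param background_ratio Background-distance ratio (see
#'   [background_distance()]).
#' @param use_background Train with the background-augmented loss.
#' @param seed Seed controlling initialisation and shuffling.
#' @param val_every Validate (and checkpoint) every this many epochs.
#' @param device Kept for config-file compatibility; only `"cpu"` exists.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-5, epochs = 1000L, batch_size = 1L,
                         test_fraction = 0.15, val_fraction_of_pool = 0.1,
                         sigma = 8, background_ratio = 0.15,
                         use_background = TRUE, seed = 1L, val_every = 1L,
                         device = "cpu") {
  if (test_fraction <= 0 || test_fraction >= 1 ||
      val_fraction_of_pool <= 0 || val_fraction_of_pool >= 1) {
    abort("fractions must lie in (0, 1)", class = "rape_argument_error")
  }
  if (batch_size != 1L) {
    abort("only batch_size = 1 is supported", class = "rape_argument_error")
  }
  structure(list(lr = lr, epochs = as.integer(epochs), batch_size = 1L,
                 test_fraction = test_fraction,
                 val_fraction_of_pool = val_fraction_of_pool,
                 sigma = sigma, background_ratio = background_ratio,
                 use_background = use_background, seed = as.integer(seed),
                 val_every = as.integer(val_every), device = device),
            class = "train_config")
}

#' Deterministic train/validation/test split
#'
#' Shuffles the items with the configured seed, holds out
#' `round(test_fraction * n)` for testing, then takes
#' `floor(val_fraction_of_pool * pool)` of the remainder for validation.
#' The three parts are disjoint and exhaustive.
#'
#' @param items A data frame (e.g. a dataset manifest), one row per image.
#' @param cfg A [train_config()] (or a list with `test_fraction`,
#'   `val_fraction_of_pool`, `seed`).
#' @return A list of tibbles `train`, `val`, `test`.
#' @export
split_dataset <- function(items, cfg = train_config()) {
  items <- tibble::as_tibble(items)
  n <- nrow(items)
  if (n < 3L) abort("need at least 3 items to split", class = "rape_argument_error")
  n_test <- round(cfg$test_fraction * n)
  n_val <- floor(cfg$val_fraction_of_pool * (n - n_test))
  if (n_test < 1 || n_val < 1 || n - n_test - n_val < 1) {
    abort("a split partition would be empty; adjust the fractions",
          class = "rape_config_error")
  }
  ord <- with_preserved_seed({
    set.seed(cfg$seed)
    sample.int(n)
  })
  idx_test <- ord[seq_len(n_test)]
  idx_val <- ord[n_test + seq_len(n_val)]
  idx_train <- ord[(n_test + n_val + 1):n]
  list(train = items[sort(idx_train), ], val = items[sort(idx_val), ],
       test = items[sort(idx_test), ])
}

# Load a manifest row into (image, points). Accepts list-columns holding
# in-memory scenes or file paths from generate_dataset().
load_item <- function(row) {
  img <- if (is.list(row$image)) row$image[[1]] else read_image(row$image)
  ann <- row$annotation
  if (is.character(ann)) {
    pts <- if (grepl("\\.xml$", ann, ignore.case = TRUE)) {
      boxes_to_centroids(read_voc_boxes(ann))
    } else {
      read_points(ann)
    }
  } else {
    pts <- ann[[1]]
  }
  list(image = img, points = pts)
}

# Turn manifest rows into training samples: images at or below the tile
# size pass through whole; larger images are resized to the canvas and cut
# into tiles, each tile becoming an independent sample with its local
# annotations.
prepare_samples <- function(manifest, model_cfg, loss_cfg, tile_size = 256L) {
  samples <- list()
  for (r in seq_len(nrow(manifest))) {
    it <- load_item(manifest[r, ])
    d <- dim(it$image)
    if (d[1] <= tile_size && d[2] <= tile_size) {
      samples <- c(samples, list(it))
    } else {
      rc <- resize_to_canvas(it$image, it$points)
      tiles <- tile_image(rc$image, tile_size)
      tpts <- points_per_tile(rc$points, tiles)
      for (i in seq_len(nrow(tiles))) {
        samples <- c(samples, list(list(image = tiles$image[[i]],
                                        points = tpts[[i]])))
      }
    }
  }
  st <- model_cfg$output_stride
  lapply(samples, function(s) {
    d <- dim(s$image)
    grid <- make_pixel_grid(d[1], d[2], st)
    post <- if (nrow(s$points) > 0) {
      point_posterior(grid, s$points, loss_cfg)
    } else {
      NULL
    }
    list(image = s$image, n = nrow(s$points), post = post)
  })
}

#' Train a counting network
#'
#' Per epoch, each training sample is pushed through the network to a
#' density map; the Bayesian (or background-augmented) loss is formed from
#' the sample's annotation posterior and back-propagated, and plain SGD
#' updates the weights. Validation MAE is computed every `val_every`
#' epochs and the checkpoint with the lowest validation MAE is returned.
#' The annotation posterior of each sample depends only on its points and
#' the loss configuration, so it is precomputed once.
#'
#' @param model_cfg A [network_config()].
#' @param manifest Dataset manifest: columns `image` and `annotation` (file
#'   paths or in-memory list-columns) and `count`.
#' @param cfg A [train_config()].
#' @param split Optional precomputed [split_dataset()] result; by default
#'   the manifest is split internally.
#' @param verbose Print a line every 10 epochs.
#' @return An object of class `rape_fit`: `model` (best checkpoint),
#'   `final_model`, `log` (tibble epoch/loss/val_mae), `cfg`, `model_cfg`
#'   and `split`.
#' @export
train_rapenet <- function(model_cfg, manifest, cfg = train_config(),
                          split = NULL, verbose = FALSE) {
  if (is.null(split)) split <- split_dataset(manifest, cfg)
  if (nrow(split$train) == 0) abort("empty training set", class = "rape_argument_error")
  loss_cfg <- loss_config(sigma = cfg$sigma,
                          background_ratio = cfg$background_ratio,
                          use_background = cfg$use_background)
  tr <- prepare_samples(split$train, model_cfg, loss_cfg)
  va <- prepare_samples(split$val, model_cfg, loss_cfg)

  set.seed(cfg$seed)
  model <- rapenet(model_cfg)
  best <- list(mae = Inf, model = model)
  log <- vector("list", cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(length(tr))
    tot <- 0
    for (s in tr[ord]) {
      fw <- forward_rapenet(model, s$image, training = TRUE, want_cache = TRUE)
      model <- fw$model
      lg <- bayes_loss_grad(s$post, unclass(fw$D), cfg$use_background)
      if (!is.finite(lg$loss)) {
        abort(sprintf(
          "non-finite loss at epoch %d (N = %d, sigma = %g); try a smaller lr",
          ep, s$n, cfg$sigma), class = "rape_numeric_error")
      }
      tot <- tot + lg$loss
      grads <- backward_rapenet(model, fw$cache, lg$grad)
      model <- sgd_step(model, grads, cfg$lr)
    }
    val_mae <- NA_real_
    if (ep %% cfg$val_every == 0L || ep == cfg$epochs) {
      pred <- vapply(va, function(s) dm_count(predict_density(model, s$image)),
                     numeric(1))
      truth <- vapply(va, function(s) s$n, numeric(1))
      val_mae <- mean(abs(pred - truth))
      if (val_mae <= best$mae) best <- list(mae = val_mae, model = model)
    }
    log[[ep]] <- tibble::tibble(epoch = ep, loss = tot / length(tr),
                                val_mae = val_mae)
    if (verbose && ep %% 10L == 0L) {
      message(sprintf("epoch %4d  loss %8.4f  val MAE %s", ep, tot / length(tr),
                      ifelse(is.na(val_mae), "-", sprintf("%.2f", val_mae))))
    }
  }
  structure(list(model = best$model, final_model = model,
                 log = dplyr::bind_rows(log), cfg = cfg, model_cfg = model_cfg,
                 split = split),
            class = "rape_fit")
}

#' @export
print.rape_fit <- function(x, ...) {
  lg <- x$log[!is.na(x$log$val_mae), ]
  cat(sprintf("<rape_fit> %d epochs, final loss %.4f, best val MAE %.3f\n",
              max(x$log$epoch), x$log$loss[nrow(x$log)], min(lg$val_mae)))
  invisible(x)
}

#' @export
tidy.rape_fit <- function(x, ...) x$log

#' @export
glance.rape_fit <- function(x, ...) {
  lg <- x$log[!is.na(x$log$val_mae), ]
  tibble::tibble(
    epochs = max(x$log$epoch),
    final_loss = x$log$loss[nrow(x$log)],
    best_val_mae = min(lg$val_mae),
    parameters = count_parameters(x$model)
  )
}

#' Evaluate a trained model on a test manifest
#'
#' Runs the counting pipeline on every test image (tiled when larger than
#' a tile, direct otherwise), pairs the density-sum counts with the
#' annotation counts, and computes the full metric set.
#'
#' @param model A `rapenet` model (or a `rape_fit`, whose best checkpoint
#'   is used).
#' @param manifest Test manifest (as in [train_rapenet()]).
#' @param ... Passed to [evaluate_counts()] (e.g. `r2_denominator`).
#' @return A list with `metrics` (a `count_metrics`) and `per_image` (an
#'   [evaluation_set()] tibble).
#' @export
evaluate_model <- function(model, manifest, ...) {
  if (inherits(model, "rape_fit")) model <- model$model
  if (nrow(manifest) == 0) abort("empty test set", class = "rape_argument_error")
  rows <- vector("list", nrow(manifest))
  tile <- 256L
  for (r in seq_len(nrow(manifest))) {
    it <- load_item(manifest[r, ])
    d <- dim(it$image)
    inferred <- if (d[1] <= tile && d[2] <= tile) {
      dm_count(predict_density(model, it$image))
    } else {
      predict_count(it$image, model, tile_size = tile)$count
    }
    rows[[r]] <- tibble::tibble(
      image_id = attr(it$points, "image_id") %||% as.character(r),
      manual = nrow(it$points), inferred = inferred)
  }
  ev <- evaluation_set(dplyr::bind_rows(rows))
  list(metrics = evaluate_counts(ev, ...), per_image = ev)
}
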