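# Shared fixtures, independent oracles, and a memoised desk-scale training
# run reused by the slower end-to-end tests.

# naive, loop-based evaluation of the Gaussian likelihood (independent of
# the vectorised implementation path)
naive_likelihood <- function(grid, z, sigma) {
  out <- matrix(0, nrow(z), grid$M)
  for (n in seq_len(nrow(z))) {
    for (m in seq_len(grid$M)) {
      dx <- grid$locations[m, 1] - z[n, 1]
      dy <- grid$locations[m, 2] - z[n, 2]
      out[n, m] <- exp(-(dx^2 + dy^2) / (2 * sigma^2)) / (2 * pi * sigma^2)
    }
  }
  out
}

# double-loop scalar oracle for the Bayesian losses (F = absolute value)
naive_bayes_loss <- function(post, D) {
  Dv <- as.vector(t(unclass(D)))
  total <- 0
  for (n in seq_len(nrow(post))) {
    e <- 0
    for (m in seq_along(Dv)) e <- e + post[n, m] * Dv[m]
    total <- total + abs(1 - e)
  }
  total
}

naive_bayes_plus_loss <- function(post, D) {
  Dv <- as.vector(t(unclass(D)))
  e <- numeric(nrow(post))
  for (n in seq_len(nrow(post))) {
    for (m in seq_along(Dv)) e[n] <- e[n] + post[n, m] * Dv[m]
  }
  sum(abs(1 - e[-1])) + abs(0 - e[1])
}

# random loss configuration on a small grid, used by the oracle-equivalence
# and normalisation tests
random_loss_case <- function(max_grid = 16L, max_points = 6L,
                             sigma = NULL) {
  h <- sample(2:max_grid, 1)
  w <- sample(2:max_grid, 1)
  st <- sample(c(1L, 2L, 4L), 1)
  grid <- make_pixel_grid(h * st, w * st, st)
  n <- sample(1:max_points, 1)
  pts <- point_annotations(
    tibble::tibble(x = runif(n, 0, w * st), y = runif(n, 0, h * st)))
  if (is.null(sigma)) sigma <- runif(1, 0.5, 6)
  D <- density_map(matrix(runif(h * w, 0, 0.5), h, w), stride = st)
  list(grid = grid, pts = pts, sigma = sigma, D = D)
}

desk_manifest <- function(n_images = 100L, seed0 = 100L) {
  cfg <- scene_config("desk")
  dplyr::bind_rows(lapply(seq_len(n_images), function(i) {
    sc <- generate_scene(cfg, seed = seed0 + i)
    tibble::tibble(image = list(sc$image), annotation = list(sc$points),
                   count = nrow(sc$points))
  }))
}

# desk-scale training profile: reduced-width backbone, learning rate and
# sigma sized for 128x128 scenes (see the methods vignette)
desk_train_config <- function(epochs = 100L, seed = 1L) {
  train_config(lr = 3e-4, epochs = epochs, sigma = 1,
               background_ratio = 0.15, use_background = TRUE,
               seed = seed, val_every = 5L)
}

desk_network_config <- function() network_config(width_multiplier = 0.125)

# train once per test session; the recovery and resolution-robustness tests
# share the fitted model
.desk_cache <- new.env(parent = emptyenv())
get_desk_fit <- function() {
  if (is.null(.desk_cache$fit)) {
    manifest <- desk_manifest()
    .desk_cache$manifest <- manifest
    .desk_cache$fit <- train_rapenet(desk_network_config(), manifest,
                                     desk_train_config())
  }
  list(fit = .desk_cache$fit, manifest = .desk_cache$manifest)
}
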