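# Bayesian point-supervision loss for density-map counting.
#
# Instead of regressing a smoothed ground-truth density, each density-map
# cell x_m is softly assigned to the annotated centroids z_n through a
# posterior p(y_n | x_m) built from isotropic Gaussian likelihoods; the loss
# penalises the deviation of every annotation's expected count
# E_n = sum_m p(y_n | x_m) D(x_m) from 1. The "background-augmented" variant
# adds a dummy annotation at distance d beyond each cell's nearest centroid
# so far-from-flower density can be pushed to zero rather than smeared onto
# the nearest flower.

#' Pixel grid of a density map
#'
#' Describes the discrete sites `x_m` of a density map produced at a given
#' output stride. Cell `(i, j)` (0-based row `i`, column `j`) sits at
#' `(j + 0.5, i + 0.5)` in grid units; annotations in input-pixel
#' coordinates are mapped onto the grid by dividing by the stride. Sites are
#' ordered row-major, so `M = height * width` matches a density map
#' flattened by rows.
#'
#' @param height_px,width_px Input image size in pixels; both must be
#'   divisible by `stride`.
#' @param stride Input pixels per density-map cell.
#' @return An object of class `pixel_grid`: a list with `height`, `width`
#'   (grid cells), `stride`, `M`, and `locations`, an `M x 2` matrix of
#'   `(x, y)` site positions in grid units.
#' @export
make_pixel_grid <- function(height_px, width_px, stride) {
  if (height_px %% stride != 0 || width_px %% stride != 0) {
    abort("image dimensions must be divisible by the stride",
          class = "rape_argument_error")
  }
  h <- height_px %/% stride
  w <- width_px %/% stride
  gx <- rep(seq_len(w) - 0.5, times = h)
  gy <- rep(seq_len(h) - 0.5, each = w)
  structure(
    list(height = h, width = w, stride = stride, M = h * w,
         locations = cbind(x = gx, y = gy)),
    class = "pixel_grid"
  )
}

# annotations (input pixels) -> grid-unit coordinates, as an N x 2 matrix
points_to_grid <- function(pts, grid) {
  cbind(pts$x / grid$stride, pts$y / grid$stride)
}

#' Gaussian likelihood matrix between annotations and grid sites
#'
#' Entry `(n, m)` is the isotropic 2-D Gaussian density with mean at
#' annotation `z_n` and per-axis variance `sigma^2`, evaluated at grid site
#' `x_m`:
#' `exp(-||x_m - z_n||^2 / (2 sigma^2)) / (2 pi sigma^2)`.
#'
#' @param grid A [make_pixel_grid()] object.
#' @param pts A [point_annotations()] set in *input-pixel* coordinates
#'   (divided internally by the grid stride), or an `N x 2` matrix already
#'   in grid units.
#' @param sigma Gaussian scale in grid units, `> 0`.
#' @return An `N x M` matrix (possibly `0 x M` when `N = 0`).
#' @export
likelihood_matrix <- function(grid, pts, sigma) {
  exp(log_likelihood_matrix(grid, pts, sigma))
}

log_likelihood_matrix <- function(grid, pts, sigma) {
  stopifnot(is.numeric(sigma), sigma > 0)
  z <- if (is.matrix(pts)) pts else points_to_grid(pts, grid)
  n <- nrow(z)
  if (n == 0L) return(matrix(0, 0L, grid$M))
  d2 <- sq_dists(z, grid$locations) # N x M
  -d2 / (2 * sigma^2) - log(2 * pi * sigma^2)
}

# squared Euclidean distances between rows of a (n x 2) and rows of b (m x 2)
sq_dists <- function(a, b) {
  outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
}

#' Dummy background point for one grid site
#'
#' Places a virtual annotation on the ray from the nearest real annotation
#' `z_near` through the site `x`, at distance `d` from `z_near`:
#' `z0 = z_near + d * (x - z_near) / ||x - z_near||`. When `x` coincides
#' with `z_near` the direction is undefined; the degenerate branch returns
#' `z_near` itself and emits a message.
#'
#' @param x 2-vector, grid site position.
#' @param z_near 2-vector, nearest annotation position.
#' @param d Positive distance to the background point.
#' @return A 2-vector.
#' @export
background_point <- function(x, z_near, d) {
  stopifnot(length(x) == 2L, length(z_near) == 2L, d > 0)
  v <- x - z_near
  nv <- sqrt(sum(v^2))
  if (nv == 0) {
    inform("background_point: site coincides with an annotation; returning the annotation")
    return(z_near)
  }
  z_near + d * v / nv
}

#' Background likelihood row
#'
#' For each grid site `x_m`, with `dist_m = ||x_m - z_n^m||` the distance to
#' its nearest annotation, the background label's likelihood is the 1-D
#' Gaussian kernel
#' `exp(-(d - dist_m)^2 / (2 sigma^2)) / (sqrt(2 pi) sigma)`,
#' i.e. the density that would be assigned by a virtual annotation at
#' distance `d` beyond the nearest real one. Note the 1-D normaliser: the
#' foreground likelihoods use the 2-D one. The asymmetry is kept as defined;
#' the posterior only depends on likelihood ratios, so it simply acts as a
#' fixed background weighting.
#'
#' @inheritParams likelihood_matrix
#' @param d Background distance in grid units, `> 0`; see
#'   [background_distance()].
#' @return A length-`M` vector.
#' @export
background_likelihood <- function(grid, pts, sigma, d) {
  exp(log_background_likelihood(grid, pts, sigma, d))
}

log_background_likelihood <- function(grid, pts, sigma, d) {
  stopifnot(sigma > 0, d > 0)
  z <- if (is.matrix(pts)) pts else points_to_grid(pts, grid)
  if (nrow(z) == 0L) {
    abort("background likelihood needs at least one annotation",
          class = "rape_argument_error")
  }
  d2 <- sq_dists(z, grid$locations)
  nearest <- sqrt(pmax(apply(d2, 2, min), 0))
  -(d - nearest)^2 / (2 * sigma^2) - log(sqrt(2 * pi) * sigma)
}

#' Posterior label probabilities per grid site
#'
#' Normalises a likelihood matrix column-wise under uniform label priors:
#' `p(y_n | x_m) = lik[n, m] / sum_k lik[k, m]`. When a background row is
#' supplied it becomes row 1 of the result and normalisation runs over the
#' `N + 1` labels.
#'
#' This entry point works on *linear-scale* likelihoods and raises an error
#' on columns that underflow to zero; [point_posterior()] is the log-space
#' path that is robust down to `sigma = 0.1`.
#'
#' @param lik `N x M` likelihood matrix.
#' @param bg Optional length-`M` background likelihood row.
#' @return A `posterior_matrix`: an `(N + [bg]) x M` column-stochastic
#'   matrix with attribute `has_background`.
#' @export
posterior_matrix <- function(lik, bg = NULL) {
  if (!is.null(bg)) lik <- rbind(matrix(bg, 1L), lik)
  if (nrow(lik) == 0L) abort("posterior needs at least one row",
                             class = "rape_argument_error")
  if (any(lik < 0)) abort("likelihoods must be non-negative",
                          class = "rape_argument_error")
  cs <- colSums(lik)
  if (any(cs == 0)) {
    abort(sprintf(
      "likelihood column %d sums to zero (numerical underflow); use point_posterior() which normalises in log space",
      which(cs == 0)[1]), class = "rape_numeric_error")
  }
  structure(sweep(lik, 2, cs, "/"),
            class = c("posterior_matrix", "matrix", "array"),
            has_background = !is.null(bg))
}

#' Posterior from annotations, computed in log space
#'
#' Builds the foreground (and optionally background) log-likelihoods and
#' normalises each column after subtracting its maximum, so small `sigma`
#' (down to 0.1 grid units) cannot underflow to an all-zero column.
#'
#' @inheritParams likelihood_matrix
#' @param cfg A [loss_config()].
#' @param d Background distance in grid units; default derives from
#'   `cfg$background_ratio` via [background_distance()].
#' @return A `posterior_matrix` (`N` rows, or `N + 1` with background as
#'   row 1).
#' @export
point_posterior <- function(grid, pts, cfg = loss_config(), d = NULL) {
  ll <- log_likelihood_matrix(grid, pts, cfg$sigma)
  if (nrow(ll) == 0L) {
    abort("no annotations: the posterior is undefined for N = 0 (the loss handles this case directly)",
          class = "rape_argument_error")
  }
  if (isTRUE(cfg$use_background)) {
    if (is.null(d)) d <- background_distance(cfg, grid)
    lb <- log_background_likelihood(grid, pts, cfg$sigma, d)
    ll <- rbind(lb, ll)
  }
  mx <- apply(ll, 2, max)
  p <- exp(sweep(ll, 2, mx, "-"))
  p <- sweep(p, 2, colSums(p), "/")
  structure(p, class = c("posterior_matrix", "matrix", "array"),
            has_background = isTRUE(cfg$use_background))
}

#' Loss configuration
#'
#' Bundles the tunables of the Bayesian counting loss: the Gaussian scale
#' `sigma` (grid units; the useful range explored for this loss family is
#' 0.1-10), the background ratio in `[0, 1]` that generates the dummy-point
#' distance `d` (see [background_distance()]), whether the background label
#' is used at all, and the per-annotation penalty `F` (default absolute
#' value, so each term is `|1 - E_n|`).
#'
#' @param sigma Gaussian scale in density-grid units.
#' @param background_ratio Fraction of the tile's shorter side used as the
#'   background distance `d`.
#' @param use_background Use the background-augmented (Bayes+) posterior?
#' @param penalty Function `F` applied to each count deviation.
#' @param d Optional absolute background distance in grid units, overriding
#'   the ratio-derived one.
#' @param sigma_range Validation bounds for `sigma`.
#' @return A `loss_config` list.
#' @export
loss_config <- function(sigma = 8, background_ratio = 0.15,
                        use_background = TRUE, penalty = abs, d = NULL,
                        sigma_range = c(0.1, 10)) {
  if (!is.numeric(sigma) || sigma < sigma_range[1] || sigma > sigma_range[2]) {
    abort(sprintf("sigma must lie in [%g, %g]", sigma_range[1], sigma_range[2]),
          class = "rape_argument_error")
  }
  if (background_ratio < 0 || background_ratio > 1) {
    abort("background_ratio must lie in [0, 1]", class = "rape_argument_error")
  }
  structure(list(sigma = sigma, background_ratio = background_ratio,
                 use_background = use_background, penalty = penalty, d = d,
                 sigma_range = sigma_range),
            class = "loss_config")
}

#' Background distance implied by a loss configuration
#'
#' The dummy background point sits at
#' `d = background_ratio * min(tile height, tile width)` (in grid units,
#' i.e. the ratio is applied to the density grid's shorter side). An
#' absolute `d` stored in the configuration takes precedence.
#'
#' @param cfg A [loss_config()].
#' @param grid A [make_pixel_grid()] object.
#' @return The distance `d` in grid units.
#' @export
background_distance <- function(cfg, grid) {
  if (!is.null(cfg$d)) return(cfg$d)
  d <- cfg$background_ratio * min(grid$height, grid$width)
  if (d <= 0) {
    abort("background distance is zero; set a positive background_ratio or d",
          class = "rape_argument_error")
  }
  d
}

expected_counts <- function(post, D) {
  v <- as.vector(t(D)) # row-major flattening matches the grid ordering
  if (ncol(post) != length(v)) {
    abort(sprintf("posterior has %d columns but the density map has %d cells",
                  ncol(post), length(v)), class = "rape_argument_error")
  }
  as.vector(post %*% v)
}

#' Bayesian counting loss (foreground only)
#'
#' `sum_n F(1 - E_n)` with `E_n = sum_m p(y_n | x_m) D(x_m)`. For an image
#' with no annotations the sum is empty; the loss degenerates to
#' `F(0 - sum(D))`, pushing the model toward an empty map.
#'
#' @param post A `posterior_matrix` *without* a background row.
#' @param D A density map (matrix, `height x width` of the grid).
#' @param cfg A [loss_config()]; only `penalty` is used here.
#' @return A scalar loss.
#' @export
bayes_loss <- function(post, D, cfg = loss_config(use_background = FALSE)) {
  if (isTRUE(attr(post, "has_background"))) {
    abort("bayes_loss expects a posterior without background; use bayes_plus_loss",
          class = "rape_argument_error")
  }
  FF <- cfg$penalty
  if (nrow(post) == 0L) return(FF(0 - sum(D)))
  e <- expected_counts(post, D)
  sum(FF(1 - e))
}

#' Background-augmented Bayesian counting loss
#'
#' `sum_{n=1..N} F(1 - E_n) + F(0 - E_0)` where row 1 of the posterior is
#' the background label whose expected count `E_0` is driven toward zero.
#'
#' @param post A `posterior_matrix` *with* the background row first.
#' @inheritParams bayes_loss
#' @return A scalar loss.
#' @export
bayes_plus_loss <- function(post, D, cfg = loss_config()) {
  if (!isTRUE(attr(post, "has_background"))) {
    abort("bayes_plus_loss expects a posterior with a background row",
          class = "rape_argument_error")
  }
  FF <- cfg$penalty
  e <- expected_counts(post, D)
  sum(FF(1 - e[-1])) + FF(0 - e[1])
}

# Loss and its (sub)gradient w.r.t. the density map, for the default
# F(v) = |v|. Returns list(loss, grad) with grad shaped like D.
bayes_loss_grad <- function(post, D, use_background) {
  h <- nrow(D); w <- ncol(D)
  if (is.null(post) || nrow(post) == 0L) { # N = 0 image
    s <- sum(D)
    return(list(loss = abs(s), grad = matrix(sign(s), h, w)))
  }
  e <- expected_counts(post, D)
  if (use_background) {
    target <- c(0, rep(1, length(e) - 1L))
  } else {
    target <- rep(1, length(e))
  }
  r <- target - e
  loss <- sum(abs(r))
  gv <- as.vector(crossprod(post, -sign(r))) # M vector, row-major
  list(loss = loss, grad = matrix(gv, h, w, byrow = TRUE))
}
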