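test_that("pixel grids enumerate density-map sites row-major in grid units", {
  g <- make_pixel_grid(256, 256, 8)
  expect_equal(c(g$height, g$width, g$M), c(32, 32, 1024))

  g2 <- make_pixel_grid(2, 2, 1)
  expect_equal(unname(g2$locations),
               cbind(c(0.5, 1.5, 0.5, 1.5), c(0.5, 0.5, 1.5, 1.5)))

  # annotations map to the grid by dividing by the stride
  pts <- point_annotations(tibble::tibble(x = 128, y = 64))
  expect_equal(unname(rapecount:::points_to_grid(pts, g)), cbind(16, 8))

  expect_error(make_pixel_grid(100, 64, 8), class = "rape_argument_error")
})

test_that("the likelihood is an isotropic 2-D Gaussian around each annotation", {
  g <- make_pixel_grid(4, 4, 1)
  # a point at a site's own location: density 1/(2*pi) at sigma 1
  pts <- point_annotations(tibble::tibble(x = 1.5, y = 2.5))
  lik <- likelihood_matrix(g, pts, sigma = 1)
  m_at <- which(g$locations[, 1] == 1.5 & g$locations[, 2] == 2.5)
  expect_equal(lik[1, m_at], 1 / (2 * pi), tolerance = 1e-12)

  # isotropy: equidistant sites get equal likelihood
  p2 <- point_annotations(tibble::tibble(x = 2, y = 2))
  l2 <- likelihood_matrix(g, p2, sigma = 1.7)
  d2 <- rowSums(sweep(g$locations, 2, c(2, 2))^2)
  for (dd in unique(round(d2, 9))) {
    expect_lt(diff(range(l2[1, abs(d2 - dd) < 1e-9])), 1e-12)
  }

  # element-by-element agreement with the scalar oracle
  set.seed(21)
  g3 <- make_pixel_grid(4, 4, 1)
  z <- cbind(runif(2, 0, 4), runif(2, 0, 4))
  expect_equal(likelihood_matrix(g3, z, sigma = 2),
               naive_likelihood(g3, z, 2), tolerance = 1e-12)

  expect_equal(nrow(likelihood_matrix(g3, point_annotations(), 1)), 0L)
})

test_that("dummy background points sit at distance d along the site ray", {
  expect_equal(background_point(c(3, 4), c(0, 0), 5), c(3, 4))
  expect_equal(background_point(c(6, 8), c(0, 0), 5), c(3, 4))
  # degenerate site-on-annotation returns the annotation, with a note
  expect_message(z0 <- background_point(c(1, 1), c(1, 1), 5))
  expect_equal(z0, c(1, 1))
})

test_that("background likelihood follows the 1-D Gaussian kernel in nearest distance", {
  g <- make_pixel_grid(8, 8, 1)
  pts <- point_annotations(tibble::tibble(x = 0.5, y = 0.5))
  # at a site whose nearest-annotation distance equals d the kernel peaks
  d <- 3
  bl <- background_likelihood(g, pts, sigma = 1, d = d)
  dist <- sqrt(rowSums(sweep(g$locations, 2, c(0.5, 0.5))^2))
  at_d <- which(abs(dist - d) < 1e-12)
  expect_gt(length(at_d), 0)
  expect_equal(bl[at_d], rep(1 / sqrt(2 * pi), length(at_d)), tolerance = 1e-12)

  # direct evaluation at sigma 2, d 6, distance 2
  idx <- which(abs(dist - 2) < 1e-9)[1]
  expect_equal(bl2 <- background_likelihood(g, pts, 2, 6)[idx],
               1 / (sqrt(2 * pi) * 2) * exp(-16 / 8), tolerance = 1e-12)

  # far tail decays towards zero
  gg <- make_pixel_grid(64, 64, 1)
  far <- background_likelihood(gg, pts, sigma = 1, d = 2)
  expect_lt(min(far), 1e-100)

  expect_error(background_likelihood(g, point_annotations(), 1, 2),
               class = "rape_argument_error")
})

test_that("posteriors are column-stochastic and match per-column normalisation", {
  g <- make_pixel_grid(5, 5, 1)
  one <- likelihood_matrix(g, point_annotations(tibble::tibble(x = 2, y = 2)), 1)
  p1 <- posterior_matrix(one)
  expect_equal(as.vector(p1), rep(1, g$M))

  # symmetric pair: the equidistant column splits 0.5 / 0.5
  pair <- likelihood_matrix(
    g, point_annotations(tibble::tibble(x = c(1.5, 3.5), y = c(2.5, 2.5))), 1)
  pp <- posterior_matrix(pair)
  mid <- which(g$locations[, 1] == 2.5 & g$locations[, 2] == 2.5)
  expect_equal(pp[, mid], c(0.5, 0.5))

  set.seed(31)
  lik <- matrix(runif(3 * 25), 3, 25)
  pr <- posterior_matrix(lik)
  expect_lt(max(abs(colSums(pr) - 1)), 1e-10)
  expect_equal(unclass(pr), sweep(lik, 2, colSums(lik), "/"), tolerance = 1e-10,
               ignore_attr = TRUE)

  # a zero column is a numerical-underflow error naming the pixel
  zl <- lik; zl[, 7] <- 0
  expect_error(posterior_matrix(zl), "7", class = "rape_numeric_error")
})

test_that("log-space posteriors survive sigma = 0.1 on a 32x32 grid", {
  g <- make_pixel_grid(32, 32, 1)
  corner <- point_annotations(tibble::tibble(x = 0.5, y = 0.5))
  cfg <- loss_config(sigma = 0.1, use_background = FALSE)
  p <- point_posterior(g, corner, cfg)
  expect_false(any(is.nan(p)))
  expect_lt(max(abs(colSums(p) - 1)), 1e-6)
  # the same configuration underflows on the linear scale
  expect_error(posterior_matrix(likelihood_matrix(g, corner, 0.1)),
               class = "rape_numeric_error")
})

test_that("Bayesian losses satisfy their closed-form identities", {
  g <- make_pixel_grid(12, 12, 1)
  pts <- point_annotations(tibble::tibble(x = runif(3, 0, 12), y = runif(3, 0, 12)))
  cfg_fg <- loss_config(sigma = 2, use_background = FALSE)
  post <- point_posterior(g, pts, cfg_fg)

  # zero density map: every expected count is 0, so the loss is N
  D0 <- density_map(matrix(0, 12, 12), 1)
  expect_identical(bayes_loss(post, D0, cfg_fg), 3)

  # a single annotation absorbs the whole map: total mass 1 gives loss 0
  one <- point_posterior(g, point_annotations(tibble::tibble(x = 3, y = 4)), cfg_fg)
  set.seed(5)
  Dm <- matrix(runif(144), 12, 12)
  Dm <- Dm / sum(Dm)
  expect_lt(abs(bayes_loss(one, density_map(Dm, 1), cfg_fg)), 1e-9)

  # background variant on a zero map: background term is |0 - 0| = 0
  cfg_bg <- loss_config(sigma = 2, background_ratio = 0.3)
  pts5 <- point_annotations(tibble::tibble(x = runif(5, 0, 12), y = runif(5, 0, 12)))
  post5 <- point_posterior(g, pts5, cfg_bg)
  expect_identical(bayes_plus_loss(post5, D0, cfg_bg), 5)

  # shape mismatches are argument errors
  expect_error(bayes_loss(post, density_map(matrix(0, 5, 5), 1), cfg_fg),
               class = "rape_argument_error")
  expect_error(bayes_plus_loss(post, D0, cfg_bg), class = "rape_argument_error")
})

test_that("vectorised losses agree with the double-loop oracle", {
  set.seed(77)
  for (rep in 1:20) {
    cs <- random_loss_case()
    cfg_fg <- loss_config(sigma = cs$sigma, use_background = FALSE)
    post <- point_posterior(cs$grid, cs$pts, cfg_fg)
    expect_equal(bayes_loss(post, cs$D, cfg_fg), naive_bayes_loss(post, cs$D),
                 tolerance = 1e-6)

    cfg_bg <- loss_config(sigma = cs$sigma, background_ratio = runif(1, 0.05, 1))
    postb <- point_posterior(cs$grid, cs$pts, cfg_bg)
    expect_equal(bayes_plus_loss(postb, cs$D, cfg_bg),
                 naive_bayes_plus_loss(postb, cs$D), tolerance = 1e-6)
  }
})

test_that("with background the expected counts conserve total density mass", {
  set.seed(13)
  for (rep in 1:10) {
    cs <- random_loss_case()
    cfg <- loss_config(sigma = cs$sigma, background_ratio = runif(1, 0.05, 1))
    post <- point_posterior(cs$grid, cs$pts, cfg)
    e <- as.vector(post %*% as.vector(t(unclass(cs$D))))
    expect_lt(abs(sum(e) - sum(cs$D)), 1e-9)
  }
})

test_that("expected counts are linear in the density map", {
  set.seed(19)
  cs <- random_loss_case()
  cfg <- loss_config(sigma = cs$sigma, background_ratio = 0.4)
  post <- point_posterior(cs$grid, cs$pts, cfg)
  e1 <- as.vector(post %*% as.vector(t(unclass(cs$D))))
  for (t in c(0, 0.5, 2, 17)) {
    Dt <- density_map(unclass(cs$D) * t, attr(cs$D, "stride"))
    et <- as.vector(post %*% as.vector(t(unclass(Dt))))
    expect_equal(et, t * e1, tolerance = 1e-12)
  }
})

test_that("an annotation-free image is pushed toward an empty map", {
  lg <- rapecount:::bayes_loss_grad(NULL, matrix(0.25, 4, 4), TRUE)
  expect_equal(lg$loss, 4)
  expect_true(all(lg$grad == 1))
})

test_that("loss configuration validates its ranges", {
  expect_error(loss_config(sigma = 0.01), class = "rape_argument_error")
  expect_error(loss_config(background_ratio = 1.5), class = "rape_argument_error")
  cfg <- loss_config(sigma = 0.05, sigma_range = c(0.01, 20))
  expect_equal(cfg$sigma, 0.05)
  g <- make_pixel_grid(16, 32, 8)
  expect_equal(background_distance(loss_config(background_ratio = 0.5), g), 1)
  expect_equal(background_distance(loss_config(d = 3.3), g), 3.3)
})
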