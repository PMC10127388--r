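test_that("plot images resize to the 512x1024 canvas with annotations intact", {
  set.seed(41)
  img <- array(runif(606 * 1105 * 3), c(606, 1105, 3))
  pts <- point_annotations(tibble::tibble(x = runif(30, 0, 1104),
                                          y = runif(30, 0, 605)),
                           image_width = 1105, image_height = 606)
  rc <- resize_to_canvas(img, pts)
  expect_equal(dim(rc$image), c(512L, 1024L, 3L))
  expect_identical(n_points(rc$points), 30L)
  expect_true(all(rc$points$x <= 1024 & rc$points$y <= 512))

  # an already-canvas-sized image passes through pixel-identically
  canvas <- array(runif(512 * 1024 * 3), c(512, 1024, 3))
  expect_identical(resize_to_canvas(canvas)$image, canvas)

  # portrait inputs are rotated to landscape first
  tall <- array(runif(1000 * 500 * 3), c(1000, 500, 3))
  expect_message(rt <- resize_to_canvas(tall), "rotated")
  expect_equal(dim(rt$image), c(512L, 1024L, 3L))

  expect_error(resize_to_canvas(array(0, c(0, 10, 3))),
               class = "rape_argument_error")
})

test_that("a 512x1024 canvas tiles into exactly 8 windows that partition it", {
  set.seed(42)
  canvas <- array(runif(512 * 1024 * 3), c(512, 1024, 3))
  ts <- tile_image(canvas)
  expect_equal(nrow(ts), 8L)
  expect_equal(sum(vapply(ts$image, function(t) prod(dim(t)[1:2]), numeric(1))),
               512 * 1024)
  # round trip is bit-exact
  expect_identical(stitch_tiles(ts), canvas)

  # every pixel belongs to exactly one tile
  coverage <- matrix(0L, 512, 1024)
  for (i in seq_len(nrow(ts))) {
    coverage[ts$y0[i] + 1:256, ts$x0[i] + 1:256] <-
      coverage[ts$y0[i] + 1:256, ts$x0[i] + 1:256] + 1L
  }
  expect_true(all(coverage == 1L))

  expect_error(tile_image(array(0, c(500, 1024, 3))),
               class = "rape_argument_error")
})

test_that("tile origins are row-major and annotations map to tile-local frames", {
  canvas <- array(0, c(512, 1024, 3))
  ts <- tile_image(canvas)
  expect_equal(ts$x0, c(0, 256, 512, 768, 0, 256, 512, 768))
  expect_equal(ts$y0, c(0, 0, 0, 0, 256, 256, 256, 256))
  pts <- point_annotations(tibble::tibble(x = c(10, 300, 1024), y = c(10, 400, 511)))
  per <- rapecount:::points_per_tile(pts, ts)
  expect_equal(vapply(per, nrow, integer(1)), c(1L, 0L, 0L, 0L, 0L, 1L, 0L, 1L))
  expect_equal(per[[6]]$x, 300 - 256)
  # the canvas-edge point lands in the last tile
  expect_equal(per[[8]]$y, 511 - 256)
})

test_that("tiled prediction conserves counts and matches the direct forward", {
  model <- rapenet(network_config(width_multiplier = 0.125), seed = 5)
  set.seed(43)
  img <- array(runif(512 * 1024 * 3), c(512, 1024, 3))
  pred <- predict_count(img, model)
  expect_identical(pred$count, sum(pred$tiles$count))
  expect_equal(dim(pred$density), c(64L, 128L))
  expect_lt(abs(dm_count(pred$density) - pred$count), 1e-9)

  # a single-tile image reduces to the direct forward pass
  tile <- array(runif(256 * 256 * 3), c(256, 256, 3))
  p1 <- predict_count(tile, model, resize = FALSE)
  expect_equal(unclass(p1$density), unclass(predict_density(model, tile)))

  # zeroed regression head produces the null count
  zm <- model
  zm$head$w1[] <- 0; zm$head$b1[] <- 0; zm$head$w2[] <- 0; zm$head$b2 <- 0
  expect_identical(predict_count(img, zm)$count, 0)
})

test_that("count conservation holds across random models and inputs", {
  set.seed(44)
  for (rep in 1:5) {
    model <- rapenet(network_config(width_multiplier = 0.125), seed = rep)
    img <- array(runif(512 * 512 * 3), c(512, 512, 3))
    pred <- predict_count(img, model, resize = FALSE)
    expect_lt(abs(dm_count(pred$density) - sum(pred$tiles$count)), 1e-9)
  }
})

test_that("heat-map rendering blends density over the image", {
  set.seed(45)
  img <- array(runif(64 * 96 * 3), c(64, 96, 3))
  D0 <- density_map(matrix(0, 8, 12), 8)
  expect_equal(render_heatmap(img, D0, alpha = 0.9), img)

  m <- matrix(0, 8, 12); m[3, 5] <- 2; m[6, 10] <- 1
  D <- density_map(m, 8)
  ov <- render_heatmap(img, D, alpha = 0.7)
  expect_equal(dim(ov), dim(img))
  # overlay strength follows the density: untouched where it is zero,
  # strictly positive at the argmax
  dev <- apply(abs(ov - img), c(1, 2), max)
  up <- rapecount:::resize_matrix(m, 64, 96)
  expect_gt(dev[which.max(up)], 0)
  expect_lt(max(dev[up == 0]), 1e-12)

  expect_error(render_heatmap(img, D, alpha = 1.2), class = "rape_argument_error")
  expect_error(density_map(matrix(-1, 2, 2)), class = "rape_validation_error")
})

test_that("density maps round-trip through the CSV grid and 16-bit PNG", {
  set.seed(46)
  D <- density_map(matrix(runif(32 * 16, 0, 3), 16, 32), 8)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_density_csv(D, csv)
  D2 <- read_density_csv(csv)
  expect_equal(unclass(D2), unclass(D), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(D2, "stride"), 8L)

  png_path <- withr::local_tempfile(fileext = ".png")
  scale <- write_density_png16(D, png_path)
  back <- png::readPNG(png_path) * scale
  expect_equal(back, unclass(D), tolerance = scale / 65535 + 1e-9,
               ignore_attr = TRUE)
})
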