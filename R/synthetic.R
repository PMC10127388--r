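# Seeded generator of field-plot-like scenes: yellow, soft-edged,
# partially overlapping elliptical "flower cluster" blobs over a textured
# green canopy, with known centroids. This is the offline stand-in for UAV
# plot imagery that makes training, losses and metrics testable end to end.

#' Scene generator configuration
#'
#' The `"plot"` profile emulates a full 512x1024 working canvas with
#' cluster counts spanning the box-labelled field range (8-686); the
#' `"desk"` profile is a 128x128 scene with 5-40 clusters sized for
#' CPU-scale training runs.
#'
#' @param profile Base profile, `"plot"` or `"desk"`; explicit arguments
#'   override its values.
#' @param height,width Scene size in pixels.
#' @param count_range Inclusive range of cluster counts per scene.
#' @param blob_radius_range Range of blob semi-major radii in pixels.
#' @param min_center_distance Minimum pairwise distance between centroids.
#' @param occlusion_prob Probability that a blob is placed clustered next
#'   to an existing one (producing the overlap/adhesion typical of peak
#'   flowering).
#' @param background_green,cluster_yellow Mean RGB of canopy and flowers.
#' @param color_jitter SD of per-blob colour jitter.
#' @param noise_sd SD of additive pixel noise.
#' @param seed Default seed used by [generate_scene()].
#' @return A `scene_config` list.
#' @export
scene_config <- function(profile = c("plot", "desk"),
                         height = NULL, width = NULL, count_range = NULL,
                         blob_radius_range = NULL, min_center_distance = NULL,
                         occlusion_prob = 0.3,
                         background_green = c(0.20, 0.38, 0.13),
                         cluster_yellow = c(0.93, 0.86, 0.20),
                         color_jitter = 0.04, noise_sd = 0.02, seed = 1L) {
  profile <- match.arg(profile)
  base <- switch(profile,
    plot = list(height = 512L, width = 1024L, count_range = c(8L, 686L),
                blob_radius_range = c(5, 12), min_center_distance = 4),
    desk = list(height = 128L, width = 128L, count_range = c(5L, 40L),
                blob_radius_range = c(4, 9), min_center_distance = 6)
  )
  cfg <- list(
    profile = profile,
    height = height %||% base$height, width = width %||% base$width,
    count_range = count_range %||% base$count_range,
    blob_radius_range = blob_radius_range %||% base$blob_radius_range,
    min_center_distance = min_center_distance %||% base$min_center_distance,
    occlusion_prob = occlusion_prob,
    background_green = background_green, cluster_yellow = cluster_yellow,
    color_jitter = color_jitter, noise_sd = noise_sd, seed = as.integer(seed)
  )
  if (cfg$count_range[1] > cfg$count_range[2] ||
      cfg$blob_radius_range[1] > cfg$blob_radius_range[2]) {
    abort("range minima must not exceed maxima", class = "rape_argument_error")
  }
  if (cfg$min_center_distance < 0 || occlusion_prob < 0 || occlusion_prob > 1) {
    abort("invalid min_center_distance or occlusion_prob",
          class = "rape_argument_error")
  }
  structure(cfg, class = "scene_config")
}

# rejection-sampled centre placement honouring min_center_distance; with
# probability occlusion_prob a centre is proposed near an existing one.
place_centers <- function(k, cfg, margin) {
  H <- cfg$height; W <- cfg$width
  dmin2 <- cfg$min_center_distance^2
  xs <- numeric(k); ys <- numeric(k)
  placed <- 0L
  budget <- 300L * k
  while (placed < k && budget > 0L) {
    budget <- budget - 1L
    if (placed > 0L && runif(1) < cfg$occlusion_prob) {
      j <- sample.int(placed, 1L)
      r <- cfg$min_center_distance + runif(1) * 2 * cfg$blob_radius_range[2]
      a <- runif(1) * 2 * pi
      x <- xs[j] + r * cos(a); y <- ys[j] + r * sin(a)
    } else {
      x <- runif(1, margin, W - 1 - margin)
      y <- runif(1, margin, H - 1 - margin)
    }
    if (x < margin || x > W - 1 - margin || y < margin || y > H - 1 - margin) next
    if (placed > 0L) {
      d2 <- (xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2
      if (min(d2) < dmin2) next
    }
    placed <- placed + 1L
    xs[placed] <- x; ys[placed] <- y
  }
  if (placed < k) {
    abort(sprintf(
      "could only place %d of %d centers; reduce the count or min_center_distance",
      placed, k), class = "rape_placement_error")
  }
  tibble::tibble(x = xs, y = ys)
}

#' Generate one synthetic field scene
#'
#' Draws `k ~ uniform(count_range)` soft-edged yellow elliptical blobs
#' (Gaussian intensity profiles with random eccentricity and orientation)
#' over a low-frequency textured green background, adds pixel noise, and
#' returns the blob centres as point annotations. Fully determined by the
#' seed. Overlapping blobs are *not* merged: `N` counts placed blobs, as a
#' human annotator would dot each cluster.
#'
#' @param cfg A [scene_config()].
#' @param seed Seed for this scene; defaults to `cfg$seed`.
#' @param count Fix the cluster count instead of sampling it.
#' @return A list of class `rape_scene`: `image` (`H x W x 3` array in
#'   `[0,1]`, 8-bit quantised), `points` (a [point_annotations()]), and
#'   `blobs`, a tibble with centres, semi-axes `rx`, `ry` and orientation
#'   `theta`.
#' @export
generate_scene <- function(cfg = scene_config(), seed = cfg$seed, count = NULL) {
  set.seed(seed)
  H <- cfg$height; W <- cfg$width
  k <- if (is.null(count)) {
    sample(seq(cfg$count_range[1], cfg$count_range[2]), 1L)
  } else {
    as.integer(count)
  }
  rmax <- cfg$blob_radius_range[2]
  centers <- place_centers(k, cfg, margin = min(rmax, (min(H, W) - 1) / 4))

  # textured background: coarse value noise upsampled bilinearly
  coarse_h <- max(2L, H %/% 32L); coarse_w <- max(2L, W %/% 32L)
  tex <- resize_matrix(matrix(runif(coarse_h * coarse_w, -1, 1), coarse_h, coarse_w),
                       H, W)
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    img[, , ch] <- cfg$background_green[ch] * (1 + 0.25 * tex) +
      rnorm(H * W, sd = cfg$noise_sd)
  }

  rr <- cfg$blob_radius_range
  blobs <- dplyr::mutate(centers,
    rx = runif(k, rr[1], rr[2]),
    ry = .data$rx * runif(k, 0.6, 1),
    theta = runif(k, 0, pi),
    jit = rnorm(k, sd = cfg$color_jitter)
  )

  # accumulate soft blob coverage; each blob is a Gaussian splat whose
  # intensity reaches ~exp(-2) at its nominal radius
  alpha <- matrix(0, H, W)
  tint <- matrix(0, H, W)
  px <- matrix(rep(0:(W - 1), each = H), H, W)
  py <- matrix(rep(0:(H - 1), W), H, W)
  for (i in seq_len(k)) {
    bx <- blobs$x[i]; by <- blobs$y[i]
    ext <- 2.2 * max(blobs$rx[i], blobs$ry[i])
    c0 <- max(1L, floor(bx - ext) + 1L); c1 <- min(W, ceiling(bx + ext) + 1L)
    r0 <- max(1L, floor(by - ext) + 1L); r1 <- min(H, ceiling(by + ext) + 1L)
    dx <- px[r0:r1, c0:c1] - bx
    dy <- py[r0:r1, c0:c1] - by
    ct <- cos(blobs$theta[i]); st <- sin(blobs$theta[i])
    u <- (dx * ct + dy * st) / blobs$rx[i]
    v <- (-dx * st + dy * ct) / blobs$ry[i]
    splat <- exp(-2 * (u^2 + v^2))
    alpha[r0:r1, c0:c1] <- alpha[r0:r1, c0:c1] + splat
    tint[r0:r1, c0:c1] <- tint[r0:r1, c0:c1] + splat * blobs$jit[i]
  }
  cover <- pmin(alpha, 1)
  for (ch in 1:3) {
    img[, , ch] <- (1 - cover) * img[, , ch] +
      cover * (cfg$cluster_yellow[ch] + tint / pmax(alpha, 1e-9))
  }
  img <- round(clamp01(img) * 255) / 255 # 8-bit grid, matching PNG output

  pts <- point_annotations(centers, image_id = sprintf("scene_%06d", seed),
                           image_width = W, image_height = H)
  structure(list(image = img, points = pts,
                 blobs = dplyr::select(blobs, -"jit"), config = cfg, seed = seed),
            class = "rape_scene")
}

#' Brightness/contrast augmentation in HSV space
#'
#' Converts to HSV, scales the value channel by `1 + brightness_factor`,
#' then stretches it about its mean by `1 + contrast_factor`, clips to the
#' valid range, and converts back to RGB on the 8-bit grid (so equality is
#' meaningful to within one intensity level). The +/-10% factors mimic
#' weather-driven exposure variation between flights.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param brightness_factor,contrast_factor Factors in `[-0.5, 0.5]`.
#' @return The augmented image.
#' @export
hsv_augment <- function(image, brightness_factor = 0, contrast_factor = 0) {
  if (abs(brightness_factor) > 0.5 || abs(contrast_factor) > 0.5) {
    abort("augmentation factors must lie in [-0.5, 0.5]",
          class = "rape_argument_error")
  }
  d <- dim(image)
  m <- matrix(image, d[1] * d[2], 3) * 255
  hsv <- farver::convert_colour(m, "rgb", "hsv")
  v <- hsv[, 3] * (1 + brightness_factor)
  v <- mean(v) + (v - mean(v)) * (1 + contrast_factor)
  hsv[, 3] <- pmin(pmax(v, 0), 1)
  rgb <- farver::convert_colour(hsv, "hsv", "rgb") / 255
  out <- array(pmin(pmax(rgb, 0), 1), d)
  round(out * 255) / 255
}

#' Generate a labelled synthetic dataset on disk
#'
#' Writes `n_images` scenes as PNGs plus annotations in the chosen dialect
#' - centroid CSVs (point labelling) or Pascal VOC XMLs with each blob's
#' bounding box (rectangular-box labelling) - and a manifest CSV with
#' header `image,annotation,count`. Deterministic given the seed: scene
#' `i` uses seed `cfg$seed + i`.
#'
#' @param cfg A [scene_config()].
#' @param n_images Number of scenes.
#' @param out_dir Output directory (created if needed).
#' @param label_style `"points"` or `"boxes"`.
#' @param augment_hsv Also write a +/-10% brightness/contrast pair per
#'   scene? (off by default; augmented copies share the original's
#'   annotations).
#' @return The manifest tibble (`image`, `annotation`, `count`), also
#'   written to `out_dir/manifest.csv`.
#' @export
generate_dataset <- function(cfg = scene_config(), n_images, out_dir,
                             label_style = c("points", "boxes"),
                             augment_hsv = FALSE) {
  label_style <- match.arg(label_style)
  if (!is_count(n_images)) abort("n_images must be a positive integer",
                                 class = "rape_argument_error")
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    abort(sprintf("cannot create output directory '%s'", out_dir),
          class = "rape_io_error")
  }
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    sc <- generate_scene(cfg, seed = cfg$seed + i)
    stem <- sprintf("scene_%04d", i)
    img_path <- file.path(out_dir, paste0(stem, ".png"))
    write_image(sc$image, img_path)
    if (label_style == "points") {
      ann_path <- file.path(out_dir, paste0(stem, ".csv"))
      write_points(sc$points, ann_path)
    } else {
      ann_path <- file.path(out_dir, paste0(stem, ".xml"))
      write_voc_boxes(blob_boxes(sc), ann_path,
                      image_width = cfg$width, image_height = cfg$height)
    }
    rows[[i]] <- tibble::tibble(image = img_path, annotation = ann_path,
                                count = nrow(sc$points))
    if (augment_hsv) {
      for (sgn in c(-0.1, 0.1)) {
        tag <- if (sgn > 0) "bright" else "dark"
        aug_path <- file.path(out_dir, sprintf("%s_%s.png", stem, tag))
        write_image(hsv_augment(sc$image, sgn, sgn), aug_path)
        rows[[i]] <- dplyr::bind_rows(rows[[i]], tibble::tibble(
          image = aug_path, annotation = ann_path, count = nrow(sc$points)))
      }
    }
  }
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

# axis-aligned bounding boxes of the rendered ellipses (at the ~exp(-2)
# intensity contour used as the blob's nominal extent)
blob_boxes <- function(scene) {
  b <- scene$blobs
  ct <- cos(b$theta); st <- sin(b$theta)
  hx <- sqrt((b$rx * ct)^2 + (b$ry * st)^2)
  hy <- sqrt((b$rx * st)^2 + (b$ry * ct)^2)
  W <- scene$config$width; H <- scene$config$height
  box_annotations(tibble::tibble(
    xmin = pmax(0, b$x - hx), ymin = pmax(0, b$y - hy),
    xmax = pmin(W - 1, b$x + hx), ymax = pmin(H - 1, b$y + hy)
  ), image_id = attr(scene$points, "image_id"))
}
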