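# Plot-level inference: resize to the 512x1024 working canvas, tile into
# 256x256 windows (a 2x4 grid -> 8 sub-images), predict a density map per
# tile, and aggregate counts.

#' Density map
#'
#' A non-negative `height x width` grid whose sum estimates the object
#' count; each cell covers `stride x stride` input pixels.
#'
#' @param values Numeric matrix, all entries `>= 0`.
#' @param stride Input pixels per cell.
#' @return A `density_map` (matrix with a `stride` attribute).
#' @export
density_map <- function(values, stride = 8L) {
  values <- as.matrix(values)
  if (any(values < 0) || any(!is.finite(values))) {
    abort("density values must be finite and non-negative",
          class = "rape_validation_error")
  }
  structure(values, class = c("density_map", "matrix", "array"),
            stride = as.integer(stride))
}

#' Predicted count of a density map
#'
#' @param D A [density_map()].
#' @return The sum of all cells.
#' @export
dm_count <- function(D) sum(unclass(D))

#' Resize an image to the working canvas
#'
#' Bilinear resampling to a fixed `512 x 1024` (height x width) canvas, the
#' resolution at which plot images are processed. Annotation points are
#' rescaled by the same per-axis factors, so the count `N` is unchanged.
#' Inputs whose long side is vertical are rotated 90 degrees first (with a
#' message), keeping the canvas landscape.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param points Optional [point_annotations()] in input-pixel coordinates.
#' @param height,width Canvas size in pixels.
#' @param auto_rotate Rotate portrait inputs to landscape first.
#' @return A list with `image` (the canvas) and `points` (rescaled, or
#'   `NULL`).
#' @export
resize_to_canvas <- function(image, points = NULL, height = 512L, width = 1024L,
                             auto_rotate = TRUE) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || any(d[1:2] == 0)) {
    abort("image must be a non-empty H x W x 3 array", class = "rape_argument_error")
  }
  if (auto_rotate && d[1] > d[2]) {
    inform("portrait input rotated 90 degrees to the landscape canvas")
    image <- aperm(image, c(2L, 1L, 3L))[d[2]:1, , , drop = FALSE]
    if (!is.null(points)) {
      points <- point_annotations(
        tibble::tibble(x = points$y, y = d[2] - 1 - points$x),
        image_id = attr(points, "image_id") %||% "")
    }
    d <- dim(image)
  }
  fx <- width / d[2]
  fy <- height / d[1]
  canvas <- resize_array(image, height, width)
  if (!is.null(points)) {
    points <- rescale_points(points, fx = fx, fy = fy,
                             image_width = width, image_height = height)
  }
  list(image = canvas, points = points)
}

#' Tile a canvas into non-overlapping windows
#'
#' Splits the canvas into a row-major grid of `tile_size x tile_size`
#' patches with recorded origins; a `512 x 1024` canvas with the default
#' 256-pixel window yields exactly 8 sub-images. The tiles partition the
#' canvas, so stitching them back is bit-exact.
#'
#' @param canvas `H x W x C` array with both sides divisible by
#'   `tile_size`.
#' @param tile_size Window side length in pixels.
#' @return A `tile_set` tibble with columns `tile`, `x0`, `y0` (0-based
#'   canvas origin of each patch) and a list-column `image`.
#' @export
tile_image <- function(canvas, tile_size = 256L) {
  d <- dim(canvas)
  if (d[1] %% tile_size != 0 || d[2] %% tile_size != 0) {
    abort(sprintf("canvas %dx%d not divisible by tile size %d",
                  d[1], d[2], tile_size), class = "rape_argument_error")
  }
  nr <- d[1] %/% tile_size
  nc <- d[2] %/% tile_size
  rows <- tidyr::expand_grid(ty = seq_len(nr) - 1L, tx = seq_len(nc) - 1L)
  tiles <- purrr::pmap(rows, function(ty, tx) {
    canvas[ty * tile_size + seq_len(tile_size),
           tx * tile_size + seq_len(tile_size), , drop = FALSE]
  })
  out <- tibble::tibble(
    tile = seq_len(nrow(rows)),
    x0 = rows$tx * tile_size, y0 = rows$ty * tile_size,
    image = tiles
  )
  structure(out, class = c("tile_set", class(out)),
            tile_size = as.integer(tile_size),
            canvas_height = d[1], canvas_width = d[2])
}

#' Reassemble tiles into a canvas
#'
#' @param tiles A `tile_set` from [tile_image()].
#' @return The stitched `H x W x C` array.
#' @export
stitch_tiles <- function(tiles) {
  ts <- attr(tiles, "tile_size")
  h <- attr(tiles, "canvas_height"); w <- attr(tiles, "canvas_width")
  nc3 <- dim(tiles$image[[1]])[3]
  out <- array(0, c(h, w, nc3))
  for (i in seq_len(nrow(tiles))) {
    out[tiles$y0[i] + seq_len(ts), tiles$x0[i] + seq_len(ts), ] <- tiles$image[[i]]
  }
  out
}

# assign annotation points to tiles by centroid location; returns a list of
# point_annotations in tile-local coordinates, one per tile row.
points_per_tile <- function(points, tiles) {
  ts <- attr(tiles, "tile_size")
  W <- attr(tiles, "canvas_width"); H <- attr(tiles, "canvas_height")
  # points sitting exactly on the right/bottom canvas edge belong to the
  # last tile of their row/column
  px <- pmin(points$x, W - 1e-9)
  py <- pmin(points$y, H - 1e-9)
  purrr::map(seq_len(nrow(tiles)), function(i) {
    x0 <- tiles$x0[i]; y0 <- tiles$y0[i]
    keep <- px >= x0 & px < x0 + ts & py >= y0 & py < y0 + ts
    point_annotations(tibble::tibble(x = pmin(px[keep] - x0, ts),
                                     y = pmin(py[keep] - y0, ts)),
                      image_id = attr(points, "image_id") %||% "",
                      image_width = ts, image_height = ts)
  })
}

#' Count flower clusters in a plot image
#'
#' The full inference pipeline: resize to the working canvas, tile into 8
#' windows, run the network on each tile in evaluation mode, assemble the
#' per-tile density maps into one canvas-scale map, and report the count as
#' the sum of the per-tile counts (identical tiles are disjoint, so the
#' total is exact by construction).
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param model A `rapenet` model.
#' @param tile_size Window side in pixels; must be divisible by the model's
#'   output stride.
#' @param canvas_height,canvas_width Working-canvas size.
#' @param resize Resize to the canvas first; set `FALSE` to run directly on
#'   an already tile-divisible image.
#' @return A list of class `count_prediction`: `count`, `density` (a
#'   canvas-scale [density_map()]), and `tiles`, a tibble of per-tile
#'   origins and counts.
#' @export
predict_count <- function(image, model, tile_size = 256L,
                          canvas_height = 512L, canvas_width = 1024L,
                          resize = TRUE) {
  st <- model$cfg$output_stride
  if (tile_size %% st != 0) {
    abort(sprintf("tile size %d not divisible by model output stride %d",
                  tile_size, st), class = "rape_config_error")
  }
  if (resize) image <- resize_to_canvas(image, height = canvas_height,
                                        width = canvas_width)$image
  d <- dim(image)
  tiles <- tile_image(image, tile_size = min(tile_size, d[1], d[2]))
  ts <- attr(tiles, "tile_size")
  g <- ts %/% st
  full <- matrix(0, d[1] %/% st, d[2] %/% st)
  counts <- numeric(nrow(tiles))
  for (i in seq_len(nrow(tiles))) {
    Dt <- predict_density(model, tiles$image[[i]])
    counts[i] <- dm_count(Dt)
    full[tiles$y0[i] %/% st + seq_len(g), tiles$x0[i] %/% st + seq_len(g)] <-
      unclass(Dt)
  }
  structure(list(count = sum(counts),
                 density = density_map(full, stride = st),
                 tiles = tibble::tibble(tile = tiles$tile, x0 = tiles$x0,
                                        y0 = tiles$y0, count = counts)),
            class = "count_prediction")
}

#' @export
print.count_prediction <- function(x, ...) {
  cat(sprintf("<count_prediction> %.2f clusters over %d tiles\n",
              x$count, nrow(x$tiles)))
  invisible(x)
}

#' Render a density heat map over an image
#'
#' Upsamples the density map to the image size, maps normalised density
#' through a sequential colour map (inferno), and alpha-blends it over the
#' image with per-pixel weight `alpha * density / max(density)` - so a zero
#' map leaves the image untouched and the density argmax receives the
#' strongest overlay.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param D A [density_map()].
#' @param alpha Maximum overlay opacity in `[0, 1]`.
#' @return The blended `H x W x 3` array.
#' @export
render_heatmap <- function(image, D, alpha = 0.6) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) {
    abort("alpha must lie in [0, 1]", class = "rape_argument_error")
  }
  d <- dim(image)
  m <- unclass(D)
  up <- resize_matrix(m, d[1], d[2])
  up <- pmax(up, 0)
  mx <- max(up)
  wgt <- if (mx > 0) alpha * up / mx else up * 0
  pal <- grDevices::hcl.colors(256L, "Inferno")
  idx <- pmin(255L, floor(255 * (if (mx > 0) up / mx else up))) + 1L
  cols <- grDevices::col2rgb(pal[idx]) / 255
  out <- image
  for (ch in 1:3) {
    cm <- matrix(cols[ch, ], d[1], d[2])
    out[, , ch] <- (1 - wgt) * image[, , ch] + wgt * cm
  }
  clamp01(out)
}

resize_matrix <- function(m, height, width) {
  if (nrow(m) == height && ncol(m) == width) return(m)
  t(as.array(EBImage::resize(EBImage::Image(t(m)), w = width, h = height)))
}

#' Write / read a density map as a float CSV grid
#'
#' The file starts with a comment line
#' `# density_map height=<h> width=<w> stride=<s>` followed by `h` rows of
#' `w` comma-separated floats (full precision, row-major).
#'
#' @param D A [density_map()].
#' @param path Output path.
#' @return `path` invisibly; `read_density_csv()` returns the
#'   [density_map()].
#' @export
write_density_csv <- function(D, path) {
  m <- unclass(D)
  hdr <- sprintf("# density_map height=%d width=%d stride=%d",
                 nrow(m), ncol(m), attr(D, "stride"))
  lines <- c(hdr, apply(m, 1, function(r) paste(format(r, digits = 17), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_density_csv
#' @export
read_density_csv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  get <- function(key) as.integer(sub(sprintf(".*%s=(\\d+).*", key), "\\1", hdr))
  h <- get("height"); w <- get("width"); s <- get("stride")
  vals <- do.call(rbind, lapply(lines[-1], function(l) as.numeric(strsplit(l, ",")[[1]])))
  stopifnot(nrow(vals) == h, ncol(vals) == w)
  density_map(vals, stride = s)
}

#' Write a density map as a 16-bit PNG
#'
#' Cell values are divided by `scale` and quantised to 16 bits, so the file
#' stores `round(65535 * value / scale)`; choose `scale >= max(D)` (default
#' exactly that) and record it to recover absolute densities.
#'
#' @param D A [density_map()].
#' @param path Output PNG path.
#' @param scale Value mapped to the maximum code; defaults to `max(D)` (or
#'   1 for an empty map).
#' @return The scale used, invisibly.
#' @export
write_density_png16 <- function(D, path, scale = NULL) {
  m <- unclass(D)
  if (is.null(scale)) scale <- if (max(m) > 0) max(m) else 1
  codes <- round(65535 * clamp01(m / scale))
  write_png16_gray(codes, path)
  invisible(scale)
}

# Minimal 16-bit greyscale PNG writer (no installed package emits 16-bit
# PNG). Scanlines use filter 0; the IDAT payload is a zlib stream from
# memCompress. Round-trips exactly through png::readPNG.
write_png16_gray <- function(codes, path) {
  h <- nrow(codes); w <- ncol(codes)
  be <- function(x, n) as.raw(rev((x %/% 256^(0:(n - 1))) %% 256))
  hi <- as.raw(codes %/% 256L)
  lo <- as.raw(codes %% 256L)
  scan <- raw(h * (1L + 2L * w))
  for (r in seq_len(h)) {
    off <- (r - 1L) * (1L + 2L * w)
    scan[off + 1L] <- as.raw(0L)
    inter <- raw(2L * w)
    inter[seq(1L, 2L * w, by = 2L)] <- hi[r + h * (seq_len(w) - 1L)]
    inter[seq(2L, 2L * w, by = 2L)] <- lo[r + h * (seq_len(w) - 1L)]
    scan[off + 1L + seq_len(2L * w)] <- inter
  }
  chunk <- function(type, data) {
    body <- c(charToRaw(type), data)
    c(be(length(data), 4L), body, be(crc32(body), 4L))
  }
  ihdr <- c(be(w, 4L), be(h, 4L), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  idat <- memCompress(scan, type = "gzip") # zlib-wrapped deflate
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           chunk("IHDR", ihdr), chunk("IDAT", idat), chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- 4294967295 # 0xFFFFFFFF as double; bit ops done in two halves
  v <- as.integer(bytes)
  for (b in v) {
    idx <- bitwAnd(bitwXor(as.integer(crc %% 256), b), 255L) + 1L
    crc <- floor(crc / 256) %% 16777216 # >> 8 on a 32-bit value held as double
    crc <- bitwXor_dbl(crc, tab[idx])
  }
  bitwXor_dbl(crc, 4294967295)
}

# xor of two non-negative doubles < 2^32 (R's bitwXor is 32-bit signed only)
bitwXor_dbl <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  hi * 65536 + lo
}

crc32_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    t <- numeric(256)
    for (n in 0:255) {
      c <- n
      for (k in 1:8) {
        odd <- c %% 2 == 1
        c <- floor(c / 2)
        if (odd) c <- bitwXor_dbl(c, 3988292384) # 0xEDB88320
      }
      t[n + 1] <- c
    }
    tab <<- t
    tab
  }
})
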