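# Images are numeric arrays dim c(height, width, 3), values in [0, 1],
# row = y (downward), column = x (rightward), 0-based pixel (0,0) at top-left.
# EBImage stores (x, y, channel), so conversion is a transpose of the first
# two dimensions.

as_ebimage <- function(img) {
  EBImage::Image(aperm(img, c(2L, 1L, 3L)), colormode = "Color")
}

from_ebimage <- function(eb) {
  a <- aperm(as.array(eb), c(2L, 1L, 3L))
  unname(a)
}

#' Read an RGB image
#'
#' Reads a PNG or JPEG file into the array convention used throughout the
#' package: `dim = c(height, width, 3)` with intensities in `[0, 1]`.
#'
#' @param path Path to a PNG or JPEG file.
#' @return A numeric `height x width x 3` array.
#' @export
read_image <- function(path) {
  eb <- EBImage::readImage(path)
  a <- as.array(eb)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE] # drop alpha
  from_ebimage(a)
}

#' Write an RGB image
#'
#' @param img A `height x width x 3` array in `[0, 1]`.
#' @param path Output path; format chosen from the extension (PNG or JPEG).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  EBImage::writeImage(as_ebimage(clamp01(img)), path)
  invisible(path)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# channel concatenation for feature arrays (H x W x C)
cbind_channels <- function(lst) {
  dims <- dim(lst[[1]])
  ctot <- sum(vapply(lst, function(a) dim(a)[3], integer(1)))
  out <- array(0, c(dims[1], dims[2], ctot))
  at <- 0L
  for (a in lst) {
    nc <- dim(a)[3]
    out[, , at + seq_len(nc)] <- a
    at <- at + nc
  }
  out
}

# bilinear resize of an H x W x C array via EBImage
resize_array <- function(img, height, width) {
  d <- dim(img)
  if (d[1] == height && d[2] == width) return(img)
  from_ebimage(EBImage::resize(as_ebimage(img), w = width, h = height))
}

# evaluate `expr` without disturbing the caller's RNG stream
with_preserved_seed <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(expr)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == floor(x)
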