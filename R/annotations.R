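#' Point (centroid) annotations
#'
#' Constructs the package's representation of centroid labels: one `(x, y)`
#' pixel coordinate per flower cluster. Coordinates are real-valued, 0-based,
#' origin at the image's top-left corner, `x` rightward (column) and `y`
#' downward (row). The cluster count `N` is simply the number of rows.
#'
#' @param points A data frame (or matrix) with columns `x` and `y`, or `NULL`
#'   for an empty set.
#' @param image_id Identifier of the annotated image.
#' @param image_width,image_height Optional image bounds in pixels; when
#'   known they are carried along and used to clamp rescaled points.
#' @return A tibble of class `point_annotations` with columns `x`, `y` and
#'   attributes `image_id`, `image_width`, `image_height`.
#' @seealso [read_points()], [boxes_to_centroids()], [rescale_points()]
#' @export
point_annotations <- function(points = NULL, image_id = "",
                              image_width = NULL, image_height = NULL) {
  if (is.null(points)) points <- tibble::tibble(x = double(), y = double())
  points <- tibble::as_tibble(as.data.frame(points))
  if (!all(c("x", "y") %in% names(points))) {
    abort("point annotations need `x` and `y` columns", class = "rape_parse_error")
  }
  points <- tibble::tibble(x = as.double(points$x), y = as.double(points$y))
  if (nrow(points) > 0 && (any(!is.finite(points$x)) || any(!is.finite(points$y)))) {
    abort("point coordinates must be finite", class = "rape_parse_error")
  }
  if (nrow(points) > 0 && (any(points$x < 0) || any(points$y < 0))) {
    abort("point coordinates must be non-negative", class = "rape_validation_error")
  }
  structure(points,
    class = c("point_annotations", class(points)),
    image_id = image_id,
    image_width = image_width, image_height = image_height
  )
}

#' Number of annotated points
#'
#' @param p A [point_annotations()] set.
#' @return Integer count `N`.
#' @export
n_points <- function(p) nrow(p)

#' Rectangular-box annotations
#'
#' Boxes follow the LabelImg convention: `(xmin, ymin, xmax, ymax)` in
#' pixels, origin top-left, closed intervals, `xmin <= xmax`,
#' `ymin <= ymax`, all coordinates non-negative.
#'
#' @param boxes A data frame with columns `xmin`, `ymin`, `xmax`, `ymax`,
#'   or `NULL` for an empty set.
#' @param image_id Identifier of the annotated image.
#' @return A tibble of class `box_annotations`.
#' @export
box_annotations <- function(boxes = NULL, image_id = "") {
  if (is.null(boxes)) {
    boxes <- tibble::tibble(xmin = double(), ymin = double(),
                            xmax = double(), ymax = double())
  }
  boxes <- tibble::as_tibble(as.data.frame(boxes))
  need <- c("xmin", "ymin", "xmax", "ymax")
  if (!all(need %in% names(boxes))) {
    abort("box annotations need xmin, ymin, xmax, ymax columns",
          class = "rape_parse_error")
  }
  boxes <- tibble::as_tibble(lapply(boxes[need], as.double))
  bad <- which(boxes$xmin > boxes$xmax | boxes$ymin > boxes$ymax)
  if (length(bad) > 0) {
    abort(sprintf("box %d has xmin > xmax or ymin > ymax", bad[1]),
          class = "rape_validation_error")
  }
  if (nrow(boxes) > 0 && any(unlist(boxes) < 0)) {
    abort("box coordinates must be non-negative", class = "rape_validation_error")
  }
  structure(boxes, class = c("box_annotations", class(boxes)),
            image_id = image_id)
}

#' Read rectangular-box labels from a Pascal VOC XML file
#'
#' Parses the LabelImg dialect of Pascal VOC: one `<object>` per box with a
#' `<bndbox>` holding `xmin`, `ymin`, `xmax`, `ymax`. Boxes are returned in
#' document order.
#'
#' @param path Path to the XML annotation file.
#' @return A [box_annotations()] tibble; the `image_id` attribute is taken
#'   from the document's `<filename>` element when present.
#' @export
read_voc_boxes <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(sprintf("malformed VOC XML '%s': %s", path, conditionMessage(e)),
          class = "rape_parse_error")
  })
  fname <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
  if (is.na(fname)) fname <- basename(path)
  nodes <- xml2::xml_find_all(doc, ".//object/bndbox")
  get_num <- function(node, tag) {
    v <- xml2::xml_text(xml2::xml_find_first(node, paste0("./", tag)))
    if (is.na(v)) abort(sprintf("bndbox missing <%s> in '%s'", tag, path),
                        class = "rape_parse_error")
    as.numeric(v)
  }
  boxes <- purrr::map_dfr(nodes, function(nd) {
    tibble::tibble(xmin = get_num(nd, "xmin"), ymin = get_num(nd, "ymin"),
                   xmax = get_num(nd, "xmax"), ymax = get_num(nd, "ymax"))
  })
  box_annotations(boxes, image_id = fname)
}

#' Write rectangular-box labels as Pascal VOC XML
#'
#' @param b A [box_annotations()] set.
#' @param path Output XML path.
#' @param image_width,image_height Optional `<size>` fields.
#' @return `path`, invisibly.
#' @export
write_voc_boxes <- function(b, path, image_width = NULL, image_height = NULL) {
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", attr(b, "image_id") %||% "")
  if (!is.null(image_width)) {
    sz <- xml2::xml_add_child(doc, "size")
    xml2::xml_add_child(sz, "width", as.character(image_width))
    xml2::xml_add_child(sz, "height", as.character(image_height))
    xml2::xml_add_child(sz, "depth", "3")
  }
  for (i in seq_len(nrow(b))) {
    ob <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(ob, "name", "flower_cluster")
    bb <- xml2::xml_add_child(ob, "bndbox")
    xml2::xml_add_child(bb, "xmin", format(b$xmin[i], scientific = FALSE))
    xml2::xml_add_child(bb, "ymin", format(b$ymin[i], scientific = FALSE))
    xml2::xml_add_child(bb, "xmax", format(b$xmax[i], scientific = FALSE))
    xml2::xml_add_child(bb, "ymax", format(b$ymax[i], scientific = FALSE))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read centroid labels from CSV or JSON
#'
#' Two dialects are accepted: a two-column CSV with header `x,y`, and a JSON
#' file whose top level is an array of `{"x": ..., "y": ...}` objects. An
#' empty record list is valid and yields `N = 0`.
#'
#' @param path Path to a `.csv` or `.json` file.
#' @param image_id Identifier to attach; defaults to the file name.
#' @return A [point_annotations()] tibble.
#' @export
read_points <- function(path, image_id = basename(path)) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    # base read.csv: strtod parsing is correctly rounded, so the CSV dialect
    # round-trips doubles exactly
    df <- tryCatch(
      utils::read.csv(path, colClasses = "numeric"),
      error = function(e) abort(sprintf("cannot parse point CSV '%s'", path),
                                class = "rape_parse_error")
    )
  } else if (ext == "json") {
    rec <- tryCatch(jsonlite::fromJSON(path), error = function(e) {
      abort(sprintf("cannot parse point JSON '%s'", path), class = "rape_parse_error")
    })
    if (length(rec) == 0) rec <- data.frame(x = double(), y = double())
    df <- as.data.frame(rec)
  } else {
    abort(sprintf("unsupported point-annotation extension '%s'", ext),
          class = "rape_parse_error")
  }
  if (!all(c("x", "y") %in% names(df))) {
    abort(sprintf("'%s' lacks x/y fields", path), class = "rape_parse_error")
  }
  point_annotations(df[, c("x", "y")], image_id = image_id)
}

#' Write centroid labels to CSV or JSON
#'
#' The CSV dialect round-trips coordinates exactly (full double precision).
#'
#' @param p A [point_annotations()] set.
#' @param path Output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_points <- function(p, path) {
  ext <- tolower(tools::file_ext(path))
  df <- tibble::tibble(x = p$x, y = p$y)
  if (ext == "csv") {
    # %.17g guarantees an exact double round trip through the text dialect
    readr::write_csv(tibble::tibble(x = sprintf("%.17g", df$x),
                                    y = sprintf("%.17g", df$y)), path)
  } else if (ext == "json") {
    jsonlite::write_json(df, path, digits = NA, dataframe = "rows")
  } else {
    abort(sprintf("unsupported point-annotation extension '%s'", ext),
          class = "rape_parse_error")
  }
  invisible(path)
}

#' Convert boxes to centroid points
#'
#' Each rectangular box is reduced to its center
#' `((xmin + xmax) / 2, (ymin + ymax) / 2)`; the point count equals the box
#' count, so degenerate (zero-width or zero-height) boxes still contribute
#' one centroid.
#'
#' @param b A [box_annotations()] set.
#' @param image_width,image_height Optional bounds carried to the result.
#' @return A [point_annotations()] set with one point per box.
#' @export
boxes_to_centroids <- function(b, image_width = NULL, image_height = NULL) {
  point_annotations(
    tibble::tibble(x = (b$xmin + b$xmax) / 2, y = (b$ymin + b$ymax) / 2),
    image_id = attr(b, "image_id") %||% "",
    image_width = image_width, image_height = image_height
  )
}

#' Rescale centroid points
#'
#' Multiplies coordinates by per-axis factors, e.g. when an image is resized.
#' `N` is never changed; if image bounds are supplied (or carried on the
#' input) any point pushed outside them is clamped to the boundary with a
#' warning, so resizing cannot silently drop annotations.
#'
#' @param p A [point_annotations()] set.
#' @param fx,fy Positive scale factors for x and y.
#' @param image_width,image_height Bounds of the *target* image in pixels;
#'   default rescales any bounds carried on `p`.
#' @return A rescaled [point_annotations()] set.
#' @export
rescale_points <- function(p, fx, fy = fx, image_width = NULL, image_height = NULL) {
  if (!is.numeric(fx) || !is.numeric(fy) || fx <= 0 || fy <= 0) {
    abort("scale factors must be positive", class = "rape_argument_error")
  }
  w0 <- attr(p, "image_width"); h0 <- attr(p, "image_height")
  if (is.null(image_width) && !is.null(w0)) image_width <- w0 * fx
  if (is.null(image_height) && !is.null(h0)) image_height <- h0 * fy
  x <- p$x * fx
  y <- p$y * fy
  if (!is.null(image_width) && !is.null(image_height) && nrow(p) > 0) {
    out <- x < 0 | x > image_width | y < 0 | y > image_height
    if (any(out)) {
      warn(sprintf("%d point(s) clamped to image bounds after rescale", sum(out)))
      x <- pmin(pmax(x, 0), image_width)
      y <- pmin(pmax(y, 0), image_height)
    }
  }
  point_annotations(tibble::tibble(x = x, y = y),
                    image_id = attr(p, "image_id") %||% "",
                    image_width = image_width, image_height = image_height)
}
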