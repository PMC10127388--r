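#' Paired manual/inferred counts for evaluation
#'
#' @param data A data frame with one row per image.
#' @param manual,inferred,image_id Tidy-select style column names (bare or
#'   character) holding the manual count, the inferred count, and an image
#'   identifier (optional).
#' @return A tibble of class `evaluation_set` with columns `image_id`,
#'   `manual`, `inferred`.
#' @export
evaluation_set <- function(data, manual = "manual", inferred = "inferred",
                           image_id = NULL) {
  data <- tibble::as_tibble(data)
  mq <- rlang::enquo(manual); iq <- rlang::enquo(inferred)
  m <- dplyr::pull(data, !!mq)
  i <- dplyr::pull(data, !!iq)
  id <- if (rlang::quo_is_null(rlang::enquo(image_id))) {
    if ("image_id" %in% names(data)) data$image_id else as.character(seq_along(m))
  } else {
    as.character(dplyr::pull(data, !!rlang::enquo(image_id)))
  }
  if (length(m) < 1) abort("evaluation set needs at least one item",
                           class = "rape_argument_error")
  if (any(!is.finite(m)) || any(!is.finite(i)) || any(m < 0) || any(i < 0)) {
    abort("counts must be finite and non-negative", class = "rape_validation_error")
  }
  out <- tibble::tibble(image_id = id, manual = as.double(m),
                        inferred = as.double(i))
  structure(out, class = c("evaluation_set", class(out)))
}

#' Count-accuracy metrics
#'
#' Computes the seven regression-counting statistics over paired manual
#' (`M_i`) and inferred (`I_i`) counts:
#' \describe{
#'   \item{Acc}{`1 - mean(|M - I| / M)` (reported as a fraction; images
#'     with `M = 0` are excluded from this average with a warning).}
#'   \item{MAE}{`mean(|M - I|)`.}
#'   \item{rMAE}{`sqrt(MAE)`.}
#'   \item{rMSE}{`sqrt(mean((M - I)^2))`.}
#'   \item{rrMSE}{`100 * rMSE / mean(M)`, a percentage of the mean manual
#'     count.}
#'   \item{R2}{`1 - sum((M - I)^2) / sum((I - mean(I))^2)` - note the
#'     *inferred*-count spread in the denominator, kept as defined for this
#'     metric family; `r2_denominator = "manual"` switches to the
#'     conventional `sum((M - mean(M))^2)`.}
#' }
#'
#' @param ev An [evaluation_set()] (or data frame with `manual` and
#'   `inferred` columns).
#' @param r2_denominator Spread used in the R2 denominator.
#' @param round_counts Round inferred counts to the nearest integer before
#'   computing (counts are otherwise kept as real density sums).
#' @return An object of class `count_metrics` with fields `acc`, `mae`,
#'   `rmae`, `rmse`, `rrmse`, `r2`, `n`. R2 is `NA` (with a warning) when
#'   its denominator is zero.
#' @export
evaluate_counts <- function(ev, r2_denominator = c("inferred", "manual"),
                            round_counts = FALSE) {
  r2_denominator <- match.arg(r2_denominator)
  if (!inherits(ev, "evaluation_set")) ev <- evaluation_set(ev)
  m <- ev$manual
  i <- ev$inferred
  if (round_counts) i <- round(i)
  n <- length(m)
  err <- m - i
  mae <- mean(abs(err))
  rmse <- sqrt(mean(err^2))
  mbar <- mean(m)
  ibar <- mean(i)
  pos <- m > 0
  if (!all(pos)) warn(sprintf("%d item(s) with manual count 0 excluded from Acc",
                              sum(!pos)))
  acc <- if (any(pos)) 1 - mean(abs(err[pos]) / m[pos]) else NA_real_
  if (mbar == 0) abort("rrMSE undefined: mean manual count is zero",
                       class = "rape_argument_error")
  rrmse <- 100 * rmse / mbar
  den <- if (r2_denominator == "inferred") sum((i - ibar)^2) else sum((m - mbar)^2)
  if (den == 0) {
    warn("R2 undefined: zero spread in the denominator; reported as NA")
    r2 <- NA_real_
  } else {
    r2 <- 1 - sum(err^2) / den
  }
  structure(list(acc = acc, mae = mae, rmae = sqrt(mae), rmse = rmse,
                 rrmse = rrmse, r2 = r2, n = n,
                 r2_denominator = r2_denominator),
            class = "count_metrics")
}

#' @export
print.count_metrics <- function(x, ...) {
  cat(sprintf(
    "<count_metrics> n = %d\n  Acc %.4f | MAE %.3f | rMAE %.3f | rMSE %.3f | rrMSE %.2f%% | R2 (%s) %.4f\n",
    x$n, x$acc, x$mae, x$rmae, x$rmse, x$rrmse, x$r2_denominator, x$r2))
  invisible(x)
}

#' @export
tidy.count_metrics <- function(x, ...) {
  tibble::tibble(
    metric = c("acc", "mae", "rmae", "rmse", "rrmse", "r2"),
    value = c(x$acc, x$mae, x$rmae, x$rmse, x$rrmse, x$r2)
  )
}

#' @export
glance.count_metrics <- function(x, ...) {
  tibble::tibble(acc = x$acc, mae = x$mae, rmae = x$rmae, rmse = x$rmse,
                 rrmse = x$rrmse, r2 = x$r2, n = x$n)
}

#' Write an evaluation report
#'
#' One CSV row per image (`image_id`, `manual`, `inferred`, absolute and
#' relative error) plus a `summary` row, and optionally the metrics as a
#' JSON object.
#'
#' @param ev An [evaluation_set()].
#' @param path CSV output path.
#' @param json_path Optional JSON output path for the metric summary.
#' @param ... Passed to [evaluate_counts()].
#' @return The [evaluate_counts()] result, invisibly.
#' @export
write_count_report <- function(ev, path, json_path = NULL, ...) {
  cm <- evaluate_counts(ev, ...)
  per <- dplyr::mutate(tibble::as_tibble(ev),
                       abs_error = abs(.data$manual - .data$inferred),
                       rel_error = ifelse(.data$manual > 0,
                                          .data$abs_error / .data$manual, NA_real_))
  summary_row <- tibble::tibble(
    image_id = "summary", manual = mean(ev$manual), inferred = mean(ev$inferred),
    abs_error = cm$mae, rel_error = 1 - cm$acc)
  readr::write_csv(dplyr::bind_rows(per, summary_row), path)
  if (!is.null(json_path)) {
    jsonlite::write_json(as.list(glance(cm)), json_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(cm)
}
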