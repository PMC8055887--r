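#' Point-annotation sets
#'
#' A point-annotation set records the expert-labeled cell centers of one
#' microscopy tile: integer pixel coordinates (0-based, `x` = column,
#' `y` = row) plus a class index in `{0, 1, 2}` (see [cell_classes()]).
#' The same container holds predicted cell centers ([detection_set()]), so
#' ground truth and predictions are interchangeable for evaluation.
#'
#' @param points Data frame (or tibble) with integer columns `x`, `y`,
#'   `class`. A zero-row data frame gives an empty set.
#' @param image_id Non-empty string identifying the tile.
#' @param width,height Image dimensions in pixels.
#' @param patient_id Optional string grouping tiles by patient.
#'
#' @return An `annotation_set`: a list with fields `image_id`, `width`,
#'   `height`, `patient_id` and `points` (a tibble).
#' @examples
#' a <- annotation_set(data.frame(x = 10L, y = 20L, class = 2L),
#'                     image_id = "t1", width = 64, height = 64)
#' class_counts(a)
#' @export
annotation_set <- function(points, image_id, width, height, patient_id = NULL) {
  if (!is.character(image_id) || length(image_id) != 1L || !nzchar(image_id))
    abort("`image_id` must be a non-empty string")
  width <- as.integer(width); height <- as.integer(height)
  if (is.na(width) || is.na(height) || width < 1L || height < 1L)
    abort("`width` and `height` must be positive integers")
  pts <- as_tibble(points)
  if (nrow(pts) == 0L)
    pts <- tibble(x = integer(), y = integer(), class = integer())
  if (!all(c("x", "y", "class") %in% names(pts)))
    abort("`points` must have columns x, y, class")
  pts <- tibble(x = as.integer(pts$x), y = as.integer(pts$y),
                class = as.integer(pts$class))
  validate_points(pts, width, height)
  structure(
    list(image_id = image_id, width = width, height = height,
         patient_id = if (is.null(patient_id) || is.na(patient_id)) NULL
                      else as.character(patient_id),
         points = pts),
    class = "annotation_set")
}

validate_points <- function(pts, width, height) {
  if (anyNA(pts)) abort("annotation points contain missing values")
  bad <- which(pts$x < 0L | pts$x >= width | pts$y < 0L | pts$y >= height)
  if (length(bad))
    abort(sprintf("point %d (x=%d, y=%d) lies outside the %dx%d image",
                  bad[1], pts$x[bad[1]], pts$y[bad[1]], width, height))
  badc <- which(!(pts$class %in% 0:2))
  if (length(badc))
    abort(sprintf("point %d has unknown class %s (must be 0, 1 or 2)",
                  badc[1], pts$class[badc[1]]))
  invisible(pts)
}

#' Predicted cell centers
#'
#' Same container as [annotation_set()] but tagged as model output; produced
#' by [extract_centers()] and [run_pipeline()].
#'
#' @inheritParams annotation_set
#' @return A `detection_set`, which is also an `annotation_set`.
#' @export
detection_set <- function(points, image_id, width, height, patient_id = NULL) {
  s <- annotation_set(points, image_id, width, height, patient_id)
  class(s) <- c("detection_set", class(s))
  s
}

#' @export
print.annotation_set <- function(x, ...) {
  kind <- if (inherits(x, "detection_set")) "detection_set" else "annotation_set"
  cat(sprintf("<%s> image '%s' (%dx%d)%s, %d points\n", kind, x$image_id,
              x$width, x$height,
              if (is.null(x$patient_id)) "" else paste0(", patient ", x$patient_id),
              nrow(x$points)))
  cc <- class_counts(x)
  cat(sprintf("  %s: %d\n", names(cc), cc), sep = "")
  invisible(x)
}

#' @export
as_tibble.annotation_set <- function(x, ...) {
  pts <- x$points
  pts$class_name <- CLASS_NAMES[pts$class + 1L]
  pts$image_id <- x$image_id
  pts$patient_id <- if (is.null(x$patient_id)) NA_character_ else x$patient_id
  pts
}

#' Count annotated cells per class
#'
#' @param set An [annotation_set()] or [detection_set()].
#' @return Named integer vector of length 3 (immunopositive, immunonegative,
#'   lymphocyte); the values sum to the number of points.
#' @export
class_counts <- function(set) {
  stopifnot(inherits(set, "annotation_set"))
  counts <- tabulate(set$points$class + 1L, nbins = 3L)
  setNames(as.integer(counts), CLASS_NAMES)
}

#' Read point annotations from JSON or CSV
#'
#' JSON files carry the full schema
#' `{"image_id", "width", "height", "patient_id", "points": [{"x","y","class"}]}`.
#' CSV files hold one image per file with header `x,y,class`; the image
#' dimensions and id are then supplied by the caller (or taken from the file
#' name and a paired image).
#'
#' @param path File to read.
#' @param format `"json"` or `"csv"` (default: from the file extension).
#' @param image_id,width,height,patient_id Metadata for the CSV format
#'   (ignored for JSON, which stores them in the file).
#' @return An [annotation_set()] (a [detection_set()] if the JSON was written
#'   from one).
#' @export
load_annotations <- function(path, format = c("auto", "json", "csv"),
                             image_id = NULL, width = NULL, height = NULL,
                             patient_id = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  if (format == "json") {
    obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                    error = function(e)
                      abort(sprintf("malformed JSON in %s: %s", path,
                                    conditionMessage(e))))
    req <- c("image_id", "width", "height", "points")
    miss <- setdiff(req, names(obj))
    if (length(miss))
      abort(sprintf("%s: missing field(s) %s", path,
                    paste(miss, collapse = ", ")))
    pts <- obj$points
    if (length(pts) == 0L || (is.data.frame(pts) && nrow(pts) == 0L))
      pts <- tibble(x = integer(), y = integer(), class = integer())
    set <- annotation_set(pts, obj$image_id, obj$width, obj$height,
                          obj$patient_id)
    if (isTRUE(obj$detections)) class(set) <- c("detection_set", class(set))
    set
  } else {
    df <- tryCatch(utils::read.csv(path, colClasses = "integer"),
                   error = function(e)
                     abort(sprintf("malformed CSV in %s: %s", path,
                                   conditionMessage(e))))
    if (!all(c("x", "y", "class") %in% names(df)))
      abort(sprintf("%s: CSV header must be x,y,class", path))
    if (is.null(image_id))
      image_id <- sub("\\.csv$", "", basename(path), ignore.case = TRUE)
    if (is.null(width) || is.null(height))
      abort("CSV annotations need `width` and `height` from the paired image")
    annotation_set(df, image_id, width, height, patient_id)
  }
}

#' Write point annotations to JSON or CSV
#'
#' Saving and re-loading is the identity on valid sets (coordinates are
#' integers, so the round trip is bit-exact).
#'
#' @param set An [annotation_set()] or [detection_set()].
#' @param path Output file.
#' @param format `"json"` or `"csv"` (default: from the file extension).
#' @return `path`, invisibly.
#' @export
save_annotations <- function(set, path, format = c("auto", "json", "csv")) {
  stopifnot(inherits(set, "annotation_set"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  if (format == "json") {
    obj <- list(image_id = set$image_id, width = set$width,
                height = set$height,
                patient_id = set$patient_id,
                points = set$points)
    if (inherits(set, "detection_set")) obj$detections <- TRUE
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null", dataframe = "rows")
  } else {
    utils::write.csv(set$points, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
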