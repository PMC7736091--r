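## Annotation JSON and measurement/label CSV input-output.
##
## Annotation schema (one radiograph per file):
## {
##   "image_id": "...",
##   "pixel_spacing": 0.143,            # optional, mm/pixel, display only
##   "hips": [
##     {"side": "right",
##      "acetabular_arc": [[x, y], ...],
##      "femoral_arc":    [[x, y], ...],
##      "sourcil_medial":    [x, y],
##      "teardrop_inferior": [x, y]},
##     {"side": "left", ...}
##   ]
## }
## Coordinates are pixels in image convention (origin top-left, y down)
## and are preserved to full double precision on a write/read round trip.

.requireField <- function(x, field, where) {
  if (is.null(x[[field]]))
    schemaError(sprintf("missing required field '%s' in %s", field, where))
  x[[field]]
}

.asPoint <- function(x, field) {
  p <- suppressWarnings(as.numeric(unlist(x)))
  if (length(p) != 2L || any(!is.finite(p)))
    schemaError(sprintf("field '%s' must be a finite [x, y] pair", field))
  p
}

.asArc <- function(x, field) {
  rows <- lapply(x, function(r) {
    p <- suppressWarnings(as.numeric(unlist(r)))
    if (length(p) != 2L || any(!is.finite(p)))
      schemaError(sprintf("field '%s' must be a list of finite [x, y] pairs", field))
    p
  })
  do.call(rbind, rows)
}

.parseHip <- function(h, where) {
  side <- .requireField(h, "side", where)
  if (!is.character(side) || length(side) != 1L || !side %in% .SIDES)
    schemaError(sprintf("unknown side token '%s' in %s", as.character(side)[1L], where))
  aArc <- .asArc(.requireField(h, "acetabular_arc", where), "acetabular_arc")
  fArc <- .asArc(.requireField(h, "femoral_arc", where), "femoral_arc")
  sm <- .asPoint(.requireField(h, "sourcil_medial", where), "sourcil_medial")
  td <- .asPoint(.requireField(h, "teardrop_inferior", where), "teardrop_inferior")
  hipAnnotation(side,
    contourTrace(aArc, "acetabular_arc", side),
    contourTrace(fArc, "femoral_arc", side),
    sm, td)
}

#' Read a pelvis annotation file
#'
#' Parses the documented JSON schema into a [PelvisAnnotation-class],
#' preserving point order and full coordinate precision. Schema violations
#' raise an error naming the offending field.
#'
#' @param path path to an annotation JSON file.
#' @return A [PelvisAnnotation-class].
#' @seealso [writeAnnotation()]
#' @export
readAnnotation <- function(path) {
  if (!file.exists(path)) inputError(sprintf("no such file: %s", path))
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  imageId <- .requireField(x, "image_id", path)
  hips <- .requireField(x, "hips", path)
  if (length(hips) != 2L)
    schemaError(sprintf("expected exactly 2 hips in %s, found %d", path, length(hips)))
  parsed <- lapply(hips, .parseHip, where = path)
  sides <- vapply(parsed, function(h) h@side, character(1))
  if (!setequal(sides, .SIDES))
    schemaError(sprintf("need one 'left' and one 'right' hip in %s", path))
  ps <- x[["pixel_spacing"]]
  pelvisAnnotation(imageId,
    left = parsed[[which(sides == "left")]],
    right = parsed[[which(sides == "right")]],
    pixelSpacing = if (is.null(ps)) NA_real_ else as.numeric(ps))
}

.hipToList <- function(h) {
  list(side = h@side,
    acetabular_arc = unname(h@acetabularArc@points),
    femoral_arc = unname(h@femoralArc@points),
    sourcil_medial = h@sourcilMedial,
    teardrop_inferior = h@teardropInferior)
}

#' Write a pelvis annotation file
#'
#' Serialises a [PelvisAnnotation-class] to the documented JSON schema.
#' `readAnnotation(writeAnnotation(ann, path))` reproduces `ann` exactly
#' (text fields bit-identical, coordinates to full double precision).
#'
#' @param ann a valid [PelvisAnnotation-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnnotation <- function(ann, path) {
  stopifnot(is(ann, "PelvisAnnotation"))
  validObject(ann)
  x <- list(image_id = ann@imageId)
  if (!is.na(ann@pixelSpacing)) x$pixel_spacing <- ann@pixelSpacing
  x$hips <- list(.hipToList(ann@right), .hipToList(ann@left))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Measurement CSV column order
#'
#' One row per hip: `image_id`, `side`, `tonnis_deg`, `sharp_deg`,
#' `ce_deg`, `head_cx`, `head_cy`, `head_r`. Angles in degrees (Toennis
#' and CE signed), head centre/radius in pixels.
#' @export
measurementColumns <- function() {
  c("image_id", "side", "tonnis_deg", "sharp_deg", "ce_deg",
    "head_cx", "head_cy", "head_r")
}

#' Write / read measurement records
#'
#' Measurements are stored as UTF-8 CSV with the column order of
#' [measurementColumns()]; numeric values survive a round trip to full
#' double precision.
#'
#' @param records a nonempty data.frame containing the measurement
#'   columns.
#' @param path file path.
#' @return `writeMeasurements()` returns `path` invisibly;
#'   `readMeasurements()` returns a data.frame.
#' @export
writeMeasurements <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    inputError("'records' must be a nonempty data.frame")
  missing <- setdiff(measurementColumns(), names(records))
  if (length(missing))
    inputError(sprintf("missing measurement columns: %s",
      paste(missing, collapse = ", ")))
  df <- records[, measurementColumns(), drop = FALSE]
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMeasurements
#' @export
readMeasurements <- function(path) {
  if (!file.exists(path)) inputError(sprintf("no such file: %s", path))
  utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
}

#' Write / read classification labels
#'
#' Labels CSV: `image_id`, `side`, `rule`, `label`.
#'
#' @param labels a data.frame with the four label columns.
#' @param path file path.
#' @export
writeLabels <- function(labels, path) {
  cols <- c("image_id", "side", "rule", "label")
  missing <- setdiff(cols, names(labels))
  if (length(missing))
    inputError(sprintf("missing label columns: %s", paste(missing, collapse = ", ")))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(labels[, cols, drop = FALSE], con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLabels
#' @export
readLabels <- function(path) {
  if (!file.exists(path)) inputError(sprintf("no such file: %s", path))
  utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
}
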