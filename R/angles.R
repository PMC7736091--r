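## The three hip-development indices, computed from a LandmarkSet in a
## PelvisFrame. Sign conventions (the index definitions leave signs
## implicit, but observed clinical ranges include negative Toennis and CE
## values, so signs are required):
##   Toennis: positive when the sourcil upslopes (lateral edge superior to
##            the medial edge), negative when it downslopes.
##   CE:      positive when the acetabular margin lies lateral to the
##            vertical through the head centre, negative when medial.
##   Sharp:   unsigned, reported as the acute interior angle in (0, 90).

.VERTICALS <- c("pelvic", "image")

.ceAxes <- function(frame, side, vertical) {
  if (vertical == "pelvic") {
    list(sup = frame@superiorUnit, lat = lateralUnit(frame, side))
  } else {
    ## literal image reading: vertical = image column direction; lateral
    ## from the standard AP layout (patient's left at larger x)
    list(sup = c(0, -1), lat = if (side == "left") c(1, 0) else c(-1, 0))
  }
}

#' Toennis angle (acetabular index of the weight-bearing zone)
#'
#' The angle between the sourcil chord (medial to lateral edge of the
#' acetabular weight-bearing area, line c) and the pelvic horizontal
#' (line a, via its parallel line b through the medial edge). Signed:
#' positive for an upsloping sourcil. Values above 10 degrees indicate
#' dysplasia.
#'
#' @param lm a [LandmarkSet-class].
#' @param frame a [PelvisFrame-class].
#' @return Signed degrees.
#' @export
tonnisAngle <- function(lm, frame) {
  w <- lm@sourcilLateral - lm@sourcilMedial
  if (.norm2(w) == 0)
    degenerateGeometryError("sourcil medial and lateral points coincide")
  atan2(.dot2(w, frame@superiorUnit), .dot2(w, lateralUnit(frame, lm@side))) * 180 / pi
}

#' Sharp angle (acetabular angle)
#'
#' The acute interior angle between line a and the line from the teardrop
#' inferior point to the acetabular lateral margin (line d). Unsigned,
#' in (0, 90). Values above 45 degrees indicate dysplasia.
#'
#' @inheritParams tonnisAngle
#' @return Degrees in `[0, 90]`.
#' @export
sharpAngle <- function(lm, frame) {
  v <- lm@acetabularLateralMargin - lm@teardropInferior
  if (.norm2(v) == 0)
    degenerateGeometryError("teardrop and acetabular lateral margin coincide")
  a <- vertexAngle(v, frame@axisUnit)
  if (a > 90) 180 - a else a
}

#' Centre-edge (CE) angle of Wiberg
#'
#' The angle at the femoral head centre between the pelvic vertical
#' (line e, perpendicular to line a through the centre) and the line to
#' the acetabular lateral margin (line f). Signed: positive when the
#' margin lies lateral to line e. Values below 20 degrees indicate
#' dysplasia; 20-25 degrees is borderline.
#'
#' @inheritParams tonnisAngle
#' @param vertical `"pelvic"` (default) measures against the perpendicular
#'   to line a; `"image"` against the literal image column direction.
#' @return Signed degrees.
#' @export
ceAngle <- function(lm, frame, vertical = c("pelvic", "image")) {
  vertical <- match.arg(vertical)
  v <- lm@acetabularLateralMargin - lm@headCenter
  if (.norm2(v) == 0)
    degenerateGeometryError("head centre and acetabular lateral margin coincide")
  ax <- .ceAxes(frame, lm@side, vertical)
  a <- vertexAngle(v, ax$sup)
  if (.dot2(v, ax$lat) < 0) -a else a
}

#' Measure both hips of an annotated pelvis
#'
#' Builds the pelvic frame once from the two teardrop points (sides taken
#' from the annotation labels), extracts landmarks per hip and computes
#' the three angles. A failure in one hip yields `NA` angles for that side
#' (with a warning carrying the side and reason) and does not abort the
#' other hip.
#'
#' @param ann a valid [PelvisAnnotation-class].
#' @param vertical passed to [ceAngle()].
#' @return A data.frame with one row per hip and the columns of
#'   [measurementColumns()].
#' @examples
#' ann <- buildPelvisPhantom(phantomSpec(10, 53.13, 26.565), imageId = "demo")
#' measurePelvis(ann)
#' @export
measurePelvis <- function(ann, vertical = c("pelvic", "image")) {
  vertical <- match.arg(vertical)
  stopifnot(is(ann, "PelvisAnnotation"))
  frame <- buildFrame(ann@left@teardropInferior, ann@right@teardropInferior,
    sides = c("left", "right"))
  measureOne <- function(hip) {
    tryCatch({
      lm <- extractLandmarks(hip, frame)
      data.frame(image_id = ann@imageId, side = hip@side,
        tonnis_deg = tonnisAngle(lm, frame),
        sharp_deg = sharpAngle(lm, frame),
        ce_deg = ceAngle(lm, frame, vertical),
        head_cx = lm@headCenter[1L], head_cy = lm@headCenter[2L],
        head_r = lm@headRadius, stringsAsFactors = FALSE)
    }, hipmorph_error = function(e) {
      warning(sprintf("measurement failed for %s hip of '%s': %s",
        hip@side, ann@imageId, conditionMessage(e)), call. = FALSE)
      data.frame(image_id = ann@imageId, side = hip@side,
        tonnis_deg = NA_real_, sharp_deg = NA_real_, ce_deg = NA_real_,
        head_cx = NA_real_, head_cy = NA_real_, head_r = NA_real_,
        stringsAsFactors = FALSE)
    })
  }
  rbind(measureOne(ann@right), measureOne(ann@left))
}

#' Measure angles from a LandmarkSet
#'
#' Convenience wrapper returning the three indices at once.
#'
#' @inheritParams ceAngle
#' @return Named numeric vector `c(tonnis_deg, sharp_deg, ce_deg)`.
#' @export
angleTriple <- function(lm, frame, vertical = c("pelvic", "image")) {
  vertical <- match.arg(vertical)
  c(tonnis_deg = tonnisAngle(lm, frame),
    sharp_deg = sharpAngle(lm, frame),
    ce_deg = ceAngle(lm, frame, vertical))
}
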