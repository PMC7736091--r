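## Automatic landmark extraction from traced contours.
##
## The femoral head centre is localised by fitting the circle through
## three well-spread points on the femoral arc: the most superior point,
## the most lateral point, and the intersection of the lateral-point ->
## teardrop segment with the arc (the medial head point). The acetabular
## lateral margin is the lateral endpoint of the acetabular arc. All
## directions are taken in the pelvic frame (line a), so the extraction
## is equivariant under in-plane rotation of the whole annotation.

#' Locate the three femoral head points
#'
#' Returns (superior, lateral, medial) points on the femoral arc: the
#' extremal vertices along the frame's superior and lateral directions,
#' and the intersection of the segment from the lateral point to the
#' teardrop with the arc that lies closest to the teardrop (the medial
#' part of the femoral head).
#'
#' @param femoralArc a femoral [ContourTrace-class] (>= 3 points).
#' @param teardrop the teardrop inferior point for the same side.
#' @param frame a [PelvisFrame-class].
#' @param side `"left"` or `"right"`.
#' @return A list with elements `superior`, `lateral`, `medial`.
#' @section Errors: landmark-extraction error when the segment misses the
#'   arc; degenerate-geometry error when the three points are collinear.
#' @export
locateFemoralPoints <- function(femoralArc, teardrop, frame, side) {
  teardrop <- as.numeric(teardrop)
  sup <- extremalPoint(femoralArc, frame@superiorUnit)
  lat <- extremalPoint(femoralArc, lateralUnit(frame, side))
  ints <- segmentPolylineIntersections(lat, teardrop, femoralArc)
  if (nrow(ints) == 0L)
    landmarkExtractionError(
      "segment from the lateral head point to the teardrop does not intersect the femoral arc")
  med <- as.numeric(ints[nrow(ints), ])  # ordered by distance from 'lat'; last = closest to teardrop
  span <- max(.norm2(lat - sup), .norm2(med - sup), .norm2(med - lat))
  if (span == 0 || abs(.cross2(lat - sup, med - sup)) / 2 < .EPS_AREA * span^2)
    degenerateGeometryError("the three femoral head points are collinear")
  list(superior = sup, lateral = lat, medial = med)
}

#' Fit the femoral head circle
#'
#' The circumcircle of the three head points. As a plausibility check, a
#' warning is emitted when the median absolute distance of the femoral
#' arc's head-region vertices (those within 1.5 fitted radii of the
#' centre) from the fitted circle exceeds 5% of the radius — on real
#' traces that indicates a poorly circular head or badly placed points.
#'
#' @param superior,lateral,medial the three head points (non-collinear).
#' @param femoralArc the full femoral arc, used only for the residual
#'   check; pass `NULL` to skip it.
#' @return A [Circle-class].
#' @export
fitFemoralHead <- function(superior, lateral, medial, femoralArc = NULL) {
  circ <- circumcircle(superior, lateral, medial)
  if (!is.null(femoralArc)) {
    pts <- if (is(femoralArc, "ContourTrace")) femoralArc@points else as.matrix(femoralArc)
    d <- sqrt((pts[, 1L] - circ@center[1L])^2 + (pts[, 2L] - circ@center[2L])^2)
    head_region <- d <= 1.5 * circ@radius
    if (any(head_region)) {
      medres <- stats::median(abs(d[head_region] - circ@radius))
      if (medres > 0.05 * circ@radius)
        warning(sprintf(
          "femoral head fit is implausible: median arc residual %.2f px exceeds 5%% of radius %.2f px",
          medres, circ@radius), call. = FALSE)
    }
  }
  circ
}

#' Locate the acetabular lateral margin
#'
#' The outer upper margin of the acetabulum: of the two endpoints of the
#' acetabular arc, the one projecting further along the lateral direction.
#' When the endpoint projections differ by less than 1 px the endpoint
#' rule is ambiguous and the function falls back to the extremal vertex of
#' the whole arc along the superolateral diagonal
#' `(lateral + superior) / ||.||`.
#'
#' @param acetabularArc an acetabular [ContourTrace-class].
#' @param frame a [PelvisFrame-class].
#' @param side `"left"` or `"right"`.
#' @return A numeric length-2 point.
#' @export
locateAcetabularLateralMargin <- function(acetabularArc, frame, side) {
  pts <- acetabularArc@points
  lat <- lateralUnit(frame, side)
  e1 <- as.numeric(pts[1L, ]); e2 <- as.numeric(pts[nrow(pts), ])
  p1 <- .dot2(e1, lat); p2 <- .dot2(e2, lat)
  if (abs(p1 - p2) < 1) {
    return(extremalPoint(acetabularArc, .unit2(lat + frame@superiorUnit)))
  }
  if (p1 > p2) e1 else e2
}

#' Extract all measurement landmarks for one hip
#'
#' Runs the full landmark pipeline on a [HipAnnotation-class]: acetabular
#' lateral margin, the three femoral head points, the fitted head circle.
#' The teardrop inferior and sourcil medial points are carried over from
#' the annotation (they are manual inputs); the sourcil lateral edge is
#' identified with the acetabular lateral margin, so one anchor point
#' serves the Toennis, Sharp and CE constructions consistently.
#'
#' @param hip a valid [HipAnnotation-class].
#' @param frame a [PelvisFrame-class].
#' @return A [LandmarkSet-class].
#' @section Errors: lower-level extraction errors are re-raised with the
#'   hip side attached to the message.
#' @export
extractLandmarks <- function(hip, frame) {
  stopifnot(is(hip, "HipAnnotation"))
  tryCatch(
    {
      margin <- locateAcetabularLateralMargin(hip@acetabularArc, frame, hip@side)
      fp <- locateFemoralPoints(hip@femoralArc, hip@teardropInferior, frame, hip@side)
      circ <- fitFemoralHead(fp$superior, fp$lateral, fp$medial, hip@femoralArc)
      new("LandmarkSet",
        headCenter = circ@center, headRadius = circ@radius,
        headSuperior = fp$superior, headLateral = fp$lateral,
        headMedial = fp$medial,
        acetabularLateralMargin = margin,
        sourcilMedial = hip@sourcilMedial,
        sourcilLateral = margin,
        teardropInferior = hip@teardropInferior,
        side = hip@side)
    },
    hipmorph_error = function(e) {
      stop(structure(
        list(message = sprintf("%s [%s hip]", conditionMessage(e), hip@side),
          call = conditionCall(e)),
        class = class(e)))
    })
}
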