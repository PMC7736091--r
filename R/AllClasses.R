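## S4 data model. Points are plain numeric length-2 vectors (x, y) in pixel
## units, image convention: origin top-left, y increases inferiorly.

.isPoint <- function(p) is.numeric(p) && length(p) == 2L && all(is.finite(p))

.SIDES <- c("left", "right")
.ROLES <- c("acetabular_arc", "femoral_arc")

#' ContourTrace: one traced bony arc
#'
#' An ordered open polyline of pixel coordinates tracing a single bony arc
#' on an AP pelvis radiograph: either the acetabular arc (outer acetabular
#' rim to the bottom of the acetabular fossa) or the femoral arc (femoral
#' head to femoral neck), for one hip.
#'
#' @slot points numeric matrix, one row per vertex, columns x and y
#'   (pixels, y increases inferiorly). At least 3 rows; no two consecutive
#'   rows identical; first and last rows differ (open polyline).
#' @slot role `"acetabular_arc"` or `"femoral_arc"`.
#' @slot side anatomical side, `"left"` or `"right"`.
#'
#' @seealso [contourTrace()] for the user constructor.
#' @export
setClass("ContourTrace",
  representation(points = "matrix", role = "character", side = "character"),
  validity = function(object) {
    p <- object@points
    if (!is.numeric(p) || ncol(p) != 2L)
      return("points must be a numeric matrix with 2 columns (x, y)")
    if (nrow(p) < 3L) return("a contour trace needs at least 3 points")
    if (!all(is.finite(p))) return("contour coordinates must be finite")
    d <- diff(p)
    if (any(rowSums(d * d) == 0))
      return("no two consecutive contour points may be identical")
    if (all(p[1L, ] == p[nrow(p), ]))
      return("contour must be an open polyline (first point != last point)")
    if (length(object@role) != 1L || !object@role %in% .ROLES)
      return(sprintf("role must be one of: %s", paste(.ROLES, collapse = ", ")))
    if (length(object@side) != 1L || !object@side %in% .SIDES)
      return("side must be 'left' or 'right'")
    TRUE
  }
)

#' @param points numeric n x 2 matrix (or coercible) of vertices.
#' @param role,side see slot documentation.
#' @return A `ContourTrace`.
#' @rdname ContourTrace-class
#' @export
contourTrace <- function(points, role, side) {
  points <- as.matrix(points)
  dimnames(points) <- list(NULL, c("x", "y"))
  storage.mode(points) <- "double"
  new("ContourTrace", points = points, role = role, side = side)
}

#' HipAnnotation: the traced input for one hip
#'
#' Bundles everything the measurement pipeline consumes for a single hip:
#' the two manually traced arcs plus the two manually marked points (the
#' medial edge of the sourcil, i.e. the inner edge of the acetabular
#' weight-bearing area, and the inferior edge of the teardrop). Manual
#' steps of the workflow are represented as data, never computed.
#'
#' The sourcil medial point must fall inside the bounding box of the
#' acetabular arc expanded by `getOption("hipmorph.sourcilMargin", 25)`
#' pixels on each side (a sanity guard against swapped annotations).
#'
#' @slot side `"left"` or `"right"`.
#' @slot acetabularArc,femoralArc `ContourTrace` objects whose `side`
#'   matches and whose `role` matches the slot.
#' @slot sourcilMedial,teardropInferior numeric length-2 points (pixels).
#' @export
setClass("HipAnnotation",
  representation(side = "character", acetabularArc = "ContourTrace",
    femoralArc = "ContourTrace", sourcilMedial = "numeric",
    teardropInferior = "numeric"),
  validity = function(object) {
    if (length(object@side) != 1L || !object@side %in% .SIDES)
      return("side must be 'left' or 'right'")
    if (object@acetabularArc@role != "acetabular_arc")
      return("acetabularArc must have role 'acetabular_arc'")
    if (object@femoralArc@role != "femoral_arc")
      return("femoralArc must have role 'femoral_arc'")
    if (object@acetabularArc@side != object@side ||
        object@femoralArc@side != object@side)
      return("trace sides must match the annotation side")
    if (!.isPoint(object@sourcilMedial)) return("sourcilMedial must be a finite (x, y) point")
    if (!.isPoint(object@teardropInferior)) return("teardropInferior must be a finite (x, y) point")
    m <- getOption("hipmorph.sourcilMargin", 25)
    bb <- apply(object@acetabularArc@points, 2L, range)
    sm <- object@sourcilMedial
    if (sm[1L] < bb[1L, 1L] - m || sm[1L] > bb[2L, 1L] + m ||
        sm[2L] < bb[1L, 2L] - m || sm[2L] > bb[2L, 2L] + m)
      return("sourcilMedial lies outside the acetabular arc bounding box (plus margin)")
    TRUE
  }
)

#' @param side,acetabularArc,femoralArc,sourcilMedial,teardropInferior see
#'   slot documentation.
#' @rdname HipAnnotation-class
#' @export
hipAnnotation <- function(side, acetabularArc, femoralArc, sourcilMedial,
                          teardropInferior) {
  new("HipAnnotation", side = side, acetabularArc = acetabularArc,
    femoralArc = femoralArc, sourcilMedial = as.numeric(sourcilMedial),
    teardropInferior = as.numeric(teardropInferior))
}

#' PelvisAnnotation: one annotated radiograph
#'
#' @slot imageId nonempty identifier of the radiograph.
#' @slot left,right `HipAnnotation` for each anatomical side.
#' @slot pixelSpacing mm per pixel, `NA_real_` when unknown. Display
#'   metadata only: all angles are scale invariant and computed in pixels.
#' @export
setClass("PelvisAnnotation",
  representation(imageId = "character", left = "HipAnnotation",
    right = "HipAnnotation", pixelSpacing = "numeric"),
  validity = function(object) {
    if (length(object@imageId) != 1L || is.na(object@imageId) ||
        !nzchar(object@imageId))
      return("imageId must be a nonempty string")
    if (object@left@side != "left" || object@right@side != "right")
      return("hip annotation sides must match their slots")
    if (all(object@left@teardropInferior == object@right@teardropInferior))
      return("the two teardrop points must be distinct")
    if (length(object@pixelSpacing) != 1L)
      return("pixelSpacing must be a single number (NA when unknown)")
    if (!is.na(object@pixelSpacing) && object@pixelSpacing <= 0)
      return("pixelSpacing must be positive")
    TRUE
  }
)

#' @param imageId,left,right,pixelSpacing see slot documentation.
#' @rdname PelvisAnnotation-class
#' @export
pelvisAnnotation <- function(imageId, left, right, pixelSpacing = NA_real_) {
  new("PelvisAnnotation", imageId = imageId, left = left, right = right,
    pixelSpacing = as.numeric(pixelSpacing))
}

#' Circle in pixel coordinates
#'
#' @slot center numeric length-2 point. @slot radius pixels, positive.
#' @export
setClass("Circle",
  representation(center = "numeric", radius = "numeric"),
  validity = function(object) {
    if (!.isPoint(object@center)) return("center must be a finite (x, y) point")
    if (length(object@radius) != 1L || !is.finite(object@radius) ||
        object@radius <= 0)
      return("radius must be a positive finite number")
    TRUE
  }
)

#' PelvisFrame: the pelvic coordinate frame (line a)
#'
#' Anchored on the line through the two teardrop inferior points (line a).
#' All "horizontal"/"vertical" notions in the angle definitions are taken
#' relative to this frame, making measurements invariant to in-plane image
#' rotation. `axisUnit` points from the anatomical right teardrop toward
#' the anatomical left teardrop (image left-to-right in a standard AP
#' view); `superiorUnit` is its perpendicular pointing superiorly
#' (decreasing y in an unrotated image).
#'
#' @slot teardropLeft,teardropRight numeric length-2 points.
#' @slot axisUnit,superiorUnit orthonormal numeric length-2 vectors.
#' @seealso [buildFrame()], [lateralUnit()]
#' @export
setClass("PelvisFrame",
  representation(teardropLeft = "numeric", teardropRight = "numeric",
    axisUnit = "numeric", superiorUnit = "numeric"),
  validity = function(object) {
    for (nm in c("teardropLeft", "teardropRight", "axisUnit", "superiorUnit"))
      if (!.isPoint(slot(object, nm))) return(sprintf("%s must be a finite (x, y) vector", nm))
    tol <- 1e-12
    if (abs(sum(object@axisUnit^2) - 1) > 1e-9 ||
        abs(sum(object@superiorUnit^2) - 1) > 1e-9)
      return("axisUnit and superiorUnit must have unit norm")
    if (abs(sum(object@axisUnit * object@superiorUnit)) > 1e-9)
      return("axisUnit and superiorUnit must be orthogonal")
    TRUE
  }
)

#' LandmarkSet: derived measurement landmarks for one hip
#'
#' The points an angle measurement needs, as extracted from a
#' `HipAnnotation`: the fitted femoral head circle, the three head points
#' it was fitted through, the acetabular lateral margin (which also serves
#' as the lateral edge of the sourcil), and the two manually marked points
#' carried over from the annotation.
#'
#' @slot headCenter centre of the fitted femoral head circle.
#' @slot headRadius its radius (pixels, positive).
#' @slot headSuperior,headLateral,headMedial the three non-collinear head
#'   points; each lies on the fitted circle to within 1e-6 px.
#' @slot acetabularLateralMargin outer upper margin of the acetabulum.
#' @slot sourcilMedial,sourcilLateral inner and outer edges of the
#'   weight-bearing area; `sourcilLateral` equals
#'   `acetabularLateralMargin` (one anchor point serves both the Toennis
#'   and Sharp/CE constructions).
#' @slot teardropInferior lower edge of the teardrop.
#' @slot side `"left"` or `"right"`.
#' @export
setClass("LandmarkSet",
  representation(headCenter = "numeric", headRadius = "numeric",
    headSuperior = "numeric", headLateral = "numeric", headMedial = "numeric",
    acetabularLateralMargin = "numeric", sourcilMedial = "numeric",
    sourcilLateral = "numeric", teardropInferior = "numeric",
    side = "character"),
  validity = function(object) {
    pts <- c("headCenter", "headSuperior", "headLateral", "headMedial",
      "acetabularLateralMargin", "sourcilMedial", "sourcilLateral",
      "teardropInferior")
    for (nm in pts)
      if (!.isPoint(slot(object, nm))) return(sprintf("%s must be a finite (x, y) point", nm))
    if (!is.finite(object@headRadius) || object@headRadius <= 0)
      return("headRadius must be positive")
    for (nm in c("headSuperior", "headLateral", "headMedial")) {
      d <- sqrt(sum((slot(object, nm) - object@headCenter)^2))
      if (abs(d - object@headRadius) > 1e-6)
        return(sprintf("%s does not lie on the fitted head circle", nm))
    }
    if (any(object@sourcilLateral != object@acetabularLateralMargin))
      return("sourcilLateral must equal acetabularLateralMargin")
    if (length(object@side) != 1L || !object@side %in% .SIDES)
      return("side must be 'left' or 'right'")
    TRUE
  }
)

#' ConfusionTable: reference-vs-predicted label counts
#'
#' A k x k cross-tabulation, rows = reference-standard labels, columns =
#' predicted labels, in a fixed shared class order. Feeds all agreement
#' statistics ([diagnosticMetrics()], [cohenKappa()], [mcnemarTest()],
#' [bowkerTest()], [multiclassAccuracy()]).
#'
#' @slot classes ordered character vector of class labels (k >= 2).
#' @slot counts k x k matrix of non-negative integers, `dimnames`
#'   reference x predicted.
#' @seealso [confusionTable()]
#' @export
setClass("ConfusionTable",
  representation(classes = "character", counts = "matrix"),
  validity = function(object) {
    k <- length(object@classes)
    if (k < 2L) return("at least 2 classes are required")
    if (anyDuplicated(object@classes)) return("classes must be unique")
    cnt <- object@counts
    if (!is.numeric(cnt) || nrow(cnt) != k || ncol(cnt) != k)
      return("counts must be a k x k numeric matrix")
    if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
      return("counts must be non-negative integers")
    TRUE
  }
)

#' ROCResult: a receiver operating characteristic analysis
#'
#' @slot thresholds candidate decision thresholds: midpoints between
#'   consecutive distinct scores plus -Inf and +Inf.
#' @slot sensitivity,specificity operating point per threshold.
#' @slot auc area under the curve (trapezoid rule), in `[0, 1]`.
#' @slot optimalThreshold the threshold maximising Youden's J
#'   (sensitivity + specificity - 1), ties broken toward higher
#'   specificity.
#' @slot orientation `"higher_is_positive"` or `"lower_is_positive"`
#'   (scores are negated internally for the latter; thresholds are
#'   reported on the original scale).
#' @seealso [rocCurve()]
#' @export
setClass("ROCResult",
  representation(thresholds = "numeric", sensitivity = "numeric",
    specificity = "numeric", auc = "numeric", optimalThreshold = "numeric",
    orientation = "character"),
  validity = function(object) {
    n <- length(object@thresholds)
    if (length(object@sensitivity) != n || length(object@specificity) != n)
      return("thresholds, sensitivity and specificity must have equal length")
    if (!is.finite(object@auc) || object@auc < 0 || object@auc > 1)
      return("auc must lie in [0, 1]")
    if (!object@orientation %in% c("higher_is_positive", "lower_is_positive"))
      return("orientation must be 'higher_is_positive' or 'lower_is_positive'")
    TRUE
  }
)
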