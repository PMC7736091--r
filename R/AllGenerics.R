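## Generics, accessors and show methods.

#' Accessors for hipmorph classes
#'
#' `side()` returns the anatomical side; `tracePoints()` the vertex matrix
#' of a contour; `headCenter()`/`headRadius()` the fitted femoral head;
#' `counts()` and `tableN()` the count matrix and total of a
#' `ConfusionTable`; `auc()` the area under a ROC curve.
#'
#' @param object an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("side", function(object) standardGeneric("side"))
#' @rdname accessors
#' @export
setMethod("side", "ContourTrace", function(object) object@side)
#' @rdname accessors
#' @export
setMethod("side", "HipAnnotation", function(object) object@side)
#' @rdname accessors
#' @export
setMethod("side", "LandmarkSet", function(object) object@side)

#' @rdname accessors
#' @export
setGeneric("tracePoints", function(object) standardGeneric("tracePoints"))
#' @rdname accessors
#' @export
setMethod("tracePoints", "ContourTrace", function(object) object@points)

#' @rdname accessors
#' @export
setGeneric("headCenter", function(object) standardGeneric("headCenter"))
#' @rdname accessors
#' @export
setMethod("headCenter", "LandmarkSet", function(object) object@headCenter)
#' @rdname accessors
#' @export
setMethod("headCenter", "Circle", function(object) object@center)

#' @rdname accessors
#' @export
setGeneric("headRadius", function(object) standardGeneric("headRadius"))
#' @rdname accessors
#' @export
setMethod("headRadius", "LandmarkSet", function(object) object@headRadius)
#' @rdname accessors
#' @export
setMethod("headRadius", "Circle", function(object) object@radius)

#' @rdname accessors
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))
#' @rdname accessors
#' @export
setMethod("counts", "ConfusionTable", function(object) object@counts)

#' @rdname accessors
#' @export
setGeneric("tableN", function(object) standardGeneric("tableN"))
#' @rdname accessors
#' @export
setMethod("tableN", "ConfusionTable", function(object) sum(object@counts))

#' @rdname accessors
#' @export
setGeneric("auc", function(object) standardGeneric("auc"))
#' @rdname accessors
#' @export
setMethod("auc", "ROCResult", function(object) object@auc)

setMethod("show", "ContourTrace", function(object) {
  cat(sprintf("ContourTrace (%s, %s): %d points\n",
    object@role, object@side, nrow(object@points)))
})

setMethod("show", "HipAnnotation", function(object) {
  cat(sprintf("HipAnnotation (%s hip)\n", object@side))
  cat(sprintf("  acetabular arc: %d points; femoral arc: %d points\n",
    nrow(object@acetabularArc@points), nrow(object@femoralArc@points)))
  cat(sprintf("  sourcil medial (%.2f, %.2f); teardrop inferior (%.2f, %.2f)\n",
    object@sourcilMedial[1], object@sourcilMedial[2],
    object@teardropInferior[1], object@teardropInferior[2]))
})

setMethod("show", "PelvisAnnotation", function(object) {
  cat(sprintf("PelvisAnnotation '%s'%s\n", object@imageId,
    if (is.na(object@pixelSpacing)) "" else
      sprintf(" (%.4f mm/px)", object@pixelSpacing)))
  show(object@right); show(object@left)
})

setMethod("show", "Circle", function(object) {
  cat(sprintf("Circle: centre (%.3f, %.3f), radius %.3f px\n",
    object@center[1], object@center[2], object@radius))
})

setMethod("show", "PelvisFrame", function(object) {
  cat(sprintf("PelvisFrame: line a through (%.2f, %.2f) [R] and (%.2f, %.2f) [L]\n",
    object@teardropRight[1], object@teardropRight[2],
    object@teardropLeft[1], object@teardropLeft[2]))
  cat(sprintf("  axis (%.5f, %.5f); superior (%.5f, %.5f)\n",
    object@axisUnit[1], object@axisUnit[2],
    object@superiorUnit[1], object@superiorUnit[2]))
})

setMethod("show", "LandmarkSet", function(object) {
  cat(sprintf("LandmarkSet (%s hip)\n", object@side))
  cat(sprintf("  femoral head: centre (%.3f, %.3f), radius %.3f px\n",
    object@headCenter[1], object@headCenter[2], object@headRadius))
  cat(sprintf("  acetabular lateral margin (%.3f, %.3f)\n",
    object@acetabularLateralMargin[1], object@acetabularLateralMargin[2]))
  cat(sprintf("  sourcil medial (%.3f, %.3f); teardrop (%.3f, %.3f)\n",
    object@sourcilMedial[1], object@sourcilMedial[2],
    object@teardropInferior[1], object@teardropInferior[2]))
})

setMethod("show", "ConfusionTable", function(object) {
  cat(sprintf("ConfusionTable: %d classes, n = %d (rows = reference)\n",
    length(object@classes), sum(object@counts)))
  print(object@counts)
})

setMethod("show", "ROCResult", function(object) {
  cat(sprintf("ROCResult (%s): AUC = %.4f, Youden-optimal threshold = %.4g\n",
    object@orientation, object@auc, object@optimalThreshold))
})
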