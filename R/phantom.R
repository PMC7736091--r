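## Geometric hip phantoms: annotations with prescribed ground-truth
## angles, built by inverting the angle definitions analytically. The
## measurement pipeline consumes contours, so no image synthesis is
## needed; a phantom is simply a pair of arcs plus the two manual points,
## constructed so that the exact target angles are recovered on
## measurement.
##
## Construction (per hip, in the frame's lateral l / superior s basis,
## teardrop T on line a):
##   rim     P = T + 2R (cos(sharp) l + sin(sharp) s)
##   centre  C = P - 0.9R (sin(ce) l + cos(ce) s)
##   sourcil M = P - 0.8R (cos(tonnis) l + sin(tonnis) s)
##   femoral arc: sampled on the circle (C, R) from 170 deg medial of
##     superior to 100 deg lateral, always including the exact superior
##     and lateral points;
##   acetabular arc: polyline from P through M down to a point just above
##     the teardrop (bottom of the acetabular fossa).
## P and M are exact vertices, so the Toennis and Sharp angles are exact
## by construction; the CE angle is exact up to the (sub-0.01 px) error
## of refitting the head circle through polyline-sampled points.

#' Phantom specification
#'
#' Target angles and sampling parameters for one synthetic hip.
#'
#' @param tonnisDeg,sharpDeg,ceDeg target angles in degrees. `sharpDeg`
#'   must lie in (5, 85); the construction additionally requires the head
#'   centre to land superior to line a and the teardrop to stay outside
#'   the head circle (violations raise a phantom-construction error at
#'   build time).
#' @param headRadius femoral head radius in pixels.
#' @param teardropSeparation distance between the two teardrops (pixels);
#'   a pelvis-level parameter carried on the spec for convenience.
#' @param arcSampling number of points per sampled arc.
#' @param jitterSd standard deviation (pixels) of i.i.d. Gaussian jitter
#'   added to every contour vertex (0 = noise-free). The two manual
#'   points are never jittered.
#' @param seed integer seed used when `jitterSd > 0`.
#' @return A list of class `phantomSpec`.
#' @export
phantomSpec <- function(tonnisDeg, sharpDeg, ceDeg, headRadius = 25,
                        teardropSeparation = 140, arcSampling = 100L,
                        jitterSd = 0, seed = 1L) {
  for (v in c(tonnisDeg, sharpDeg, ceDeg, headRadius, teardropSeparation,
    jitterSd))
    if (!is.finite(v)) inputError("phantom parameters must be finite")
  if (sharpDeg <= 5 || sharpDeg >= 85)
    inputError("sharpDeg must lie in (5, 85)")
  if (headRadius <= 0) inputError("headRadius must be positive")
  if (teardropSeparation <= 0) inputError("teardropSeparation must be positive")
  if (arcSampling < 10L) inputError("arcSampling must be at least 10")
  if (jitterSd < 0) inputError("jitterSd must be non-negative")
  structure(list(tonnisDeg = tonnisDeg, sharpDeg = sharpDeg, ceDeg = ceDeg,
    headRadius = headRadius, teardropSeparation = teardropSeparation,
    arcSampling = as.integer(arcSampling), jitterSd = jitterSd,
    seed = as.integer(seed)), class = "phantomSpec")
}

.deg <- pi / 180

#' Build one phantom hip annotation
#'
#' Constructs a [HipAnnotation-class] whose measured Toennis, Sharp and
#' CE angles equal the targets in `spec` (to well under 0.1 degree when
#' `jitterSd = 0`). The teardrop is taken from `frame` for the given
#' side.
#'
#' @param spec a [phantomSpec()].
#' @param side `"left"` or `"right"`.
#' @param frame a [PelvisFrame-class] providing line a and the teardrop.
#' @return A [HipAnnotation-class].
#' @section Errors: phantom-construction error when the target angles put
#'   the head centre on/below line a or the teardrop inside the head
#'   circle.
#' @export
buildHipPhantom <- function(spec, side, frame) {
  stopifnot(inherits(spec, "phantomSpec"))
  side <- match.arg(side, .SIDES)
  Td <- frameTeardrop(frame, side)
  l <- lateralUnit(frame, side)
  s <- frame@superiorUnit
  R <- spec$headRadius
  P <- Td + 2 * R * (cos(spec$sharpDeg * .deg) * l + sin(spec$sharpDeg * .deg) * s)
  C <- P - 0.9 * R * (sin(spec$ceDeg * .deg) * l + cos(spec$ceDeg * .deg) * s)
  M <- P - 0.8 * R * (cos(spec$tonnisDeg * .deg) * l + sin(spec$tonnisDeg * .deg) * s)
  if (.dot2(C - Td, s) <= 0)
    phantomConstructionError(
      "target angles place the femoral head centre on or below line a")
  if (.norm2(C - Td) <= R)
    phantomConstructionError("teardrop falls inside the femoral head circle")
  ## femoral arc on the circle (C, R); theta measured from superior toward
  ## lateral, exact superior (0) and lateral (90) vertices forced in. The
  ## arc reaches 170 deg medially so the medial chord exit stays on the
  ## arc across the whole clinical angle box (worst case, Sharp 56 +
  ## CE 47, exits near -161 deg).
  theta <- sort(unique(c(seq(-170, 100, length.out = spec$arcSampling), 0, 90)))
  femoral <- t(vapply(theta, function(th)
    C + R * (sin(th * .deg) * l + cos(th * .deg) * s), numeric(2)))
  ## acetabular arc: rim P -> sourcil medial M -> fossa bottom E
  E <- Td + 0.4 * R * s
  nA <- max(spec$arcSampling, 12L)
  n1 <- max(4L, nA %/% 3L); n2 <- nA - n1
  seg1 <- cbind(seq(P[1L], M[1L], length.out = n1 + 1L),
                seq(P[2L], M[2L], length.out = n1 + 1L))
  seg2 <- cbind(seq(M[1L], E[1L], length.out = n2 + 1L),
                seq(M[2L], E[2L], length.out = n2 + 1L))
  acet <- rbind(seg1, seg2[-1L, , drop = FALSE])
  if (spec$jitterSd > 0) {
    rng <- .withSeed(spec$seed, {
      list(f = matrix(stats::rnorm(length(femoral), 0, spec$jitterSd), ncol = 2L),
           a = matrix(stats::rnorm(length(acet), 0, spec$jitterSd), ncol = 2L))
    })
    femoral <- femoral + rng$f
    acet <- acet + rng$a
  }
  hipAnnotation(side,
    contourTrace(acet, "acetabular_arc", side),
    contourTrace(femoral, "femoral_arc", side),
    sourcilMedial = M, teardropInferior = Td)
}

## evaluate expr with a temporary RNG state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Build a whole phantom pelvis
#'
#' Places the two teardrops `teardropSeparation` apart on a horizontal
#' line a (optionally rotated) and builds both hips.
#'
#' @param specRight,specLeft [phantomSpec()] per side (`specLeft`
#'   defaults to `specRight`).
#' @param imageId identifier for the resulting annotation.
#' @param origin midpoint of the two teardrops.
#' @param rotationDeg in-plane rotation of the whole pelvis about
#'   `origin` (the ground-truth angles are unchanged: all indices are
#'   measured relative to line a).
#' @return A [PelvisAnnotation-class].
#' @examples
#' ann <- buildPelvisPhantom(phantomSpec(10, 53.13, 26.565), imageId = "demo")
#' measurePelvis(ann)
#' @export
buildPelvisPhantom <- function(specRight, specLeft = specRight,
                               imageId = "phantom",
                               origin = c(150, 120), rotationDeg = 0) {
  stopifnot(inherits(specRight, "phantomSpec"), inherits(specLeft, "phantomSpec"))
  sep <- specRight$teardropSeparation
  tR <- origin + c(-sep / 2, 0)
  tL <- origin + c(sep / 2, 0)
  if (rotationDeg != 0) {
    tR <- rotatePoints(tR, rotationDeg, origin)
    tL <- rotatePoints(tL, rotationDeg, origin)
  }
  frame <- buildFrame(tL, tR, sides = c("left", "right"))
  ## distinct jitter streams per side
  specL <- specLeft; specL$seed <- specLeft$seed + 1L
  pelvisAnnotation(imageId,
    left = buildHipPhantom(specL, "left", frame),
    right = buildHipPhantom(specRight, "right", frame))
}
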