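# Shared fixtures built in code.
#
# The "worked hip" is the hand-checkable geometry used across modules:
# teardrop T = (80, 120), femoral head centre C = (100, 100) with radius
# 25, acetabular rim P = (110, 80), sourcil medial M = (90.30, 83.47),
# horizontal line a. Lateral is +x, so under the standard AP layout
# (patient's left at larger image x) this is an anatomical LEFT hip with
# the contralateral teardrop at (-60, 120). Expected angles:
# Toennis atan(3.47/19.7) ~ 9.989 deg, Sharp atan(40/30) = 53.130 deg,
# CE atan(10/20) = 26.565 deg.

workedFrame <- function() {
  buildFrame(c(80, 120), c(-60, 120), sides = c("left", "right"))
}

# femoral arc sampled on the circle (C, r), theta from superior toward
# lateral; 0 and 90 forced in so the extremal vertices are exact
workedFemoralArc <- function(C = c(100, 100), r = 25, side = "left",
                             thetaRange = c(-170, 100), n = 101) {
  lat <- if (side == "left") c(1, 0) else c(-1, 0)
  th <- sort(unique(c(seq(thetaRange[1], thetaRange[2], length.out = n), 0, 90)))
  pts <- t(vapply(th, function(a)
    C + r * (sin(a * pi / 180) * lat + cos(a * pi / 180) * c(0, -1)),
    numeric(2)))
  contourTrace(pts, "femoral_arc", side)
}

# exact medial head point of the worked geometry: intersection of the
# segment (125,100) -> (80,120) with the circle, root t = 2250/2425
workedMedialPoint <- function() {
  t <- 2250 / 2425
  c(125 - 45 * t, 100 + 20 * t)
}

workedAcetabularArc <- function(P = c(110, 80), M = c(90.30, 83.47),
                                E = c(82, 110), side = "left", n = 30) {
  n1 <- n %/% 3
  seg1 <- cbind(seq(P[1], M[1], length.out = n1 + 1),
                seq(P[2], M[2], length.out = n1 + 1))
  seg2 <- cbind(seq(M[1], E[1], length.out = n - n1 + 1),
                seq(M[2], E[2], length.out = n - n1 + 1))
  contourTrace(rbind(seg1, seg2[-1, ]), "acetabular_arc", side)
}

# mirror about the pelvic midline x = 10 (teardrops at -60 and 80)
.mirrorX <- function(p) c(20 - p[1], p[2])
.mirrorM <- function(m) cbind(20 - m[, 1], m[, 2])

workedHip <- function(side = "left") {
  if (side == "left") {
    hipAnnotation("left", workedAcetabularArc(),
      workedFemoralArc(side = "left"),
      sourcilMedial = c(90.30, 83.47), teardropInferior = c(80, 120))
  } else {
    hipAnnotation("right",
      contourTrace(.mirrorM(tracePoints(workedAcetabularArc())), "acetabular_arc", "right"),
      contourTrace(.mirrorM(tracePoints(workedFemoralArc(side = "left"))), "femoral_arc", "right"),
      sourcilMedial = .mirrorX(c(90.30, 83.47)),
      teardropInferior = .mirrorX(c(80, 120)))
  }
}

workedPelvis <- function(imageId = "worked") {
  pelvisAnnotation(imageId, left = workedHip("left"), right = workedHip("right"))
}

# apply an affine map f(point) -> point to every coordinate of an annotation
transformAnnotation <- function(ann, f) {
  tHip <- function(h) {
    fM <- function(m) t(apply(m, 1, f))
    hipAnnotation(side(h),
      contourTrace(fM(tracePoints(h@acetabularArc)), "acetabular_arc", side(h)),
      contourTrace(fM(tracePoints(h@femoralArc)), "femoral_arc", side(h)),
      sourcilMedial = f(h@sourcilMedial),
      teardropInferior = f(h@teardropInferior))
  }
  pelvisAnnotation(ann@imageId, left = tHip(ann@left), right = tHip(ann@right),
    pixelSpacing = ann@pixelSpacing)
}

# draw target angle triples uniformly over the clinical observed ranges
randomTargets <- function(n) {
  cbind(tonnis = runif(n, -8, 33), sharp = runif(n, 30, 56),
    ce = runif(n, -4, 47))
}

expect_point_equal <- function(actual, expected, tol = 1e-9) {
  expect_lt(sqrt(sum((as.numeric(actual) - as.numeric(expected))^2)), tol)
}
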