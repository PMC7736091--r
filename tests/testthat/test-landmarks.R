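test_that("femoral head points are located on the worked geometry", {
  fr <- workedFrame()
  fp <- locateFemoralPoints(workedFemoralArc(), c(80, 120), fr, "left")
  expect_point_equal(fp$superior, c(100, 75), tol = 1e-9)
  expect_point_equal(fp$lateral, c(125, 100), tol = 1e-9)
  # medial point: chord intersection near the analytic circle crossing
  expect_point_equal(fp$medial, workedMedialPoint(), tol = 0.05)
})

test_that("a teardrop segment that misses the arc raises a landmark error", {
  fr <- workedFrame()
  # short almost-flat arc far from the teardrop->lateral segment
  arc <- contourTrace(rbind(c(100, 75), c(110, 74), c(120, 75.5)),
    "femoral_arc", "left")
  expect_error(locateFemoralPoints(arc, c(300, 300), fr, "left"),
    class = "hipmorph_landmark_extraction")
})

test_that("landmark extraction is rotation equivariant", {
  ctr <- c(100, 100)
  for (ang in c(10, -35)) {
    fr <- workedFrame()
    frR <- buildFrame(rotatePoints(c(80, 120), ang, ctr),
      rotatePoints(c(-60, 120), ang, ctr), sides = c("left", "right"))
    arcR <- contourTrace(rotatePoints(tracePoints(workedFemoralArc()), ang, ctr),
      "femoral_arc", "left")
    fp0 <- locateFemoralPoints(workedFemoralArc(), c(80, 120), fr, "left")
    fpR <- locateFemoralPoints(arcR, rotatePoints(c(80, 120), ang, ctr), frR, "left")
    for (nm in c("superior", "lateral", "medial"))
      expect_point_equal(fpR[[nm]], rotatePoints(fp0[[nm]], ang, ctr), tol = 1e-6)
  }
})

test_that("fitFemoralHead recovers the generating circle", {
  fp <- locateFemoralPoints(workedFemoralArc(n = 5001), c(80, 120),
    workedFrame(), "left")
  circ <- fitFemoralHead(fp$superior, fp$lateral, fp$medial,
    workedFemoralArc(n = 5001))
  expect_point_equal(headCenter(circ), c(100, 100), tol = 1e-6)
  expect_equal(headRadius(circ), 25, tolerance = 1e-6)
})

test_that("fitFemoralHead warns when the arc is not plausibly circular", {
  # ellipse with 30% eccentricity: median residual well above 5% of r
  th <- seq(-170, 100, length.out = 101) * pi / 180
  ell <- contourTrace(cbind(100 + 35 * sin(th), 100 - 25 * cos(th)),
    "femoral_arc", "left")
  sup <- extremalPoint(ell, c(0, -1)); lat <- extremalPoint(ell, c(1, 0))
  med <- as.numeric(tracePoints(ell)[5, ])
  expect_warning(fitFemoralHead(sup, lat, med, ell), "implausible")
})

test_that("head centre recovery stays below 2 px under 1 px jitter", {
  fr <- buildFrame(c(220, 120), c(80, 120), sides = c("left", "right"))
  set.seed(424)
  errs <- replicate(150, {
    tg <- randomTargets(1)
    hip <- buildHipPhantom(phantomSpec(tg[1], tg[2], tg[3], jitterSd = 1,
      seed = sample.int(1e6, 1)), "right", fr)
    hip0 <- buildHipPhantom(phantomSpec(tg[1], tg[2], tg[3]), "right", fr)
    lm <- suppressWarnings(extractLandmarks(hip, fr))
    lm0 <- extractLandmarks(hip0, fr)
    sqrt(sum((headCenter(lm) - headCenter(lm0))^2))
  })
  expect_lt(mean(errs), 2)
})

test_that("acetabular lateral margin picks the lateral endpoint, with a superolateral fallback", {
  fr <- workedFrame()
  expect_point_equal(
    locateAcetabularLateralMargin(workedAcetabularArc(), fr, "left"),
    c(110, 80), tol = 1e-12)

  # mirrored right hip gives the mirrored answer
  arcR <- contourTrace(.mirrorM(tracePoints(workedAcetabularArc())),
    "acetabular_arc", "right")
  expect_point_equal(locateAcetabularLateralMargin(arcR, fr, "right"),
    .mirrorX(c(110, 80)), tol = 1e-12)

  # near-tie endpoints (lateral projections differ by < 1 px): fall back
  # to the superolateral extremal vertex of the whole arc
  tie <- contourTrace(rbind(c(100, 80), c(108, 70), c(100.5, 90)),
    "acetabular_arc", "left")
  expect_point_equal(locateAcetabularLateralMargin(tie, fr, "left"),
    c(108, 70), tol = 1e-12)
})

test_that("extractLandmarks assembles a consistent LandmarkSet", {
  fr <- workedFrame()
  lm <- extractLandmarks(workedHip("left"), fr)
  expect_s4_class(lm, "LandmarkSet")
  expect_point_equal(headCenter(lm), c(100, 100), tol = 0.01)
  expect_equal(headRadius(lm), 25, tolerance = 0.01)
  expect_identical(lm@sourcilLateral, lm@acetabularLateralMargin)
  expect_point_equal(lm@sourcilMedial, c(90.30, 83.47), tol = 1e-12)
  expect_point_equal(lm@teardropInferior, c(80, 120), tol = 1e-12)

  # mirror-identical geometry on the contralateral side
  lmR <- extractLandmarks(workedHip("right"), fr)
  expect_point_equal(headCenter(lmR), .mirrorX(c(100, 100)), tol = 0.01)
  expect_equal(headRadius(lmR), headRadius(lm), tolerance = 1e-9)
})

test_that("extraction failures carry the hip side", {
  fr <- workedFrame()
  hip <- workedHip("left")
  # a femoral arc the teardrop chord cannot reach
  hip@femoralArc <- contourTrace(rbind(c(100, 75), c(110, 74), c(120, 75.5)),
    "femoral_arc", "left")
  err <- tryCatch(extractLandmarks(hip, fr), error = function(e) e)
  expect_s3_class(err, "hipmorph_landmark_extraction")
  expect_match(conditionMessage(err), "left hip")
})

test_that("noise-free phantom landmarks recover the generating circle to 1e-6 px", {
  fr <- buildFrame(c(220, 120), c(80, 120), sides = c("left", "right"))
  set.seed(515)
  tg <- randomTargets(5)
  for (i in seq_len(nrow(tg))) {
    spec <- phantomSpec(tg[i, 1], tg[i, 2], tg[i, 3], arcSampling = 20001L)
    hip <- buildHipPhantom(spec, "right", fr)
    lm <- extractLandmarks(hip, fr)
    # generating circle: centre = rim - 0.9 R along the CE direction
    l <- lateralUnit(fr, "right"); s <- fr@superiorUnit
    Td <- c(80, 120)
    P <- Td + 50 * (cos(tg[i, 2] * pi / 180) * l + sin(tg[i, 2] * pi / 180) * s)
    C <- P - 22.5 * (sin(tg[i, 3] * pi / 180) * l + cos(tg[i, 3] * pi / 180) * s)
    expect_point_equal(headCenter(lm), C, tol = 1e-6)
    expect_equal(headRadius(lm), 25, tolerance = 1e-6)
  }
})
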