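test_that("circumcircle recovers known circles and is permutation invariant", {
  c1 <- circumcircle(c(0, 1), c(1, 0), c(-1, 0))
  expect_point_equal(headCenter(c1), c(0, 0), tol = 1e-12)
  expect_equal(headRadius(c1), 1, tolerance = 1e-12)

  # hand-solved perpendicular-bisector system (points quoted to 2 dp)
  c2 <- circumcircle(c(100, 75), c(125, 100), c(83.25, 118.56))
  expect_point_equal(headCenter(c2), c(100, 100), tol = 0.01)
  expect_equal(headRadius(c2), 25, tolerance = 1e-3)

  set.seed(101)
  for (i in 1:50) {
    pts <- matrix(runif(6, -50, 50), 3, 2)
    ref <- circumcircle(pts[1, ], pts[2, ], pts[3, ])
    perm <- pts[sample(3), ]
    alt <- circumcircle(perm[1, ], perm[2, ], perm[3, ])
    expect_point_equal(headCenter(alt), headCenter(ref), tol = 1e-6)
    expect_equal(headRadius(alt), headRadius(ref), tolerance = 1e-9)
    # all three points lie on the circle
    for (j in 1:3)
      expect_equal(sqrt(sum((pts[j, ] - headCenter(ref))^2)), headRadius(ref),
        tolerance = 1e-9)
  }
})

test_that("circumcircle rejects collinear and coincident points", {
  expect_error(circumcircle(c(0, 0), c(1, 1), c(2, 2)),
    class = "hipmorph_degenerate_geometry")
  expect_error(circumcircle(c(0, 0), c(0, 0), c(2, 2)),
    class = "hipmorph_degenerate_geometry")
  # near-collinear below the area tolerance
  expect_error(circumcircle(c(0, 0), c(1, 1e-12), c(2, 0)),
    class = "hipmorph_degenerate_geometry")
})

test_that("buildFrame produces the documented orthonormal frame", {
  fr <- buildFrame(c(80, 120), c(220, 121))
  # sides inferred from x-order: left hip at larger x
  expect_equal(fr@teardropLeft, c(220, 121))
  d <- c(140, 1) / sqrt(140^2 + 1)
  expect_point_equal(fr@axisUnit, d, tol = 1e-12)
  expect_equal(sum(fr@axisUnit * fr@superiorUnit), 0, tolerance = 1e-12)
  expect_lt(fr@superiorUnit[2], 0)  # superior points toward decreasing y
  expect_equal(sqrt(sum(fr@axisUnit^2)), 1, tolerance = 1e-12)
  expect_point_equal(lateralUnit(fr, "left"), -lateralUnit(fr, "right"),
    tol = 1e-15)

  # invariant under swapping arguments (x-order inference)
  fr2 <- buildFrame(c(220, 121), c(80, 120))
  expect_identical(fr@axisUnit, fr2@axisUnit)
  expect_identical(fr@teardropRight, fr2@teardropRight)

  expect_error(buildFrame(c(1, 2), c(1, 2)),
    class = "hipmorph_degenerate_geometry")
})

test_that("buildFrame is rotation equivariant under explicit side assignment", {
  tl <- c(220, 121); tr <- c(80, 120); ctr <- c(150, 120)
  fr <- buildFrame(tl, tr, sides = c("left", "right"))
  for (ang in c(30, 90, 170)) {
    frR <- buildFrame(rotatePoints(tl, ang, ctr), rotatePoints(tr, ang, ctr),
      sides = c("left", "right"))
    expect_point_equal(frR@axisUnit, rotatePoints(fr@axisUnit, ang), tol = 1e-9)
    expect_point_equal(frR@superiorUnit, rotatePoints(fr@superiorUnit, ang),
      tol = 1e-9)
  }
})

test_that("extremalPoint matches an exhaustive scan and breaks ties clockwise", {
  sq <- contourTrace(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5)),
    "femoral_arc", "left")
  # top of the image is smaller y; tie between (0,0) and (1,0) broken by
  # the clockwise perpendicular of (0,-1), which points toward +x
  expect_equal(extremalPoint(sq, c(0, -1)), c(1, 0))
  expect_equal(extremalPoint(sq, c(1, 0.1)), c(1, 1))

  set.seed(202)
  for (i in 1:200) {
    pts <- matrix(rnorm(2 * sample(3:40, 1), sd = 30), ncol = 2)
    tr <- tryCatch(contourTrace(pts, "femoral_arc", "left"),
      error = function(e) NULL)
    if (is.null(tr)) next
    dir <- rnorm(2); dir <- dir / sqrt(sum(dir^2))
    got <- extremalPoint(tr, dir)
    pr <- as.numeric(pts %*% dir)
    expect_equal(sum(got * dir), max(pr), tolerance = 1e-9)
  }
})

test_that("segmentPolylineIntersections finds ordered crossings with a guard", {
  arc <- workedFemoralArc(n = 2001)
  # derived root t = 2250/2425 on the segment (125,100) -> (80,120)
  ints <- segmentPolylineIntersections(c(125, 100), c(80, 120), arc)
  expect_gte(nrow(ints), 1)
  expect_point_equal(ints[nrow(ints), ], workedMedialPoint(), tol = 0.01)

  # disjoint segment
  expect_equal(nrow(segmentPolylineIntersections(c(0, 0), c(10, 0), arc)), 0)

  # a segment starting exactly on a vertex of the polyline drops the start
  start <- tracePoints(arc)[50, ]
  ints2 <- segmentPolylineIntersections(start, start + c(500, 0), arc)
  if (nrow(ints2) > 0)
    expect_gt(min(sqrt(rowSums((ints2 - matrix(start, nrow(ints2), 2,
      byrow = TRUE))^2))), 1e-6)

  expect_error(segmentPolylineIntersections(c(1, 1), c(1, 1), arc),
    class = "hipmorph_input")
})

test_that("intersections are ordered by distance from the segment start", {
  # horizontal segment through a full sampled circle: two crossings
  th <- seq(0, 359, by = 1) * pi / 180
  circ <- contourTrace(cbind(100 + 25 * cos(th), 100 + 25 * sin(th)),
    "femoral_arc", "left")
  ints <- segmentPolylineIntersections(c(0, 100), c(200, 100), circ)
  expect_equal(nrow(ints), 2)
  expect_lt(ints[1, 1], ints[2, 1])
  expect_equal(ints[, 1], c(75, 125), tolerance = 0.05)
})

test_that("vertexAngle computes clamped arccos angles in degrees", {
  expect_equal(vertexAngle(c(1, 0), c(0, 1)), 90)
  expect_equal(vertexAngle(c(1, 0), c(1, 0)), 0)
  expect_equal(vertexAngle(c(3, -4), c(1, 0)), 53.13010, tolerance = 1e-5)
  expect_equal(vertexAngle(c(1, 0), c(-2, 0)), 180)
  expect_error(vertexAngle(c(0, 0), c(1, 0)),
    class = "hipmorph_degenerate_geometry")
})

test_that("geometry is equivariant under rotation and translation", {
  set.seed(303)
  for (i in 1:20) {
    pts <- matrix(runif(6, -50, 50), 3, 2)
    circ <- tryCatch(circumcircle(pts[1, ], pts[2, ], pts[3, ]),
      error = function(e) NULL)
    if (is.null(circ)) next
    ang <- runif(1, -180, 180); shift <- runif(2, -100, 100)
    f <- function(p) rotatePoints(p, ang, c(10, 20)) + shift
    circ2 <- circumcircle(f(pts[1, ]), f(pts[2, ]), f(pts[3, ]))
    expect_point_equal(headCenter(circ2), f(headCenter(circ)), tol = 1e-6)
    expect_equal(headRadius(circ2), headRadius(circ), tolerance = 1e-9)
  }
})
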