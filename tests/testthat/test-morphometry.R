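test_that("pixel distances honour anisotropic spacing", {
  expect_equal(euclideanMM(c(100, 100), c(100, 160), c(0.7, 0.7)), 42)
  expect_equal(euclideanMM(c(0, 0), c(30, 40), c(1, 0.5)), sqrt(1300))
  expect_equal(euclideanMM(c(5, 9), c(5, 9), c(1.2, 0.8)), 0)
  expect_error(euclideanMM(c(0, 0), c(1, 1), c(0, 1)), "positive")
})

test_that("shoelace area matches hand and closed-form oracles", {
  sq <- contourPolygon(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  expect_equal(polygonArea(sq), 1)
  tri <- contourPolygon(cbind(c(0, 1, 0), c(0, 0, 1)))
  expect_equal(polygonArea(tri), 0.5)
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  gon <- contourPolygon(cbind(10 * cos(th), 10 * sin(th)))
  expect_equal(polygonArea(gon), 0.5 * 360 * 100 * sin(2 * pi / 360),
               tolerance = 1e-12)
  expect_error(polygonArea(rbind(c(0, 0), c(1, 1))), "3 vertices")
})

test_that("skin crossing returns the first contour crossing beyond the tip", {
  th <- seq(0, 2 * pi, length.out = 20001)[-20001]
  circ <- contourPolygon(cbind(100 * cos(th), 100 * sin(th)))
  m3 <- skinCrossing(c(0, 0), c(0, 80), circ)
  expect_equal(m3, c(0, 100), tolerance = 1e-3)
  ell <- contourPolygon(cbind(150 * cos(th), 100 * sin(th)))
  expect_equal(skinCrossing(c(0, 0), c(0, 50), ell), c(0, 100),
               tolerance = 1e-3)
  # 45-degree ray: analytic ray-ellipse intersection as oracle
  t45 <- sqrt(2) * 150 * 100 / sqrt(150^2 + 100^2)
  m3 <- skinCrossing(c(0, 0), c(10, 10), ell)
  expect_equal(sqrt(sum(m3^2)), t45, tolerance = 1e-3)
  expect_error(skinCrossing(c(0, 0), c(0, 0), circ), "must differ")
  # m2 outside the contour: no crossing with t > 1
  expect_error(skinCrossing(c(0, 0), c(0, 150), circ), "inconsistent")
})

test_that("quadrant areas match the hand-decomposed rectangle oracle", {
  sq <- contourPolygon(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  q <- quadrantAreas(sq, c(0.25, 0.25))
  # (+x left, +y posterior): a1 anterior-right = 0.25 x 0.25
  expect_equal(unname(q$areas),
               c(0.25 * 0.25, 0.75 * 0.25, 0.75 * 0.75, 0.25 * 0.75),
               tolerance = 1e-12)
  expect_equal(q$total, 1, tolerance = 1e-12)
  asp <- areaAspects(q)
  expect_equal(unname(asp), c(0.75, 0.75), tolerance = 1e-12)
  expect_error(quadrantAreas(sq, c(2, 2)), "inside")
})

test_that("quadrants of a centred circle are four equal parts", {
  th <- seq(0, 2 * pi, length.out = 3601)[-3601]
  circ <- contourPolygon(cbind(100 * cos(th), 100 * sin(th)))
  q <- quadrantAreas(circ, c(0, 0))
  expect_equal(unname(q$fractions), rep(0.25, 4), tolerance = 1e-6)
  expect_equal(unname(areaAspects(q)), c(0.5, 0.5), tolerance = 1e-6)
})

test_that("quadrant areas are conserved and mirror correctly on random polygons", {
  set.seed(99)
  for (k in 1:50) {
    star <- k %% 2 == 1
    v <- if (star) randomStarPolygon(sample(5:40, 1)) else
      randomConvexPolygon(sample(8:30, 1))
    poly <- contourPolygon(v)
    centre <- if (star) runif(2, -0.05, 0.05) else c(0, 0)
    q <- quadrantAreas(poly, centre)
    expect_equal(sum(q$areas), polygonArea(poly),
                 tolerance = 1e-9)
  }
  # mirrored contour: f_left -> 1 - f_left, f_back unchanged
  v <- randomStarPolygon(25)
  a <- areaAspects(quadrantAreas(contourPolygon(v), c(0.02, 0.03)))
  vm <- cbind(-v[, 1], v[, 2])
  b <- areaAspects(quadrantAreas(contourPolygon(vm), c(-0.02, 0.03)))
  expect_equal(b[["f_back"]], a[["f_back"]], tolerance = 1e-12)
  expect_equal(b[["f_left"]], 1 - a[["f_left"]], tolerance = 1e-12)
})

test_that("translation invariance and spacing scaling behave as expected", {
  spec <- quickSpec()
  ph <- makePhantom(spec, seed = 2)
  slice <- getSlice(ph$volume, 0)
  poly <- extractBodyContour(slice)
  mk <- phantomMarkers(spec, ph$truth)[[1]]
  m <- measureVertebra(slice, mk, poly)
  # joint translation of contour and markers changes nothing
  shift <- c(13.5, -7.25)
  poly2 <- contourPolygon(sweep(contourVertices(poly), 2, -shift))
  mk2 <- mk
  mk2$m1_px <- mk$m1_px + rev(shift) / slice@spacing
  mk2$m2_px <- mk$m2_px + rev(shift) / slice@spacing
  m2 <- measureVertebra(slice, mk2, poly2)
  expect_equal(m2$L12_mm, m$L12_mm, tolerance = 1e-9)
  expect_equal(m2$L13_mm, m$L13_mm, tolerance = 1e-6)
  expect_equal(m2$f_back, m$f_back, tolerance = 1e-6)
  # scaling the spacing scales lengths, leaves fractions unchanged
  s <- 2.5
  slice3 <- new("CTSlice", data = sliceData(slice),
                spacing = slice@spacing * s)
  poly3 <- contourPolygon(contourVertices(poly) * s)
  m3 <- measureVertebra(slice3, mk, poly3)
  expect_equal(m3$L12_mm, s * m$L12_mm, tolerance = 1e-9)
  expect_equal(m3$L13_mm, s * m$L13_mm, tolerance = 1e-9)
  expect_equal(m3$f_back, m$f_back, tolerance = 1e-9)
  expect_equal(m3$f_left, m$f_left, tolerance = 1e-9)
})

test_that("measurement on a phantom recovers the analytic truth", {
  spec <- quickSpec()
  ph <- makePhantom(spec, seed = 4)
  slice <- getSlice(ph$volume, 0)
  poly <- extractBodyContour(slice)
  mk <- phantomMarkers(spec, ph$truth)[[1]]
  m <- measureVertebra(slice, mk, poly)
  tol <- sqrt(sum(slice@spacing^2))   # one pixel diagonal
  expect_lt(abs(m$L12_mm - ph$truth@L12), tol)
  expect_lt(abs(m$L13_mm - ph$truth@L13), tol)
  expect_true(m$L13_mm >= m$L12_mm)
  # determinism
  expect_identical(m, measureVertebra(slice, mk, poly))
})

test_that("missing spinous tip degrades gracefully", {
  spec <- quickSpec()
  ph <- makePhantom(spec, seed = 4)
  slice <- getSlice(ph$volume, 0)
  poly <- extractBodyContour(slice)
  mk <- phantomMarkers(spec, ph$truth)[[1]]
  mk$m2_px <- NULL
  m <- measureVertebra(slice, mk, poly)
  expect_true(is.na(m$L12_mm) && is.na(m$L13_mm))
  expect_false(is.na(m$f_back) || is.na(m$f_left))
  # a substitute posterior direction restores L13 but not L12
  m2 <- measureVertebra(slice, mk, poly, substituteDirection = c(0, 1))
  expect_true(is.na(m2$L12_mm))
  expect_false(is.na(m2$L13_mm))
})
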