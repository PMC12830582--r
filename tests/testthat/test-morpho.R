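test_that("shoelace area and perimeter reproduce closed forms", {
  sq <- rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0), c(0, 0))
  expect_equal(polygonArea(sq), 1.0)
  expect_equal(polygonPerimeter(sq), 4.0)
  tri <- rbind(c(0, 0), c(0, 4), c(3, 0))
  expect_equal(polygonArea(tri), 6.0)
  # regular 1000-gon of circumradius 30: area 0.5*n*R^2*sin(2pi/n),
  # perimeter n*2R*sin(pi/n); both within 0.01% of the circle values
  n <- 1000L; R <- 30
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  poly <- cbind(R * cos(th), R * sin(th))
  expect_equal(polygonArea(poly), 0.5 * n * R^2 * sin(2 * pi / n))
  expect_lt(abs(polygonArea(poly) / (pi * R^2) - 1), 1e-4)
  expect_equal(polygonPerimeter(poly), n * 2 * R * sin(pi / n))
  expect_lt(abs(polygonPerimeter(poly) / (2 * pi * R) - 1), 1e-4)
  # orientation independence and repeated vertices
  expect_equal(polygonArea(sq[rev(seq_len(nrow(sq))), ]), 1.0)
  expect_equal(polygonPerimeter(rbind(sq, sq[1, ])), 4.0)
  expect_error(polygonArea(rbind(c(0, 0), c(1, 1))), "3 distinct")
})

test_that("deformation satisfies the isoperimetric identities", {
  # circle: exactly zero
  expect_equal(as.numeric(deformation(pi * 30^2, 2 * pi * 30)), 0)
  # square of side s: D = 1 - sqrt(pi)/2, independent of s
  for (s in c(1, 5, 137))
    expect_equal(as.numeric(deformation(s^2, 4 * s)), 1 - sqrt(pi) / 2,
                 tolerance = 1e-12)
  # ellipse 2:1 (a=20, b=10): dense-polygon perimeter agrees with
  # Ramanujan's approximation to 1e-3 and both give the same D
  a <- 20; b <- 10
  poly <- ellipsePolygon(a, b, n = 20000L)
  lPoly <- polygonPerimeter(poly)
  lRam <- ramanujanPerimeter(a, b)
  expect_lt(abs(lPoly - lRam) / lRam, 1e-3)
  dPoly <- as.numeric(deformation(polygonArea(poly), lPoly))
  dRam <- as.numeric(deformation(pi * a * b, lRam))
  expect_lt(abs(dPoly - dRam), 1e-3)
  expect_error(deformation(-1, 5), "positive")
  expect_error(deformation(5, 0), "positive")
})

test_that("deformation is scale invariant and monotone in elongation", {
  set.seed(3)
  base <- ellipsePolygon(17, 11, n = 4000L, phase = 0.3)
  d0 <- as.numeric(deformation(polygonArea(base), polygonPerimeter(base)))
  for (s in c(1e-3, 0.5, 7, 1e4)) {
    p <- base * s
    expect_equal(as.numeric(deformation(polygonArea(p),
                                        polygonPerimeter(p))),
                 d0, tolerance = 1e-12)
  }
  # same area, growing aspect ratio: D(circle) < D(2:1) < D(4:1)
  A <- 400 * pi
  dWith <- function(ar) {
    a <- sqrt(A * ar / pi); b <- A / (pi * a)
    p <- ellipsePolygon(a, b, n = 20000L)
    as.numeric(deformation(polygonArea(p), polygonPerimeter(p)))
  }
  expect_lt(dWith(1), dWith(2))
  expect_lt(dWith(2), dWith(4))
})

test_that("sub-pixel contours keep digitized circles near D = 0", {
  m <- diskMask(30)
  p <- extractContour(m)
  expect_lt(abs(polygonArea(p) / (pi * 30^2) - 1), 0.01)
  D <- deformation(polygonArea(p), polygonPerimeter(p))
  expect_lt(abs(as.numeric(D)), 0.02)
  # isoperimetric bound on digitized convex shapes with min radius >= 10:
  # raw D >= -0.02 and clamping is rare
  set.seed(8)
  raws <- replicate(25, {
    a <- runif(1, 10, 25); b <- runif(1, 10, a)
    ob <- renderObject(objectSpec("intact", semi_axes = c(a, b),
                                  orientation = runif(1, 0, pi)))
    p <- extractContour(ob$mask)
    attr(deformation(polygonArea(p), polygonPerimeter(p)), "raw")
  })
  expect_true(all(raws >= -0.02))
  expect_lt(mean(raws < 0), 0.01 + 1e-9)
})

test_that("event features assemble area, deformation and shape measures", {
  m <- diskMask(30)
  ev <- list(mask = m, crop = matrix(100L, nrow(m), ncol(m)),
             contour = extractContour(m), crop_offset = c(0L, 0L))
  f <- computeEventFeatures(ev, pixel_size_um = 0.5)
  expect_lt(abs(f$A_um2 / (pi * 15^2) - 1), 0.02)
  f1 <- computeEventFeatures(ev, pixel_size_um = 1.0)
  expect_equal(f1$A_um2, 4 * f$A_um2)
  expect_lt(abs(f$aspect_ratio - 1), 0.02)
  expect_equal(f$mean_brightness, 100)
})

test_that("KDE mode estimation is accurate and deterministic", {
  expect_equal(estimateMode(rep(0.05, 1000))$mode, 0.05)
  expect_error(estimateMode(numeric(0)), "empty")
  set.seed(21)
  v <- rnorm(9000, 0.06, 0.01)
  expect_lt(abs(estimateMode(v)$mode - 0.06), 0.005)
  # bimodal: mode sits at the taller peak
  set.seed(22)
  w <- c(rnorm(3000, 0, 0.5), rnorm(1000, 4, 0.5))
  expect_lt(abs(estimateMode(w)$mode - 0), 0.5)
  # consistency: error shrinks from n = 1e3 to n = 1e4
  set.seed(23)
  e1 <- abs(estimateMode(rnorm(1e3, 0.06, 0.01))$mode - 0.06)
  e2 <- abs(estimateMode(rnorm(1e4, 0.06, 0.01))$mode - 0.06)
  expect_lt(e2, e1)
  # determinism
  expect_identical(estimateMode(v), estimateMode(v))
})

test_that("sample summaries normalize fractions and gate on intact events", {
  f <- data.frame(deform = c(rep(0.05, 90), rep(0.2, 10)),
                  A_um2 = c(rep(50, 90), rep(20, 10)))
  labs <- c(rep("intact", 90), rep("dead", 10))
  s <- suppressWarnings(summarizeSample(f, labs, droplet_counts = rep(0, 100)))
  expect_equal(unname(s@classFractions["intact"]), 0.9)
  expect_equal(unname(s@classFractions["dead"]), 0.1)
  expect_equal(sum(s@classFractions), 1.0)
  expect_equal(s@meanDroplets, 0.0)
  expect_true(s@lowCount)
  expect_warning(summarizeSample(f, labs), "intact")
  # fractions sum to one for arbitrary label mixes
  set.seed(9)
  for (i in 1:5) {
    n <- sample(5:50, 1)
    labs2 <- sample(eventClasses(), n, replace = TRUE)
    f2 <- data.frame(deform = runif(n, 0, 0.3), A_um2 = runif(n, 10, 90))
    s2 <- suppressWarnings(summarizeSample(f2, labs2, min_intact = 1L))
    expect_equal(sum(s2@classFractions), 1.0)
  }
  expect_error(summarizeSample(f[0, ], character(0)), "zero events")
  expect_error(suppressWarnings(summarizeSample(f, rep("odd", 100))),
               "unknown class")
})
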