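test_that("rendered masks match the analytic polygon geometry", {
  set.seed(10)
  # intact ellipse: mask area within 2% of pi*a*b, no droplets
  for (ab in list(c(20, 16), c(25, 20), c(18, 15))) {
    ob <- renderObject(objectSpec("intact", semi_axes = ab))
    expect_lt(abs(sum(ob$mask) / (pi * ab[1] * ab[2]) - 1), 0.02)
    expect_equal(ob$area_px2, polygonArea(ob$polygon))
  }
  # ground-truth geometry invariant across sampled classes (min semi-axis
  # >= 10 px): rasterized area within 2% of the polygon area
  for (cl in c("intact", "anomalous")) {
    for (i in 1:5) {
      sp <- sampleObjectSpec(cl)
      ob <- renderObject(sp)
      expect_lt(abs(sum(ob$mask) / ob$area_px2 - 1), 0.02)
    }
  }
})

test_that("droplets are rendered as disjoint dark disks inside the mask", {
  set.seed(11)
  sp <- objectSpec("intact", semi_axes = c(24, 20), n_droplets = 3)
  ob <- renderObject(sp)
  expect_identical(nrow(ob$droplets), 3L)
  # disjoint: pairwise center distances exceed two radii
  d <- as.matrix(dist(ob$droplets[, c("row", "col")]))
  expect_true(all(d[upper.tri(d)] > 2 * ob$droplets$radius[1]))
  # inside: every droplet center lies well inside the mask
  for (i in 1:3) {
    rr <- round(ob$droplets$row[i]) + 1L
    cc <- round(ob$droplets$col[i]) + 1L
    expect_true(ob$mask[rr, cc])
  }
  # dark: droplet center pixels darker than the interior median
  interior <- stats::median(ob$patch[ob$mask])
  for (i in 1:3)
    expect_lt(ob$patch[round(ob$droplets$row[i]) + 1L,
                       round(ob$droplets$col[i]) + 1L], interior - 30)
})

test_that("aggregates render as one connected component and can be small", {
  set.seed(12)
  members <- list(
    list(offset = c(0, -8), semi_axes = c(14, 12), orientation = 0),
    list(offset = c(0, 8), semi_axes = c(14, 12), orientation = 0))
  sp <- objectSpec("aggregate", semi_axes = c(14, 12), members = members)
  ob <- renderObject(sp)
  lab <- dcshape:::ebLabel(ob$mask)
  expect_identical(max(lab), 1L)
  # debris stays below a quarter of the median intact area
  intactAreas <- replicate(9, sum(renderObject(
    sampleObjectSpec("intact"))$mask))
  for (i in 1:5) {
    deb <- renderObject(sampleObjectSpec("debris"))
    expect_lt(sum(deb$mask), 0.25 * stats::median(intactAreas))
  }
})

test_that("frame generation is deterministic and manifests are complete", {
  mkspecs <- function() lapply(1:3, function(i)
    frameSpec(objects = list(objectSpec("intact", center = c(48, 60 + 40 * i),
                                        semi_axes = c(15, 12)))))
  a <- generateFrames(mkspecs(), seed = 7)
  b <- generateFrames(mkspecs(), seed = 7)
  expect_identical(a$frames, b$frames)
  expect_identical(a$manifest$objects, b$manifest$objects)
  expect_identical(nrow(a$manifest$objects), 3L)
  expect_identical(a$manifest$objects$frame_index, 0:2)
  # empty spec: pure background frame, empty manifest
  e <- generateFrames(list(frameSpec(noise_sigma = 2)), seed = 1)
  expect_identical(nrow(e$manifest$objects), 0L)
  expect_lt(stats::sd(as.numeric(e$frames[[1]])), 5)
  # ground-truth polygons are closed
  expect_true(all(vapply(a$manifest$polygons, function(p)
    all(p[1, ] == p[nrow(p), ]), logical(1))))
})

test_that("object placement respects frame bounds and separation", {
  # explicit center too close to the border is rejected
  sp <- objectSpec("intact", center = c(10, 128), semi_axes = c(20, 18))
  expect_error(generateFrames(list(frameSpec(objects = list(sp))), seed = 1),
               "fit inside frame")
  # saturation is reported with the frame index
  crowded <- frameSpec(height = 96L, width = 128L,
                       objects = replicate(6, sampleObjectSpec("intact"),
                                           simplify = FALSE))
  expect_error(generateFrames(list(crowded), seed = 1), "saturation")
})

test_that("labeled training sets honor requested counts and class layout", {
  counts <- c(intact = 8, anomalous = 5, dead = 4, aggregate = 3, debris = 2)
  dir <- withr::local_tempdir()
  ts <- generateTrainingSet(counts, out_dir = dir, seed = 3)
  expect_identical(as.integer(table(ts$labels)[names(counts)]),
                   as.integer(counts))
  for (cl in names(counts))
    expect_length(list.files(file.path(dir, cl)), counts[[cl]])
  # crop sizes vary
  expect_gt(length(unique(vapply(ts$images, nrow, integer(1)))), 1L)
  # zero-count class absent
  ts0 <- generateTrainingSet(c(intact = 4, dead = 0), seed = 4)
  expect_identical(sort(unique(ts0$labels)), "intact")
  # determinism
  ts2 <- generateTrainingSet(counts, seed = 3)
  expect_identical(ts$images, ts2$images)
})

test_that("training sets at a tenth of the reference class sizes", {
  scaled <- c(intact = 490L, anomalous = 146L, dead = 253L,
              aggregate = 78L, debris = 183L)
  ts <- generateTrainingSet(scaled, seed = 5)
  expect_identical(as.integer(table(ts$labels)[names(scaled)]),
                   unname(scaled))
  expect_length(ts$images, 1150L)
})
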