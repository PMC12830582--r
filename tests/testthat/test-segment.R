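test_that("temporal-median background suppresses transient objects", {
  p <- segmentationParams()
  # static scene: background equals the scene up to the noise floor
  base <- matrix(150L, 40, 60)
  frames <- withr::with_seed(1, lapply(1:12, function(i)
    dcshape:::clip8(base + rnorm(length(base), 0, 2))))
  bg <- estimateBackground(frames, p)
  expect_s4_class(bg, "BackgroundModel")
  expect_lt(max(abs(bg@background - 150)), 4)
  # a pixel covered by an object in under half the frames drops out
  frames2 <- frames
  for (i in 1:5) frames2[[i]][10:20, 10:20] <- 40L   # 5 of 12 frames
  bg2 <- estimateBackground(frames2, p)
  expect_lt(max(abs(bg2@background[10:20, 10:20] - 150)), 8)
  # constant frames with one outlier frame: median keeps the constant
  frames3 <- c(replicate(9, base, simplify = FALSE),
               list(matrix(250L, 40, 60)))
  expect_equal(max(abs(estimateBackground(frames3, p)@background - 150)), 0)
  expect_error(estimateBackground(frames[1], p), "single frame")
  expect_error(estimateBackground(list(base, matrix(0L, 5, 5)), p),
               "one shape")
})

test_that("event detection finds planted objects and nothing on blanks", {
  # blank frame: zero events
  blank <- generateFrames(rep(list(frameSpec()), 8), seed = 5)
  bg <- estimateBackground(blank$frames, segmentationParams())
  expect_length(detectEvents(blank$frames[[1]], bg), 0L)
  # three well-separated intact cells: exactly three events
  objs <- list(objectSpec("intact", center = c(48, 60), semi_axes = c(16, 13)),
               objectSpec("intact", center = c(40, 150), semi_axes = c(18, 15)),
               objectSpec("intact", center = c(55, 220), semi_axes = c(14, 12)))
  sc <- generateFrames(c(list(frameSpec(objects = objs)),
                         rep(list(frameSpec()), 7)), seed = 6)
  bg2 <- estimateBackground(sc$frames, segmentationParams())
  ev <- detectEvents(sc$frames[[1]], bg2, frame_index = 0L)
  expect_length(ev, 3L)
  expect_true(all(vapply(ev, function(e) max(dcshape:::ebLabel(e$mask)),
                         integer(1)) == 1L))
  # an object below the area gate is dropped
  tiny <- generateFrames(c(list(frameSpec(objects = list(
    objectSpec("debris", center = c(48, 128), semi_axes = c(3.5, 3))))),
    rep(list(frameSpec()), 7)), seed = 7)
  bg3 <- estimateBackground(tiny$frames, segmentationParams())
  expect_length(detectEvents(tiny$frames[[1]], bg3), 0L)
})

test_that("raising the threshold never increases the detection count", {
  sc <- sampleScene(1, 4, seed = 31)
  frames <- c(sc$frames, generateFrames(rep(list(
    frameSpec(height = 128L, width = 512L)), 7), seed = 32)$frames)
  bg <- estimateBackground(frames, segmentationParams())
  counts <- vapply(c(6, 10, 16, 24, 40), function(th)
    length(detectEvents(frames[[1]], bg,
                        segmentationParams(threshold_offset = th))),
    integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detection is deterministic", {
  sc <- sampleScene(3, 3, seed = 33)
  a <- segmentFrames(sc$frames)
  b <- segmentFrames(sc$frames)
  expect_identical(crops(a), crops(b))
  expect_identical(contours(a), contours(b))
})

test_that("sub-pixel contours are closed, CCW and mask-consistent", {
  m <- diskMask(12)
  p <- extractContour(m)
  expect_identical(unname(p[1, ]), unname(p[nrow(p), ]))
  # CCW: positive signed area with x = col, y = row
  q <- p[-nrow(p), ]
  x <- q[, 2]; y <- q[, 1]
  expect_gt(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2, 0)
  # interior hole pre-filled gives the identical contour
  holed <- m
  holed[20:24, 20:24] <- FALSE   # strictly interior hole
  expect_identical(extractContour(dcshape:::ebFillHull(holed)), p)
  # degenerate masks are rejected
  one <- matrix(FALSE, 9, 9); one[5, 5] <- TRUE
  expect_error(extractContour(one), "5 px")
  expect_error(extractContour(matrix(FALSE, 4, 4)), "empty")
  two <- matrix(FALSE, 12, 12); two[2:4, 2:4] <- TRUE; two[8:10, 8:10] <- TRUE
  expect_error(extractContour(two), "one connected component")
})

test_that("greedy ground-truth matching is one-to-one by descending IoU", {
  sc <- sampleScene(5, 3, seed = 41)
  es <- segmentFrames(sc$frames)
  m <- matchToGroundTruth(es, sc$manifest, c(128, 512), iou_min = 0.5)
  expect_identical(m$tp + m$fn, nrow(sc$manifest$objects))
  expect_identical(m$tp + m$fp, nEvents(es))
  expect_true(all(!duplicated(m$pairs$det)) && all(!duplicated(m$pairs$gt)))
  expect_true(all(m$pairs$iou >= 0.5))
  # empty detection: every ground-truth object is a false negative
  blank <- segmentFrames(generateFrames(rep(list(
    frameSpec(height = 128L, width = 512L)), 3), seed = 42)$frames)
  m0 <- matchToGroundTruth(blank, sc$manifest, c(128, 512))
  expect_identical(m0$fn, nrow(sc$manifest$objects))
  expect_identical(m0$tp, 0L)
  # a detection overlapping two objects pairs with the higher-IoU one
  det <- m$pairs[1, ]
  ious <- vapply(seq_len(nrow(sc$manifest$objects)), function(j) {
    if (sc$manifest$objects$frame_index[j] != frameIndex(es)[det$det])
      return(0)
    dm <- dcshape:::eventFrameMask(es, det$det, c(128, 512))
    bb <- sc$manifest$masks[[j]]$bbox
    gm <- matrix(FALSE, 128, 512)
    gm[(bb[1] + 1):bb[3], (bb[2] + 1):bb[4]] <- sc$manifest$masks[[j]]$mask
    sum(dm & gm) / sum(dm | gm)
  }, numeric(1))
  expect_identical(which.max(ious), as.integer(det$gt))
})
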