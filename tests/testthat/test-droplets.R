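test_that("droplet counting recovers planted inclusions exactly", {
  set.seed(71)
  # uniform interior, no inclusions
  ob0 <- renderObject(objectSpec("intact", semi_axes = c(20, 17),
                                 texture_sigma = 0))
  expect_identical(detectDroplets(ob0$patch, ob0$mask)$n_droplets, 0L)
  # three disks at default contrast
  ob3 <- renderObject(objectSpec("intact", semi_axes = c(24, 20),
                                 n_droplets = 3))
  r3 <- detectDroplets(ob3$patch, ob3$mask)
  expect_identical(r3$n_droplets, 3L)
  expect_length(r3$droplet_areas_px2, 3L)
  expect_gt(r3$total_droplet_area_fraction, 0)
  # planted 0..5 with rendering noise: counts match the ground truth
  hits <- 0L; tot <- 0L
  for (nd in rep(0:5, 6)) {
    sp <- sampleObjectSpec("intact", n_droplets = nd)
    ob <- renderObject(sp, background_level = 190, noise_sigma = 3)
    hits <- hits + (detectDroplets(ob$patch, ob$mask)$n_droplets == nd)
    tot <- tot + 1L
  }
  expect_gte(hits / tot, 0.9)
})

test_that("area gates and rim exclusion suppress spurious inclusions", {
  set.seed(72)
  ob <- renderObject(objectSpec("intact", semi_axes = c(22, 19),
                                texture_sigma = 0, n_droplets = 1))
  base <- detectDroplets(ob$patch, ob$mask)
  expect_identical(base$n_droplets, 1L)
  # a 2-px dark speck below the minimum area does not change the count
  patch <- ob$patch
  ctr <- round(ob$center) + 1L
  patch[ctr[1] + 8, ctr[2] + c(0, 1)] <- 40L
  withSpeck <- detectDroplets(patch, ob$mask)
  expect_identical(withSpeck$n_droplets, 1L)
  # darkening the boundary ring (rim artifact) adds no droplets
  dist <- dcshape:::plainMat(EBImage::distmap(EBImage::Image(ob$mask * 1)))
  ring <- ob$mask & dist <= 2
  patch2 <- ob$patch
  patch2[ring] <- 60L
  expect_identical(detectDroplets(patch2, ob$mask)$n_droplets, 1L)
  # inclusions fainter than the relative threshold are not detected
  faint <- renderObject(objectSpec("intact", semi_axes = c(22, 19),
                                   texture_sigma = 0, n_droplets = 2,
                                   droplet_contrast = 8))
  expect_identical(detectDroplets(faint$patch, faint$mask)$n_droplets, 0L)
})

test_that("adding an inclusion never decreases the count", {
  set.seed(73)
  for (i in 1:4) {
    sp <- sampleObjectSpec("intact", n_droplets = 2L)
    ob <- renderObject(sp)
    n2 <- detectDroplets(ob$patch, ob$mask)$n_droplets
    # re-render the same cell with one more droplet
    sp3 <- sp; sp3$n_droplets <- 3L
    ob3 <- renderObject(sp3)
    n3 <- detectDroplets(ob3$patch, ob3$mask)$n_droplets
    expect_gte(n3, n2)
  }
})

test_that("tiny cells yield a flagged zero rather than an error", {
  m <- matrix(FALSE, 9, 9); m[4:6, 4:6] <- TRUE
  r <- detectDroplets(matrix(100L, 9, 9), m)
  expect_identical(r$n_droplets, 0L)
  expect_identical(r$flag, "empty_eroded_mask")
})

test_that("sample droplet statistics average over intact cells only", {
  s <- dropletStats(c(0, 0, 3, 7), c(0, 0, 0.1, 0.5),
                    c("intact", "intact", "intact", "dead"))
  expect_equal(s$mean_droplets_per_cell, 1.0)
  expect_identical(s$n, 3L)
  z <- dropletStats(c(0, 0), c(0, 0), c("intact", "intact"))
  expect_equal(z$mean_droplets_per_cell, 0.0)
  expect_equal(z$mean_droplet_area_per_cell, 0.0)
  expect_error(dropletStats(1, 0.1, "dead"), "zero intact")
  # Poisson-planted droplets: the sample mean recovers the rate
  set.seed(74)
  nd <- pmin(rpois(400, 2), 5L)
  counts <- integer(length(nd))
  for (i in seq_along(nd)) {
    ob <- renderObject(sampleObjectSpec("intact", n_droplets = nd[i]),
                       background_level = 190, noise_sigma = 3)
    counts[i] <- detectDroplets(ob$patch, ob$mask)$n_droplets
  }
  st <- dropletStats(counts, numeric(length(nd)),
                     rep("intact", length(nd)))
  expect_lt(abs(st$mean_droplets_per_cell - mean(nd)), 0.15)
  expect_lt(abs(st$mean_droplets_per_cell - 2), 0.2)
})
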