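test_that("preprocessing resizes, normalizes and stays deterministic", {
  crop <- matrix(sample(0:255, 50 * 80, TRUE), 50, 80)
  st <- list(mu = 100, sd = 25)
  x <- preprocessCrop(crop, 224L, st)
  expect_identical(dim(x), c(224L, 224L))
  expect_identical(x, preprocessCrop(crop, 224L, st))
  # constant image at mu maps to all zeros
  z <- preprocessCrop(matrix(100, 30, 30), 64L, st)
  expect_equal(max(abs(z)), 0)
  expect_error(preprocessCrop(matrix(numeric(0), 0, 0)), "zero-size")
})

test_that("augmentation families behave as documented", {
  img <- matrix(sample(0:255, 40 * 40, TRUE), 40, 40)
  off <- c(crop = FALSE, rotation = FALSE, hflip = FALSE, affine = FALSE,
           perspective = FALSE, brightness_contrast = FALSE)
  expect_identical(augmentImage(img, off), img)
  # hflip-only with probability 1 mirrors left-right
  hf <- off; hf["hflip"] <- TRUE
  expect_identical(augmentImage(img, hf, p = 1), img[, 40:1])
  # seeded streams replay identically
  all_on <- !off
  a <- withr::with_seed(5, replicate(4, augmentImage(img, all_on),
                                     simplify = FALSE))
  b <- withr::with_seed(5, replicate(4, augmentImage(img, all_on),
                                     simplify = FALSE))
  expect_identical(a, b)
})

test_that("stratified splits preserve proportions without overlap", {
  labels <- rep(c("intact", "dead"), each = 100)
  sp <- stratifiedSplit(labels, 0.2, seed = 1)
  expect_identical(length(sp$val), 40L)
  expect_identical(sum(labels[sp$val] == "intact"), 20L)
  expect_length(intersect(sp$train, sp$val), 0L)
  expect_setequal(c(sp$train, sp$val), seq_along(labels))
  expect_identical(sp, stratifiedSplit(labels, 0.2, seed = 1))
  # the documented rounding rule on the scaled reference counts
  counts <- c(intact = 490, anomalous = 146, dead = 253, aggregate = 78,
              debris = 183)
  labels2 <- rep(names(counts), counts)
  sp2 <- stratifiedSplit(labels2, 0.2, seed = 2)
  valCounts <- table(labels2[sp2$val])[names(counts)]
  expect_identical(unname(as.integer(valCounts)), c(98L, 29L, 51L, 16L, 37L))
  expect_error(stratifiedSplit(c("a", "b", "b"), 0.2, 1), "fewer than 2")
})

test_that("inverse-frequency weights follow w = N/(K n) exactly", {
  expect_equal(unname(classWeights(c(a = 10, b = 10, c = 10))), rep(1, 3))
  counts <- c(intact = 4904, anomalous = 1456, dead = 2525, aggregate = 784,
              debris = 1829)
  w <- classWeights(counts)
  N <- sum(counts)
  expect_equal(unname(w["intact"]), N / (5 * 4904))
  expect_equal(unname(w["aggregate"]), N / (5 * 784))
  expect_equal(round(unname(w["intact"]), 3), 0.469)
  expect_equal(round(unname(w["aggregate"]), 3), 2.933)
  # count-weighted mean of weights is exactly one
  expect_equal(sum(counts * w), N)
  expect_equal(classWeights(2 * counts), w)
  expect_error(classWeights(c(a = 5, b = 0)), "zero-count")
})

test_that("the network produces 5-class logits and a fast tiny variant", {
  cfg <- trainConfig(backbone = "tiny", input_size = 64L, seed = 1)
  m <- withr::with_seed(1, buildModel(cfg))
  expect_gt(m$n_par, 1e5)
  X <- array(rnorm(64 * 64), c(64 * 64, 1, 1))
  t0 <- Sys.time()
  logits <- dcshape:::nnModelForward(m, X, training = FALSE)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1)
  expect_identical(dim(logits), c(5L, 1L))
  # dropout only perturbs the forward pass in training mode
  d1 <- dcshape:::nnModelForward(m, X, training = FALSE)
  expect_identical(logits, d1)
  # the full ResNet18-style backbone builds at the reference input geometry
  big <- withr::with_seed(1, buildModel(trainConfig(backbone = "resnet18",
                                                    input_size = 224L)))
  expect_gt(big$n_par, 1e7)
  nm <- vapply(big$layers, function(l) l$type, character(1))
  expect_identical(nm[1:4], c("conv", "bn", "relu", "maxpool"))
  expect_identical(sum(nm == "resblock"), 8L)
  expect_identical(tail(nm, 5),
                   c("flatten", "dense", "relu", "dropout", "dense"))
})

test_that("training converges, stops early and restores the best epoch", {
  sets <- smallTrainValSets(30, seed = 61)
  cfg <- trainConfig(backbone = "tiny", input_size = 32L, epochs = 3L,
                     lr = 1e-3, batch_size = 32L, seed = 1)
  clf <- trainClassifier(sets$train, sets$val, cfg)
  expect_s4_class(clf, "DCClassifier")
  expect_lte(nrow(clf@history), 3L)
  expect_lt(clf@history$train_loss[3], clf@history$train_loss[1])
  # reproducibility under the seed
  clf2 <- trainClassifier(sets$train, sets$val, cfg)
  expect_identical(clf@history, clf2@history)
  # frozen run (lr = 0): validation loss cannot improve after the first
  # epoch, so early stopping halts before the epoch limit
  cfg0 <- trainConfig(backbone = "tiny", input_size = 32L, epochs = 30L,
                      lr = 0, batch_size = 32L, early_stop_patience = 2L,
                      seed = 1,
                      augment = c(crop = FALSE, rotation = FALSE,
                                  hflip = FALSE, affine = FALSE,
                                  perspective = FALSE,
                                  brightness_contrast = FALSE))
  clf0 <- trainClassifier(sets$train, sets$val, cfg0)
  # halts before the epoch limit (batch-norm running statistics still
  # evolve over the first epochs, so the exact stop point is not epoch 3)
  expect_lt(nrow(clf0@history), 30L)
  expect_gte(nrow(clf0@history), 3L)
  # best-epoch weights restored: re-evaluated val loss equals the minimum
  yVa <- match(sets$val$labels, clf@labels)
  inputs <- lapply(sets$val$images, preprocessCrop, 32L, clf@normStats)
  w <- stats::setNames(rep(1, 5), clf@labels)
  ev <- dcshape:::evalModel(clf@model, inputs, yVa,
                            classWeights(table(sets$train$labels))[clf@labels],
                            32L)
  expect_equal(ev$loss, min(clf@history$val_loss), tolerance = 1e-8)
})

test_that("predictions are proper probabilities and deterministic", {
  sets <- smallTrainValSets(25, seed = 62)
  cfg <- trainConfig(backbone = "tiny", input_size = 32L, epochs = 2L,
                     lr = 1e-3, batch_size = 32L, seed = 2)
  clf <- trainClassifier(sets$train, sets$val, cfg)
  pr <- predictEvents(clf, sets$val$images)
  expect_equal(unname(rowSums(pr$probs)), rep(1, length(sets$val$images)),
               tolerance = 1e-6)
  expect_true(all(pr$labels %in% eventClasses()))
  pr2 <- predictEvents(clf, sets$val$images)
  expect_identical(pr$probs, pr2$probs)
  # save / load round trip preserves predictions
  f <- withr::local_tempfile(fileext = ".rds")
  saveClassifier(clf, f)
  expect_true(file.exists(paste0(f, ".json")))
  clf2 <- loadClassifier(f)
  pr3 <- predictEvents(clf2, sets$val$images)
  expect_equal(pr$probs, pr3$probs, tolerance = 1e-12)
})

test_that("confusion matrices count correctly with row sums preserved", {
  cm <- confusionMatrix(c("intact", "dead"), c("intact", "intact"))
  expect_identical(cm$counts["intact", "intact"], 1L)
  expect_identical(cm$counts["dead", "intact"], 1L)
  expect_identical(sum(cm$counts), 2L)
  # perfect predictions: identity pattern, unit recalls
  labs <- rep(eventClasses(), times = c(5, 4, 3, 2, 1))
  cmP <- confusionMatrix(labs, labs)
  expect_identical(unname(diag(cmP$counts)), c(5L, 4L, 3L, 2L, 1L))
  expect_equal(unname(cmP$recall), rep(1, 5))
  # everything predicted debris: all mass in the debris column
  cmD <- confusionMatrix(labs, rep("debris", length(labs)))
  expect_identical(as.integer(rowSums(cmD$counts)), c(5L, 4L, 3L, 2L, 1L))
  expect_identical(sum(cmD$counts[, "debris"]), length(labs))
  # hand-built 5x5 example: recall = diagonal / row sum
  set.seed(7)
  tl <- sample(eventClasses(), 60, TRUE)
  pl <- sample(eventClasses(), 60, TRUE)
  cmH <- confusionMatrix(tl, pl)
  for (cl in eventClasses()) {
    rs <- sum(tl == cl)
    expect_identical(sum(cmH$counts[cl, ]), rs)
    if (rs > 0)
      expect_equal(unname(cmH$recall[cl]),
                   sum(tl == cl & pl == cl) / rs)
  }
  expect_error(confusionMatrix("intact", "weird"), "unknown label")
})
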