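# Five-class event-image classification: preprocessing, augmentation,
# stratified splitting, inverse-frequency class weights, model construction
# (ResNet18-style and a tiny 2-stage variant), training with early stopping
# and LR-on-plateau, prediction and confusion matrices.

#' Preprocess a crop into a normalized model input
#'
#' Bilinear resize to `input_size` x `input_size`, single grayscale channel,
#' then standardization with the training-set statistics.  Deterministic (no
#' augmentation happens here).
#'
#' @param crop 8-bit matrix of any rectangular size.
#' @param input_size side of the square output (default 224).
#' @param stats list with `mu` and `sd` computed from training pixels.
#' @return `input_size` x `input_size` double matrix.
#' @export
preprocessCrop <- function(crop, input_size = 224L,
                           stats = list(mu = 0, sd = 1)) {
  if (is.null(dim(crop)) || any(dim(crop) == 0L)) stop("zero-size crop")
  m <- ebResize(crop + 0, input_size, input_size)
  (m - stats$mu) / stats$sd
}

## --- geometric warps ------------------------------------------------------

## bilinear inverse warp: H maps output (row, col, 1) -> source coordinates
warpImage <- function(img, H, bg = NULL) {
  h <- nrow(img); w <- ncol(img)
  if (is.null(bg)) bg <- stats::median(c(img[1, ], img[h, ], img[, 1],
                                         img[, w]))
  rr <- matrix(0:(h - 1), h, w)
  cc <- matrix(0:(w - 1), h, w, byrow = TRUE)
  den <- H[3, 1] * rr + H[3, 2] * cc + H[3, 3]
  sr <- (H[1, 1] * rr + H[1, 2] * cc + H[1, 3]) / den
  sc <- (H[2, 1] * rr + H[2, 2] * cc + H[2, 3]) / den
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  inside <- r0 >= 0 & c0 >= 0 & r0 <= h - 2 & c0 <= w - 2
  r0c <- pmin(pmax(r0, 0), h - 2) + 1
  c0c <- pmin(pmax(c0, 0), w - 2) + 1
  g <- function(dr, dc) img[cbind(as.vector(r0c + dr), as.vector(c0c + dc))]
  v <- (1 - fr) * (1 - fc) * g(0, 0) + fr * (1 - fc) * g(1, 0) +
    (1 - fr) * fc * g(0, 1) + fr * fc * g(1, 1)
  out <- matrix(v, h, w)
  out[!inside] <- bg
  out
}

## homography (output -> source) from 4 point correspondences, DLT
solveHomography <- function(dst, src) {
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    r <- dst[i, 1]; c <- dst[i, 2]; R <- src[i, 1]; C <- src[i, 2]
    A[2 * i - 1, ] <- c(r, c, 1, 0, 0, 0, -r * R, -c * R); b[2 * i - 1] <- R
    A[2 * i, ] <- c(0, 0, 0, r, c, 1, -r * C, -c * C); b[2 * i] <- C
  }
  h <- solve(A, b)
  matrix(c(h[1:3], h[4:6], h[7:8], 1), 3, 3, byrow = TRUE)
}

centeredAffine <- function(h, w, ang = 0, scale = c(1, 1), shear = 0,
                           shift = c(0, 0)) {
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  R <- matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2, 2, byrow = TRUE)
  S <- matrix(c(1 / scale[1], shear, 0, 1 / scale[2]), 2, 2, byrow = TRUE)
  M <- R %*% S
  H <- diag(3)
  H[1:2, 1:2] <- M
  H[1:2, 3] <- c(cy, cx) - M %*% c(cy + shift[1], cx + shift[2])
  H
}

#' Randomly augment a training image
#'
#' Applies up to six transform families — random cropping, rotation,
#' horizontal flip, affine adjustment, perspective distortion and
#' brightness/contrast variation — each with probability `p` when enabled.
#' Draws from the current RNG stream, so a seeded caller gets a reproducible
#' augmentation sequence.  With all toggles off this is the identity.
#'
#' @param img 8-bit matrix.
#' @param toggles named logical vector over the six families (as in
#'   [trainConfig()]'s `augment`).
#' @param p per-family application probability (default 0.5).
#' @return augmented 8-bit integer matrix (size may change under cropping).
#' @export
augmentImage <- function(img, toggles = c(crop = TRUE, rotation = TRUE,
                                          hflip = TRUE, affine = TRUE,
                                          perspective = TRUE,
                                          brightness_contrast = TRUE),
                         p = 0.5) {
  out <- img + 0
  h <- nrow(out); w <- ncol(out)
  if (isTRUE(toggles["crop"]) && stats::runif(1) < p) {
    s <- stats::runif(1, 0.8, 1)
    ch <- max(8L, round(h * s)); cw <- max(8L, round(w * s))
    r0 <- sample.int(h - ch + 1L, 1L); c0 <- sample.int(w - cw + 1L, 1L)
    out <- out[r0:(r0 + ch - 1L), c0:(c0 + cw - 1L), drop = FALSE]
    h <- ch; w <- cw
  }
  if (isTRUE(toggles["rotation"]) && stats::runif(1) < p) {
    ang <- stats::runif(1, -pi / 12, pi / 12)
    out <- warpImage(out, centeredAffine(h, w, ang = ang))
  }
  if (isTRUE(toggles["hflip"]) && stats::runif(1) < p)
    out <- out[, w:1, drop = FALSE]
  if (isTRUE(toggles["affine"]) && stats::runif(1) < p) {
    H <- centeredAffine(h, w, scale = stats::runif(2, 0.9, 1.1),
                        shear = stats::runif(1, -0.1, 0.1),
                        shift = stats::runif(2, -0.05, 0.05) * c(h, w))
    out <- warpImage(out, H)
  }
  if (isTRUE(toggles["perspective"]) && stats::runif(1) < p) {
    j <- 0.06
    dst <- rbind(c(0, 0), c(0, w - 1), c(h - 1, w - 1), c(h - 1, 0))
    src <- dst + cbind(stats::runif(4, -j, j) * h, stats::runif(4, -j, j) * w)
    out <- warpImage(out, solveHomography(dst, src))
  }
  if (isTRUE(toggles["brightness_contrast"]) && stats::runif(1) < p) {
    ct <- stats::runif(1, 0.9, 1.1); br <- stats::runif(1, -15, 15)
    out <- (out - 128) * ct + 128 + br
  }
  clip8(out)
}

#' Stratified train/validation split
#'
#' Per-class split preserving class proportions: the validation count of a
#' class with n items is `max(1, round(val_fraction * n))`; the rest train.
#' No overlap; the union is the full dataset; identical seeds give identical
#' splits.
#'
#' @param labels character vector of class labels.
#' @param val_fraction validation fraction (default 0.2).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `val`.
#' @export
#' @examples
#' stratifiedSplit(rep(c("a", "b"), each = 10), 0.2, seed = 1)
stratifiedSplit <- function(labels, val_fraction = 0.2, seed = 1L) {
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("val_fraction must be in (0, 1)")
  tab <- table(labels)
  small <- names(tab)[tab < 2L]
  if (length(small))
    stop("class with fewer than 2 items: ", paste(small, collapse = ", "))
  withSeed(seed, {
    val <- integer(0)
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      nv <- max(1L, as.integer(round(val_fraction * length(idx))))
      val <- c(val, sort(sample(idx, nv)))
    }
    val <- sort(val)
    list(train = setdiff(seq_along(labels), val), val = val)
  })
}

#' Inverse-frequency class weights
#'
#' w_c = N / (K * n_c) over the K classes present, so rare classes weigh
#' more; the count-weighted mean of the weights is exactly 1
#' (sum_c n_c * w_c = N).
#'
#' @param counts named integer vector of per-class training counts.
#' @return named numeric vector of weights.
#' @export
#' @examples
#' classWeights(c(intact = 4904, anomalous = 1456, dead = 2525,
#'                aggregate = 784, debris = 1829))
classWeights <- function(counts) {
  if (any(counts <= 0))
    stop("zero-count class present in training: ",
         paste(names(counts)[counts <= 0], collapse = ", "))
  N <- sum(counts)
  K <- length(counts)
  w <- N / (K * counts)
  names(w) <- names(counts)
  w
}

#' Build an untrained event classifier network
#'
#' The full backbone follows ResNet18: a 7x7/2 stem, max pooling, four
#' stages of two basic residual blocks; the standard global pooling and
#' final fully connected layer are replaced by a head of
#' flatten -> dense(hidden) -> ReLU -> dropout -> dense(n_classes).
#' The "tiny" variant keeps the stem and two residual stages for CPU-scale
#' work.  Input is a single grayscale channel.
#'
#' @param config a [TrainConfig-class].
#' @param n_classes number of output classes (default 5).
#' @return list with `layers`, `input_size`, `n_par`, `backbone`.
#' @export
#' @examples
#' m <- buildModel(trainConfig(backbone = "tiny", input_size = 64))
#' m$n_par
buildModel <- function(config, n_classes = 5L) {
  sz <- config@input_size
  layers <- list()
  if (config@backbone == "tiny") {
    widths <- c(8L, 8L, 16L)
    stem <- nnConv(1L, widths[1], 7L, 2L, 3L, sz, sz)
    H <- stem$Hout
    layers <- list(stem, nnBN(widths[1]), nnReLU(), nnMaxPool(H, H))
    H <- H %/% 2L
    b1 <- nnResBlock(widths[1], widths[2], 1L, H, H)
    b2 <- nnResBlock(widths[2], widths[3], 2L, b1$Hout, b1$Hout)
    layers <- c(layers, list(b1, b2))
    H <- b2$Hout; Cl <- widths[3]
  } else {
    stem <- nnConv(1L, 64L, 7L, 2L, 3L, sz, sz)
    H <- stem$Hout
    layers <- list(stem, nnBN(64L), nnReLU(), nnMaxPool(H, H))
    H <- H %/% 2L
    Cl <- 64L
    for (width in c(64L, 128L, 256L, 512L)) {
      s <- if (width == 64L) 1L else 2L
      ba <- nnResBlock(Cl, width, s, H, H)
      bb <- nnResBlock(width, width, 1L, ba$Hout, ba$Hout)
      layers <- c(layers, list(ba, bb))
      H <- bb$Hout; Cl <- width
    }
  }
  layers <- c(layers, list(
    nnFlatten(),
    nnDense(H * H * Cl, config@hidden_width),
    nnReLU(),
    nnDropout(config@dropout_p),
    nnDense(config@hidden_width, as.integer(n_classes))))
  list(layers = layers, input_size = sz, n_par = nnCountParams(layers),
       backbone = config@backbone)
}

## stack preprocessed matrices into an (S, 1, N) input array
stackInputs <- function(mats) {
  sz <- nrow(mats[[1]])
  array(unlist(mats, use.names = FALSE), c(sz * sz, 1L, length(mats)))
}

#' Train the event classifier
#'
#' Weighted cross-entropy (inverse-frequency class weights from the training
#' counts), Adam, early stopping on validation loss (best-epoch weights are
#' restored), learning-rate reduction on validation plateau, optional
#' augmentation of the training stream only.  Normalization statistics are
#' computed from training pixels only.  Seeded and reproducible.
#'
#' @param train_set,val_set lists with `images` (8-bit matrices) and
#'   `labels`; must be disjoint.
#' @param config a [TrainConfig-class].
#' @param labels class labels in encoding order; defaults to the
#'   [eventClasses()] present in the training set.
#' @param class_weighting "inverse" (default, inverse-frequency weights from
#'   the training counts) or "uniform" (unweighted loss, for ablation).
#' @param verbose print per-epoch progress.
#' @return a [DCClassifier-class].
#' @export
trainClassifier <- function(train_set, val_set, config = trainConfig(),
                            labels = NULL,
                            class_weighting = c("inverse", "uniform"),
                            verbose = FALSE) {
  class_weighting <- match.arg(class_weighting)
  if (!length(train_set$images) || !length(val_set$images))
    stop("training and validation sets must be non-empty")
  if (is.null(labels)) {
    seen <- unique(c(train_set$labels, val_set$labels))
    labels <- intersect(eventClasses(), seen)
    if (!length(labels)) labels <- sort(seen)
  }
  yTr <- match(train_set$labels, labels)
  yVa <- match(val_set$labels, labels)
  if (anyNA(yTr) || anyNA(yVa)) stop("label outside the class list")
  K <- length(labels)

  withSeed(config@seed, {
    # training-set-only normalization statistics, on resized raw images
    resTr <- lapply(train_set$images, ebResize, config@input_size,
                    config@input_size)
    px <- unlist(resTr, use.names = FALSE)
    stats <- list(mu = mean(px), sd = max(stats::sd(px), 1e-6))
    resVa <- lapply(val_set$images, function(m)
      (ebResize(m + 0, config@input_size, config@input_size) - stats$mu) /
        stats$sd)
    counts <- table(factor(labels[yTr], levels = labels))
    w <- if (class_weighting == "inverse")
      classWeights(as.numeric(counts) |> stats::setNames(labels))
    else stats::setNames(rep(1, K), labels)
    model <- buildModel(config, n_classes = K)
    anyAug <- any(config@augment)

    nTr <- length(resTr)
    bestLoss <- Inf; bestSnap <- NULL; sinceBest <- 0L; sincePlateau <- 0L
    lr <- config@lr
    hist <- list()
    t <- 0L
    players <- nnParamLayers(model$layers)
    for (epoch in seq_len(config@epochs)) {
      ord <- sample.int(nTr)
      epLoss <- 0; nb <- 0L
      for (start in seq(1L, nTr, by = config@batch_size)) {
        idx <- ord[start:min(start + config@batch_size - 1L, nTr)]
        mats <- lapply(idx, function(i) {
          im <- train_set$images[[i]]
          if (anyAug) im <- augmentImage(im, config@augment)
          (ebResize(im + 0, config@input_size, config@input_size) -
             stats$mu) / stats$sd
        })
        X <- stackInputs(mats)
        logits <- nnModelForward(model, X, training = TRUE)
        ce <- nnWeightedCE(logits, yTr[idx], w)
        if (!is.finite(ce$loss))
          stop("training diverged (non-finite loss) at epoch ", epoch)
        nnModelBackward(model, ce$grad)
        t <- t + 1L
        nnAdamStep(players, lr, t)
        epLoss <- epLoss + ce$loss; nb <- nb + 1L
      }
      ev <- evalModel(model, resVa, yVa, w, config@batch_size)
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = epLoss / nb,
                                  val_loss = ev$loss, val_acc = ev$acc,
                                  val_balanced_acc = ev$bal_acc, lr = lr)
      if (verbose)
        message(sprintf(
          "epoch %3d  train %.4f  val %.4f  acc %.3f  bal %.3f  lr %g",
          epoch, epLoss / nb, ev$loss, ev$acc, ev$bal_acc, lr))
      if (ev$loss < bestLoss - 1e-6) {
        bestLoss <- ev$loss
        bestSnap <- nnSnapshot(model$layers)
        sinceBest <- 0L; sincePlateau <- 0L
      } else {
        sinceBest <- sinceBest + 1L
        sincePlateau <- sincePlateau + 1L
        if (sincePlateau >= config@lr_plateau_patience) {
          lr <- lr * config@lr_factor
          sincePlateau <- 0L
        }
        if (sinceBest >= config@early_stop_patience) break
      }
    }
    if (!is.null(bestSnap)) nnRestore(model$layers, bestSnap)
    methods::new("DCClassifier", model = model, labels = labels,
                 normStats = stats, history = do.call(rbind, hist),
                 config = config)
  })
}

evalModel <- function(model, inputs, y, w, batch_size) {
  N <- length(inputs)
  loss <- 0; sw <- 0
  pred <- integer(N)
  for (start in seq(1L, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, N)
    X <- stackInputs(inputs[idx])
    logits <- nnModelForward(model, X, training = FALSE)
    ce <- nnWeightedCE(logits, y[idx], w)
    wv <- sum(w[y[idx]])
    loss <- loss + ce$loss * wv; sw <- sw + wv
    pred[idx] <- apply(ce$probs, 2, which.max)
  }
  recalls <- vapply(unique(y), function(k) mean(pred[y == k] == k),
                    numeric(1))
  list(loss = loss / sw, acc = mean(pred == y), bal_acc = mean(recalls),
       pred = pred)
}

#' Predict class labels and probabilities for event images
#'
#' Evaluation mode (dropout off, batch-norm running statistics): identical
#' inputs give identical outputs.  Softmax probabilities sum to one per
#' event; the label is the argmax, ties broken by the lowest class index.
#'
#' @param classifier a [DCClassifier-class].
#' @param images list of 8-bit crop matrices, or a [DCEventSet-class].
#' @param batch_size evaluation batch size.
#' @return list with `labels` (character), `probs` (N x K matrix) and
#'   `class_prob` (probability of the assigned class).
#' @export
predictEvents <- function(classifier, images, batch_size = 64L) {
  if (methods::is(images, "DCEventSet")) images <- crops(images)
  if (!length(images))
    return(list(labels = character(0),
                probs = matrix(numeric(0), 0, length(classifier@labels)),
                class_prob = numeric(0)))
  cfg <- classifier@config
  inputs <- lapply(images, preprocessCrop, cfg@input_size,
                   classifier@normStats)
  N <- length(inputs)
  K <- length(classifier@labels)
  probs <- matrix(NA_real_, N, K, dimnames = list(NULL, classifier@labels))
  for (start in seq(1L, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, N)
    X <- stackInputs(inputs[idx])
    logits <- nnModelForward(classifier@model, X, training = FALSE)
    z <- logits - matrix(apply(logits, 2, max), K, length(idx), byrow = TRUE)
    ez <- exp(z)
    probs[idx, ] <- t(ez) / colSums(ez)
  }
  lab <- apply(probs, 1, which.max)       # which.max takes the first tie
  list(labels = classifier@labels[lab], probs = probs,
       class_prob = probs[cbind(seq_len(N), lab)])
}

#' Attach classifier predictions to an event set
#'
#' @param eventset a [DCEventSet-class].
#' @param classifier a [DCClassifier-class].
#' @return the event set with `class_label` and `class_prob` feature columns.
#' @export
classifyEvents <- function(eventset, classifier) {
  pr <- predictEvents(classifier, eventset)
  f <- eventFeatures(eventset)
  f$class_label <- pr$labels
  f$class_prob <- pr$class_prob
  eventFeatures(eventset) <- f
  eventset
}

#' Confusion matrix and per-class recall
#'
#' @param true_labels,pred_labels aligned character vectors.
#' @param labels class labels fixing row/column order (default
#'   [eventClasses()]).
#' @return list with `counts` (rows = true, cols = predicted) and `recall`
#'   (diagonal over row sums).
#' @export
#' @examples
#' confusionMatrix(c("intact", "dead"), c("intact", "intact"))$counts
confusionMatrix <- function(true_labels, pred_labels,
                            labels = eventClasses()) {
  if (length(true_labels) != length(pred_labels))
    stop("label vectors must align")
  bad <- setdiff(unique(c(true_labels, pred_labels)), labels)
  if (length(bad)) stop("unknown label value: ", paste(bad, collapse = ", "))
  counts <- table(factor(true_labels, levels = labels),
                  factor(pred_labels, levels = labels))
  counts <- matrix(as.integer(counts), length(labels), length(labels),
                   dimnames = list(true = labels, predicted = labels))
  rs <- rowSums(counts)
  recall <- ifelse(rs > 0, diag(counts) / rs, NA_real_)
  names(recall) <- labels
  list(counts = counts, recall = recall)
}

#' Save / load a trained classifier
#'
#' The weights go to an RDS file, the manifest (label mapping with its
#' integer encoding, normalization statistics, configuration, history) to a
#' JSON sidecar.
#'
#' @param classifier a [DCClassifier-class].
#' @param path weights file; the manifest is written next to it as
#'   `<path>.json`.
#' @return invisibly, `path`.
#' @export
saveClassifier <- function(classifier, path) {
  snap <- nnSnapshot(classifier@model$layers)
  saveRDS(list(snapshot = snap, backbone = classifier@model$backbone,
               input_size = classifier@model$input_size,
               labels = classifier@labels, normStats = classifier@normStats,
               history = classifier@history,
               config = configToList(classifier@config)),
          path, version = 2)
  manifest <- list(labels = as.list(stats::setNames(
    seq_along(classifier@labels), classifier@labels)),
    norm = classifier@normStats, config = configToList(classifier@config),
    n_par = classifier@model$n_par)
  jsonlite::write_json(manifest, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveClassifier
#' @export
loadClassifier <- function(path) {
  s <- readRDS(path)
  cfg <- do.call(trainConfig, s$config)
  model <- buildModel(cfg, n_classes = length(s$labels))
  nnRestore(model$layers, s$snapshot)
  methods::new("DCClassifier", model = model, labels = s$labels,
               normStats = s$normStats, history = s$history, config = cfg)
}

configToList <- function(cfg) {
  list(input_size = cfg@input_size, epochs = cfg@epochs,
       batch_size = cfg@batch_size, lr = cfg@lr, dropout_p = cfg@dropout_p,
       hidden_width = cfg@hidden_width, val_fraction = cfg@val_fraction,
       early_stop_patience = cfg@early_stop_patience,
       lr_plateau_patience = cfg@lr_plateau_patience,
       lr_factor = cfg@lr_factor, backbone = cfg@backbone, seed = cfg@seed,
       augment = cfg@augment)
}
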