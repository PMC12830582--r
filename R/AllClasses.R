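#' The five deformability-cytometry event classes
#'
#' Returns the canonical event-class labels in their stable integer encoding
#' (1-based): intact, anomalous, dead, aggregate, debris.  Every classifier
#' manifest records this mapping.
#'
#' @return character vector of length 5.
#' @export
#' @examples
#' eventClasses()
eventClasses <- function() c("intact", "anomalous", "dead", "aggregate", "debris")

#' Segmentation parameters
#'
#' Parameters of the event-detection pipeline: temporal-median background
#' window, Gaussian smoothing, fixed-offset thresholding of the absolute
#' background difference, morphological opening/closing, area gating and
#' border policy.
#'
#' @slot bg_window frames used for the temporal median background.
#' @slot smooth_sigma Gaussian smoothing sigma (px) applied to |frame - bg|.
#' @slot threshold_offset threshold on |frame - background| (gray levels).
#' @slot min_area_px,max_area_px component area gate (px^2).
#' @slot morph_open_radius,morph_close_radius disc radii (px) for binary
#'   opening then closing.
#' @slot border_policy drop events touching the frame border?
#' @slot refine_mask re-threshold each component at half its robust
#'   amplitude to localize the boundary at the true edge (FWHM-style).
#' @slot max_events_per_frame keep at most this many (largest) events.
#' @slot crop_margin_px margin (px) around the tight bounding box kept in
#'   each event crop.
#' @slot contour_sigma Gaussian sigma (px) used to smooth the mask indicator
#'   before sub-pixel iso-contour extraction.
#' @export
setClass("SegmentationParams", representation(
  bg_window = "integer", smooth_sigma = "numeric", threshold_offset = "numeric",
  min_area_px = "numeric", max_area_px = "numeric",
  morph_open_radius = "integer", morph_close_radius = "integer",
  border_policy = "logical", refine_mask = "logical",
  max_events_per_frame = "integer",
  crop_margin_px = "integer", contour_sigma = "numeric"))

setValidity("SegmentationParams", function(object) {
  msg <- character()
  if (object@min_area_px >= object@max_area_px)
    msg <- c(msg, "min_area_px must be < max_area_px")
  if (object@morph_open_radius < 0L || object@morph_close_radius < 0L)
    msg <- c(msg, "morphology radii must be >= 0")
  if (object@bg_window < 2L) msg <- c(msg, "bg_window must be >= 2")
  if (object@threshold_offset <= 0) msg <- c(msg, "threshold_offset must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct segmentation parameters
#'
#' @param bg_window frames in the background median window (default 100).
#' @param smooth_sigma Gaussian sigma in px (default 1).
#' @param threshold_offset gray-level threshold on |frame - background|
#'   (default 8).
#' @param min_area_px,max_area_px area gate in px^2 (defaults 50 and 15000).
#' @param morph_open_radius,morph_close_radius disc radii in px (defaults 1
#'   and 2).
#' @param border_policy exclude events touching the frame border (default
#'   TRUE).
#' @param refine_mask half-amplitude boundary refinement (default TRUE).
#' @param max_events_per_frame keep at most this many largest events per
#'   frame (default 8).
#' @param crop_margin_px crop margin in px (default 5).
#' @param contour_sigma mask smoothing sigma for contour extraction
#'   (default 1).
#' @return a [SegmentationParams-class] object.
#' @export
#' @examples
#' segmentationParams(threshold_offset = 10)
segmentationParams <- function(bg_window = 100L, smooth_sigma = 1.0,
                               threshold_offset = 8, min_area_px = 50,
                               max_area_px = 15000, morph_open_radius = 1L,
                               morph_close_radius = 2L, border_policy = TRUE,
                               refine_mask = TRUE,
                               max_events_per_frame = 8L, crop_margin_px = 5L,
                               contour_sigma = 1.0) {
  new("SegmentationParams", bg_window = as.integer(bg_window),
      smooth_sigma = smooth_sigma, threshold_offset = threshold_offset,
      min_area_px = min_area_px, max_area_px = max_area_px,
      morph_open_radius = as.integer(morph_open_radius),
      morph_close_radius = as.integer(morph_close_radius),
      border_policy = border_policy, refine_mask = refine_mask,
      max_events_per_frame = as.integer(max_events_per_frame),
      crop_margin_px = as.integer(crop_margin_px),
      contour_sigma = contour_sigma)
}

#' Lipid-droplet detection parameters
#'
#' @slot relative_threshold fraction of the within-mask intensity range below
#'   the median that a pixel must fall to count as droplet candidate.
#' @slot min_contrast absolute floor (gray levels) on the candidate depth
#'   below the median, so that interior texture in low-range cells cannot
#'   masquerade as inclusions.
#' @slot min_droplet_area_px minimum component area (px^2).
#' @slot max_area_fraction maximum component area as a fraction of cell area.
#' @slot erosion_margin_px rim-exclusion erosion radius (px).
#' @export
setClass("DropletParams", representation(
  relative_threshold = "numeric", min_contrast = "numeric",
  min_droplet_area_px = "numeric",
  max_area_fraction = "numeric", erosion_margin_px = "integer"))

setValidity("DropletParams", function(object) {
  msg <- character()
  if (object@relative_threshold <= 0 || object@relative_threshold >= 1)
    msg <- c(msg, "relative_threshold must be in (0, 1)")
  if (object@min_droplet_area_px < 1) msg <- c(msg, "min_droplet_area_px must be >= 1")
  if (object@erosion_margin_px < 0L) msg <- c(msg, "erosion_margin_px must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct droplet-detection parameters
#'
#' @param relative_threshold default 0.35.
#' @param min_contrast default 15 gray levels.
#' @param min_droplet_area_px default 4.
#' @param max_area_fraction default 0.25.
#' @param erosion_margin_px default 2.
#' @return a [DropletParams-class] object.
#' @export
dropletParams <- function(relative_threshold = 0.35, min_contrast = 15,
                          min_droplet_area_px = 4,
                          max_area_fraction = 0.25, erosion_margin_px = 2L) {
  new("DropletParams", relative_threshold = relative_threshold,
      min_contrast = min_contrast,
      min_droplet_area_px = min_droplet_area_px,
      max_area_fraction = max_area_fraction,
      erosion_margin_px = as.integer(erosion_margin_px))
}

#' Classifier training configuration
#'
#' Mirrors the reference DC training recipe: 224x224 grayscale inputs, 100
#' epochs, batch 64, Adam, dropout 0.3, stratified 80/20 split,
#' inverse-frequency class weights, early stopping and learning-rate
#' reduction on validation plateau.  Learning rate, hidden width and the
#' patience values are configurable because no standard values exist for
#' them.
#'
#' @slot input_size side of the square model input (px).
#' @slot epochs maximum training epochs.
#' @slot batch_size minibatch size.
#' @slot lr initial Adam learning rate.
#' @slot dropout_p dropout probability in the classifier head.
#' @slot hidden_width width of the fully connected hidden layer.
#' @slot val_fraction validation fraction of the stratified split.
#' @slot early_stop_patience epochs without val-loss improvement before stop.
#' @slot lr_plateau_patience epochs without improvement before LR reduction.
#' @slot lr_factor multiplicative LR reduction factor.
#' @slot backbone "resnet18" or "tiny".
#' @slot seed integer seed for split, init, shuffling and augmentation.
#' @slot augment named logical vector toggling the six transform families.
#' @export
setClass("TrainConfig", representation(
  input_size = "integer", epochs = "integer", batch_size = "integer",
  lr = "numeric", dropout_p = "numeric", hidden_width = "integer",
  val_fraction = "numeric", early_stop_patience = "integer",
  lr_plateau_patience = "integer", lr_factor = "numeric",
  backbone = "character", seed = "integer", augment = "logical"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@val_fraction <= 0 || object@val_fraction >= 1)
    msg <- c(msg, "val_fraction must be in (0, 1)")
  if (object@dropout_p < 0 || object@dropout_p >= 1)
    msg <- c(msg, "dropout_p must be in [0, 1)")
  if (object@early_stop_patience < 1L || object@lr_plateau_patience < 1L)
    msg <- c(msg, "patience values must be >= 1")
  if (!object@backbone %in% c("resnet18", "tiny"))
    msg <- c(msg, "backbone must be 'resnet18' or 'tiny'")
  aug <- c("crop", "rotation", "hflip", "affine", "perspective",
           "brightness_contrast")
  if (!all(aug %in% names(object@augment)))
    msg <- c(msg, "augment must name all six transform families")
  if (length(msg)) msg else TRUE
})

#' Construct a training configuration
#'
#' @param input_size default 224 (the reference input geometry).
#' @param epochs default 100.
#' @param batch_size default 64.
#' @param lr initial learning rate, default 1e-4.
#' @param dropout_p default 0.3.
#' @param hidden_width default 256.
#' @param val_fraction default 0.2.
#' @param early_stop_patience default 10.
#' @param lr_plateau_patience default 5.
#' @param lr_factor default 0.5.
#' @param backbone "resnet18" (default) or "tiny" (2-stage desk-scale
#'   variant).
#' @param seed default 1.
#' @param augment named logical vector; defaults enable all six families.
#' @return a [TrainConfig-class] object.
#' @export
#' @examples
#' trainConfig(backbone = "tiny", input_size = 64, epochs = 10)
trainConfig <- function(input_size = 224L, epochs = 100L, batch_size = 64L,
                        lr = 1e-4, dropout_p = 0.3, hidden_width = 256L,
                        val_fraction = 0.2, early_stop_patience = 10L,
                        lr_plateau_patience = 5L, lr_factor = 0.5,
                        backbone = "resnet18", seed = 1L,
                        augment = c(crop = TRUE, rotation = TRUE, hflip = TRUE,
                                    affine = TRUE, perspective = TRUE,
                                    brightness_contrast = TRUE)) {
  new("TrainConfig", input_size = as.integer(input_size),
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      lr = lr, dropout_p = dropout_p, hidden_width = as.integer(hidden_width),
      val_fraction = val_fraction,
      early_stop_patience = as.integer(early_stop_patience),
      lr_plateau_patience = as.integer(lr_plateau_patience),
      lr_factor = lr_factor, backbone = backbone, seed = as.integer(seed),
      augment = augment)
}

#' Per-pixel background model
#'
#' @slot background floating-point per-pixel background estimate.
#' @slot window_size number of frames entering the temporal median.
#' @slot method estimator tag (currently "temporal_median").
#' @export
setClass("BackgroundModel", representation(
  background = "matrix", window_size = "integer", method = "character"))

setValidity("BackgroundModel", function(object) {
  if (!all(is.finite(object@background))) "background must be finite" else TRUE
})

#' Segmented DC events with aligned per-event features
#'
#' The central container: variable-size raw crops, binary masks and
#' sub-pixel contours for every detected event, aligned with a feature
#' table and acquisition metadata.  Persisted as an HDF5 event store (see
#' [writeEventStore()]).
#'
#' @slot crops list of 8-bit integer matrices (raw sub-images).
#' @slot masks list of logical matrices, same shapes as `crops`.
#' @slot contours list of closed polygons (n x 2, 0-based (row, col) in crop
#'   coordinates, first vertex repeated last).
#' @slot frameIndex integer source frame per event (0-based).
#' @slot bbox integer N x 4 matrix, half-open tight boxes
#'   (row0, col0, row1, col1) in frame coordinates, 0-based.
#' @slot cropOffset integer N x 2 matrix, (row0, col0) of each crop in its
#'   frame, 0-based.
#' @slot features data.frame with one row per event.
#' @slot meta list of run metadata (pixel size, configuration snapshot, ...).
#' @export
setClass("DCEventSet", representation(
  crops = "list", masks = "list", contours = "list", frameIndex = "integer",
  bbox = "matrix", cropOffset = "matrix", features = "data.frame",
  meta = "list"))

setValidity("DCEventSet", function(object) {
  n <- length(object@crops)
  msg <- character()
  if (length(object@masks) != n || length(object@contours) != n ||
      length(object@frameIndex) != n)
    msg <- c(msg, "crops, masks, contours and frameIndex must share one length")
  if (nrow(object@bbox) != n || nrow(object@cropOffset) != n)
    msg <- c(msg, "bbox and cropOffset must have one row per event")
  if (nrow(object@features) != n)
    msg <- c(msg, "features must have one row per event")
  if (n > 0) {
    sameShape <- vapply(seq_len(n), function(i)
      identical(dim(object@crops[[i]]), dim(object@masks[[i]])), logical(1))
    if (!all(sameShape)) msg <- c(msg, "each mask must match its crop's shape")
  }
  if (length(msg)) msg else TRUE
})

#' Trained five-class event classifier
#'
#' @slot model list holding the layer stack and weights.
#' @slot labels character vector of class labels in encoding order.
#' @slot normStats list with `mu` and `sd` computed from training pixels
#'   only (no validation leakage).
#' @slot history data.frame of per-epoch loss/accuracy/learning rate.
#' @slot config the [TrainConfig-class] used.
#' @export
setClass("DCClassifier", representation(
  model = "list", labels = "character", normStats = "list",
  history = "data.frame", config = "TrainConfig"))

setValidity("DCClassifier", function(object) {
  msg <- character()
  if (length(object@labels) < 2L) msg <- c(msg, "need at least two classes")
  if (!all(c("mu", "sd") %in% names(object@normStats)))
    msg <- c(msg, "normStats must hold mu and sd")
  if (length(msg)) msg else TRUE
})

#' Per-sample aggregate summary
#'
#' @slot classFractions named fractions over all events (sum to 1).
#' @slot modeDeform KDE mode of deformation over intact events (list with
#'   mode, n, bw).
#' @slot modeArea KDE mode of projected area (um^2) over intact events.
#' @slot meanDroplets mean droplet count per intact cell.
#' @slot meanDropletAreaFraction mean droplet area fraction per intact cell.
#' @slot nEvents,nIntact event counts.
#' @slot lowCount TRUE when fewer than the per-experiment floor of intact
#'   events (900) entered the summaries.
#' @export
setClass("SampleSummary", representation(
  classFractions = "numeric", modeDeform = "list", modeArea = "list",
  meanDroplets = "numeric", meanDropletAreaFraction = "numeric",
  nEvents = "integer", nIntact = "integer", lowCount = "logical"))
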