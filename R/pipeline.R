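# End-to-end orchestration: a single YAML-configurable run directory with
# idempotent, seeded commands mirroring a DC acquisition-analysis chain:
# simulate -> segment -> features -> train -> classify -> droplets -> report.

#' Default run configuration
#'
#' All paths live under `root`.  Sections: `paths`, `simulate`, `segment`,
#' `droplets`, `train`, plus top-level `seed`, `pixel_size_um` and run
#' annotations (`meta`, e.g. flow rates).  [readRunConfig()] merges a YAML
#' file over these defaults.
#'
#' @param root run directory.
#' @return nested configuration list.
#' @export
defaultRunConfig <- function(root = ".") {
  list(
    seed = 1L,
    pixel_size_um = 0.147,
    paths = list(
      frames = file.path(root, "frames.tif"),
      manifest_csv = file.path(root, "manifest.csv"),
      manifest_json = file.path(root, "manifest_polygons.json"),
      crops_dir = file.path(root, "training_crops"),
      store = file.path(root, "events.h5"),
      model = file.path(root, "classifier.rds"),
      report_dir = file.path(root, "report")),
    simulate = list(
      n_frames = 30L, objects_per_frame = 3L,
      class_mix = c(intact = 0.55, anomalous = 0.15, dead = 0.12,
                    aggregate = 0.08, debris = 0.10),
      droplet_lambda = 1.0,
      frame = list(height = 96L, width = 384L, background_level = 190,
                   background_gradient = 10, noise_sigma = 3),
      train_counts = c(intact = 120L, anomalous = 120L, dead = 120L,
                       aggregate = 120L, debris = 120L)),
    segment = list(bg_window = 100L, smooth_sigma = 1.0, threshold_offset = 8,
                   min_area_px = 50, max_area_px = 15000,
                   morph_open_radius = 1L, morph_close_radius = 2L,
                   border_policy = TRUE, max_events_per_frame = 8L),
    droplets = list(relative_threshold = 0.35, min_contrast = 15,
                    min_droplet_area_px = 4,
                    max_area_fraction = 0.25, erosion_margin_px = 2L),
    train = list(backbone = "tiny", input_size = 64L, epochs = 8L,
                 batch_size = 64L, lr = 1e-3, dropout_p = 0.3,
                 val_fraction = 0.2, early_stop_patience = 10L,
                 lr_plateau_patience = 5L, lr_factor = 0.5),
    meta = list(flow_rate_sample_ul_s = 0.04, flow_rate_sheath_ul_s = 0.12,
                software = "dcshape"))
}

#' Read a YAML run configuration
#'
#' Values in the file override the defaults of [defaultRunConfig()]
#' recursively; missing keys keep their defaults.
#'
#' @param path YAML file.
#' @param root run directory for defaults (default: the file's directory).
#' @return configuration list.
#' @export
readRunConfig <- function(path, root = dirname(path)) {
  usr <- yaml::read_yaml(path)
  mergeConfig(defaultRunConfig(root), usr)
}

mergeConfig <- function(base, usr) {
  for (nm in names(usr)) {
    if (is.list(base[[nm]]) && is.list(usr[[nm]]))
      base[[nm]] <- mergeConfig(base[[nm]], usr[[nm]])
    else base[[nm]] <- usr[[nm]]
  }
  base
}

segParamsFromConfig <- function(cfg)
  do.call(segmentationParams, cfg$segment)

dropParamsFromConfig <- function(cfg)
  do.call(dropletParams, cfg$droplets)

trainConfigFromConfig <- function(cfg) {
  args <- cfg$train
  args$seed <- cfg$seed
  do.call(trainConfig, args)
}

writeProvenance <- function(cfg, stage, extra = list()) {
  dir.create(cfg$paths$report_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- c(list(stage = stage, config_hash = objectHash(cfg),
                 seed = cfg$seed,
                 package_version = as.character(
                   utils::packageVersion("dcshape")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            extra)
  jsonlite::write_json(prov,
                       file.path(cfg$paths$report_dir,
                                 sprintf("provenance_%s.json", stage)),
                       auto_unbox = TRUE, digits = NA)
  invisible(prov)
}

#' Pipeline commands
#'
#' Each command is idempotent given identical configuration and seed, writes
#' a provenance block (configuration hash, package version, timestamp) into
#' the report directory, and fails with an actionable message when an
#' upstream artifact is missing.  Re-running a command with the same seed
#' reproduces its data outputs byte-identically (provenance files carry the
#' only timestamps).
#'
#' * `dcSimulate`: synthetic frames (multi-page TIFF), ground-truth manifest
#'   (CSV + polygon JSON) and a labeled training-crop directory.
#' * `dcSegment`: background estimation and event detection into the HDF5
#'   event store.
#' * `dcFeatures`: contour morphometry into the store and a CSV table.
#' * `dcTrain`: classifier training from the crop directory.
#' * `dcClassify`: class labels and probabilities into the store.
#' * `dcDroplets`: droplet counts into the store.
#' * `dcReport`: sample summary JSON, feature CSV and a 2-D
#'   (area, deformation) histogram table for scatter/density plots.
#' * `dcRunAll`: the full chain in order.
#'
#' @param cfg configuration list from [defaultRunConfig()] or
#'   [readRunConfig()].
#' @param verbose print training progress in `dcTrain`.
#' @return each command invisibly returns its main artifact path (or, for
#'   `dcReport`, the [SampleSummary-class]).
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
dcSimulate <- function(cfg) {
  sim <- cfg$simulate
  mix <- unlist(sim$class_mix)
  mix <- mix / sum(mix)
  specs <- withSeed(cfg$seed, {
    lapply(seq_len(sim$n_frames), function(i) {
      objs <- lapply(seq_len(sim$objects_per_frame), function(j) {
        cl <- sample(names(mix), 1, prob = mix)
        nd <- if (cl == "intact" && sim$droplet_lambda > 0)
          min(stats::rpois(1, sim$droplet_lambda), 5L) else 0L
        sampleObjectSpec(cl, n_droplets = nd)
      })
      frameSpec(height = sim$frame$height, width = sim$frame$width,
                background_level = sim$frame$background_level,
                background_gradient = sim$frame$background_gradient,
                noise_sigma = sim$frame$noise_sigma, objects = objs)
    })
  })
  out <- generateFrames(specs, seed = cfg$seed + 1L)
  dir.create(dirname(cfg$paths$frames), recursive = TRUE,
             showWarnings = FALSE)
  writeFrames(out$frames, cfg$paths$frames)
  writeManifest(out$manifest, cfg$paths$manifest_csv,
                cfg$paths$manifest_json)
  generateTrainingSet(unlist(sim$train_counts), out_dir = cfg$paths$crops_dir,
                      seed = cfg$seed + 2L,
                      droplet_lambda = sim$droplet_lambda)
  writeProvenance(cfg, "simulate",
                  list(n_frames = sim$n_frames,
                       n_objects = nrow(out$manifest$objects)))
  invisible(cfg$paths$frames)
}

#' @rdname pipeline
#' @export
dcSegment <- function(cfg) {
  if (!file.exists(cfg$paths$frames))
    stop("no frames at ", cfg$paths$frames, " - run dcSimulate first ",
         "(or point paths$frames at an acquisition)")
  frames <- readFrames(cfg$paths$frames)
  es <- segmentFrames(frames, segParamsFromConfig(cfg),
                      meta = c(list(pixel_size_um = cfg$pixel_size_um,
                                    seed = cfg$seed,
                                    frame_height = nrow(frames[[1]]),
                                    frame_width = ncol(frames[[1]])),
                               cfg$meta))
  writeEventStore(es, cfg$paths$store)
  writeProvenance(cfg, "segment", list(n_events = nEvents(es)))
  invisible(cfg$paths$store)
}

#' @rdname pipeline
#' @export
dcFeatures <- function(cfg) {
  es <- requireStore(cfg, "dcSegment")
  es <- computeFeatures(es, cfg$pixel_size_um)
  writeEventStore(es, cfg$paths$store)
  dir.create(cfg$paths$report_dir, recursive = TRUE, showWarnings = FALSE)
  exportFeaturesCSV(es, file.path(cfg$paths$report_dir, "features.csv"))
  writeProvenance(cfg, "features")
  invisible(cfg$paths$store)
}

#' @rdname pipeline
#' @export
dcTrain <- function(cfg, verbose = FALSE) {
  if (!dir.exists(cfg$paths$crops_dir))
    stop("no training crops at ", cfg$paths$crops_dir,
         " - run dcSimulate first (or point paths$crops_dir at labeled data)")
  ds <- loadTrainingSet(cfg$paths$crops_dir)
  tc <- trainConfigFromConfig(cfg)
  sp <- stratifiedSplit(ds$labels, tc@val_fraction, seed = tc@seed)
  clf <- trainClassifier(
    list(images = ds$images[sp$train], labels = ds$labels[sp$train]),
    list(images = ds$images[sp$val], labels = ds$labels[sp$val]),
    tc, verbose = verbose)
  saveClassifier(clf, cfg$paths$model)
  writeProvenance(cfg, "train",
                  list(best_val_loss = min(clf@history$val_loss),
                       epochs_run = nrow(clf@history)))
  invisible(cfg$paths$model)
}

#' @rdname pipeline
#' @export
dcClassify <- function(cfg) {
  es <- requireStore(cfg, "dcFeatures")
  if (!file.exists(cfg$paths$model))
    stop("no classifier at ", cfg$paths$model, " - run dcTrain first")
  clf <- loadClassifier(cfg$paths$model)
  es <- classifyEvents(es, clf)
  writeEventStore(es, cfg$paths$store)
  writeProvenance(cfg, "classify")
  invisible(cfg$paths$store)
}

#' @rdname pipeline
#' @export
dcDroplets <- function(cfg) {
  es <- requireStore(cfg, "dcSegment")
  es <- dropletEvents(es, dropParamsFromConfig(cfg))
  writeEventStore(es, cfg$paths$store)
  writeProvenance(cfg, "droplets")
  invisible(cfg$paths$store)
}

#' @rdname pipeline
#' @export
dcReport <- function(cfg) {
  es <- requireStore(cfg, "dcSegment")
  f <- eventFeatures(es)
  if (is.null(f$class_label))
    stop("event store has no class labels - run dcClassify first")
  if (is.null(f$deform))
    stop("event store has no morphometry - run dcFeatures first")
  summ <- suppressWarnings(
    summarizeSample(f, f$class_label, f$n_droplets, f$droplet_area_frac))
  dir.create(cfg$paths$report_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(summaryToList(summ),
                       file.path(cfg$paths$report_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  exportFeaturesCSV(es, file.path(cfg$paths$report_dir, "features.csv"))
  hist2d <- deformAreaHistogram(f)
  utils::write.csv(hist2d,
                   file.path(cfg$paths$report_dir, "deform_area_hist.csv"),
                   row.names = FALSE)
  writeProvenance(cfg, "report")
  invisible(summ)
}

#' @rdname pipeline
#' @export
dcRunAll <- function(cfg, verbose = FALSE) {
  dcSimulate(cfg)
  dcSegment(cfg)
  dcFeatures(cfg)
  dcTrain(cfg, verbose = verbose)
  dcClassify(cfg)
  dcDroplets(cfg)
  dcReport(cfg)
}

requireStore <- function(cfg, upstream) {
  if (!file.exists(cfg$paths$store))
    stop("no event store at ", cfg$paths$store, " - run ", upstream,
         " first")
  readEventStore(cfg$paths$store)
}

#' Convert a SampleSummary to a plain list (for JSON export)
#'
#' @param summ a [SampleSummary-class].
#' @return nested list.
#' @export
summaryToList <- function(summ) {
  list(class_fractions = as.list(summ@classFractions),
       mode_deformation = summ@modeDeform,
       mode_area_um2 = summ@modeArea,
       mean_droplets_per_intact_cell = summ@meanDroplets,
       mean_droplet_area_fraction = summ@meanDropletAreaFraction,
       n_events = summ@nEvents, n_intact = summ@nIntact,
       below_count_floor = summ@lowCount)
}

#' 2-D (area, deformation) histogram table
#'
#' Fixed-grid counts over the observed range, the data behind the standard
#' DC deformation-versus-area scatter/density plot.
#'
#' @param features data.frame with `A_um2` and `deform` columns.
#' @param bins grid size per axis (default 32).
#' @return data.frame with bin edges and counts.
#' @export
deformAreaHistogram <- function(features, bins = 32L) {
  a <- features$A_um2; d <- features$deform
  ok <- is.finite(a) & is.finite(d)
  a <- a[ok]; d <- d[ok]
  ab <- seq(min(a), max(a), length.out = bins + 1L)
  db <- seq(min(d), max(d), length.out = bins + 1L)
  ai <- pmin(findInterval(a, ab, rightmost.closed = TRUE), bins)
  di <- pmin(findInterval(d, db, rightmost.closed = TRUE), bins)
  counts <- table(factor(ai, levels = seq_len(bins)),
                  factor(di, levels = seq_len(bins)))
  grid <- expand.grid(area_bin = seq_len(bins), deform_bin = seq_len(bins))
  data.frame(area_lo = ab[grid$area_bin], area_hi = ab[grid$area_bin + 1L],
             deform_lo = db[grid$deform_bin],
             deform_hi = db[grid$deform_bin + 1L],
             count = as.integer(counts[cbind(grid$area_bin,
                                             grid$deform_bin)]))
}
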