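# Frame I/O (TIFF stacks / PNG directories), the HDF5 event store, and the
# flat feature-table export.

#' Read a frame sequence
#'
#' Accepts a multi-page 8-bit TIFF stack or a directory of equally shaped
#' 8-bit PNG/TIFF images (sorted by file name).  Frames are returned in
#' index order.  Non-8-bit inputs are rejected rather than silently
#' rescaled.
#'
#' @param path TIFF file or directory.
#' @return list of 8-bit integer matrices; frame i has index i - 1.
#' @export
readFrames <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("no image files in ", path)
    frames <- lapply(files, readOneImage)
    d <- dim(frames[[1]])
    bad <- which(!vapply(frames, function(f) identical(dim(f), d),
                         logical(1)))
    if (length(bad))
      stop("mixed frame shapes; offending file(s): ",
           paste(basename(files[bad]), collapse = ", "))
    return(frames)
  }
  if (!file.exists(path)) stop("cannot read ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, checkTiff8)
}

readOneImage <- function(f) {
  ext <- tolower(tools::file_ext(f))
  if (ext == "png") {
    img <- png::readPNG(f, info = TRUE)
    info <- attr(img, "info")
    if (!is.null(info$bit.depth) && info$bit.depth != 8L)
      stop("not an 8-bit image: ", f)
    if (length(dim(img)) == 3L) img <- img[, , 1]   # gray channel
    clip8(img * 255)
  } else {
    checkTiff8(tiff::readTIFF(f, as.is = TRUE))
  }
}

checkTiff8 <- function(img) {
  bps <- attr(img, "bits.per.sample")
  if (!is.null(bps) && bps != 8L) stop("not an 8-bit TIFF (", bps, " bits)")
  if (length(dim(img)) == 3L) img <- img[, , 1]
  if (max(img) > 255) stop("not an 8-bit TIFF (values exceed 255)")
  m <- img
  storage.mode(m) <- "integer"
  m
}

#' Write frames to disk
#'
#' @param frames list of 8-bit integer matrices.
#' @param path output path: `.tif`/`.tiff` writes a multi-page 8-bit TIFF,
#'   anything else is treated as a directory of PNGs.
#' @return invisibly, `path`.
#' @export
writeFrames <- function(frames, path) {
  for (f in frames) assertFrame(f)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(lapply(frames, function(f) f / 255), path,
                    bits.per.sample = 8L)
  } else {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(frames))
      png::writePNG(frames[[i]] / 255,
                    file.path(path, sprintf("frame_%05d.png", i - 1L)))
  }
  invisible(path)
}

## HDF5 event-store layout (analogous in spirit to the community .rtdc
## container, not claimed bit-compatible):
##   /events/image_data, image_dims   ragged uint8 crops (flattened + h,w)
##   /events/mask_data,  mask_dims    ragged uint8 masks
##   /events/contour_data, contour_len ragged float64 polygons (n x 2)
##   /events/frame_index, bbox, crop_offset, event_id
##   /features/<name>                 aligned 1-D arrays
##   /meta/json                       full run-configuration snapshot

#' Write a DCEventSet to an HDF5 event store
#'
#' All `/events` and `/features` datasets share one length; crops, masks,
#' contours and features round-trip bit-exactly through
#' [readEventStore()].
#'
#' @param eventset a [DCEventSet-class].
#' @param path output `.h5` file (overwritten).
#' @return invisibly, `path`.
#' @export
writeEventStore <- function(eventset, path) {
  methods::validObject(eventset)
  n <- nEvents(eventset)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "events")
  rhdf5::h5createGroup(path, "features")
  rhdf5::h5createGroup(path, "meta")
  dims <- function(lst) {
    if (!length(lst)) return(matrix(integer(0), 0, 2))
    t(vapply(lst, dim, integer(2)))
  }
  flat <- function(lst, mode = "integer") {
    if (!length(lst)) return(vector(mode, 0))
    v <- unlist(lapply(lst, as.vector), use.names = FALSE)
    storage.mode(v) <- mode
    v
  }
  rhdf5::h5write(n, path, "events/n")
  if (n > 0L) {
    rhdf5::h5write(flat(eventset@crops), path, "events/image_data")
    rhdf5::h5write(dims(eventset@crops), path, "events/image_dims")
    rhdf5::h5write(flat(lapply(eventset@masks, function(m) m * 1L)), path,
                   "events/mask_data")
    rhdf5::h5write(dims(eventset@masks), path, "events/mask_dims")
    rhdf5::h5write(flat(eventset@contours, "double"), path,
                   "events/contour_data")
    rhdf5::h5write(vapply(eventset@contours, nrow, integer(1)), path,
                   "events/contour_len")
    rhdf5::h5write(eventset@frameIndex, path, "events/frame_index")
    rhdf5::h5write(eventset@bbox, path, "events/bbox")
    rhdf5::h5write(eventset@cropOffset, path, "events/crop_offset")
    rhdf5::h5write(eventset@features$event_id %||% character(n), path,
                   "events/event_id")
    for (nm in setdiff(names(eventset@features), "event_id")) {
      v <- eventset@features[[nm]]
      if (is.factor(v)) v <- as.character(v)
      rhdf5::h5write(v, path, paste0("features/", nm))
    }
  }
  rhdf5::h5write(as.character(jsonlite::toJSON(eventset@meta, digits = NA,
                                               auto_unbox = TRUE,
                                               null = "null")),
                 path, "meta/json")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read an HDF5 event store
#'
#' Verifies the store-length consistency invariant on open; missing feature
#' datasets are simply absent from the feature table (callers check with
#' `"deform" %in% names(eventFeatures(x))`).
#'
#' @param path `.h5` file written by [writeEventStore()].
#' @return a [DCEventSet-class].
#' @export
readEventStore <- function(path) {
  if (!file.exists(path)) stop("no event store at ", path)
  on.exit(rhdf5::h5closeAll())
  ls <- rhdf5::h5ls(path)
  meta <- jsonlite::fromJSON(as.character(rhdf5::h5read(path, "meta/json")),
                             simplifyVector = TRUE)
  n <- as.integer(rhdf5::h5read(path, "events/n"))
  if (n == 0L) {
    return(methods::new("DCEventSet", crops = list(), masks = list(),
                        contours = list(), frameIndex = integer(0),
                        bbox = matrix(integer(0), 0, 4,
                                      dimnames = list(NULL, c("row0", "col0",
                                                              "row1", "col1"))),
                        cropOffset = matrix(integer(0), 0, 2,
                                            dimnames = list(NULL,
                                                            c("row0", "col0"))),
                        features = data.frame(event_id = character(0),
                                              stringsAsFactors = FALSE),
                        meta = as.list(meta)))
  }
  rag <- function(data, dims) {
    n <- nrow(dims)
    out <- vector("list", n)
    at <- 0L
    for (i in seq_len(n)) {
      len <- dims[i, 1] * dims[i, 2]
      out[[i]] <- matrix(data[(at + 1):(at + len)], dims[i, 1], dims[i, 2])
      at <- at + len
    }
    out
  }
  idims <- matrix(as.integer(rhdf5::h5read(path, "events/image_dims")),
                  ncol = 2)
  mdims <- matrix(as.integer(rhdf5::h5read(path, "events/mask_dims")),
                  ncol = 2)
  crops <- rag(as.integer(rhdf5::h5read(path, "events/image_data")), idims)
  masks <- lapply(rag(as.integer(rhdf5::h5read(path, "events/mask_data")),
                      mdims), function(m) m > 0L)
  clen <- as.integer(rhdf5::h5read(path, "events/contour_len"))
  cdata <- as.numeric(rhdf5::h5read(path, "events/contour_data"))
  contours <- rag(cdata, cbind(clen, 2L))
  contours <- lapply(contours, function(p) {
    colnames(p) <- c("row", "col"); p
  })
  featNames <- ls$name[ls$group == "/features"]
  feats <- data.frame(event_id = as.character(
    rhdf5::h5read(path, "events/event_id")), stringsAsFactors = FALSE)
  for (nm in featNames) {
    v <- rhdf5::h5read(path, paste0("features/", nm))
    if (length(v) != n)
      stop(sprintf("store inconsistency: features/%s has length %d, events %d",
                   nm, length(v), n))
    feats[[nm]] <- as.vector(v)
  }
  bbox <- matrix(as.integer(rhdf5::h5read(path, "events/bbox")), ncol = 4,
                 dimnames = list(NULL, c("row0", "col0", "row1", "col1")))
  coff <- matrix(as.integer(rhdf5::h5read(path, "events/crop_offset")),
                 ncol = 2, dimnames = list(NULL, c("row0", "col0")))
  obj <- methods::new("DCEventSet", crops = crops, masks = masks,
                      contours = contours,
                      frameIndex = as.integer(
                        rhdf5::h5read(path, "events/frame_index")),
                      bbox = bbox, cropOffset = coff, features = feats,
                      meta = as.list(meta))
  methods::validObject(obj)
  obj
}

#' Export the flat per-event feature table as CSV
#'
#' One row per event.  Always includes event_id, frame_index, area_px2,
#' area_um2, perimeter_px, deform, class_label, class_prob and n_droplets
#' (NA where a stage has not been run yet), plus any further feature
#' columns present.
#'
#' @param eventset a [DCEventSet-class].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
exportFeaturesCSV <- function(eventset, path) {
  n <- nEvents(eventset)
  f <- eventFeatures(eventset)
  px <- runMeta(eventset)$pixel_size_um %||% NA_real_
  tab <- data.frame(
    event_id = f$event_id %||% character(n),
    frame_index = frameIndex(eventset),
    area_px2 = f$A_px2 %||% rep(NA_real_, n),
    area_um2 = f$A_um2 %||% (if (!is.na(px)) (f$A_px2 %||% rep(NA_real_, n)) *
                               px^2 else rep(NA_real_, n)),
    perimeter_px = f$l_px %||% rep(NA_real_, n),
    deform = f$deform %||% rep(NA_real_, n),
    class_label = f$class_label %||% rep(NA_character_, n),
    class_prob = f$class_prob %||% rep(NA_real_, n),
    n_droplets = f$n_droplets %||% rep(NA_integer_, n),
    stringsAsFactors = FALSE)
  extra <- setdiff(names(f), c(names(tab), "A_px2", "A_um2", "l_px"))
  for (nm in extra) tab[[nm]] <- f[[nm]]
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Load a labeled training set from per-class directories
#'
#' Reads the directory layout written by [generateTrainingSet()]: one
#' sub-directory per class of 8-bit grayscale images.
#'
#' @param dir root directory.
#' @return list with `images` (8-bit integer matrices) and `labels`.
#' @export
loadTrainingSet <- function(dir) {
  classes <- intersect(eventClasses(), list.dirs(dir, full.names = FALSE,
                                                 recursive = FALSE))
  if (!length(classes)) stop("no class sub-directories under ", dir)
  images <- list(); labels <- character(0)
  for (cl in classes) {
    files <- sort(list.files(file.path(dir, cl), full.names = TRUE,
                             pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE))
    for (f in files) {
      images[[length(images) + 1L]] <- readOneImage(f)
      labels[length(labels) + 1L] <- cl
    }
  }
  list(images = images, labels = labels)
}
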