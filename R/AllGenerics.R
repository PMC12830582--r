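#' @name DCEventSet-accessors
#' @title Accessors for DCEventSet objects
#' @description Accessor generics for the event container: number of events,
#'   raw crops, masks, contours, source frame indices, the feature table and
#'   run metadata.
#' @param x a [DCEventSet-class].
#' @param value replacement value.
#' @return the corresponding slot content.
NULL

#' @rdname DCEventSet-accessors
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' @rdname DCEventSet-accessors
#' @export
setGeneric("crops", function(x) standardGeneric("crops"))

#' @rdname DCEventSet-accessors
#' @export
setGeneric("masks", function(x) standardGeneric("masks"))

#' @rdname DCEventSet-accessors
#' @export
setGeneric("contours", function(x) standardGeneric("contours"))

#' @rdname DCEventSet-accessors
#' @export
setGeneric("frameIndex", function(x) standardGeneric("frameIndex"))

#' @rdname DCEventSet-accessors
#' @export
setGeneric("eventFeatures", function(x) standardGeneric("eventFeatures"))

#' @rdname DCEventSet-accessors
#' @export
setGeneric("eventFeatures<-", function(x, value) standardGeneric("eventFeatures<-"))

#' @rdname DCEventSet-accessors
#' @export
setGeneric("runMeta", function(x) standardGeneric("runMeta"))

setMethod("nEvents", "DCEventSet", function(x) length(x@crops))
setMethod("crops", "DCEventSet", function(x) x@crops)
setMethod("masks", "DCEventSet", function(x) x@masks)
setMethod("contours", "DCEventSet", function(x) x@contours)
setMethod("frameIndex", "DCEventSet", function(x) x@frameIndex)
setMethod("eventFeatures", "DCEventSet", function(x) x@features)
setMethod("eventFeatures<-", "DCEventSet", function(x, value) {
  stopifnot(is.data.frame(value), nrow(value) == length(x@crops))
  x@features <- value
  methods::validObject(x)
  x
})
setMethod("runMeta", "DCEventSet", function(x) x@meta)

setMethod("show", "DCEventSet", function(object) {
  cat(sprintf("DCEventSet with %d events across %d frames\n",
              length(object@crops),
              length(unique(object@frameIndex))))
  if (ncol(object@features))
    cat("features:", paste(names(object@features), collapse = ", "), "\n")
  px <- object@meta$pixel_size_um
  if (!is.null(px)) cat(sprintf("pixel size: %g um/px\n", px))
})

setMethod("show", "DCClassifier", function(object) {
  cat(sprintf("DCClassifier (%s backbone, input %dx%d)\n",
              object@config@backbone, object@config@input_size,
              object@config@input_size))
  cat("classes:", paste(object@labels, collapse = ", "), "\n")
  cat(sprintf("parameters: %s; trained epochs: %d\n",
              format(object@model$n_par, big.mark = ","),
              nrow(object@history)))
  if (nrow(object@history)) {
    best <- which.min(object@history$val_loss)
    cat(sprintf("best val loss %.4f (epoch %d), val accuracy %.3f\n",
                object@history$val_loss[best], best,
                object@history$val_acc[best]))
  }
})

setMethod("show", "SampleSummary", function(object) {
  cat(sprintf("SampleSummary: %d events (%d intact%s)\n", object@nEvents,
              object@nIntact,
              if (object@lowCount) ", below the 900-event floor" else ""))
  fr <- paste(sprintf("%s %.3f", names(object@classFractions),
                      object@classFractions), collapse = ", ")
  cat("class fractions:", fr, "\n")
  cat(sprintf("mode deformation %.4f, mode area %.1f um^2, %.2f droplets/cell\n",
              object@modeDeform$mode %||% NA_real_,
              object@modeArea$mode %||% NA_real_, object@meanDroplets))
})

setMethod("show", "SegmentationParams", function(object) {
  cat("SegmentationParams:",
      sprintf("bg_window=%d, smooth_sigma=%g, threshold_offset=%g,",
              object@bg_window, object@smooth_sigma, object@threshold_offset),
      sprintf("area=[%g, %g], open=%d, close=%d, border_policy=%s",
              object@min_area_px, object@max_area_px, object@morph_open_radius,
              object@morph_close_radius, object@border_policy), "\n")
})
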