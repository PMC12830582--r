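# Contour morphometry: projected area A, perimeter l, and the isoperimetric
# deformation D = 1 - 2*sqrt(pi*A)/l, plus per-sample KDE-mode summaries.

#' Polygon area (shoelace formula)
#'
#' Orientation-independent absolute area of a closed simple polygon.
#'
#' @param contour n x 2 matrix of (row, col) vertices; a repeated closing
#'   vertex is tolerated.
#' @return area in px^2.
#' @export
#' @examples
#' polygonArea(rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0)))  # unit square
polygonArea <- function(contour) {
  p <- dropClosingVertex(contour)
  if (nrow(unique(p)) < 3L) stop("need at least 3 distinct vertices")
  x <- p[, 2]; y <- p[, 1]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Polygon perimeter
#'
#' Sum of Euclidean edge lengths of the closed polygon (repeated vertices
#' contribute zero length).
#'
#' @inheritParams polygonArea
#' @return perimeter in px.
#' @export
polygonPerimeter <- function(contour) {
  p <- dropClosingVertex(contour)
  if (nrow(unique(p)) < 3L) stop("need at least 3 distinct vertices")
  q <- rbind(p, p[1L, , drop = FALSE])
  sum(sqrt(rowSums(diff(q)^2)))
}

dropClosingVertex <- function(contour) {
  p <- as.matrix(contour)
  if (nrow(p) > 1L && all(p[1L, ] == p[nrow(p), ]))
    p <- p[-nrow(p), , drop = FALSE]
  p
}

#' Deformation statistic
#'
#' D = 1 - 2*sqrt(pi*A)/l: zero for a circle (the isoperimetric identity)
#' and growing with elongation or boundary irregularity.  Digitization can
#' push D of near-circular contours slightly negative; values are clamped to
#' `[0, 1)` and the clamp is reported via the `"clamped"` attribute so
#' estimator bias is never hidden.
#'
#' @param A_px2 projected area (> 0).
#' @param l_px contour perimeter (> 0).
#' @return deformation in `[0, 1)`; attribute `clamped` counts clamped
#'   entries and attribute `raw` holds the unclamped values.
#' @export
#' @examples
#' deformation(pi * 30^2, 2 * pi * 30)      # circle: 0
#' deformation(1, 4)                        # unit square: 1 - sqrt(pi)/2
deformation <- function(A_px2, l_px) {
  if (any(A_px2 <= 0) || any(l_px <= 0))
    stop("area and perimeter must be positive")
  raw <- 1 - 2 * sqrt(pi * A_px2) / l_px
  d <- pmin(pmax(raw, 0), 1 - .Machine$double.eps)
  attr(d, "raw") <- raw
  attr(d, "clamped") <- sum(raw < 0 | raw >= 1)
  d
}

#' Compute the full morphometric feature vector of one event
#'
#' Area and perimeter come from the sub-pixel contour polygon; the centroid,
#' principal-axis aspect ratio and mean brightness come from the mask and
#' raw crop.
#'
#' @param event one event record from [detectEvents()], or a
#'   [DCEventSet-class] plus index `i`.
#' @param pixel_size_um micrometers per pixel (default 0.147; this is a
#'   configuration value, never derived from hardware names).
#' @param i event index when `event` is a [DCEventSet-class].
#' @return one-row data.frame: A_px2, A_um2, l_px, deform, centroid_row,
#'   centroid_col (frame coordinates), aspect_ratio, mean_brightness.
#' @export
computeEventFeatures <- function(event, pixel_size_um = 0.147, i = NULL) {
  if (methods::is(event, "DCEventSet")) {
    stopifnot(!is.null(i))
    ev <- list(mask = event@masks[[i]], crop = event@crops[[i]],
               contour = event@contours[[i]],
               crop_offset = event@cropOffset[i, ])
  } else ev <- event
  A <- polygonArea(ev$contour)
  l <- polygonPerimeter(ev$contour)
  D <- deformation(A, l)
  idx <- which(ev$mask, arr.ind = TRUE)
  cr <- mean(idx[, 1]) - 1   # 0-based crop coordinates
  cc <- mean(idx[, 2]) - 1
  # principal-axis second moments of the mask
  mu_rr <- mean((idx[, 1] - 1 - cr)^2)
  mu_cc <- mean((idx[, 2] - 1 - cc)^2)
  mu_rc <- mean((idx[, 1] - 1 - cr) * (idx[, 2] - 1 - cc))
  tr <- mu_rr + mu_cc
  det2 <- sqrt(max((mu_rr - mu_cc)^2 / 4 + mu_rc^2, 0))
  l1 <- tr / 2 + det2; l2 <- max(tr / 2 - det2, .Machine$double.eps)
  off <- ev$crop_offset %||% c(0, 0)
  data.frame(A_px2 = A, A_um2 = A * pixel_size_um^2, l_px = l,
             deform = as.numeric(D),
             centroid_row = cr + off[1], centroid_col = cc + off[2],
             aspect_ratio = sqrt(l1 / l2),
             mean_brightness = mean(ev$crop[ev$mask]))
}

#' Compute features for every event in a set
#'
#' @param eventset a [DCEventSet-class].
#' @param pixel_size_um micrometers per pixel.
#' @return the event set with feature columns added to [eventFeatures()].
#' @export
computeFeatures <- function(eventset, pixel_size_um = 0.147) {
  n <- nEvents(eventset)
  if (n == 0L) return(eventset)
  rows <- lapply(seq_len(n), function(i)
    computeEventFeatures(eventset, pixel_size_um, i = i))
  feat <- do.call(rbind, rows)
  keep <- eventset@features[, setdiff(names(eventset@features), names(feat)),
                            drop = FALSE]
  eventset@features <- cbind(keep, feat)
  eventset@meta$pixel_size_um <- pixel_size_um
  methods::validObject(eventset)
  eventset
}

#' Mode of a sample via Gaussian kernel density estimation
#'
#' Silverman's rule-of-thumb bandwidth (`bw.nrd0`), density evaluated on a
#' 512-point grid spanning the sample range; the mode is the grid argmax.
#' Deterministic given the input.  Used for the per-experiment summary
#' statistic (mode of deformation / projected area).
#'
#' @param values numeric vector (n >= 1, finite).
#' @param bw bandwidth rule or value passed to [stats::density()]
#'   (default "nrd0", Silverman).
#' @return list with `mode`, `n`, `bw`.
#' @export
#' @examples
#' estimateMode(c(rep(0.05, 10), 0.2))$mode
estimateMode <- function(values, bw = "nrd0") {
  if (length(values) == 0L) stop("empty sample")
  if (!all(is.finite(values))) stop("values must be finite")
  if (length(unique(values)) == 1L)
    return(list(mode = values[1], n = length(values), bw = 0))
  den <- stats::density(values, bw = bw, n = 512L,
                        from = min(values), to = max(values))
  list(mode = den$x[which.max(den$y)], n = length(values), bw = den$bw)
}

#' Per-sample summary: class fractions, mode deformation/area, droplets
#'
#' Class fractions are computed over all events and sum to one; the
#' deformation and area modes and the droplet means are computed over
#' intact-labeled events only (the physiologically meaningful subset).  A
#' low-count flag is raised when fewer than `min_intact` intact events are
#' available, mirroring the per-experiment floor of 900 cells.
#'
#' @param features data.frame with columns `deform` and `A_um2`.
#' @param class_labels character vector aligned with `features`.
#' @param droplet_counts optional numeric vector aligned with `features`.
#' @param droplet_area_frac optional numeric vector of per-event droplet
#'   area fractions.
#' @param min_intact per-experiment floor (default 900).
#' @return a [SampleSummary-class].
#' @export
summarizeSample <- function(features, class_labels, droplet_counts = NULL,
                            droplet_area_frac = NULL, min_intact = 900L) {
  n <- nrow(features)
  if (n == 0L) stop("zero events: nothing to summarize")
  if (length(class_labels) != n)
    stop("class_labels must align with features")
  cls <- factor(class_labels, levels = eventClasses())
  if (anyNA(cls)) stop("unknown class label")
  fr <- as.numeric(table(cls)) / n
  names(fr) <- eventClasses()
  intact <- which(cls == "intact")
  lowCount <- length(intact) < min_intact
  if (lowCount)
    warning(sprintf("only %d intact events (floor is %d)", length(intact),
                    min_intact))
  modeD <- if (length(intact)) estimateMode(features$deform[intact]) else
    list(mode = NA_real_, n = 0L, bw = NA_real_)
  modeA <- if (length(intact)) estimateMode(features$A_um2[intact]) else
    list(mode = NA_real_, n = 0L, bw = NA_real_)
  meanDrop <- if (!is.null(droplet_counts) && length(intact))
    mean(droplet_counts[intact]) else NA_real_
  meanDropArea <- if (!is.null(droplet_area_frac) && length(intact))
    mean(droplet_area_frac[intact]) else NA_real_
  methods::new("SampleSummary", classFractions = fr, modeDeform = modeD,
               modeArea = modeA, meanDroplets = meanDrop,
               meanDropletAreaFraction = meanDropArea,
               nEvents = as.integer(n), nIntact = length(intact),
               lowCount = lowCount)
}
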