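# Synthetic DC frame generator with exact ground truth.
#
# Objects are star-convex radial shapes: an ellipse base radius (polar form
# about the center) times a sinusoidal boundary perturbation.  Aggregates are
# unions of overlapping ellipses.  All appearance constants are parameterized
# caricatures of real brightfield events (dark interior, bright diffraction
# rim, dark droplet inclusions); nothing here attempts photorealism.

## class-typical rendering/appearance defaults; hard_mode narrows the
## intact-vs-anomalous boundary-perturbation gap (the separability knob)
classStyle <- function(object_class, hard_mode = FALSE) {
  switch(object_class,
    intact = list(a = c(18, 28), b_frac = c(0.75, 0.95), offset = -35,
                  texture = 5, tex_scale = 0.8, rim = 30, amp = c(0, 0),
                  lobes = 0L),
    anomalous = list(a = c(16, 30), b_frac = c(0.70, 0.95), offset = -30,
                     texture = 12, tex_scale = 1.8, rim = 25,
                     amp = if (hard_mode) c(0.08, 0.12) else c(0.15, 0.30),
                     lobes = 3:7),
    dead = list(a = c(8, 12), b_frac = c(0.85, 1.0), offset = -18,
                texture = 15, tex_scale = 0.5, rim = 8, amp = c(0.04, 0.10),
                lobes = 5:9),
    aggregate = list(a = c(12, 20), b_frac = c(0.80, 0.95), offset = -32,
                     texture = 6, tex_scale = 0.8, rim = 25, amp = c(0, 0),
                     lobes = 0L),
    debris = list(a = c(7, 10), b_frac = c(0.70, 1.0), offset = -25,
                  texture = 8, tex_scale = 0.8, rim = 5, amp = c(0.10, 0.20),
                  lobes = 3:4),
    stop("unknown event class: ", object_class))
}

#' Specify one synthetic object
#'
#' Describes a single rendered object: a star-convex shape (ellipse base
#' radius times a sinusoidal boundary perturbation) for single objects, or a
#' union of overlapping member ellipses for aggregates.
#'
#' @param object_class one of [eventClasses()].
#' @param center numeric (row, col) in frame pixels (0-based pixel centers),
#'   or NULL to let the frame generator place the object.
#' @param semi_axes numeric (a, b) semi-axes in px.
#' @param orientation radians.
#' @param intensity_offset signed interior gray-level offset relative to
#'   background (negative = darker, the brightfield convention).
#' @param texture_sigma gray-level sd of the interior texture.
#' @param texture_scale spatial smoothing sigma of the texture (small =
#'   granular, large = blotchy).
#' @param rim_gain gray-level gain of the bright diffraction rim.
#' @param perturb_amp relative amplitude of the radial boundary perturbation.
#' @param perturb_lobes integer lobe count of the perturbation.
#' @param perturb_phase radians.
#' @param n_droplets dark droplet inclusions to plant (integer >= 0).
#' @param droplet_radius_px droplet radius in px.
#' @param droplet_contrast gray levels darker than the cell interior.
#' @param members for aggregates: list of member lists with fields
#'   `offset` (row, col relative to center), `semi_axes`, `orientation`.
#' @param id optional object id.
#' @return a list of class `dcObjectSpec`.
#' @export
#' @examples
#' sp <- objectSpec("intact", center = c(48, 128), semi_axes = c(22, 18))
objectSpec <- function(object_class, center = NULL, semi_axes = c(22, 18),
                       orientation = 0, intensity_offset = -35,
                       texture_sigma = 5, texture_scale = 0.8, rim_gain = 30,
                       perturb_amp = 0, perturb_lobes = 0L, perturb_phase = 0,
                       n_droplets = 0L, droplet_radius_px = 3,
                       droplet_contrast = 60, members = NULL, id = NA_character_) {
  object_class <- match.arg(object_class, eventClasses())
  if (any(semi_axes <= 0)) stop("semi_axes must be > 0")
  if (n_droplets < 0) stop("n_droplets must be >= 0")
  if (object_class == "aggregate" && is.null(members))
    stop("aggregate specs need 'members'")
  structure(list(object_class = object_class, center = center,
                 semi_axes = semi_axes, orientation = orientation,
                 intensity_offset = intensity_offset,
                 texture_sigma = texture_sigma, texture_scale = texture_scale,
                 rim_gain = rim_gain, perturb_amp = perturb_amp,
                 perturb_lobes = as.integer(perturb_lobes),
                 perturb_phase = perturb_phase,
                 n_droplets = as.integer(n_droplets),
                 droplet_radius_px = droplet_radius_px,
                 droplet_contrast = droplet_contrast, members = members,
                 id = id), class = "dcObjectSpec")
}

#' Draw a class-typical object specification
#'
#' Samples shape and appearance parameters from the class-typical ranges
#' using the current RNG stream.  `hard_mode` narrows the intact-vs-anomalous
#' boundary-perturbation gap, making the hardest class boundary harder.
#'
#' @param object_class one of [eventClasses()].
#' @param center optional (row, col); NULL defers placement.
#' @param n_droplets droplets to plant (cells are enlarged slightly when
#'   several droplets must fit).
#' @param hard_mode logical.
#' @return a `dcObjectSpec`.
#' @export
sampleObjectSpec <- function(object_class, center = NULL, n_droplets = 0L,
                             hard_mode = FALSE) {
  st <- classStyle(object_class, hard_mode)
  aRange <- st$a
  bFrac <- st$b_frac
  if (n_droplets > 0) {        # guarantee room for the requested inclusions
    aRange[1] <- max(aRange[1], 15 + 2 * n_droplets)
    aRange[2] <- max(aRange[2], aRange[1] + 2)
    bFrac[1] <- max(bFrac[1], 0.85)
  }
  a <- stats::runif(1, aRange[1], aRange[2])
  b <- a * stats::runif(1, bFrac[1], bFrac[2])
  amp <- if (diff(st$amp) > 0 || st$amp[1] > 0)
    stats::runif(1, st$amp[1], st$amp[2]) else 0
  lobes <- if (length(st$lobes) > 1 || st$lobes[1] > 0)
    sample(st$lobes, 1) else 0L
  members <- NULL
  if (object_class == "aggregate") {
    k <- sample(2:4, 1)
    members <- vector("list", k)
    pos <- c(0, 0)
    prev_a <- a
    for (j in seq_len(k)) {
      aj <- stats::runif(1, st$a[1], st$a[2])
      bj <- aj * stats::runif(1, st$b_frac[1], st$b_frac[2])
      if (j > 1) {             # chain members so consecutive ellipses overlap
        ang <- stats::runif(1, 0, 2 * pi)
        d <- stats::runif(1, 0.45, 0.75) * (prev_a + aj) / 2
        pos <- pos + d * c(cos(ang), sin(ang))
      }
      members[[j]] <- list(offset = pos, semi_axes = c(aj, bj),
                           orientation = stats::runif(1, 0, pi))
      prev_a <- aj
    }
    ctr <- vapply(members, function(m) m$offset, numeric(2))
    shift <- rowMeans(ctr)     # re-center the union on the spec center
    for (j in seq_len(k)) members[[j]]$offset <- members[[j]]$offset - shift
  }
  objectSpec(object_class, center = center, semi_axes = c(a, b),
             orientation = stats::runif(1, 0, pi),
             intensity_offset = st$offset, texture_sigma = st$texture,
             texture_scale = st$tex_scale, rim_gain = st$rim,
             perturb_amp = amp, perturb_lobes = lobes,
             perturb_phase = stats::runif(1, 0, 2 * pi),
             n_droplets = n_droplets, members = members)
}

#' Specify one synthetic frame
#'
#' @param height,width frame size in px (default 96 x 256, a channel-like
#'   field of view).
#' @param background_level 8-bit background gray level.
#' @param background_gradient gray-level change edge-to-edge across the width.
#' @param noise_sigma Gaussian pixel noise sd (gray levels).
#' @param objects list of `dcObjectSpec`.
#' @param channel_wall_rows optional integer pair; rows up to the first and
#'   from the second are rendered as dark channel walls.
#' @return a list of class `dcFrameSpec`.
#' @export
frameSpec <- function(height = 96L, width = 256L, background_level = 190,
                      background_gradient = 10, noise_sigma = 3,
                      objects = list(), channel_wall_rows = NULL) {
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  lo <- background_level - abs(background_gradient)
  hi <- background_level + abs(background_gradient)
  if (lo < 0 || hi > 255)
    stop("background_level +/- gradient must stay within 0..255")
  structure(list(height = as.integer(height), width = as.integer(width),
                 background_level = background_level,
                 background_gradient = background_gradient,
                 noise_sigma = noise_sigma, objects = objects,
                 channel_wall_rows = channel_wall_rows),
            class = "dcFrameSpec")
}

## polar radius of an ellipse about its center, psi measured from major axis
ellipseRadius <- function(theta, a, b, orientation) {
  psi <- theta - orientation
  a * b / sqrt((b * cos(psi))^2 + (a * sin(psi))^2)
}

specRadius <- function(spec, theta) {
  r <- ellipseRadius(theta, spec$semi_axes[1], spec$semi_axes[2],
                     spec$orientation)
  if (spec$perturb_amp > 0)
    r <- r * (1 + spec$perturb_amp *
                sin(spec$perturb_lobes * theta + spec$perturb_phase))
  r
}

## ground-truth polygon, 0-based local (row, col) about `center`, closed CCW
specPolygon <- function(spec, center, n = 720L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r <- specRadius(spec, th)
  p <- cbind(row = center[1] + r * cos(th), col = center[2] + r * sin(th))
  p <- orientCCW(p)
  rbind(p, p[1L, , drop = FALSE])
}

## rasterize the spec's inside-test on local pixel-center grid (h x w crop,
## center given in local 0-based coordinates)
specMask <- function(spec, h, w, center) {
  rr <- matrix(0:(h - 1), h, w) - center[1]
  cc <- matrix(0:(w - 1), h, w, byrow = TRUE) - center[2]
  if (spec$object_class == "aggregate") {
    m <- matrix(FALSE, h, w)
    for (mb in spec$members) {
      r0 <- rr - mb$offset[1]
      c0 <- cc - mb$offset[2]
      psi <- mb$orientation
      xr <- r0 * cos(psi) + c0 * sin(psi)
      yr <- -r0 * sin(psi) + c0 * cos(psi)
      m <- m | (xr / mb$semi_axes[1])^2 + (yr / mb$semi_axes[2])^2 <= 1
    }
    m
  } else {
    rho <- sqrt(rr^2 + cc^2)
    th <- atan2(cc, rr)
    rho <= specRadius(spec, th)
  }
}

maxRadius <- function(spec) {
  if (spec$object_class == "aggregate") {
    max(vapply(spec$members, function(m)
      sqrt(sum(m$offset^2)) + max(m$semi_axes), numeric(1)))
  } else max(spec$semi_axes) * (1 + spec$perturb_amp)
}

#' Render one synthetic object
#'
#' Rasterizes the object on a local crop: interior intensity offset, smoothed
#' texture, a bright rim just inside the boundary and anti-aliased dark
#' droplet disks.  Uses the current RNG stream (seed upstream for
#' reproducibility).
#'
#' @param spec a `dcObjectSpec`; its `center` is ignored here (the object is
#'   rendered centered in its own crop).
#' @param background_level gray level the patch is rendered on.
#' @param margin crop margin in px beyond the maximal radius.
#' @param noise_sigma background noise added to the patch.
#' @return list with `patch` (8-bit integer matrix), `mask` (logical),
#'   `delta` (signed double matrix of object-minus-background), `polygon`
#'   (closed ground-truth contour in 0-based crop coordinates), `center`
#'   (local center), `droplets` (data.frame row, col, radius in crop
#'   coordinates), `area_px2` and `perimeter_px` of the ground-truth polygon.
#' @export
#' @examples
#' set.seed(1)
#' ob <- renderObject(objectSpec("intact", semi_axes = c(20, 16)))
#' dim(ob$patch)
renderObject <- function(spec, background_level = 190, margin = 6L,
                         noise_sigma = 0) {
  rmax <- maxRadius(spec)
  half <- ceiling(rmax) + margin
  h <- w <- 2L * as.integer(half) + 1L
  ctr <- c(half, half)
  mask <- specMask(spec, h, w, ctr)
  if (!any(mask)) stop("degenerate object spec: empty mask")
  dist <- plainMat(EBImage::distmap(EBImage::Image(mask * 1)))

  delta <- matrix(0, h, w)
  delta[mask] <- spec$intensity_offset
  if (spec$texture_sigma > 0) {
    tex <- ebGblur(matrix(stats::rnorm(h * w), h, w), spec$texture_scale)
    tex <- tex / stats::sd(tex) * spec$texture_sigma
    delta[mask] <- delta[mask] + tex[mask]
  }
  rim <- mask & dist <= 1.5                     # bright diffraction rim
  delta[rim] <- spec$rim_gain

  droplets <- data.frame(row = numeric(0), col = numeric(0),
                         radius = numeric(0))
  if (spec$n_droplets > 0) {
    rd <- spec$droplet_radius_px
    cand <- which(dist >= rd + 3, arr.ind = TRUE) - 1  # 0-based centers
    placed <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(placed) < spec$n_droplets) {
      tries <- tries + 1L
      if (tries > 400L || nrow(cand) == 0L)
        stop("droplet placement failed for object ",
             if (is.na(spec$id)) "<unnamed>" else spec$id)
      p <- cand[sample.int(nrow(cand), 1), ] + stats::runif(2, -0.5, 0.5)
      if (nrow(placed) &&
          min(sqrt(rowSums((placed - matrix(p, nrow(placed), 2,
                                            byrow = TRUE))^2))) < 2 * rd + 2)
        next
      placed <- rbind(placed, p)
    }
    rr <- matrix(0:(h - 1), h, w)
    cc <- matrix(0:(w - 1), h, w, byrow = TRUE)
    for (i in seq_len(nrow(placed))) {
      d <- sqrt((rr - placed[i, 1])^2 + (cc - placed[i, 2])^2)
      cov <- pmin(pmax(rd + 0.5 - d, 0), 1)    # anti-aliased coverage
      delta <- delta - spec$droplet_contrast * cov
    }
    droplets <- data.frame(row = placed[, 1], col = placed[, 2],
                           radius = rd)
  }

  patch <- matrix(background_level, h, w) + delta
  if (noise_sigma > 0) patch <- patch + stats::rnorm(h * w, 0, noise_sigma)

  if (spec$object_class == "aggregate") {
    poly <- maskPolygon(mask)                  # union boundary from the mask
  } else {
    poly <- specPolygon(spec, ctr)
  }
  list(patch = clip8(patch), mask = mask, delta = delta, polygon = poly,
       center = ctr, droplets = droplets,
       area_px2 = polygonArea(poly), perimeter_px = polygonPerimeter(poly))
}

#' Generate synthetic frames with a ground-truth manifest
#'
#' Deterministic given `seed`.  Objects with NULL centers are placed
#' uniformly at random subject to a minimum 4 px separation between
#' bounding boxes and full containment in the frame; placement failure after
#' bounded retries raises an error naming the frame.
#'
#' @param specs list of `dcFrameSpec` (a single spec is recycled via
#'   `rep(list(spec), n)` by the caller).
#' @param seed integer seed.
#' @return list with `frames` (list of 8-bit integer matrices) and
#'   `manifest` (class `dcManifest`): `$objects` data.frame (object_id,
#'   frame_index, class, center, semi-axes, n_droplets, analytic area and
#'   perimeter), plus aligned lists `$polygons`, `$droplets`, `$masks`
#'   (frame-coordinate mask with its bounding box).
#' @export
#' @examples
#' fs <- frameSpec(objects = list(sampleObjectSpec("intact")))
#' out <- generateFrames(list(fs), seed = 7)
#' nrow(out$manifest$objects)
generateFrames <- function(specs, seed) {
  withSeed(seed, {
    frames <- vector("list", length(specs))
    rows <- list(); polys <- list(); drops <- list(); gtmasks <- list()
    oid <- 0L
    for (fi in seq_along(specs)) {
      fs <- specs[[fi]]
      h <- fs$height; w <- fs$width
      gcol <- matrix(0:(w - 1), h, w, byrow = TRUE) / max(1, w - 1)
      frame <- matrix(fs$background_level, h, w) +
        fs$background_gradient * (gcol - 0.5)
      if (!is.null(fs$channel_wall_rows)) {
        wr <- fs$channel_wall_rows
        frame[seq_len(wr[1] + 1L), ] <- frame[seq_len(wr[1] + 1L), ] - 60
        frame[(wr[2] + 1L):h, ] <- frame[(wr[2] + 1L):h, ] - 60
      }
      placedBoxes <- matrix(numeric(0), 0, 4)  # r0, c0, r1, c1 (half-open)
      for (sp in fs$objects) {
        rend <- NULL
        half <- ceiling(maxRadius(sp)) + 6L
        if (is.null(sp$center)) {
          ok <- FALSE
          for (try in 1:300) {
            ctr <- c(stats::runif(1, half + 1, h - half - 2),
                     stats::runif(1, half + 1, w - half - 2))
            box <- c(ctr[1] - half, ctr[2] - half, ctr[1] + half,
                     ctr[2] + half)
            sep <- !nrow(placedBoxes) ||
              all(box[1] > placedBoxes[, 3] + 4 | box[3] < placedBoxes[, 1] - 4 |
                  box[2] > placedBoxes[, 4] + 4 | box[4] < placedBoxes[, 2] - 4)
            if (sep) { ok <- TRUE; break }
          }
          if (!ok) stop("placement saturation in frame ", fi - 1L)
          sp$center <- ctr
        } else {
          ctr <- sp$center
          if (ctr[1] - half < 0 || ctr[2] - half < 0 ||
              ctr[1] + half > h - 1 || ctr[2] + half > w - 1)
            stop("object does not fit inside frame ", fi - 1L)
        }
        placedBoxes <- rbind(placedBoxes, c(ctr[1] - half, ctr[2] - half,
                                            ctr[1] + half, ctr[2] + half))
        oid <- oid + 1L
        sp$id <- sprintf("obj%05d", oid)
        rend <- renderObject(sp, background_level = 0, margin = 6L)
        # paste the signed delta into the frame at the integer-aligned crop
        r0 <- round(ctr[1]) - rend$center[1]   # 0-based frame row of crop row 0
        c0 <- round(ctr[2]) - rend$center[2]
        hh <- nrow(rend$delta); ww <- ncol(rend$delta)
        frame[(r0 + 1):(r0 + hh), (c0 + 1):(c0 + ww)] <-
          frame[(r0 + 1):(r0 + hh), (c0 + 1):(c0 + ww)] + rend$delta
        # ground truth in frame coordinates
        offs <- c(r0, c0)
        poly <- rend$polygon + matrix(offs, nrow(rend$polygon), 2, byrow = TRUE)
        dr <- rend$droplets
        if (nrow(dr)) { dr$row <- dr$row + r0; dr$col <- dr$col + c0 }
        rows[[oid]] <- data.frame(
          object_id = sp$id, frame_index = fi - 1L, class = sp$object_class,
          center_row = r0 + rend$center[1], center_col = c0 + rend$center[2],
          a_px = sp$semi_axes[1], b_px = sp$semi_axes[2],
          orientation = sp$orientation, n_droplets = sp$n_droplets,
          area_px2 = rend$area_px2, perimeter_px = rend$perimeter_px,
          stringsAsFactors = FALSE)
        polys[[oid]] <- poly
        drops[[oid]] <- dr
        gtmasks[[oid]] <- list(mask = rend$mask,
                               bbox = c(r0, c0, r0 + hh, c0 + ww))
      }
      if (fs$noise_sigma > 0)
        frame <- frame + stats::rnorm(h * w, 0, fs$noise_sigma)
      frames[[fi]] <- clip8(frame)
    }
    objects <- if (length(rows)) do.call(rbind, rows) else
      data.frame(object_id = character(0), frame_index = integer(0),
                 class = character(0), center_row = numeric(0),
                 center_col = numeric(0), a_px = numeric(0), b_px = numeric(0),
                 orientation = numeric(0), n_droplets = integer(0),
                 area_px2 = numeric(0), perimeter_px = numeric(0))
    manifest <- structure(list(objects = objects, polygons = polys,
                               droplets = drops, masks = gtmasks),
                          class = "dcManifest")
    list(frames = frames, manifest = manifest)
  })
}

#' Write a ground-truth manifest to disk
#'
#' One CSV row per object plus a JSON sidecar carrying the exact polygons
#' and droplet positions.
#'
#' @param manifest a `dcManifest`.
#' @param csv_path,json_path output paths.
#' @return invisibly, the paths.
#' @export
writeManifest <- function(manifest, csv_path, json_path) {
  utils::write.csv(manifest$objects, csv_path, row.names = FALSE)
  side <- list(
    polygons = lapply(manifest$polygons, function(p) unname(as.matrix(p))),
    droplets = lapply(manifest$droplets, function(d) unname(as.matrix(d))))
  jsonlite::write_json(side, json_path, digits = NA, auto_unbox = TRUE)
  invisible(c(csv = csv_path, json = json_path))
}

#' Generate a labeled training set of event crops
#'
#' Emulates a manually labeled event-image collection at any requested
#' per-class size.  Crop sizes vary with object size, as the classifier must
#' handle variable input dimensions.
#'
#' @param counts named integer vector over [eventClasses()] (missing names
#'   count as zero).
#' @param out_dir optional directory; when given, one sub-directory per
#'   class of 8-bit grayscale PNGs is written.
#' @param seed integer seed.
#' @param droplet_lambda Poisson mean of planted droplets in intact cells
#'   (default 0).
#' @param hard_mode narrow the intact/anomalous gap (default FALSE).
#' @return invisibly, a list with `images` (list of 8-bit matrices),
#'   `labels` (character), `specs` (list of `dcObjectSpec`).
#' @export
#' @examples
#' ts <- generateTrainingSet(c(intact = 5, debris = 5), seed = 1)
#' table(ts$labels)
generateTrainingSet <- function(counts, out_dir = NULL, seed = 1L,
                                droplet_lambda = 0, hard_mode = FALSE) {
  if (is.null(names(counts)) || !all(names(counts) %in% eventClasses()))
    stop("'counts' must be named by event classes")
  if (any(counts < 0)) stop("counts must be >= 0")
  withSeed(seed, {
    images <- list(); labels <- character(0); specs <- list()
    k <- 0L
    for (cl in eventClasses()) {
      n <- as.integer(counts[cl] %||% 0L)
      if (is.na(n) || n == 0L) next
      if (!is.null(out_dir))
        dir.create(file.path(out_dir, cl), recursive = TRUE,
                   showWarnings = FALSE)
      for (i in seq_len(n)) {
        nd <- if (cl == "intact" && droplet_lambda > 0)
          min(stats::rpois(1, droplet_lambda), 5L) else 0L
        sp <- sampleObjectSpec(cl, n_droplets = nd, hard_mode = hard_mode)
        bg <- stats::runif(1, 180, 200)
        rend <- renderObject(sp, background_level = bg, margin = 6L,
                             noise_sigma = 3)
        k <- k + 1L
        images[[k]] <- rend$patch
        labels[k] <- cl
        specs[[k]] <- sp
        if (!is.null(out_dir)) {
          png::writePNG(rend$patch / 255,
                        file.path(out_dir, cl, sprintf("%s_%05d.png", cl, i)))
        }
      }
    }
    invisible(list(images = images, labels = labels, specs = specs))
  })
}
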