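# internal helpers shared across modules

#' Run an expression under a temporary RNG seed
#'
#' Saves the caller's `.Random.seed`, seeds the generator, evaluates `expr`
#' and restores the previous state, so that seeded operations never perturb
#' the session RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## clip to 8-bit and return a plain integer matrix
clip8 <- function(x) {
  m <- pmin(pmax(round(x), 0), 255)
  storage.mode(m) <- "integer"
  attributes(m) <- list(dim = dim(m))
  m
}

## is x an 8-bit integer-valued grayscale matrix?
assertFrame <- function(x, what = "frame") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("%s must be a numeric matrix", what))
  if (any(x < 0 | x > 255) || any(x != round(x)))
    stop(sprintf("%s must hold 8-bit integer gray levels (0..255)", what))
  invisible(TRUE)
}

## strip EBImage's Image class back to a plain matrix
plainMat <- function(x) {
  m <- EBImage::imageData(x)
  attributes(m) <- list(dim = dim(m))
  m
}

## EBImage round trips: matrices go in, plain matrices come out
ebGblur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  plainMat(EBImage::gblur(EBImage::Image(m), sigma = sigma))
}

ebBrush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

## binary opening / closing with disc brushes; radius 0 is a no-op
ebOpen <- function(bw, radius) {
  if (radius <= 0) return(bw)
  plainMat(EBImage::opening(bw, ebBrush(radius))) > 0.5
}

ebClose <- function(bw, radius) {
  if (radius <= 0) return(bw)
  plainMat(EBImage::closing(bw, ebBrush(radius))) > 0.5
}

## connected-component labeling, 8-connectivity
ebLabel <- function(bw) {
  m <- plainMat(EBImage::bwlabel(EBImage::Image(bw * 1)))
  storage.mode(m) <- "integer"
  m
}

ebFillHull <- function(bw) {
  plainMat(EBImage::fillHull(EBImage::Image(bw * 1))) > 0.5
}

ebErode <- function(bw, radius) {
  if (radius <= 0) return(bw)
  plainMat(EBImage::erode(EBImage::Image(bw * 1), ebBrush(radius))) > 0.5
}

## bilinear resize of a numeric matrix to h x w
ebResize <- function(m, h, w) {
  plainMat(EBImage::resize(EBImage::Image(m), w = h, h = w))
}

## md5 of an arbitrary R object, via a temporary serialized file (base tools)
objectHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
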