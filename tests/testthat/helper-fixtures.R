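# shared fixtures, all generated in code

## digitized filled disk mask, center at pixel (cc, cc), 0-based radius r
diskMask <- function(r, n = 2L * ceiling(r) + 21L) {
  cc <- (n + 1) / 2
  xg <- row(matrix(0, n, n)) - cc
  yg <- col(matrix(0, n, n)) - cc
  xg^2 + yg^2 <= r^2
}

## analytic ellipse polygon (row, col), closed, n vertices
ellipsePolygon <- function(a, b, n = 10000L, phase = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1L)
  cbind(row = a * cos(th + phase), col = b * sin(th + phase))
}

## Ramanujan's ellipse perimeter approximation
ramanujanPerimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

## scene of n_frames frames with k sampled objects each (wide field so that
## several objects fit with the enforced separation)
sampleScene <- function(n_frames, k, seed,
                        mix = c(intact = 0.55, anomalous = 0.15, dead = 0.12,
                                aggregate = 0.08, debris = 0.10),
                        height = 128L, width = 512L) {
  specs <- withr::with_seed(seed, lapply(seq_len(n_frames), function(i) {
    objs <- lapply(seq_len(k), function(j)
      sampleObjectSpec(sample(names(mix), 1, prob = mix)))
    frameSpec(height = height, width = width, objects = objs)
  }))
  generateFrames(specs, seed = seed + 1000L)
}

smallTrainValSets <- function(per_class, seed, hard_mode = FALSE,
                              classes = eventClasses()) {
  counts <- stats::setNames(rep(per_class, length(classes)), classes)
  ts <- generateTrainingSet(counts, seed = seed, hard_mode = hard_mode)
  sp <- stratifiedSplit(ts$labels, 0.2, seed = seed)
  list(train = list(images = ts$images[sp$train],
                    labels = ts$labels[sp$train]),
       val = list(images = ts$images[sp$val], labels = ts$labels[sp$val]))
}
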