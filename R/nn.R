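# Minimal CNN engine: im2col convolutions via BLAS gemm with precomputed
# index maps, sparse-matrix col2im for the backward pass, batch
# normalization, residual blocks, dropout, Adam.  Activations are stored as
# arrays of dim (S, C, N) with S = H*W flattened column-major (row fastest),
# matching R's native matrix layout.
#
# Layers are environments (mutable): $par holds parameters, $grad the
# accumulated gradients, $opt the Adam state, plus cached forward buffers.

nnConv <- function(Cin, Cout, k, stride, pad, H, W) {
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Hout <- (Hp - k) %/% stride + 1L
  Wout <- (Wp - k) %/% stride + 1L
  offs <- as.vector(outer(seq_len(k), (seq_len(k) - 1L) * Hp, "+"))
  starts <- as.vector(outer(seq(0L, by = stride, length.out = Hout),
                            seq(0L, by = stride * Hp, length.out = Wout),
                            "+"))
  idx0 <- outer(offs, starts, "+")                     # k2 x Sout
  k2 <- k * k
  Sout <- Hout * Wout
  idx <- matrix(0L, k2 * Cin, Sout)
  for (c in seq_len(Cin))
    idx[((c - 1L) * k2 + 1L):(c * k2), ] <- idx0 + (c - 1L) * Hp * Wp
  # original-pixel rows inside the padded, flattened (HpWp*C, N) matrix
  yy <- rep(seq_len(H), W) + pad
  xx <- rep(seq_len(W), each = H) + pad
  pidx1 <- yy + (xx - 1L) * Hp
  pidx <- as.vector(outer(pidx1, (seq_len(Cin) - 1L) * Hp * Wp, "+"))
  scat <- Matrix::sparseMatrix(i = as.vector(idx),
                               j = seq_len(length(idx)), x = 1,
                               dims = c(Hp * Wp * Cin, length(idx)))
  e <- new.env(parent = emptyenv())
  e$type <- "conv"
  e$k <- k; e$Cin <- Cin; e$Cout <- Cout
  e$S <- H * W; e$Sout <- Sout; e$Hout <- Hout; e$Wout <- Wout
  e$Hp <- Hp; e$Wp <- Wp
  e$idx <- as.vector(idx); e$pidx <- pidx; e$scat <- scat
  e$pad <- pad
  e$par <- list(W = matrix(stats::rnorm(Cout * k2 * Cin,
                                        sd = sqrt(2 / (k2 * Cin))),
                           Cout, k2 * Cin),
                b = numeric(Cout))
  e
}

nnConvForward <- function(e, X, training) {
  N <- dim(X)[3]
  Xm <- X; dim(Xm) <- c(e$S * e$Cin, N)
  if (e$pad > 0L) {
    Xp <- matrix(0, e$Hp * e$Wp * e$Cin, N)
    Xp[e$pidx, ] <- Xm
  } else Xp <- Xm
  cols <- Xp[e$idx, , drop = FALSE]
  dim(cols) <- c(e$k^2 * e$Cin, e$Sout * N)
  Y <- e$par$W %*% cols + e$par$b
  if (training) e$cols <- cols else e$cols <- NULL
  dim(Y) <- c(e$Cout, e$Sout, N)
  aperm(Y, c(2, 1, 3))
}

nnConvBackward <- function(e, dY) {
  N <- dim(dY)[3]
  Dm <- aperm(dY, c(2, 1, 3))
  dim(Dm) <- c(e$Cout, e$Sout * N)
  e$grad <- list(W = Dm %*% t(e$cols), b = rowSums(Dm))
  dcols <- crossprod(e$par$W, Dm)
  dim(dcols) <- c(length(e$idx), N)
  dXp <- as.matrix(e$scat %*% dcols)
  dXm <- if (e$pad > 0L) dXp[e$pidx, , drop = FALSE] else dXp
  e$cols <- NULL
  array(dXm, c(e$S, e$Cin, N))
}

nnBN <- function(C) {
  e <- new.env(parent = emptyenv())
  e$type <- "bn"; e$C <- C; e$eps <- 1e-5; e$momentum <- 0.1
  e$par <- list(gamma = rep(1, C), beta = numeric(C))
  e$run_mean <- numeric(C); e$run_var <- rep(1, C)
  e
}

nnBNForward <- function(e, X, training) {
  S <- dim(X)[1]; N <- dim(X)[3]; M <- S * N
  Xc <- aperm(X, c(1, 3, 2)); dim(Xc) <- c(M, e$C)
  if (training) {
    mu <- colMeans(Xc)
    v <- colMeans(Xc^2) - mu^2
    e$run_mean <- (1 - e$momentum) * e$run_mean + e$momentum * mu
    e$run_var <- (1 - e$momentum) * e$run_var + e$momentum * v
  } else { mu <- e$run_mean; v <- e$run_var }
  invstd <- 1 / sqrt(v + e$eps)
  xhat <- (Xc - matrix(mu, M, e$C, byrow = TRUE)) *
    matrix(invstd, M, e$C, byrow = TRUE)
  Y <- xhat * matrix(e$par$gamma, M, e$C, byrow = TRUE) +
    matrix(e$par$beta, M, e$C, byrow = TRUE)
  if (training) { e$xhat <- xhat; e$invstd <- invstd; e$S <- S; e$N <- N }
  dim(Y) <- c(S, N, e$C)
  aperm(Y, c(1, 3, 2))
}

nnBNBackward <- function(e, dY) {
  S <- e$S; N <- e$N; M <- S * N
  dYc <- aperm(dY, c(1, 3, 2)); dim(dYc) <- c(M, e$C)
  e$grad <- list(gamma = colSums(dYc * e$xhat), beta = colSums(dYc))
  g <- matrix(e$par$gamma * e$invstd, M, e$C, byrow = TRUE)
  m1 <- matrix(colMeans(dYc), M, e$C, byrow = TRUE)
  m2 <- matrix(colMeans(dYc * e$xhat), M, e$C, byrow = TRUE)
  dXc <- g * (dYc - m1 - e$xhat * m2)
  e$xhat <- NULL
  dim(dXc) <- c(S, N, e$C)
  aperm(dXc, c(1, 3, 2))
}

nnReLU <- function() {
  e <- new.env(parent = emptyenv()); e$type <- "relu"; e$par <- list(); e
}

nnMaxPool <- function(H, W) {
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  Hout <- H %/% 2L; Wout <- W %/% 2L
  oy <- rep(seq_len(Hout), Wout); ox <- rep(seq_len(Wout), each = Hout)
  lin <- function(y, x) y + (x - 1L) * H
  e <- new.env(parent = emptyenv())
  e$type <- "maxpool"; e$par <- list()
  e$S <- H * W; e$Sout <- Hout * Wout; e$Hout <- Hout; e$Wout <- Wout
  e$i1 <- lin(2L * oy - 1L, 2L * ox - 1L)
  e$i2 <- lin(2L * oy, 2L * ox - 1L)
  e$i3 <- lin(2L * oy - 1L, 2L * ox)
  e$i4 <- lin(2L * oy, 2L * ox)
  e
}

nnMaxPoolForward <- function(e, X, training) {
  C <- dim(X)[2]; N <- dim(X)[3]
  Xm <- X; dim(Xm) <- c(e$S, C * N)
  a <- Xm[e$i1, , drop = FALSE]; b <- Xm[e$i2, , drop = FALSE]
  cc <- Xm[e$i3, , drop = FALSE]; d <- Xm[e$i4, , drop = FALSE]
  Y <- pmax(a, b, cc, d)
  if (training) {
    m1 <- a == Y; m2 <- b == Y & !m1; m3 <- cc == Y & !(m1 | m2)
    e$masks <- list(m1, m2, m3, !(m1 | m2 | m3))
    e$C <- C; e$N <- N
  }
  array(Y, c(e$Sout, C, N))
}

nnMaxPoolBackward <- function(e, dY) {
  C <- e$C; N <- e$N
  dYm <- dY; dim(dYm) <- c(e$Sout, C * N)
  dXm <- matrix(0, e$S, C * N)
  dXm[e$i1, ] <- dYm * e$masks[[1]]
  dXm[e$i2, ] <- dYm * e$masks[[2]]
  dXm[e$i3, ] <- dYm * e$masks[[3]]
  dXm[e$i4, ] <- dYm * e$masks[[4]]
  e$masks <- NULL
  array(dXm, c(e$S, C, N))
}

nnDropout <- function(p) {
  e <- new.env(parent = emptyenv())
  e$type <- "dropout"; e$p <- p; e$par <- list(); e
}

nnFlatten <- function() {
  e <- new.env(parent = emptyenv()); e$type <- "flatten"; e$par <- list(); e
}

nnDense <- function(din, dout) {
  e <- new.env(parent = emptyenv())
  e$type <- "dense"; e$din <- din; e$dout <- dout
  e$par <- list(W = matrix(stats::rnorm(dout * din, sd = sqrt(2 / din)),
                           dout, din),
                b = numeric(dout))
  e
}

## basic residual block: conv-bn-relu-conv-bn (+ 1x1 projection when the
## shape changes), relu after the skip addition
nnResBlock <- function(Cin, Cout, stride, H, W) {
  e <- new.env(parent = emptyenv())
  e$type <- "resblock"; e$par <- list()
  e$conv1 <- nnConv(Cin, Cout, 3L, stride, 1L, H, W)
  H2 <- e$conv1$Hout; W2 <- e$conv1$Wout
  e$bn1 <- nnBN(Cout)
  e$conv2 <- nnConv(Cout, Cout, 3L, 1L, 1L, H2, W2)
  e$bn2 <- nnBN(Cout)
  e$proj <- if (stride != 1L || Cin != Cout) {
    p <- new.env(parent = emptyenv())
    p$conv <- nnConv(Cin, Cout, 1L, stride, 0L, H, W)
    p$bn <- nnBN(Cout)
    p
  } else NULL
  e$Hout <- H2; e$Wout <- W2
  e
}

nnForward <- function(layer, X, training) {
  switch(layer$type,
    conv = nnConvForward(layer, X, training),
    bn = nnBNForward(layer, X, training),
    relu = {
      Y <- pmax(X, 0)
      if (training) layer$mask <- X > 0
      Y
    },
    maxpool = nnMaxPoolForward(layer, X, training),
    dropout = {
      if (training && layer$p > 0) {
        keep <- 1 - layer$p
        m <- array((stats::runif(length(X)) < keep) / keep, dim(X))
        layer$mask <- m
        X * m
      } else X
    },
    flatten = {
      layer$inDim <- dim(X)
      dim(X) <- c(dim(X)[1] * dim(X)[2], dim(X)[3])
      X
    },
    dense = {
      if (training) layer$X <- X
      layer$par$W %*% X + layer$par$b
    },
    resblock = {
      f <- nnForward(layer$conv1, X, training)
      f <- nnForward(layer$bn1, f, training)
      if (training) layer$mask1 <- f > 0
      f <- pmax(f, 0)
      f <- nnForward(layer$conv2, f, training)
      f <- nnForward(layer$bn2, f, training)
      s <- if (!is.null(layer$proj)) {
        s0 <- nnForward(layer$proj$conv, X, training)
        nnForward(layer$proj$bn, s0, training)
      } else X
      y <- f + s
      if (training) layer$maskOut <- y > 0
      pmax(y, 0)
    },
    stop("unknown layer type ", layer$type))
}

nnBackward <- function(layer, dY) {
  switch(layer$type,
    conv = nnConvBackward(layer, dY),
    bn = nnBNBackward(layer, dY),
    relu = { d <- dY * layer$mask; layer$mask <- NULL; d },
    maxpool = nnMaxPoolBackward(layer, dY),
    dropout = {
      if (!is.null(layer$mask)) { d <- dY * layer$mask; layer$mask <- NULL; d }
      else dY
    },
    flatten = { dim(dY) <- layer$inDim; dY },
    dense = {
      layer$grad <- list(W = dY %*% t(layer$X), b = rowSums(dY))
      d <- crossprod(layer$par$W, dY)
      layer$X <- NULL
      d
    },
    resblock = {
      dy <- dY * layer$maskOut
      layer$maskOut <- NULL
      df <- nnBackward(layer$bn2, dy)
      df <- nnBackward(layer$conv2, df)
      df <- df * layer$mask1
      layer$mask1 <- NULL
      df <- nnBackward(layer$bn1, df)
      dx <- nnBackward(layer$conv1, df)
      ds <- if (!is.null(layer$proj)) {
        d0 <- nnBackward(layer$proj$bn, dy)
        nnBackward(layer$proj$conv, d0)
      } else dy
      dx + ds
    },
    stop("unknown layer type ", layer$type))
}

## flat list of parameter-bearing environments (recursing into blocks)
nnParamLayers <- function(layers) {
  out <- list()
  for (l in layers) {
    if (l$type == "resblock") {
      out <- c(out, nnParamLayers(list(l$conv1, l$bn1, l$conv2, l$bn2)))
      if (!is.null(l$proj))
        out <- c(out, nnParamLayers(list(l$proj$conv, l$proj$bn)))
    } else if (length(l$par)) out <- c(out, list(l))
  }
  out
}

nnCountParams <- function(layers) {
  sum(vapply(nnParamLayers(layers), function(l)
    sum(vapply(l$par, length, numeric(1))), numeric(1)))
}

nnAdamStep <- function(playersList, lr, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  for (l in playersList) {
    if (is.null(l$opt))
      l$opt <- list(m = lapply(l$par, function(p) p * 0),
                    v = lapply(l$par, function(p) p * 0))
    for (nm in names(l$par)) {
      g <- l$grad[[nm]]
      l$opt$m[[nm]] <- beta1 * l$opt$m[[nm]] + (1 - beta1) * g
      l$opt$v[[nm]] <- beta2 * l$opt$v[[nm]] + (1 - beta2) * g^2
      mhat <- l$opt$m[[nm]] / (1 - beta1^t)
      vhat <- l$opt$v[[nm]] / (1 - beta2^t)
      l$par[[nm]] <- l$par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
}

## weight snapshot / restore (for best-epoch restoration and serialization)
nnSnapshot <- function(layers) {
  lapply(nnParamLayers(layers), function(l) {
    s <- list(par = l$par)
    if (l$type == "bn") { s$run_mean <- l$run_mean; s$run_var <- l$run_var }
    s
  })
}

nnRestore <- function(layers, snap) {
  pl <- nnParamLayers(layers)
  stopifnot(length(pl) == length(snap))
  for (i in seq_along(pl)) {
    pl[[i]]$par <- snap[[i]]$par
    if (pl[[i]]$type == "bn") {
      pl[[i]]$run_mean <- snap[[i]]$run_mean
      pl[[i]]$run_var <- snap[[i]]$run_var
    }
  }
  invisible(layers)
}

nnModelForward <- function(model, X, training = FALSE) {
  for (l in model$layers) X <- nnForward(l, X, training)
  X
}

nnModelBackward <- function(model, dY) {
  for (l in rev(model$layers)) dY <- nnBackward(l, dY)
  invisible(dY)
}

## weighted softmax cross-entropy (PyTorch-style weight normalization):
## L = sum_i w[y_i] * (-log p[y_i]) / sum_i w[y_i]
nnWeightedCE <- function(logits, y, w) {
  K <- nrow(logits); N <- ncol(logits)
  z <- logits - matrix(apply(logits, 2, max), K, N, byrow = TRUE)
  ez <- exp(z)
  p <- ez / matrix(colSums(ez), K, N, byrow = TRUE)
  wv <- w[y]
  sw <- sum(wv)
  pick <- cbind(y, seq_len(N))
  loss <- sum(wv * (-log(pmax(p[pick], 1e-12)))) / sw
  dZ <- p * matrix(wv, K, N, byrow = TRUE)
  dZ[pick] <- dZ[pick] - wv
  list(loss = loss, grad = dZ / sw, probs = p)
}
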