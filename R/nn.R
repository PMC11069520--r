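#' @include preprocess.R
NULL

# Minimal convolutional-network engine used by the image translator.
# Activations are (H, W, C) arrays; convolutions are evaluated as im2col
# index gathers followed by BLAS matrix products, and gradients flow back
# through the same index maps with rowsum() scatter-adds. Everything is
# plain R, deterministic under set.seed(), and sized for the B-scan
# resolutions this package trains at.

.nnLayer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  for (nm in names(list(...))) assign(nm, list(...)[[nm]], envir = e)
  e$prep <- list()     # per-input-shape cached index maps
  e
}

# im2col index map for a k x k convolution with the given stride/padding.
# Returns indices into c(as.vector(x), 0): the final sentinel encodes
# zero padding; reflect mode maps taps back inside the image instead.
.convPrep <- function(H, W, C, k, stride, pad, padmode) {
  Ho <- (H + 2 * pad - k) %/% stride + 1L
  Wo <- (W + 2 * pad - k) %/% stride + 1L
  io <- rep(seq_len(Ho), Wo); jo <- rep(seq_len(Wo), each = Ho)
  base_r <- (io - 1L) * stride - pad     # top-left corner (0-based)
  base_c <- (jo - 1L) * stride - pad
  npos <- Ho * Wo
  k2 <- k * k
  sentinel <- H * W * C + 1L
  bigIdx <- matrix(0L, npos, k2 * C)
  tap <- 0L
  for (dc in seq_len(k)) for (dr in seq_len(k)) {
    tap <- tap + 1L
    r <- base_r + dr; cc <- base_c + dc
    if (padmode == "reflect") {
      r <- .mirrorIndex(r, H); cc <- .mirrorIndex(cc, W)
      ok <- rep(TRUE, npos)
    } else {
      ok <- r >= 1L & r <= H & cc >= 1L & cc <= W
      r[!ok] <- 1L; cc[!ok] <- 1L
    }
    sp <- r + (cc - 1L) * H
    for (ch in seq_len(C)) {
      col <- (ch - 1L) * k2 + tap
      idx <- sp + (ch - 1L) * H * W
      idx[!ok] <- sentinel
      bigIdx[, col] <- idx
    }
  }
  list(bigIdx = bigIdx, Ho = Ho, Wo = Wo, npos = npos)
}

.getPrep <- function(L, d) {
  key <- paste(d, collapse = "x")
  if (is.null(L$prep[[key]]))
    L$prep[[key]] <- .convPrep(d[1], d[2], d[3], L$k, L$stride, L$pad,
                               L$padmode)
  L$prep[[key]]
}

.convLayer <- function(cin, cout, k, stride = 1L, pad = 0L,
                       padmode = "zero") {
  .nnLayer("conv", cin = cin, cout = cout, k = k, stride = as.integer(stride),
           pad = as.integer(pad), padmode = padmode,
           W = matrix(stats::rnorm(k * k * cin * cout, 0, 0.02),
                      k * k * cin, cout),
           b = numeric(cout))
}

.layerForward <- function(L, x, train) {
  switch(L$type,
    conv = {
      d <- dim(x)
      p <- .getPrep(L, d)
      xv <- c(as.vector(x), 0)
      X <- matrix(xv[p$bigIdx], p$npos)
      Y <- X %*% L$W
      Y <- sweep(Y, 2, L$b, `+`)
      L$cacheX <- X; L$cacheD <- d
      array(Y, c(p$Ho, p$Wo, L$cout))
    },
    upsample = {
      d <- dim(x)
      io <- rep(seq_len(d[1] * 2L), d[2] * 2L)
      jo <- rep(seq_len(d[2] * 2L), each = d[1] * 2L)
      sp <- ((io + 1L) %/% 2L) + (((jo + 1L) %/% 2L) - 1L) * d[1]
      idx <- as.vector(outer(sp, (seq_len(d[3]) - 1L) * d[1] * d[2], `+`))
      L$cacheIdx <- idx; L$cacheD <- d
      array(x[idx], c(d[1] * 2L, d[2] * 2L, d[3]))
    },
    inorm = {
      d <- dim(x)
      m <- matrix(x, d[1] * d[2], d[3])
      mu <- colMeans(m)
      xc <- sweep(m, 2, mu)
      sd <- sqrt(colMeans(xc * xc) + 1e-5)
      xh <- sweep(xc, 2, sd, `/`)
      L$cacheXh <- xh; L$cacheSd <- sd; L$cacheD <- d
      array(xh, d)
    },
    relu = { L$cacheMask <- x > 0; x * L$cacheMask },
    lrelu = { L$cacheMask <- x > 0; ifelse(L$cacheMask, x, L$slope * x) },
    tanh = { y <- tanh(x); L$cacheY <- y; y },
    dropout = {
      if (train && L$rate > 0) {
        mask <- (array(stats::runif(length(x)), dim(x)) >= L$rate) /
          (1 - L$rate)
        L$cacheMask <- mask
        x * mask
      } else { L$cacheMask <- NULL; x }
    },
    resblock = {
      y <- x
      for (S in L$layers) y <- .layerForward(S, y, train)
      x + y
    },
    stop("unknown layer type: ", L$type))
}

.layerBackward <- function(L, dy) {
  switch(L$type,
    conv = {
      p <- .getPrep(L, L$cacheD)
      dY <- matrix(dy, p$npos)
      L$gW <- crossprod(L$cacheX, dY)
      L$gb <- colSums(dY)
      dX <- tcrossprod(dY, L$W)
      sums <- rowsum(as.vector(dX), as.vector(p$bigIdx))
      dxv <- numeric(prod(L$cacheD) + 1L)
      dxv[as.integer(rownames(sums))] <- sums
      array(dxv[-length(dxv)], L$cacheD)
    },
    upsample = {
      sums <- rowsum(as.vector(dy), L$cacheIdx)
      dxv <- numeric(prod(L$cacheD))
      dxv[as.integer(rownames(sums))] <- sums
      array(dxv, L$cacheD)
    },
    inorm = {
      d <- L$cacheD
      dm <- matrix(dy, d[1] * d[2], d[3])
      xh <- L$cacheXh
      t1 <- sweep(dm, 2, colMeans(dm))
      t2 <- sweep(xh, 2, colMeans(dm * xh), `*`)
      array(sweep(t1 - t2, 2, L$cacheSd, `/`), d)
    },
    relu = dy * L$cacheMask,
    lrelu = ifelse(L$cacheMask, dy, L$slope * dy),
    tanh = dy * (1 - L$cacheY^2),
    dropout = if (is.null(L$cacheMask)) dy else dy * L$cacheMask,
    resblock = {
      dres <- dy
      for (S in rev(L$layers)) dres <- .layerBackward(S, dres)
      dy + dres
    },
    stop("unknown layer type: ", L$type))
}

.netForward <- function(layers, x, train = FALSE) {
  for (L in layers) x <- .layerForward(L, x, train)
  x
}

.netBackward <- function(layers, dy) {
  for (L in rev(layers)) dy <- .layerBackward(L, dy)
  dy
}

.collectConvs <- function(layers) {
  out <- list()
  for (L in layers) {
    if (L$type == "conv") out <- c(out, list(L))
    if (L$type == "resblock") out <- c(out, .collectConvs(L$layers))
  }
  out
}

.nnParameterCount <- function(layers) {
  sum(vapply(.collectConvs(layers),
             function(L) length(L$W) + length(L$b), numeric(1)))
}

# Adam step over every conv layer's accumulated gradients (gW/gb).
.adamInit <- function(layers) {
  for (L in .collectConvs(layers)) {
    L$mW <- L$W * 0; L$vW <- L$W * 0
    L$mb <- L$b * 0; L$vb <- L$b * 0
    L$tstep <- 0L
  }
}

.adamStep <- function(layers, lr, beta1, beta2, eps = 1e-8) {
  for (L in .collectConvs(layers)) {
    L$tstep <- L$tstep + 1L
    bc1 <- 1 - beta1^L$tstep; bc2 <- 1 - beta2^L$tstep
    L$mW <- beta1 * L$mW + (1 - beta1) * L$gW
    L$vW <- beta2 * L$vW + (1 - beta2) * L$gW^2
    L$W <- L$W - lr * (L$mW / bc1) / (sqrt(L$vW / bc2) + eps)
    L$mb <- beta1 * L$mb + (1 - beta1) * L$gb
    L$vb <- beta2 * L$vb + (1 - beta2) * L$gb^2
    L$b <- L$b - lr * (L$mb / bc1) / (sqrt(L$vb / bc2) + eps)
  }
}

# Binary cross-entropy with logits; returns loss and d(loss)/d(logits).
.bceLogits <- function(z, target) {
  p <- 1 / (1 + exp(-z))
  loss <- mean(ifelse(z >= 0, z - z * target + log1p(exp(-z)),
                      -z * target + log1p(exp(z))))
  list(loss = loss, dz = (p - target) / length(z))
}

# Serialize / restore layer parameters (index-map caches are rebuilt).
.nnStateGet <- function(layers) {
  lapply(layers, function(L) {
    if (L$type == "resblock")
      list(type = "resblock", layers = .nnStateGet(L$layers))
    else if (L$type == "conv") list(type = "conv", W = L$W, b = L$b)
    else list(type = L$type)
  })
}

.nnStateSet <- function(layers, state) {
  for (i in seq_along(layers)) {
    L <- layers[[i]]
    if (L$type == "resblock") .nnStateSet(L$layers, state[[i]]$layers)
    else if (L$type == "conv") { L$W <- state[[i]]$W; L$b <- state[[i]]$b }
  }
  invisible(layers)
}
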