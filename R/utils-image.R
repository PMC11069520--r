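#' @include AllClasses.R
NULL

# Separable image utilities shared by the phantom, preprocessing and
# metrics stages. Everything here is deterministic and allocation-light:
# resampling is expressed as per-axis dense weight matrices applied with
# BLAS, local statistics as integral images.

.clampIndex <- function(i, n) pmin(pmax(i, 1L), n)

# Mirror (reflect-101 style, edge pixel not duplicated would be reflect-
# 101; we use symmetric half-sample mirroring which duplicates the edge).
.mirrorIndex <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n
  i <- ((i - 1L) %% p + p) %% p          # 0-based, period 2n
  ifelse(i < n, i + 1L, p - i)
}

.lanczos <- function(x, a) {
  out <- numeric(length(x))
  core <- abs(x) < a
  z <- x[core]
  out[core] <- ifelse(abs(z) < 1e-12, 1,
                      a * sin(pi * z) * sin(pi * z / a) / (pi * pi * z * z))
  out
}

# Dense (nOut x nIn) Lanczos interpolation matrix for source sample
# positions 1..nIn and requested real-valued output coordinates (in source
# index space). Rows are renormalized to sum to 1 so constants are
# preserved exactly (DC preservation); out-of-range taps are clamped to
# the edge sample.
.lanczosMatrix <- function(nIn, coords, a = 3) {
  stopifnot(a >= 1, all(is.finite(coords)))
  W <- matrix(0, nrow = length(coords), ncol = nIn)
  for (o in seq_along(coords)) {
    x <- coords[o]
    lo <- floor(x) - a + 1
    taps <- lo:(lo + 2 * a - 1)
    w <- .lanczos(x - taps, a)
    taps <- .clampIndex(as.integer(taps), nIn)
    s <- sum(w)
    if (abs(s) < 1e-12) { taps <- .clampIndex(as.integer(round(x)), nIn); w <- 1; s <- 1 }
    w <- w / s
    for (k in seq_along(taps)) W[o, taps[k]] <- W[o, taps[k]] + w[k]
  }
  W
}

# Apply matrix W (nOut x nIn) along the given axis of a 3-D array.
.applyAxis <- function(arr, axis, W) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = d[axis])
  out <- W %*% m
  d2 <- d; d2[axis] <- nrow(W)
  aperm(array(out, d2[perm]), order(perm))
}

# Resample a 3-D array at arbitrary per-axis source coordinates (in index
# space of the source array) with separable Lanczos kernels.
.resampleArray <- function(arr, coords, a = 3) {
  for (ax in 1:3) {
    if (is.null(coords[[ax]])) next
    n <- dim(arr)[ax]
    co <- coords[[ax]]
    if (length(co) == n && max(abs(co - seq_len(n))) < 1e-12) next
    arr <- .applyAxis(arr, ax, .lanczosMatrix(n, co, a))
  }
  arr
}

# Evenly spaced output coordinates mapping an output grid of nOut samples
# onto a source span [c0, c1] (inclusive index range), pixel-center
# convention: output sample i sits at c0 + (i - 0.5) / nOut * (c1 - c0 + 1)
# - 0.5 relative offset. Used for crop + resample in one pass.
.gridCoords <- function(nOut, c0, c1) {
  span <- c1 - c0 + 1
  c0 - 0.5 + (seq_len(nOut) - 0.5) * span / nOut
}

# 1-D Gaussian smoothing along rows (axis 1) of a matrix, replicate edges.
.gaussSmoothCols <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2)); k <- k / sum(k)
  n <- nrow(m)
  idx <- outer(seq_len(n), (-r):r, `+`)
  idx <- matrix(.clampIndex(idx, n), nrow = n)
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) out <- out + k[j] * m[idx[, j], , drop = FALSE]
  out
}

# Same smoothing along both axes of a matrix (surfaces regularization).
.gaussSmooth2D <- function(m, sigma) {
  if (sigma <= 0) return(m)
  t(.gaussSmoothCols(t(.gaussSmoothCols(m, sigma)), sigma))
}

# 3x3 median filter via a 9-element partial sorting network (replicated
# edges); avoids per-pixel apply() calls on large lateral grids.
.median3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- .clampIndex(seq_len(nr) - 1L, nr); dn <- .clampIndex(seq_len(nr) + 1L, nr)
  lf <- .clampIndex(seq_len(nc) - 1L, nc); rt <- .clampIndex(seq_len(nc) + 1L, nc)
  p <- list(m[up, lf], m[up, ], m[up, rt],
            m[, lf],  m,      m[, rt],
            m[dn, lf], m[dn, ], m[dn, rt])
  swap <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  # median-of-9 network (Paeth)
  swap(1,2); swap(4,5); swap(7,8); swap(2,3); swap(5,6); swap(8,9)
  swap(1,2); swap(4,5); swap(7,8); swap(1,4); swap(4,7)
  swap(2,5); swap(5,8); swap(3,6); swap(6,9)
  swap(5,3); swap(5,7); swap(3,5)
  p[[5]]
}

# Local mean and sd over a square window with mirrored edges, via integral
# images. Returns list(mean, sd).
.boxStats <- function(m, window) {
  stopifnot(window >= 3, window %% 2 == 1)
  r <- (window - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  ri <- .mirrorIndex((1L - r):(nr + r), nr)
  ci <- .mirrorIndex((1L - r):(nc + r), nc)
  mp <- m[ri, ci, drop = FALSE]
  cums <- function(x) {
    s <- apply(x, 2, cumsum)
    s <- t(apply(s, 1, cumsum))
    rbind(0, cbind(0, s))  # pad so S[i+1, j+1] = sum of x[1:i, 1:j]
  }
  S1 <- cums(mp); S2 <- cums(mp * mp)
  i0 <- seq_len(nr); j0 <- seq_len(nc)
  # window rows in padded coords: (i0) .. (i0 + 2r), cols likewise
  a <- i0; b <- i0 + window; cA <- j0; cB <- j0 + window
  boxSum <- function(S) S[b, cB, drop = FALSE] - S[a, cB, drop = FALSE] -
    S[b, cA, drop = FALSE] + S[a, cA, drop = FALSE]
  nWin <- window * window
  mu <- boxSum(S1) / nWin
  v <- pmax(boxSum(S2) / nWin - mu * mu, 0)
  list(mean = mu, sd = sqrt(v))
}

# Percentile-based intensity normalization to [0, 1] (0.5-99.5 window by
# default). Degenerate (constant) input maps to 0.
.percentileNormalize <- function(arr, lower = 0.005, upper = 0.995) {
  q <- stats::quantile(arr, c(lower, upper), names = FALSE, type = 7)
  if (q[2] - q[1] < 1e-12) return(array(0, dim(arr)))
  pmin(pmax((arr - q[1]) / (q[2] - q[1]), 0), 1)
}

# Integer circular shift of a matrix (used by tests and registration).
.rollMatrix <- function(m, by) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- ((seq_len(nr) - 1L - by[1]) %% nr) + 1L
  ci <- ((seq_len(nc) - 1L - by[2]) %% nc) + 1L
  m[ri, ci, drop = FALSE]
}
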