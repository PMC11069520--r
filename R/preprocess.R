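#' @include phantom.R
NULL

#' Preprocessing configuration
#'
#' Bundles every tunable of the paired-harmonization stack so that runs
#' are fully described by one object. Defaults follow standard practice
#' for OCT B-scan conditioning; none of them are hard-coded elsewhere.
#'
#' @param grid integer(3) working/final grid (axial, fast, slow).
#' @param fov_mm numeric(3) final field of view in mm (fast, slow, axial).
#' @param working_fov_mm numeric(3) harmonized pre-crop field of view in mm
#'   (fast, slow, axial); the lateral extent both devices share and the
#'   axial span of the shallow device.
#' @param lanczos_a Lanczos kernel order (support 2a).
#' @param despeckle list(n_iter, kappa, step): Perona-Malik iteration
#'   count, conductance scale (on a 0--255 intensity scale) and time step
#'   (must be <= 0.25 for 2-D stability).
#' @param rpe list(sigma, prominence): axial Gaussian smoothing sigma in
#'   rows and the peak-prominence acceptance fraction of the A-scan max.
#' @param flatten_depth_mm physical depth at which the flattened RPE is
#'   placed in both volumes.
#' @param register list(halfband, max_shift_frac): half-height in rows of
#'   the enface projection band around the flattened RPE, and the failure
#'   threshold as a fraction of the lateral extent.
#' @param min_signal minimum signal strength for [qualityFilter()].
#' @return A list of class \code{"PreprocessConfig"}.
#' @export
preprocessConfig <- function(grid = c(256L, 256L, 256L),
                             fov_mm = c(2.6, 2.6, 2.0),
                             working_fov_mm = c(3, 3, 2),
                             lanczos_a = 3,
                             despeckle = list(n_iter = 20L, kappa = 30,
                                              step = 0.2),
                             rpe = list(sigma = 2, prominence = 0.25),
                             flatten_depth_mm = 0.9,
                             register = list(halfband = 10L,
                                             max_shift_frac = 0.25),
                             min_signal = 6L) {
  structure(list(grid = as.integer(grid), fov_mm = fov_mm,
                 working_fov_mm = working_fov_mm, lanczos_a = lanczos_a,
                 despeckle = despeckle, rpe = rpe,
                 flatten_depth_mm = flatten_depth_mm, register = register,
                 min_signal = as.integer(min_signal)),
            class = "PreprocessConfig")
}

#' Signal-strength quality filter for eye pairs
#'
#' An eye pair is retained only when both device volumes meet the minimum
#' manufacturer-style signal strength (clinical practice excludes scans
#' below 6). Each exclusion is logged with the failing device(s).
#'
#' @param pairs list of pairs; each element is either an
#'   [EyePhantom-class] with a degraded volume, or a list with elements
#'   \code{input} and \code{reference} ([OCTVolume-class]s).
#' @param min_signal minimum acceptable signal strength (default 6).
#' @return list(retained = subset of \code{pairs}, log = data.frame with
#'   columns id, retained, reason).
#' @export
qualityFilter <- function(pairs, min_signal = 6L) {
  getSS <- function(p) {
    if (is(p, "EyePhantom")) {
      if (is.null(p@degraded)) stop("phantom pair lacks a degraded volume")
      c(input = p@degraded@signalStrength,
        reference = p@reference@signalStrength)
    } else c(input = p$input@signalStrength,
             reference = p$reference@signalStrength)
  }
  keep <- logical(length(pairs)); reason <- character(length(pairs))
  for (i in seq_along(pairs)) {
    ss <- getSS(pairs[[i]])
    bad <- names(ss)[is.na(ss) | ss < min_signal]
    keep[i] <- length(bad) == 0L
    reason[i] <- if (keep[i]) "" else
      sprintf("signal strength below %d on: %s", min_signal,
              paste(bad, collapse = ", "))
  }
  ids <- vapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    id <- if (is(p, "EyePhantom")) p@params$seed else p$id
    if (is.null(id)) i else id
  }, numeric(1))
  list(retained = pairs[keep],
       log = data.frame(id = ids, retained = keep, reason = reason,
                        stringsAsFactors = FALSE))
}

#' Separable 3-D Lanczos resampling
#'
#' Resamples a volume to a new grid shape over the same field of view
#' using a separable windowed-sinc (Lanczos) kernel of order \code{a}.
#' Kernel weights are renormalized to sum to one at every output sample,
#' so constant volumes are reproduced exactly and no DC shift is
#' introduced at the edges. Calibration (mm per voxel) is rescaled
#' implicitly since the field of view is preserved.
#'
#' @param volume An [OCTVolume-class].
#' @param target_shape integer(3) output grid (axial, fast, slow), all >= 2.
#' @param a kernel order (>= 1; default 3).
#' @return The resampled [OCTVolume-class].
#' @export
lanczosResample <- function(volume, target_shape, a = 3) {
  stopifnot(is(volume, "OCTVolume"))
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape < 2L))
    stop("target_shape must be 3 integers >= 2")
  d <- dim(volume@vol)
  coords <- lapply(1:3, function(ax)
    (seq_len(target_shape[ax]) - 0.5) * d[ax] / target_shape[ax] + 0.5)
  out <- .resampleArray(volume@vol, coords, a)
  octVolume(out, fov = volume@fov, device = volume@device,
            laterality = volume@laterality,
            signalStrength = volume@signalStrength,
            meta = c(volume@meta, list(resampled_from = d)))
}

# Resample onto an explicit physical window: per-axis target sample count
# and mm span [lo, hi] measured from the volume top/edge.
.resampleWindow <- function(volume, n_out, window_mm, a = 3) {
  d <- dim(volume@vol)
  vox <- volume@fov / d
  coords <- lapply(1:3, function(ax) {
    (window_mm[[ax]][1] +
       (seq_len(n_out[ax]) - 0.5) *
         (window_mm[[ax]][2] - window_mm[[ax]][1]) / n_out[ax]) / vox[ax] + 0.5
  })
  out <- .resampleArray(volume@vol, coords, a)
  fov <- vapply(window_mm, function(w) w[2] - w[1], numeric(1))
  octVolume(out, fov = fov, device = volume@device,
            laterality = volume@laterality,
            signalStrength = volume@signalStrength,
            meta = c(volume@meta, list(window_mm = window_mm)))
}

#' Anisotropic-diffusion despeckling
#'
#' Perona-Malik diffusion applied independently to every B-scan (the
#' training unit), with exponential conductance
#' \code{g = exp(-(grad / kappa)^2)}. With \code{step <= 0.25} the 4-neighbour
#' explicit scheme obeys the discrete maximum principle, so no new
#' intensity extrema are created. \code{kappa} is quoted on a 0--255
#' intensity scale and rescaled internally to the volume's [0, 1] range.
#'
#' @param volume An [OCTVolume-class] with intensities in [0, 1].
#' @param n_iter number of diffusion iterations (0 = identity).
#' @param kappa conductance scale on a 0--255 intensity scale.
#' @param step diffusion time step; must be in (0, 0.25].
#' @return The despeckled [OCTVolume-class].
#' @export
despeckle <- function(volume, n_iter = 20L, kappa = 30, step = 0.2) {
  stopifnot(is(volume, "OCTVolume"), n_iter >= 0)
  if (step > 0.25 || step <= 0)
    stop("step must lie in (0, 0.25] for 2-D stability")
  if (n_iter == 0L) return(volume)
  k <- kappa / 255
  v <- volume@vol
  d <- dim(v)
  for (s in seq_len(d[3])) {
    m <- v[, , s]
    for (it in seq_len(n_iter)) {
      gN <- rbind(m[1, ], m[-d[1], ]) - m
      gS <- rbind(m[-1, ], m[d[1], ]) - m
      gW <- cbind(m[, 1], m[, -d[2]]) - m
      gE <- cbind(m[, -1], m[, d[2]]) - m
      m <- m + step * (gN * exp(-(gN / k)^2) + gS * exp(-(gS / k)^2) +
                       gW * exp(-(gW / k)^2) + gE * exp(-(gE / k)^2))
    }
    v[, , s] <- m
  }
  octVolume(v, fov = volume@fov, device = volume@device,
            laterality = volume@laterality,
            signalStrength = volume@signalStrength,
            meta = c(volume@meta,
                     list(despeckle = list(n_iter = n_iter, kappa = kappa,
                                           step = step))))
}

# Deepest (or shallowest) sufficiently prominent peak of a smoothed
# A-scan. Returns c(row, confidence); row is NA when nothing qualifies.
.prominences <- function(v, peaks) {
  out <- numeric(length(peaks))
  n <- length(v)
  for (j in seq_along(peaks)) {
    p <- peaks[j]
    hi <- which(v > v[p])
    lh <- hi[hi < p]; rh <- hi[hi > p]
    leftMin <- min(v[(if (length(lh)) max(lh) else 1):p])
    rightMin <- min(v[p:(if (length(rh)) min(rh) else n)])
    out[j] <- v[p] - max(leftMin, rightMin)
  }
  out
}

.dominantPeak <- function(v, prominence_frac, deepest = TRUE,
                          min_height = 0.75) {
  n <- length(v)
  dv <- diff(v)
  peaks <- which(dv[-length(dv)] > 0 & dv[-1] <= 0) + 1L
  if (!length(peaks)) return(c(NA_real_, 0))
  prom <- .prominences(v, peaks)
  keep <- prom >= prominence_frac * max(v) & v[peaks] >= min_height * max(v)
  if (!any(keep)) return(c(NA_real_, 0))
  peaks <- peaks[keep]; prom <- prom[keep]
  j <- if (deepest) which.max(peaks) else which.min(peaks)
  p <- peaks[j]
  # parabolic sub-row refinement
  row <- p
  if (p > 1 && p < n) {
    den <- v[p - 1] - 2 * v[p] + v[p + 1]
    if (abs(den) > 1e-12) row <- p + 0.5 * (v[p - 1] - v[p + 1]) / den
  }
  c(row, min(prom[j] / max(v), 1))
}

#' Estimate the RPE surface of a volume
#'
#' Per A-scan the retinal pigment epithelium is located as the deepest
#' dominant bright band: the axial profile is Gaussian-smoothed, local
#' maxima with prominence above a fraction of the A-scan maximum are kept,
#' and the deepest survivor wins (the RPE is the deepest bright band; ties
#' therefore break toward depth), with parabolic sub-row refinement.
#' A-scans with no qualifying band get confidence 0 and an interpolated
#' depth. The raw surface is then regularized across the lateral grid with
#' a 3x3 median filter and Gaussian smoothing.
#'
#' @param volume An [OCTVolume-class] (despeckled input recommended).
#' @param sigma axial Gaussian smoothing sigma in rows.
#' @param prominence prominence threshold as a fraction of the A-scan max.
#' @param smooth_sigma lateral regularization sigma in A-scans.
#' @param min_height minimum peak height as a fraction of the A-scan max;
#'   keeps the search on genuinely bright bands (stromal ridges between
#'   dark vessel lumens are prominent but dim).
#' @return A list of class \code{"RPESurface"}: \code{depth_row} (fast x
#'   slow matrix of real-valued row indices) and \code{confidence}
#'   (matching matrix in [0, 1]).
#' @export
estimateRPE <- function(volume, sigma = 2, prominence = 0.25,
                        smooth_sigma = 1.5, min_height = 0.75) {
  .estimateBand(volume, sigma, prominence, smooth_sigma, deepest = TRUE,
                min_height = min_height)
}

.estimateBand <- function(volume, sigma, prominence, smooth_sigma, deepest,
                          min_height = 0.75) {
  v <- volume@vol
  d <- dim(v)
  depth <- matrix(NA_real_, d[2], d[3])
  conf <- matrix(0, d[2], d[3])
  for (s in seq_len(d[3])) {
    m <- .gaussSmoothCols(v[, , s], sigma)
    for (f in seq_len(d[2])) {
      pk <- .dominantPeak(m[, f], prominence, deepest = deepest,
                          min_height = min_height)
      depth[f, s] <- pk[1]; conf[f, s] <- pk[2]
    }
  }
  bad <- is.na(depth)
  if (all(bad)) stop("no detectable band anywhere in the volume")
  if (any(bad)) depth[bad] <- stats::median(depth[!bad])
  # despike: replace a value by the local median only when it is a real
  # outlier; unconditional median filtering rectifies the (zero-mean)
  # sub-row estimation ripple into a depth bias
  med <- .median3x3(depth)
  spikes <- abs(depth - med) > 1
  depth[spikes] <- med[spikes]
  depth <- .gaussSmooth2D(depth, smooth_sigma)
  depth <- pmin(pmax(depth, 1), d[1])
  structure(list(depth_row = depth, confidence = conf),
            class = "RPESurface")
}

#' Flatten a volume on a boundary surface
#'
#' Shifts every A-scan axially so the given surface lands on
#' \code{target_row}; vacated samples are zero-filled. Integer row shifts
#' (the default) are exactly invertible and preserve each A-scan's
#' intensity multiset outside the zero-filled margins; sub-row mode
#' resamples with the Lanczos kernel instead.
#'
#' @param volume An [OCTVolume-class].
#' @param surface An \code{RPESurface} (from [estimateRPE()]) or a numeric
#'   fast x slow matrix of row indices.
#' @param target_row row index the surface is moved to.
#' @param subrow logical; TRUE applies fractional shifts by resampling.
#' @return The flattened [OCTVolume-class]; the applied shift map is kept
#'   in \code{meta$flatten_shift}.
#' @export
flattenVolume <- function(volume, surface, target_row, subrow = FALSE) {
  rows <- if (inherits(surface, "RPESurface")) surface$depth_row else surface
  d <- dim(volume@vol)
  if (target_row < 1 || target_row > d[1])
    stop("target_row outside the volume")
  if (!all(is.finite(rows))) stop("surface must be finite everywhere")
  v <- volume@vol
  out <- array(0, d)
  if (!subrow) {
    shift <- round(target_row - rows)   # positive = push down
    zIdx <- seq_len(d[1])
    for (s in seq_len(d[3])) {
      m <- v[, , s]
      o <- matrix(0, d[1], d[2])
      for (f in seq_len(d[2])) {
        src <- zIdx - shift[f, s]
        ok <- src >= 1L & src <= d[1]
        o[ok, f] <- m[src[ok], f]
      }
      out[, , s] <- o
    }
    shiftMap <- shift
  } else {
    shiftMap <- target_row - rows
    for (s in seq_len(d[3])) {
      m <- v[, , s]
      o <- matrix(0, d[1], d[2])
      for (f in seq_len(d[2])) {
        W <- .lanczosMatrix(d[1], seq_len(d[1]) - shiftMap[f, s])
        o[, f] <- W %*% m[, f]
      }
      out[, , s] <- o
    }
  }
  octVolume(out, fov = volume@fov, device = volume@device,
            laterality = volume@laterality,
            signalStrength = volume@signalStrength,
            meta = c(volume@meta,
                     list(flatten_shift = shiftMap,
                          flatten_target_row = target_row)))
}

# Mean-intensity enface projection over an axial row band.
.enface <- function(volume, rows) {
  rows <- rows[rows >= 1 & rows <= dim(volume@vol)[1]]
  apply(volume@vol[rows, , , drop = FALSE], c(2, 3), mean)
}

# Sub-pixel refinement of a phase-correlation peak: the whitened
# cross-power spectrum is evaluated on a finely upsampled local grid
# around the integer peak (a matrix-DFT zoom), which is exact for pure
# translations irrespective of image content.
.subpixelZoom <- function(R, shift0, halfwin = 1.5, step = 0.02) {
  d <- dim(R)
  freqs <- function(n) c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1) / n
  u <- shift0[1] + seq(-halfwin, halfwin, by = step)
  v <- shift0[2] + seq(-halfwin, halfwin, by = step)
  A <- exp(2i * pi * outer(u, freqs(d[1])))        # (nu x Nf)
  B <- exp(2i * pi * outer(freqs(d[2]), v))        # (Ns x nv)
  r <- Re(A %*% R %*% B)
  pk <- arrayInd(which.max(r), dim(r))[1, ]
  c(u[pk[1]], v[pk[2]])
}

#' Enface phase-correlation registration of a flattened pair
#'
#' Forms mean-intensity enface projections over a fixed axial band around
#' the flattened RPE for both volumes, estimates the lateral translation
#' by FFT phase correlation with parabolic sub-pixel refinement, resamples
#' the moving volume by that shift (Lanczos), and scores the result by the
#' normalized cross-correlation of the aligned projections. Shifts beyond
#' \code{max_shift_frac} of the lateral extent flag the pair as a
#' registration failure rather than returning a silently wrong alignment.
#'
#' @param reference,moving flattened [OCTVolume-class]s on matched grids.
#' @param target_row flattened RPE row (centre of the projection band).
#' @param halfband band half-height in rows.
#' @param max_shift_frac registration-failure threshold as a fraction of
#'   the lateral extent.
#' @param min_score minimum post-alignment normalized cross-correlation;
#'   poorer alignments are flagged as registration failures (the
#'   registration-accuracy screen).
#' @return list(shift = numeric(2) (fast, slow) voxel shift applied to the
#'   moving volume, registered = shifted [OCTVolume-class], score =
#'   normalized cross-correlation after alignment, success = logical).
#' @export
registerEnface <- function(reference, moving, target_row,
                           halfband = 10L, max_shift_frac = 0.25,
                           min_score = 0.35) {
  if (!identical(dim(reference@vol), dim(moving@vol)))
    stop("volumes must be on matched grids")
  rows <- (target_row - halfband):(target_row + halfband)
  eRef <- .enface(reference, rows)
  eMov <- .enface(moving, rows)

  estimate <- function(windowed) {
    a <- eRef - mean(eRef); b <- eMov - mean(eMov)
    if (windowed) {
      hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
      W <- outer(hann(nrow(a)), hann(ncol(a)))
      a <- a * W; b <- b * W
    }
    A <- stats::fft(a); B <- stats::fft(b)
    R <- A * Conj(B)
    # regularized whitening: keeps the phase-correlation delta sharp
    # while damping frequency bins that carry no signal energy
    R <- R / (Mod(R) + 0.05 * mean(Mod(R)))
    r <- Re(stats::fft(R, inverse = TRUE)) / length(R)
    peak <- arrayInd(which.max(r), dim(r))[1, ]
    s0 <- peak - 1L
    n <- dim(r)
    s0 <- ifelse(s0 > n / 2, s0 - n, s0)
    z <- .subpixelZoom(R, s0)
    ifelse(abs(z - round(z)) < 0.05, round(z), z)
  }
  # score a candidate on the interior untouched by zero-filled margins
  ncc <- function(s) {
    shifted <- .shiftMatrix(eMov, s)
    m1 <- min(ceiling(abs(s[1])) + 3L, floor(nrow(eRef) / 3))
    m2 <- min(ceiling(abs(s[2])) + 3L, floor(ncol(eRef) / 3))
    ri <- (1L + m1):(nrow(eRef) - m1)
    ci <- (1L + m2):(ncol(eRef) - m2)
    suppressWarnings(stats::cor(as.vector(eRef[ri, ci]),
                                as.vector(shifted[ri, ci])))
  }
  # plain phase correlation is exact for periodic (wrapped) content; the
  # Hann-windowed variant is robust to the border discontinuities a real
  # (zero-padded) displacement produces. Keep whichever aligns better.
  cands <- unique(list(estimate(FALSE), estimate(TRUE)))
  scores <- vapply(cands, ncc, numeric(1))
  best <- which.max(scores)
  shift <- cands[[best]]
  score <- scores[best]

  if (any(abs(shift) > max_shift_frac * dim(eRef)) ||
      !is.finite(score) || score < min_score) {
    return(list(shift = shift, registered = moving, score = score,
                success = FALSE))
  }
  registered <- .shiftLateral(moving, shift)
  list(shift = shift, registered = registered, score = score,
       success = TRUE)
}

# Shift a matrix by a real-valued (row, col) displacement; integer parts
# roll with zero fill, fractional parts use the Lanczos kernel.
.shiftMatrix <- function(m, s) {
  for (ax in 1:2) {
    si <- s[ax]
    if (abs(si) < 1e-12) next
    n <- dim(m)[ax]
    if (abs(si - round(si)) < 1e-9) {
      si <- as.integer(round(si))
      src <- seq_len(n) - si
      ok <- src >= 1L & src <= n
      out <- matrix(0, nrow(m), ncol(m))
      if (ax == 1) out[which(ok), ] <- m[src[ok], , drop = FALSE]
      else out[, which(ok)] <- m[, src[ok], drop = FALSE]
      m <- out
    } else {
      W <- .lanczosMatrix(n, seq_len(n) - si)
      m <- if (ax == 1) W %*% m else m %*% t(W)
    }
  }
  m
}

# Shift a volume laterally by (fast, slow) voxels; positive shift moves
# content toward higher indices. Integer shifts use exact rolling with
# zero fill; fractional shifts use the Lanczos kernel.
.shiftLateral <- function(volume, shift) {
  d <- dim(volume@vol)
  out <- volume@vol
  for (ax in 2:3) {
    s <- shift[ax - 1]
    if (abs(s) < 1e-9) next
    if (abs(s - round(s)) < 1e-9) {
      s <- as.integer(round(s))
      src <- seq_len(d[ax]) - s
      ok <- src >= 1L & src <= d[ax]
      tmp <- array(0, d)
      if (ax == 2) tmp[, which(ok), ] <- out[, src[ok], , drop = FALSE]
      else tmp[, , which(ok)] <- out[, , src[ok], drop = FALSE]
      out <- tmp
    } else {
      W <- .lanczosMatrix(d[ax], seq_len(d[ax]) - s)
      out <- .applyAxis(out, ax, W)
    }
  }
  octVolume(out, fov = volume@fov, device = volume@device,
            laterality = volume@laterality,
            signalStrength = volume@signalStrength,
            meta = c(volume@meta, list(lateral_shift_px = shift)))
}

#' Final crop and resample to the training grid
#'
#' Symmetric central crop of each lateral axis to the requested field of
#' view, axial crop to the requested span (taken from the volume top,
#' which holds the retina and choroid after flattening), and Lanczos
#' resampling to the final grid. Input and reference end on bit-identical
#' grids and calibrations.
#'
#' @param input_v,reference_v registered, flattened [OCTVolume-class]s.
#' @param grid integer(3) final grid (axial, fast, slow).
#' @param fov_mm numeric(3) final field of view in mm (fast, slow, axial).
#' @param shift registration shift to record in the pair provenance.
#' @param provenance optional upstream processing log entries.
#' @param a Lanczos order.
#' @return An [AlignedPair-class].
#' @export
finalizePair <- function(input_v, reference_v,
                         grid = c(256L, 256L, 256L),
                         fov_mm = c(2.6, 2.6, 2.0), shift = c(0, 0),
                         provenance = list(), a = 3) {
  cropOne <- function(v) {
    fin <- v@fov   # (axial, fast, slow)
    want <- c(fov_mm[3], fov_mm[1], fov_mm[2])
    if (any(want > fin + 1e-9))
      stop("requested field of view exceeds the available extent")
    win <- list(c(0, want[1]),                          # axial: from top
                c((fin[2] - want[2]) / 2, (fin[2] + want[2]) / 2),
                c((fin[3] - want[3]) / 2, (fin[3] + want[3]) / 2))
    .resampleWindow(v, grid, win, a)
  }
  inn <- cropOne(input_v)
  ref <- cropOne(reference_v)
  new("AlignedPair", input = inn, reference = ref,
      shift = as.numeric(shift),
      provenance = c(provenance,
                     list(final_grid = grid, final_fov_mm = fov_mm)))
}

#' Full paired-harmonization stack for one eye pair
#'
#' Runs the complete preprocessing pipeline on one shallow/deep volume
#' pair: percentile intensity normalization, Lanczos grid matching onto a
#' shared working grid, per-B-scan despeckling, RPE estimation and
#' flattening of both volumes to a common physical depth, enface
#' phase-correlation registration, and the final centred crop/resample to
#' the training grid.
#'
#' @param input,reference [OCTVolume-class]s from the shallow- and
#'   deep-penetration devices.
#' @param config a [preprocessConfig()].
#' @return list(pair = [AlignedPair-class] or NULL, success = logical,
#'   log = list of stage records).
#' @export
preprocessPair <- function(input, reference, config = preprocessConfig()) {
  log <- list()
  norm <- function(v) {
    octVolume(.percentileNormalize(v@vol), fov = v@fov, device = v@device,
              laterality = v@laterality, signalStrength = v@signalStrength,
              meta = v@meta)
  }
  input <- norm(input); reference <- norm(reference)

  # Harmonize: both devices onto one working grid over the shared lateral
  # extent and the shallow device's axial span (top-aligned).
  wf <- config$working_fov_mm
  harm <- function(v) {
    fin <- v@fov
    win <- list(c(0, min(wf[3], fin[1])),
                c((fin[2] - wf[1]) / 2, (fin[2] + wf[1]) / 2),
                c((fin[3] - wf[2]) / 2, (fin[3] + wf[2]) / 2))
    .resampleWindow(v, config$grid, win, config$lanczos_a)
  }
  input <- harm(input); reference <- harm(reference)
  log$harmonize <- list(grid = config$grid, working_fov_mm = wf)

  dsp <- config$despeckle
  input <- despeckle(input, dsp$n_iter, dsp$kappa, dsp$step)
  reference <- despeckle(reference, dsp$n_iter, dsp$kappa, dsp$step)

  targetRow <- round(config$flatten_depth_mm / (input@fov[1] / config$grid[1]))
  sIn <- estimateRPE(input, config$rpe$sigma, config$rpe$prominence)
  sRef <- estimateRPE(reference, config$rpe$sigma, config$rpe$prominence)
  input <- flattenVolume(input, sIn, targetRow)
  reference <- flattenVolume(reference, sRef, targetRow)
  log$flatten <- list(target_row = targetRow)

  reg <- registerEnface(reference, input, targetRow,
                        halfband = config$register$halfband,
                        max_shift_frac = config$register$max_shift_frac)
  log$register <- list(shift = reg$shift, score = reg$score,
                       success = reg$success)
  if (!reg$success)
    return(list(pair = NULL, success = FALSE, log = log))

  pair <- finalizePair(reg$registered, reference, grid = config$grid,
                       fov_mm = config$fov_mm, shift = reg$shift,
                       provenance = log, a = config$lanczos_a)
  list(pair = pair, success = TRUE, log = log)
}
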