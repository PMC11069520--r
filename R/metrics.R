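#' @include translate.R
NULL

#' Boundary surfaces for metric extraction
#'
#' A boundary set carries the three surfaces the choroidal metrics are
#' measured between, as real-valued row indices per (fast, slow) lateral
#' position of a specific volume grid: internal limiting membrane (ILM),
#' retinal pigment epithelium (RPE) and choroidal-scleral interface (CSI).
#' The \code{source} label records the provenance of the surfaces
#' (\code{"ground_truth"} from a phantom, \code{"estimated"} from the
#' image, or \code{"manual-proxy"} for an externally supplied
#' delineation); the CSI is never silently invented.
#'
#' @param ilm_row,rpe_row,csi_row numeric (fast x slow) matrices of row
#'   indices; must satisfy ilm < rpe < csi wherever all are defined.
#' @param source provenance label.
#' @return A list of class \code{"BoundarySet"}.
#' @export
boundarySet <- function(ilm_row, rpe_row, csi_row,
                        source = c("ground_truth", "estimated",
                                   "manual-proxy")) {
  source <- match.arg(source)
  ok <- is.finite(ilm_row) & is.finite(rpe_row) & is.finite(csi_row)
  # csi may touch rpe (zero-thickness choroid is a legal degenerate band)
  if (any(ilm_row[ok] >= rpe_row[ok]) || any(rpe_row[ok] > csi_row[ok]))
    stop("boundary ordering violated: need ilm < rpe <= csi")
  structure(list(ilm_row = ilm_row, rpe_row = rpe_row, csi_row = csi_row,
                 source = source), class = "BoundarySet")
}

#' Ground-truth boundaries of a phantom on its rendering grid
#'
#' Converts the analytic mm surfaces of an [EyePhantom-class] to row
#' indices of its (unflattened, uncropped) reference rendering.
#'
#' @param eye An [EyePhantom-class].
#' @return A \code{"BoundarySet"} with \code{source = "ground_truth"}.
#' @export
boundariesFromPhantom <- function(eye) {
  d <- dim(eye@reference@vol)
  vox <- eye@reference@fov[1] / d[1]
  boundarySet(eye@ilm / vox + 0.5, eye@rpe / vox + 0.5,
              eye@csi / vox + 0.5, source = "ground_truth")
}

# CSI estimator: the choroid is the deepest region where the (smoothed)
# profile still returns above a contrast threshold placed between the
# near-RPE stromal level and the deep background level; the CSI is the
# end of the deepest sustained above-threshold run. Scanning for the
# deepest run (rather than the first drop) keeps dark vessel lumens
# inside the choroid from truncating the band.
.estimateCSIcols <- function(m, rpeRows, vox, sustain_mm = 0.03,
                             near_mm = c(0.03, 0.09), frac = 0.5) {
  nd <- nrow(m); nf <- ncol(m)
  csi <- numeric(nf); conf <- numeric(nf)
  k <- max(2L, round(sustain_mm / vox))
  for (f in seq_len(nf)) {
    r0 <- round(rpeRows[f])
    lo <- min(nd, r0 + max(2L, round(near_mm[1] / vox)))
    hi <- min(nd, r0 + round(near_mm[2] / vox))
    stroma <- stats::median(m[lo:hi, f])
    deep <- m[min(nd, r0 + round(0.6 / vox)):nd, f]
    bg <- stats::quantile(deep, 0.1, names = FALSE)
    th <- bg + frac * max(stroma - bg, 0)
    above <- m[, f] >= th
    above[seq_len(min(lo - 1L, nd))] <- FALSE
    rl <- rle(above)
    ends <- cumsum(rl$lengths)
    good <- which(rl$values & rl$lengths >= k)
    if (!length(good)) { csi[f] <- lo; conf[f] <- 0 }
    else {
      csi[f] <- ends[max(good)] + 0.5
      conf[f] <- min(max(stroma - bg, 0) * 4, 1)
    }
  }
  list(csi = csi, conf = conf)
}

#' Estimate all three boundaries from a volume
#'
#' ILM: shallowest dominant bright band. RPE: [estimateRPE()]. CSI: per
#' A-scan, the deepest sustained drop of the (axially smoothed) sub-RPE
#' profile below a threshold placed between the near-RPE stromal level
#' and the deep background level, followed by the same lateral
#' median/Gaussian regularization as the other surfaces. On volumes
#' where the choroid carries no signal (shallow-penetration input) the
#' estimated CSI collapses toward the RPE, which is the expected,
#' honest behaviour of an image-based delineation.
#'
#' @param volume An [OCTVolume-class].
#' @param sigma axial smoothing sigma in rows.
#' @param prominence peak-prominence fraction for the RPE estimator. The
#'   ILM uses a lower prominence threshold (0.05) with a height criterion
#'   instead: the ILM band sits directly on the retinal base level, so
#'   its peak is bright but shallow.
#' @param csi_frac contrast fraction of the CSI threshold.
#' @param ilm_sigma axial smoothing sigma for the ILM estimator.
#' @param csi_row optional externally supplied CSI row matrix (the
#'   analogue of the manual CSI delineation); when given, the returned
#'   set is labelled \code{"manual-proxy"} and the image-based CSI
#'   estimator is not run.
#' @return A \code{"BoundarySet"} with \code{source = "estimated"} (or
#'   \code{"manual-proxy"} when \code{csi_row} is supplied).
#' @export
estimateBoundaries <- function(volume, sigma = 2, prominence = 0.25,
                               csi_frac = 0.5, csi_row = NULL,
                               ilm_sigma = 1) {
  rpe <- estimateRPE(volume, sigma, prominence)
  # the ILM is a one-sided vitreous-to-retina edge: heavy axial smoothing
  # drags its peak into the retina, so it gets a lighter kernel
  ilm <- .estimateBand(volume, ilm_sigma, prominence = 0.05,
                       smooth_sigma = 1.5,
                       deepest = FALSE, min_height = 0.5)
  v <- volume@vol
  d <- dim(v)
  vox <- volume@fov[1] / d[1]
  if (is.null(csi_row)) {
    csi <- matrix(NA_real_, d[2], d[3])
    for (s in seq_len(d[3])) {
      m <- .gaussSmoothCols(v[, , s], sigma)
      est <- .estimateCSIcols(m, rpe$depth_row[, s], vox, frac = csi_frac)
      csi[, s] <- est$csi
    }
    csi <- .gaussSmooth2D(.median3x3(csi), 1.5)
    src <- "estimated"
  } else {
    csi <- csi_row
    src <- "manual-proxy"
  }
  ilmRow <- pmin(ilm$depth_row, rpe$depth_row - 1)
  csiRow <- pmax(csi, rpe$depth_row + 1)
  boundarySet(ilmRow, rpe$depth_row, csiRow, source = src)
}

#' Locate the fovea and form the averaged foveal B-scan
#'
#' The foveal B-scan is the one holding the thinnest retina (minimum
#' RPE - ILM) within a central search window (middle 50\% of both lateral
#' axes by default, avoiding edge artifacts), and the working image is
#' the arithmetic mean of that B-scan with its two neighbours. Ties break
#' toward the earliest index and are flagged; a fovea at the volume edge
#' averages the available neighbours and is flagged.
#'
#' @param volume An [OCTVolume-class].
#' @param boundaries A \code{"BoundarySet"} on the volume's grid.
#' @param central_frac fraction of each lateral axis searched (centred).
#' @return list(fovea = c(fast, slow), bscan = averaged depth x fast
#'   matrix, used_scans, ambiguous, at_edge).
#' @export
locateFovea <- function(volume, boundaries, central_frac = 0.5) {
  d <- dim(volume@vol)
  rt <- boundaries$rpe_row - boundaries$ilm_row
  win <- function(n) {
    h <- floor(n * central_frac / 2)
    c0 <- floor((n + 1) / 2)
    .clampIndex((c0 - h):(c0 + h), n)
  }
  fw <- win(d[2]); sw <- win(d[3])
  sub <- rt[fw, sw, drop = FALSE]
  mn <- min(sub)
  hits <- which(sub == mn, arr.ind = TRUE)
  ambiguous <- nrow(hits) > 1L
  fovea <- c(fw[hits[1, 1]], sw[hits[1, 2]])
  s0 <- fovea[2]
  used <- s0 + (-1:1)
  used <- used[used >= 1 & used <= d[3]]
  bscan <- apply(volume@vol[, , used, drop = FALSE], c(1, 2), mean)
  list(fovea = as.integer(fovea), bscan = bscan, used_scans = used,
       ambiguous = ambiguous, at_edge = length(used) < 3L)
}

#' Subfoveal thickness from boundary rows
#'
#' Measured axially on flattened images ("perpendicular" marking
#' collapses to the axial direction after flattening):
#' (lower - upper) rows times the axial sampling, in mm.
#'
#' @param boundaries A \code{"BoundarySet"}.
#' @param fovea integer(2) (fast, slow) index.
#' @param which \code{"retina"} (ILM to RPE) or \code{"choroid"} (RPE to CSI).
#' @param axial_mm_per_row axial digital sampling in mm per row.
#' @return Thickness in mm.
#' @export
subfovealThickness <- function(boundaries, fovea,
                               which = c("retina", "choroid"),
                               axial_mm_per_row) {
  which <- match.arg(which)
  up <- if (which == "retina") boundaries$ilm_row else boundaries$rpe_row
  lo <- if (which == "retina") boundaries$rpe_row else boundaries$csi_row
  a <- up[fovea[1], fovea[2]]; b <- lo[fovea[1], fovea[2]]
  if (!is.finite(a) || !is.finite(b))
    stop("boundary undefined at the fovea")
  (b - a) * axial_mm_per_row
}

#' Choroidal area on a B-scan
#'
#' CA is integrated as sum over A-scans of (CSI - RPE) rows times the
#' pixel area, and cross-checked against a direct pixel count of the
#' band; both are returned. Crossing boundaries raise an error naming the
#' offending A-scan range.
#'
#' @param rpe_row,csi_row numeric vectors of row indices per A-scan.
#' @param vox_axial_mm,vox_fast_mm pixel sizes in mm.
#' @param n_depth optional row count for clipping the pixel count.
#' @return list(ca_mm2, ca_pixel_mm2, n_pixels).
#' @export
choroidalArea <- function(rpe_row, csi_row, vox_axial_mm, vox_fast_mm,
                          n_depth = NULL) {
  bad <- which(csi_row < rpe_row)
  if (length(bad))
    stop(sprintf("crossing boundaries (csi < rpe) at A-scans %d..%d",
                 min(bad), max(bad)))
  ca <- sum(csi_row - rpe_row) * vox_axial_mm * vox_fast_mm
  hi <- if (is.null(n_depth)) csi_row else pmin(csi_row, n_depth)
  npix <- sum(pmax(0, floor(hi) - floor(rpe_row)))
  list(ca_mm2 = ca, ca_pixel_mm2 = npix * vox_axial_mm * vox_fast_mm,
       n_pixels = npix)
}

#' Choroidal volume from boundary surfaces
#'
#' CV integrates (CSI - RPE) over the full lateral grid times the voxel
#' volume. Surfaces undefined on more than 5\% of the grid raise an
#' error; smaller gaps are filled from the finite median and flagged.
#'
#' @param rpe_row,csi_row numeric (fast x slow) matrices of row indices.
#' @param vox_mm numeric(3) voxel size in mm (axial, fast, slow).
#' @return list(cv_mm3, interpolated_frac).
#' @export
choroidalVolume <- function(rpe_row, csi_row, vox_mm) {
  h <- csi_row - rpe_row
  bad <- !is.finite(h)
  frac <- mean(bad)
  if (frac > 0.05)
    stop(sprintf("surfaces undefined on %.1f%% of the grid", 100 * frac))
  if (any(bad)) h[bad] <- stats::median(h[!bad])
  if (any(h < 0)) stop("crossing boundaries (csi < rpe)")
  list(cv_mm3 = sum(h) * prod(vox_mm), interpolated_frac = frac)
}

#' Niblack local thresholding
#'
#' Per-pixel threshold T = local_mean + k * local_sd over a square
#' window (mirrored edges); the luminal mask is the set of pixels inside
#' the band mask with intensity strictly below T. Local statistics are
#' computed over the full patch; mask membership only restricts which
#' pixels can be luminal.
#'
#' @param region numeric intensity matrix.
#' @param mask logical matrix (the choroid band); must be nonempty.
#' @param window odd window size >= 3.
#' @param k Niblack coefficient. The default +0.2 follows the standard
#'   Niblack parameterization (threshold above the local mean) with dark
#'   pixels selected below it; a negative k places the threshold below
#'   the local mean and then provably excludes the interior of any
#'   homogeneous lumen (local sd near 0 implies T < mean).
#' @return Logical matrix: the luminal (dark) pixels.
#' @export
niblackBinarize <- function(region, mask, window = 51L, k = 0.2) {
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3")
  if (!any(mask)) stop("empty band mask")
  st <- .boxStats(region, window)
  mask & (region < st$mean + k * st$sd)
}

#' Choroidal vascularity index of a foveal B-scan
#'
#' Applies the documented deterministic contrast stretch (percentile
#' window to [0, 255]), builds the choroid band between RPE and CSI,
#' binarizes with [niblackBinarize()] and returns luminal area, band
#' (choroidal) area and their ratio CVI = LA / CA. A zero-area band
#' yields an undefined (NA) CVI, never 0.
#'
#' @param bscan numeric depth x fast intensity matrix in [0, 1].
#' @param rpe_row,csi_row row-index vectors per A-scan.
#' @param vox_mm numeric(2) pixel size (axial, fast) in mm.
#' @param window,k Niblack parameters (window in pixels, capped at the
#'   B-scan width; wide windows are deliberate -- the local statistics
#'   must bridge whole vessel lumens, or their interiors fall above the
#'   local threshold).
#' @param stretch percentile window of the contrast adjustment.
#' @return list(la_mm2, ca_mm2, cvi, lumen = logical matrix).
#' @export
computeCVI <- function(bscan, rpe_row, csi_row, vox_mm, window = 51L,
                       k = 0.2, stretch = c(0.01, 0.99)) {
  window <- min(as.integer(window),
                as.integer(ncol(bscan) - 1 + ncol(bscan) %% 2))
  q <- stats::quantile(bscan, stretch, names = FALSE)
  img <- if (q[2] - q[1] < 1e-12) bscan * 0 else
    pmin(pmax((bscan - q[1]) / (q[2] - q[1]), 0), 1) * 255
  nd <- nrow(bscan)
  rows <- seq_len(nd)
  mask <- outer(rows, rpe_row, `>`) & outer(rows, csi_row, `<=`)
  nBand <- sum(mask)
  pixArea <- vox_mm[1] * vox_mm[2]
  if (nBand == 0)
    return(list(la_mm2 = 0, ca_mm2 = 0, cvi = NA_real_,
                lumen = mask & FALSE))
  lumen <- niblackBinarize(img, mask, window, k)
  la <- sum(lumen) * pixArea
  ca <- nBand * pixArea
  list(la_mm2 = la, ca_mm2 = ca, cvi = la / ca, lumen = lumen)
}

#' Full per-eye metric extraction
#'
#' Locates the fovea, forms the averaged foveal B-scan, measures
#' subfoveal retinal and choroidal thickness, choroidal area on the
#' averaged B-scan, choroidal volume over the full grid and the
#' Niblack-based CVI, all in physical units from the volume calibration.
#' Boundary rows on the averaged B-scan are the mean of the rows of the
#' scans entering the average.
#'
#' @param volume An [OCTVolume-class].
#' @param boundaries A \code{"BoundarySet"} on the volume's grid.
#' @param niblack list(window, k).
#' @param stretch contrast-stretch percentiles for CVI.
#' @param central_frac fovea search window fraction.
#' @return A [ChoroidMetrics-class].
#' @export
choroidMetrics <- function(volume, boundaries,
                           niblack = list(window = 51L, k = 0.2),
                           stretch = c(0.01, 0.99), central_frac = 0.5) {
  vox <- voxelSizeMM(volume)
  fv <- locateFovea(volume, boundaries, central_frac)
  avg <- function(m) rowMeans(m[, fv$used_scans, drop = FALSE])
  rpeB <- avg(boundaries$rpe_row); csiB <- avg(boundaries$csi_row)
  ilmB <- avg(boundaries$ilm_row)
  rt <- (rpeB[fv$fovea[1]] - ilmB[fv$fovea[1]]) * vox[1]
  ct <- (csiB[fv$fovea[1]] - rpeB[fv$fovea[1]]) * vox[1]
  caRes <- choroidalArea(rpeB, csiB, vox[1], vox[2],
                         n_depth = dim(volume@vol)[1])
  cvRes <- choroidalVolume(boundaries$rpe_row, boundaries$csi_row, vox)
  cviRes <- computeCVI(fv$bscan, rpeB, csiB, vox[1:2],
                       window = niblack[["window"]], k = niblack[["k"]],
                       stretch = stretch)
  new("ChoroidMetrics", rt = unname(rt), ct = unname(ct),
      ca = unname(caRes$ca_mm2), cv = unname(cvRes$cv_mm3),
      la = unname(cviRes$la_mm2), cvi = unname(cviRes$cvi),
      fovea = fv$fovea, source = boundaries$source,
      calibration = list(vox_mm = vox, niblack = niblack,
                         stretch = stretch,
                         ca_pixel_mm2 = caRes$ca_pixel_mm2,
                         fovea_ambiguous = fv$ambiguous,
                         fovea_at_edge = fv$at_edge))
}
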