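#' @include utils-image.R
NULL

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so phantom generation never perturbs
# user-level randomness.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.deriveSeed <- function(seed, salt) {
  as.integer((as.double(seed) * 48271 + salt) %% 2147483647)
}

#' Device acquisition profiles
#'
#' A device profile captures the acquisition geometry and noise behaviour
#' of one OCT device: grid shape, field of view, the exponential
#' attenuation of signal below the RPE (the depth-penetration limit of
#' shallow-penetration spectral-domain devices; 0 for deep-penetration
#' swept-source devices), and the multiplicative-speckle "looks" parameter
#' (larger = cleaner; \code{Inf} disables speckle).
#'
#' `sdoctProfile()` and `ssoctProfile()` return the two study devices: a
#' spectral-domain unit acquiring 245 A-scans x 245 B-scans over
#' 3 x 3 x 2 mm, and a swept-source unit acquiring 300 x 300 over
#' 3 x 3 x 3 mm.
#'
#' @param name device label.
#' @param n_ascans,n_bscans,n_depth grid counts (fast, slow, axial); all >= 8.
#' @param fov_mm numeric(3) field of view in mm, order (fast, slow, axial).
#' @param attenuation_below_rpe exponential decay coefficient per mm of
#'   depth below the RPE (>= 0; 0 disables attenuation).
#' @param speckle_looks positive number of looks of the multiplicative
#'   Gamma speckle model (mean 1, variance 1/looks); \code{Inf} = noise-free.
#' @param noise_floor sd of the additive detector-noise floor (on the
#'   [0, 1] intensity scale); signal attenuated below this level is
#'   effectively lost, which is what makes the choroidal-scleral
#'   interface invisible to the shallow-penetration device.
#' @return A list of class \code{"DeviceProfile"}.
#' @examples
#' sdoctProfile()
#' ssoctProfile(n_depth = 128)
#' @export
deviceProfile <- function(name, n_ascans, n_bscans, n_depth, fov_mm,
                          attenuation_below_rpe = 0, speckle_looks = Inf,
                          noise_floor = 0) {
  counts <- c(n_ascans = n_ascans, n_bscans = n_bscans, n_depth = n_depth)
  if (any(counts < 8)) stop("all grid counts must be >= 8")
  if (length(fov_mm) != 3 || any(fov_mm <= 0))
    stop("fov_mm must be 3 positive values (fast, slow, axial)")
  if (attenuation_below_rpe < 0) stop("attenuation_below_rpe must be >= 0")
  if (speckle_looks <= 0) stop("speckle_looks must be > 0")
  if (noise_floor < 0) stop("noise_floor must be >= 0")
  structure(list(name = name, n_ascans = as.integer(n_ascans),
                 n_bscans = as.integer(n_bscans),
                 n_depth = as.integer(n_depth),
                 fov_mm = as.numeric(fov_mm),
                 attenuation_below_rpe = attenuation_below_rpe,
                 speckle_looks = speckle_looks,
                 noise_floor = noise_floor),
            class = "DeviceProfile")
}

#' @rdname deviceProfile
#' @export
sdoctProfile <- function(n_ascans = 245L, n_bscans = 245L, n_depth = 512L,
                         fov_mm = c(3, 3, 2), attenuation_below_rpe = 6,
                         speckle_looks = 15, noise_floor = 0.02) {
  deviceProfile("sdoct", n_ascans, n_bscans, n_depth, fov_mm,
                attenuation_below_rpe, speckle_looks, noise_floor)
}

#' @rdname deviceProfile
#' @export
ssoctProfile <- function(n_ascans = 300L, n_bscans = 300L, n_depth = 512L,
                         fov_mm = c(3, 3, 3), attenuation_below_rpe = 0,
                         speckle_looks = 15, noise_floor = 0.01) {
  deviceProfile("ssoct", n_ascans, n_bscans, n_depth, fov_mm,
                attenuation_below_rpe, speckle_looks, noise_floor)
}

#' Phantom generation parameters
#'
#' Study-condition parameters for one synthetic eye. Defaults reproduce a
#' healthy macular cohort: subfoveal retinal thickness 0.22 +/- 0.02 mm,
#' choroidal thickness 0.25 +/- 0.08 mm, and a target choroidal luminal
#' (vessel) fraction of 0.65.
#'
#' @param retinal_thickness_mm c(mean, sd) of the ILM-to-RPE distance.
#' @param choroidal_thickness_mm c(mean, sd) of the RPE-to-CSI distance.
#' @param fovea_depth_mm,fovea_radius_mm Gaussian foveal pit depth and
#'   radius (sigma) applied to the ILM only.
#' @param fovea_jitter_mm sd of the random lateral displacement of the pit
#'   centre from the volume centre (0 pins it to the centre voxel).
#' @param vessel_fraction target luminal fraction of the choroid in [0, 1];
#'   vessels are rejection-placed until the realized fraction is within
#'   +/- 0.02 of this target.
#' @param vessel_radius_px c(min, max) vessel radius range in pixels of the
#'   rendering grid.
#' @param surface_undulation c(amplitude_mm, wavelength_mm) of the smooth
#'   boundary curvature.
#' @param reflectance_texture c(relative_amplitude, wavelength_mm) of the
#'   smooth lateral reflectivity modulation shared by both device
#'   renderings (the tissue's own reflectance pattern); this is the
#'   lateral structure enface registration locks onto.
#' @param lateral_offset_mm numeric(2) (fast, slow) inter-device shift
#'   injected when degrading to the shallow-penetration device.
#' @param ilm_depth_mm mean depth of the ILM below the volume top.
#' @param signal_strength integer 1--10 scan-quality index; scales the
#'   device speckle looks linearly (strength/10 of the profile looks).
#' @param seed integer RNG seed; the whole phantom is deterministic in it.
#' @return A list of class \code{"PhantomParams"}.
#' @examples
#' phantomParams(seed = 1)
#' @export
phantomParams <- function(retinal_thickness_mm = c(0.22, 0.02),
                          choroidal_thickness_mm = c(0.25, 0.08),
                          fovea_depth_mm = 0.10, fovea_radius_mm = 0.35,
                          fovea_jitter_mm = 0,
                          vessel_fraction = 0.65,
                          vessel_radius_px = c(2, 5),
                          surface_undulation = c(0.04, 1.6),
                          reflectance_texture = c(0.12, 0.45),
                          lateral_offset_mm = c(0.05, -0.04),
                          ilm_depth_mm = 0.80,
                          signal_strength = 8L, seed = 1L) {
  if (vessel_fraction < 0 || vessel_fraction > 1)
    stop("vessel_fraction must lie in [0, 1]")
  if (retinal_thickness_mm[1] <= 0 || choroidal_thickness_mm[1] <= 0)
    stop("thickness means must be > 0")
  if (signal_strength < 1 || signal_strength > 10)
    stop("signal_strength must lie in 1..10")
  structure(list(retinal_thickness_mm = retinal_thickness_mm,
                 choroidal_thickness_mm = choroidal_thickness_mm,
                 fovea_depth_mm = fovea_depth_mm,
                 fovea_radius_mm = fovea_radius_mm,
                 fovea_jitter_mm = fovea_jitter_mm,
                 vessel_fraction = vessel_fraction,
                 vessel_radius_px = vessel_radius_px,
                 surface_undulation = surface_undulation,
                 reflectance_texture = reflectance_texture,
                 lateral_offset_mm = lateral_offset_mm,
                 ilm_depth_mm = ilm_depth_mm,
                 signal_strength = as.integer(signal_strength),
                 seed = as.integer(seed)),
            class = "PhantomParams")
}

.speckleLooks <- function(profile, signal_strength) {
  profile$speckle_looks * signal_strength / 10
}

.applySpeckle <- function(arr, looks) {
  if (!is.finite(looks)) return(arr)
  arr * array(stats::rgamma(length(arr), shape = looks, rate = looks), dim(arr))
}

# Band-limited smooth undulation field over an nf x ns lateral grid.
.undulation <- function(xmm, ymm, amplitude, wavelength) {
  if (amplitude <= 0) return(matrix(0, length(xmm), length(ymm)))
  ph <- stats::runif(4, 0, 2 * pi)
  f1 <- 2 * pi / wavelength
  f2 <- 2 * pi / (wavelength * 1.37)
  amplitude * 0.5 *
    (outer(sin(f1 * xmm + ph[1]), cos(f1 * ymm + ph[2])) +
     outer(cos(f2 * xmm + ph[3]), sin(f2 * ymm + ph[4])))
}

# Aperiodic band-limited random field (sum of randomly oriented
# sinusoids), normalized to the requested sd.
.randomField <- function(xmm, ymm, amplitude, wavelength, ncomp = 6L) {
  if (amplitude <= 0) return(matrix(0, length(xmm), length(ymm)))
  f <- matrix(0, length(xmm), length(ymm))
  for (i in seq_len(ncomp)) {
    th <- stats::runif(1, 0, 2 * pi)
    kk <- 2 * pi / (wavelength * stats::runif(1, 0.7, 1.5))
    ph <- stats::runif(1, 0, 2 * pi)
    f <- f + stats::rnorm(1) *
      sin(kk * (outer(cos(th) * xmm, sin(th) * ymm, `+`)) + ph)
  }
  f * amplitude / max(stats::sd(f), 1e-12)
}

# Expand an nf x ns lateral matrix to the (nd, nf, ns) volume grid.
.lateralToVolume <- function(m, nd) {
  array(rep(as.vector(m), each = nd), c(nd, nrow(m), ncol(m)))
}

#' Generate one synthetic eye
#'
#' Builds analytic ILM/RPE/CSI boundary surfaces (smooth undulation plus a
#' Gaussian foveal pit in the ILM), rejection-places vessel cylinders in
#' the choroid until the realized luminal fraction is within +/- 0.02 of
#' the target, renders the noise-free scene on the reference-device grid
#' (bright ILM/RPE bands, mid-bright choroidal stroma, dark lumens, dark
#' vitreous and sclera) and applies multiplicative Gamma speckle. The
#' result is bit-identical for a fixed seed.
#'
#' @param params a [phantomParams()] object.
#' @param ref_profile the reference (deep-penetration) [deviceProfile()].
#' @return An [EyePhantom-class] object (degraded slot unset; see
#'   [degradeEye()] / [generatePairedEye()]).
#' @examples
#' eye <- generateEye(phantomParams(seed = 3, vessel_fraction = 0),
#'                    ssoctProfile(n_ascans = 32, n_bscans = 16, n_depth = 64))
#' eye
#' @export
generateEye <- function(params, ref_profile) {
  stopifnot(inherits(params, "PhantomParams"),
            inherits(ref_profile, "DeviceProfile"))
  .withSeed(params$seed, .generateEyeImpl(params, ref_profile))
}

.generateEyeImpl <- function(params, ref_profile) {
  nf <- ref_profile$n_ascans; ns <- ref_profile$n_bscans
  nd <- ref_profile$n_depth
  fovF <- ref_profile$fov_mm[1]; fovS <- ref_profile$fov_mm[2]
  fovA <- ref_profile$fov_mm[3]
  dxF <- fovF / nf; dxS <- fovS / ns; dxA <- fovA / nd
  xmm <- (seq_len(nf) - 0.5) * dxF
  ymm <- (seq_len(ns) - 0.5) * dxS

  # Per-eye thickness realizations (truncated so ordering cannot break).
  rt <- max(stats::rnorm(1, params$retinal_thickness_mm[1],
                         params$retinal_thickness_mm[2]),
            params$fovea_depth_mm + 0.06)
  ct <- max(stats::rnorm(1, params$choroidal_thickness_mm[1],
                         params$choroidal_thickness_mm[2]), 0.08)

  und <- .undulation(xmm, ymm, params$surface_undulation[1],
                     params$surface_undulation[2])
  base <- params$ilm_depth_mm + und

  # Foveal pit: radially symmetric Gaussian, in the ILM only.
  cx <- fovF / 2; cy <- fovS / 2
  if (params$fovea_jitter_mm > 0) {
    cx <- cx + stats::rnorm(1, 0, params$fovea_jitter_mm)
    cy <- cy + stats::rnorm(1, 0, params$fovea_jitter_mm)
  }
  r2 <- outer((xmm - cx)^2, (ymm - cy)^2, `+`)
  pit <- params$fovea_depth_mm * exp(-r2 / (2 * params$fovea_radius_mm^2))

  # The pit thins the retina toward the fovea; the configured retinal
  # thickness is the subfoveal (at-pit) ILM-RPE distance, the quantity
  # measured clinically.
  ilm <- base + pit
  rpe <- base + params$fovea_depth_mm + rt
  csi <- rpe + ct + 0.35 * .undulation(xmm, ymm, params$surface_undulation[1],
                                       params$surface_undulation[2])
  if (max(csi) > fovA - 2 * dxA)
    stop("axial field of view too shallow for the requested geometry")

  rtMap <- rpe - ilm
  fov_idx <- arrayInd(which.min(rtMap), dim(rtMap))
  fovea <- as.integer(fov_idx[1, ])

  # Voxelized choroid band and vessel placement.
  dmm <- (seq_len(nd) - 0.5) * dxA
  D <- array(dmm, c(nd, nf, ns))
  RPE3 <- .lateralToVolume(rpe, nd)
  CSI3 <- .lateralToVolume(csi, nd)
  band <- D > RPE3 & D <= CSI3
  lumen <- array(FALSE, c(nd, nf, ns))
  nBand <- sum(band)

  if (params$vessel_fraction > 0) {
    rRange <- params$vessel_radius_px
    bandRows <- stats::median((csi - rpe)) / dxA
    # adapt radii to the rendering resolution: a vessel never exceeds a
    # third of the band height
    rRange[2] <- min(rRange[2], max(rRange[1], floor(bandRows / 3)))
    if (2 * rRange[1] > bandRows)
      stop(sprintf(paste0("choroid too thin for the requested vessels: ",
                          "median band height %.1f rows < vessel diameter %d px"),
                   bandRows, 2L * as.integer(rRange[1])))
    target <- params$vessel_fraction
    attempts <- 0L
    while (sum(lumen) / nBand < target - 0.02 && attempts < 2000L) {
      attempts <- attempts + 1L
      frac <- sum(lumen) / nBand
      r <- if (target - frac < 0.06) rRange[1] else
        stats::runif(1, rRange[1], rRange[2])
      f0 <- sample.int(nf, 1)
      tfrac <- stats::runif(1, 0.15, 0.85)
      z0 <- (rpe[f0, ] + tfrac * (csi[f0, ] - rpe[f0, ])) / dxA + 0.5
      # keep a clearance of the vessel below the RPE band so lumens never
      # erode the bright band the flattening stage relies on; where the
      # band is too thin to honour the clearance the vessel simply does
      # not pass (no vessel is allowed to bite into the RPE)
      margin <- ceiling(2 * max(0.008, 1.2 * dxA) / dxA) + 1L
      zlo <- rpe[f0, ] / dxA + 0.5 + r + margin
      zhi <- csi[f0, ] / dxA + 0.5 - r
      fits <- zhi >= zlo
      z0 <- pmin(pmax(z0, zlo), pmax(zlo, zhi))
      prev <- lumen
      off <- expand.grid(dz = -floor(r):floor(r), df = -floor(r):floor(r))
      off <- off[off$dz^2 + off$df^2 <= r^2, , drop = FALSE]
      for (k in seq_len(nrow(off))) {
        zz <- as.integer(round(z0)) + off$dz[k]
        ff <- f0 + off$df[k]
        ok <- fits & zz >= 1L & zz <= nd & ff >= 1L & ff <= nf
        if (!any(ok)) next
        idx <- cbind(zz[ok], ff, which(ok))
        lumen[idx] <- TRUE
      }
      lumen <- lumen & band
      if (sum(lumen) / nBand > target + 0.02) lumen <- prev
    }
    if (abs(sum(lumen) / nBand - target) > 0.02)
      warning(sprintf("realized luminal fraction %.3f misses target %.3f",
                      sum(lumen) / nBand, target))
  }

  # Noise-free scene rendering.
  ILM3 <- .lateralToVolume(ilm, nd)
  sigB <- max(0.008, 1.2 * dxA)
  # Retina and choroidal stroma share one base level so the RPE is a
  # clean symmetric bright band (no step bias for the peak estimator);
  # contrast with the sclera marks the CSI, dark lumens mark vessels.
  # Amplitudes keep the brightest peak (~0.85) below 1 for typical
  # reflectance-texture excursions: a clipped, flat-topped band would
  # defeat sub-row peak refinement.
  scene <- 0.05 +
    (D >= ILM3) * 0.35 +          # vitreous -> retina/stroma
    (D > CSI3) * (-0.30) +        # stroma -> sclera
    0.42 * exp(-(D - ILM3)^2 / (2 * sigB^2)) +
    0.45 * exp(-(D - RPE3)^2 / (2 * sigB^2))
  scene[lumen] <- 0.15
  tex <- 1 + .randomField(xmm, ymm, params$reflectance_texture[1],
                          params$reflectance_texture[2])
  scene <- scene * .lateralToVolume(tex, nd)
  scene <- pmin(pmax(scene, 0), 1)

  looks <- .speckleLooks(ref_profile, params$signal_strength)
  refArr <- .applySpeckle(scene, looks)
  if (ref_profile$noise_floor > 0)
    refArr <- refArr + array(stats::rnorm(length(refArr), 0,
                                          ref_profile$noise_floor),
                             dim(refArr))
  refArr <- pmin(pmax(refArr, 0), 1.5)
  reference <- octVolume(refArr,
                         fov = c(fovA, fovF, fovS),
                         device = ref_profile$name,
                         signalStrength = params$signal_strength,
                         meta = list(seed = params$seed, role = "reference"))
  new("EyePhantom", ilm = ilm, rpe = rpe, csi = csi, lumen = lumen,
      fovea = fovea, params = unclass(params), scene = scene,
      reference = reference, degraded = NULL)
}

#' Realized luminal fraction of a phantom
#'
#' Ratio of lumen voxels to choroid-band voxels on the reference grid;
#' this is the phantom's ground-truth CVI by construction.
#'
#' @param eye An [EyePhantom-class].
#' @return A number in [0, 1] (NaN for an empty band).
#' @export
phantomLumenFraction <- function(eye) {
  d <- dim(eye@scene)
  dxA <- eye@reference@fov[1] / d[1]
  dmm <- (seq_len(d[1]) - 0.5) * dxA
  D <- array(dmm, d)
  band <- D > .lateralToVolume(eye@rpe, d[1]) &
    D <= .lateralToVolume(eye@csi, d[1])
  sum(eye@lumen) / sum(band)
}

#' Degrade a phantom to the shallow-penetration device
#'
#' Resamples the noise-free scene onto the shallow-penetration grid (its
#' own axial span, measured from the volume top), applies exponential
#' signal attenuation below the RPE (\code{exp(-attenuation * depth_below_rpe)}),
#' injects the configured lateral inter-device offset, and multiplies
#' independent speckle. Emulates the progressive signal loss towards the
#' choroid that limits spectral-domain imaging.
#'
#' @param eye An [EyePhantom-class].
#' @param sd_profile the shallow-penetration [deviceProfile()].
#' @param speckle logical; FALSE renders a noise-free degraded volume.
#' @return An [OCTVolume-class] on the \code{sd_profile} grid.
#' @export
degradeEye <- function(eye, sd_profile, speckle = TRUE) {
  stopifnot(inherits(sd_profile, "DeviceProfile"))
  par <- eye@params
  off <- par$lateral_offset_mm
  if (any(abs(off) > 0.5 * sd_profile$fov_mm[1:2]))
    stop("lateral offset exceeds half of the field of view")
  src <- eye@scene
  d <- dim(src)
  refFov <- eye@reference@fov            # (axial, fast, slow)
  voxR <- refFov / d
  ndT <- sd_profile$n_depth; nfT <- sd_profile$n_ascans
  nsT <- sd_profile$n_bscans
  fovT <- sd_profile$fov_mm              # (fast, slow, axial)

  dT <- (seq_len(ndT) - 0.5) * fovT[3] / ndT
  xT <- (seq_len(nfT) - 0.5) * fovT[1] / nfT + off[1]
  yT <- (seq_len(nsT) - 0.5) * fovT[2] / nsT + off[2]
  coords <- list(dT / voxR[1] + 0.5, xT / voxR[2] + 0.5, yT / voxR[3] + 0.5)
  out <- .resampleArray(src, coords)
  out <- pmin(pmax(out, 0), 1)

  alpha <- sd_profile$attenuation_below_rpe
  if (alpha > 0) {
    Wf <- .lanczosMatrix(d[2], coords[[2]])
    Ws <- .lanczosMatrix(d[3], coords[[3]])
    rpeT <- Wf %*% eye@rpe %*% t(Ws)
    below <- pmax(array(dT, c(ndT, nfT, nsT)) - .lateralToVolume(rpeT, ndT), 0)
    out <- out * exp(-alpha * below)
  }

  if (speckle) {
    looks <- .speckleLooks(sd_profile, par$signal_strength)
    out <- .withSeed(.deriveSeed(par$seed, 104729), {
      o <- .applySpeckle(out, looks)
      if (sd_profile$noise_floor > 0)
        o <- o + array(stats::rnorm(length(o), 0, sd_profile$noise_floor),
                       dim(o))
      pmin(pmax(o, 0), 1.5)
    })
  }
  octVolume(out, fov = c(fovT[3], fovT[1], fovT[2]),
            device = sd_profile$name,
            signalStrength = par$signal_strength,
            meta = list(seed = par$seed, role = "input",
                        lateral_offset_mm = off))
}

#' Generate a paired phantom eye
#'
#' Convenience wrapper: [generateEye()] on the reference profile followed
#' by [degradeEye()] on the shallow-penetration profile, stored in the
#' phantom's \code{degraded} slot.
#'
#' @inheritParams generateEye
#' @param sd_profile the shallow-penetration [deviceProfile()].
#' @param speckle logical, forwarded to [degradeEye()].
#' @return An [EyePhantom-class] with both renderings populated.
#' @export
generatePairedEye <- function(params, ref_profile, sd_profile,
                              speckle = TRUE) {
  eye <- generateEye(params, ref_profile)
  eye@degraded <- degradeEye(eye, sd_profile, speckle = speckle)
  eye
}

#' Analytic ground-truth metrics of a phantom
#'
#' Computes the per-eye measurements directly from the phantom geometry
#' with no image processing: subfoveal retinal and choroidal thickness
#' from the surfaces at the fovea, choroidal area by integrating
#' (CSI - RPE) across the foveal B-scan, choroidal volume by integrating
#' over the full lateral grid, and luminal area / CVI from the voxelized
#' lumen mask on the foveal B-scan. A zero-thickness choroid yields CA =
#' CV = 0 with CVI flagged undefined (NA), never 0.
#'
#' @param eye An [EyePhantom-class].
#' @param center_halfwidth_px optional half-width (in fast-axis pixels of
#'   the reference grid) of a centred window around the fovea over which
#'   area and luminal area are integrated; default uses the full B-scan.
#' @return A [ChoroidMetrics-class] with \code{source = "ground_truth"}.
#' @export
groundTruthMetrics <- function(eye, center_halfwidth_px = NULL) {
  d <- dim(eye@scene)
  voxA <- eye@reference@fov[1] / d[1]
  voxF <- eye@reference@fov[2] / d[2]
  voxS <- eye@reference@fov[3] / d[3]
  fv <- eye@fovea
  rt <- eye@rpe[fv[1], fv[2]] - eye@ilm[fv[1], fv[2]]
  ct <- eye@csi[fv[1], fv[2]] - eye@rpe[fv[1], fv[2]]

  cols <- seq_len(d[2])
  if (!is.null(center_halfwidth_px))
    cols <- .clampIndex((fv[1] - center_halfwidth_px):(fv[1] + center_halfwidth_px),
                        d[2])
  cols <- unique(cols)
  ctProfile <- eye@csi[cols, fv[2]] - eye@rpe[cols, fv[2]]
  ca <- sum(ctProfile) * voxF
  cv <- sum(eye@csi - eye@rpe) * voxF * voxS

  dmm <- (seq_len(d[1]) - 0.5) * voxA
  bandB <- outer(dmm, eye@rpe[cols, fv[2]], `>`) &
    outer(dmm, eye@csi[cols, fv[2]], `<=`)
  lumB <- eye@lumen[, cols, fv[2], drop = TRUE]
  nBand <- sum(bandB); nLum <- sum(lumB & bandB)
  la <- nLum * voxA * voxF
  cvi <- if (nBand == 0) NA_real_ else nLum / nBand
  new("ChoroidMetrics", rt = unname(rt), ct = unname(ct),
      ca = unname(ca), cv = unname(cv), la = unname(la),
      cvi = unname(cvi), fovea = fv, source = "ground_truth",
      calibration = list(vox_mm = c(axial = voxA, fast = voxF, slow = voxS),
                         center_halfwidth_px = center_halfwidth_px))
}
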