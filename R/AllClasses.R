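#' @include AllGenerics.R
NULL

.AXES <- c("axial", "fast", "slow")

setClassUnion("OCTVolumeOrNULL", "NULL")

#' OCTVolume: a calibrated 3-D OCT intensity volume
#'
#' Container for one acquired (or simulated) OCT volume. The intensity
#' array is stored depth-first: dimension 1 is the axial (depth) axis with
#' row 1 at the vitreous (top), dimension 2 the fast lateral axis (A-scan
#' index within a B-scan) and dimension 3 the slow lateral axis (B-scan
#' index). The physical field of view is carried in mm for each axis so
#' that voxel sizes are always recoverable.
#'
#' @slot vol numeric 3-D array, intensities (normalized volumes use [0, 1]).
#' @slot fov named numeric(3), field of view in mm for axes
#'   \code{c(axial, fast, slow)}.
#' @slot device character scalar device label (e.g. \code{"sdoct"}).
#' @slot laterality character scalar, \code{"OD"}, \code{"OS"} or \code{"NA"}.
#' @slot signalStrength integer 1--10 manufacturer-style quality index
#'   (\code{NA} when unknown).
#' @slot meta list of free-form provenance entries.
#'
#' @seealso [octVolume()] for construction, [accessors].
#' @export
setClass("OCTVolume",
  representation(
    vol = "array",
    fov = "numeric",
    device = "character",
    laterality = "character",
    signalStrength = "integer",
    meta = "list"
  )
)

setIs("OCTVolume", "OCTVolumeOrNULL")

setValidity("OCTVolume", function(object) {
  msg <- NULL
  if (length(dim(object@vol)) != 3L)
    msg <- c(msg, "volume array must be 3-D (axial, fast, slow)")
  if (length(object@fov) != 3L || any(!is.finite(object@fov)) ||
      any(object@fov <= 0))
    msg <- c(msg, "fov must be 3 positive finite mm values")
  if (!identical(names(object@fov), .AXES))
    msg <- c(msg, "fov must be named c(axial, fast, slow)")
  ss <- object@signalStrength
  if (length(ss) != 1L || (!is.na(ss) && (ss < 1L || ss > 10L)))
    msg <- c(msg, "signalStrength must be a single integer in 1..10 or NA")
  if (is.null(msg)) TRUE else msg
})

#' Construct an OCTVolume
#'
#' @param vol numeric 3-D array ordered (axial, fast, slow).
#' @param fov numeric(3) field of view in mm, order (axial, fast, slow).
#' @param device device label.
#' @param laterality eye laterality label.
#' @param signalStrength integer quality index in 1--10, or NA.
#' @param meta list of provenance entries.
#' @return An [OCTVolume-class] object.
#' @examples
#' v <- octVolume(array(0, c(8, 8, 4)), fov = c(2, 3, 3))
#' dim(v)
#' voxelSizeMM(v)
#' @export
octVolume <- function(vol, fov, device = "generic", laterality = "NA",
                      signalStrength = NA_integer_, meta = list()) {
  fov <- as.numeric(fov)
  names(fov) <- .AXES
  new("OCTVolume", vol = vol, fov = fov, device = device,
      laterality = laterality,
      signalStrength = as.integer(signalStrength), meta = meta)
}

#' @rdname accessors
#' @export
setMethod("volData", "OCTVolume", function(object) object@vol)

#' @rdname accessors
#' @export
setMethod("fovMM", "OCTVolume", function(object) object@fov)

#' @rdname accessors
#' @export
setMethod("voxelSizeMM", "OCTVolume", function(object) object@fov / dim(object@vol))

#' @rdname accessors
#' @export
setMethod("deviceLabel", "OCTVolume", function(object) object@device)

#' @rdname accessors
#' @export
setMethod("signalStrength", "OCTVolume", function(object) object@signalStrength)

#' @describeIn OCTVolume dimensions of the intensity array.
#' @param x,object An \code{OCTVolume}.
#' @export
setMethod("dim", "OCTVolume", function(x) dim(x@vol))

#' @describeIn OCTVolume compact display.
#' @export
setMethod("show", "OCTVolume", function(object) {
  d <- dim(object@vol)
  cat(sprintf(
    "OCTVolume '%s' [%s]: %d x %d x %d voxels (axial x fast x slow), fov %.2f x %.2f x %.2f mm, signal %s\n",
    object@device, object@laterality, d[1], d[2], d[3],
    object@fov[1], object@fov[2], object@fov[3],
    ifelse(is.na(object@signalStrength), "NA",
           as.character(object@signalStrength))))
})

#' EyePhantom: ground-truth geometry plus rendered paired volumes
#'
#' One synthetic eye: analytic boundary surfaces (internal limiting
#' membrane, retinal pigment epithelium, choroidal-scleral interface) in mm
#' depth per lateral position, the voxelized choroidal vessel-lumen mask in
#' reference-volume coordinates, the fovea location, and the two rendered
#' volumes (deep-penetration reference and shallow-penetration degraded
#' copy). A noise-free rendering (\code{scene}) is kept so that degradation
#' can inject device-specific speckle independently of the reference's own
#' speckle.
#'
#' @slot ilm,rpe,csi numeric matrices (fast x slow) of boundary depth in mm.
#' @slot lumen logical array in reference-volume voxel coordinates.
#' @slot fovea integer(2), (fast, slow) index of the foveal pit.
#' @slot params list, the generating [phantomParams()] (with realized values).
#' @slot scene numeric array, noise-free reference-grid rendering.
#' @slot reference [OCTVolume-class], deep-penetration rendering.
#' @slot degraded \code{OCTVolume} or \code{NULL}, shallow-penetration copy.
#' @export
setClass("EyePhantom",
  representation(
    ilm = "matrix", rpe = "matrix", csi = "matrix",
    lumen = "array", fovea = "integer", params = "list",
    scene = "array", reference = "OCTVolume",
    degraded = "OCTVolumeOrNULL"
  )
)

setValidity("EyePhantom", function(object) {
  msg <- NULL
  if (!all(object@ilm < object@rpe) || !all(object@rpe < object@csi))
    msg <- c(msg, "boundary ordering violated: need ilm < rpe < csi everywhere")
  if (!identical(dim(object@lumen), dim(object@reference@vol)))
    msg <- c(msg, "lumen mask must share the reference volume grid")
  rt <- object@rpe - object@ilm
  fi <- object@fovea
  if (length(fi) != 2L || rt[fi[1], fi[2]] > min(rt) + 1e-12)
    msg <- c(msg, "fovea index must locate the minimum retinal thickness")
  if (is.null(msg)) TRUE else msg
})

#' @rdname accessors
#' @export
setMethod("referenceVolume", "EyePhantom", function(object) object@reference)

#' @rdname accessors
#' @export
setMethod("degradedVolume", "EyePhantom", function(object) object@degraded)

#' @rdname accessors
#' @export
setMethod("ilmSurface", "EyePhantom", function(object) object@ilm)

#' @rdname accessors
#' @export
setMethod("rpeSurface", "EyePhantom", function(object) object@rpe)

#' @rdname accessors
#' @export
setMethod("csiSurface", "EyePhantom", function(object) object@csi)

#' @rdname accessors
#' @export
setMethod("lumenMask", "EyePhantom", function(object) object@lumen)

#' @rdname accessors
#' @export
setMethod("foveaIndex", "EyePhantom", function(object) object@fovea)

#' @describeIn EyePhantom compact display.
#' @param object An \code{EyePhantom}.
#' @export
setMethod("show", "EyePhantom", function(object) {
  cat(sprintf(
    "EyePhantom: %d x %d lateral grid, RT %.3f mm, CT %.3f mm, lumen fraction %.3f, fovea (%d, %d)\n",
    nrow(object@ilm), ncol(object@ilm),
    mean(object@rpe - object@ilm), mean(object@csi - object@rpe),
    phantomLumenFraction(object), object@fovea[1], object@fovea[2]))
})

#' AlignedPair: a co-registered, identically-gridded volume pair
#'
#' The end product of paired preprocessing: the shallow-penetration input
#' volume and the deep-penetration reference volume on one shared grid and
#' calibration, ready for translator training or evaluation.
#'
#' @slot input,reference [OCTVolume-class] objects on identical grids.
#' @slot shift numeric(2), lateral (fast, slow) shift applied to the moving
#'   volume during registration, in voxels.
#' @slot provenance list: processing log (stage parameters, crops, shifts).
#' @export
setClass("AlignedPair",
  representation(
    input = "OCTVolume", reference = "OCTVolume",
    shift = "numeric", provenance = "list"
  )
)

setValidity("AlignedPair", function(object) {
  msg <- NULL
  if (!identical(dim(object@input@vol), dim(object@reference@vol)))
    msg <- c(msg, "input and reference must share one grid")
  if (!isTRUE(all.equal(object@input@fov, object@reference@fov)))
    msg <- c(msg, "input and reference must share one calibration")
  d <- dim(object@input@vol)
  if (any(abs(object@shift) >= 0.25 * d[2:3]))
    msg <- c(msg, "registration shift exceeds a quarter of the lateral extent")
  if (is.null(msg)) TRUE else msg
})

#' @rdname accessors
#' @export
setMethod("inputVolume", "AlignedPair", function(object) object@input)

#' @rdname accessors
#' @export
setMethod("referenceVolume", "AlignedPair", function(object) object@reference)

#' @rdname accessors
#' @export
setMethod("pairShift", "AlignedPair", function(object) object@shift)

#' @rdname accessors
#' @export
setMethod("pairProvenance", "AlignedPair", function(object) object@provenance)

#' @describeIn AlignedPair dimensions of the shared grid.
#' @param x,object An \code{AlignedPair}.
#' @export
setMethod("dim", "AlignedPair", function(x) dim(x@input@vol))

#' @describeIn AlignedPair compact display.
#' @export
setMethod("show", "AlignedPair", function(object) {
  d <- dim(object@input@vol)
  cat(sprintf(
    "AlignedPair: %d x %d x %d, fov %.2f x %.2f x %.2f mm, shift (%.2f, %.2f) px\n",
    d[1], d[2], d[3], object@input@fov[1], object@input@fov[2],
    object@input@fov[3], object@shift[1], object@shift[2]))
})

#' ChoroidMetrics: per-eye retinal and choroidal measurements
#'
#' Subfoveal retinal thickness (RT) and choroidal thickness (CT) in mm,
#' choroidal area (CA) on the foveal B-scan in mm^2, choroidal volume (CV)
#' in mm^3, luminal area (LA) in mm^2 and the choroidal vascularity index
#' CVI = LA / CA (a ratio in [0, 1], \code{NA} when CA = 0 so a degenerate
#' band is flagged as undefined rather than reported as 0).
#'
#' @slot rt,ct,ca,cv,la,cvi numeric scalars (see description; NA = undefined).
#' @slot fovea integer(2) (fast, slow) fovea index used.
#' @slot source character: \code{"ground_truth"}, \code{"estimated"} or
#'   \code{"manual-proxy"} boundary provenance.
#' @slot calibration list: voxel sizes and parameters used.
#' @export
setClass("ChoroidMetrics",
  representation(
    rt = "numeric", ct = "numeric", ca = "numeric", cv = "numeric",
    la = "numeric", cvi = "numeric", fovea = "integer",
    source = "character", calibration = "list"
  )
)

setValidity("ChoroidMetrics", function(object) {
  msg <- NULL
  vals <- c(object@rt, object@ct, object@ca, object@cv, object@la)
  if (any(!is.na(vals) & vals < 0))
    msg <- c(msg, "lengths/areas/volumes must be >= 0")
  if (!is.na(object@la) && !is.na(object@ca) && object@la > object@ca + 1e-9)
    msg <- c(msg, "luminal area cannot exceed choroidal area")
  if (!is.na(object@cvi) && (object@cvi < 0 || object@cvi > 1))
    msg <- c(msg, "cvi must lie in [0, 1] when defined")
  if (is.null(msg)) TRUE else msg
})

#' @rdname accessors
#' @export
setMethod("foveaIndex", "ChoroidMetrics", function(object) object@fovea)

#' @describeIn ChoroidMetrics one-row data.frame of the measurements.
#' @param x A \code{ChoroidMetrics}.
#' @param row.names,optional,... passed for generic compatibility (unused).
#' @export
setMethod("as.data.frame", "ChoroidMetrics",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(rt_mm = x@rt, ct_mm = x@ct, ca_mm2 = x@ca, cv_mm3 = x@cv,
               la_mm2 = x@la, cvi = x@cvi,
               fovea_fast = x@fovea[1], fovea_slow = x@fovea[2],
               source = x@source, stringsAsFactors = FALSE)
  })

#' @describeIn ChoroidMetrics compact display.
#' @param object A \code{ChoroidMetrics}.
#' @export
setMethod("show", "ChoroidMetrics", function(object) {
  cat(sprintf(
    "ChoroidMetrics [%s]: RT %.3f mm, CT %.3f mm, CA %.3f mm2, CV %.3f mm3, LA %.3f mm2, CVI %s\n",
    object@source, object@rt, object@ct, object@ca, object@cv, object@la,
    ifelse(is.na(object@cvi), "undefined", sprintf("%.3f", object@cvi))))
})

#' AgreementReport: per-metric agreement statistics for paired measurements
#'
#' Holds one row per metric with Pearson r, ICC(2,1) and MAE, each with a
#' seeded percentile-bootstrap 95\% confidence interval, F-test p-values,
#' and Bland-Altman bias and limits of agreement.
#'
#' @slot stats data.frame with columns metric, n, pearson_r, pearson_lo,
#'   pearson_hi, pearson_p, icc, icc_lo, icc_hi, icc_p, mae, mae_lo,
#'   mae_hi, ba_bias, ba_lo, ba_hi.
#' @slot nBoot integer bootstrap iteration count.
#' @slot seed integer bootstrap seed.
#' @export
setClass("AgreementReport",
  representation(stats = "data.frame", nBoot = "integer", seed = "integer"))

#' @describeIn AgreementReport the statistics table.
#' @param x An \code{AgreementReport}.
#' @param row.names,optional,... passed for generic compatibility (unused).
#' @export
setMethod("as.data.frame", "AgreementReport",
  function(x, row.names = NULL, optional = FALSE, ...) x@stats)

#' @describeIn AgreementReport compact display.
#' @param object An \code{AgreementReport}.
#' @export
setMethod("show", "AgreementReport", function(object) {
  cat(sprintf("AgreementReport (%d bootstrap iterations, seed %d)\n",
              object@nBoot, object@seed))
  df <- object@stats
  for (i in seq_len(nrow(df)))
    cat(sprintf(
      "  %-4s n=%3d r=%.3f [%.3f, %.3f] icc=%.3f [%.3f, %.3f] mae=%.4f [%.4f, %.4f] bias=%.4f\n",
      df$metric[i], df$n[i], df$pearson_r[i], df$pearson_lo[i],
      df$pearson_hi[i], df$icc[i], df$icc_lo[i], df$icc_hi[i],
      df$mae[i], df$mae_lo[i], df$mae_hi[i], df$ba_bias[i]))
})
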