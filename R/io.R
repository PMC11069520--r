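#' @include utils-image.R
NULL

.sidecarPath <- function(path) paste0(sub("\\.(tif|tiff|nii|nii\\.gz)$", "",
                                          path, ignore.case = TRUE),
                                      ".json")

.volMeta <- function(volume) {
  list(fov_mm = as.list(volume@fov), device = volume@device,
       laterality = volume@laterality,
       signal_strength = volume@signalStrength,
       dim = dim(volume@vol))
}

#' Read and write OCT volumes
#'
#' Volumes are written either as multi-page TIFF (one 16-bit page per
#' B-scan, depth x fast) or as NIfTI with mm voxel spacing in the header.
#' A JSON sidecar carries the calibration and device metadata that TIFF
#' cannot hold; intensities are clipped to [0, 1] on write.
#'
#' @param volume An [OCTVolume-class].
#' @param path output file (\code{.tif} or \code{.nii}/\code{.nii.gz}).
#' @param format \code{"tiff"} or \code{"nifti"}; inferred from the
#'   extension by default.
#' @return \code{writeOCTVolume}: the path, invisibly.
#' @export
writeOCTVolume <- function(volume, path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.nii(\\.gz)?$", path)) "nifti" else "tiff"
  v <- pmin(pmax(volume@vol, 0), 1)
  if (format == "tiff") {
    pages <- lapply(seq_len(dim(v)[3]), function(s) v[, , s])
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    vox <- volume@fov / dim(v)
    img <- RNifti::asNifti(v, pixdim = vox)
    RNifti::writeNifti(img, path)
  }
  jsonlite::write_json(.volMeta(volume), .sidecarPath(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeOCTVolume
#' @return \code{readOCTVolume}: the restored [OCTVolume-class].
#' @export
readOCTVolume <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.nii(\\.gz)?$", path)) "nifti" else "tiff"
  meta <- NULL
  sp <- .sidecarPath(path)
  if (file.exists(sp)) meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (format == "tiff") {
    pages <- tiff::readTIFF(path, all = TRUE)
    v <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  } else {
    img <- RNifti::readNifti(path)
    v <- array(as.numeric(img), dim(img))
  }
  fov <- if (!is.null(meta)) unlist(meta$fov_mm) else
    if (format == "nifti") RNifti::pixdim(RNifti::readNifti(path)) * dim(v)
    else stop("no calibration sidecar found for TIFF volume")
  octVolume(v, fov = fov,
            device = if (is.null(meta)) "unknown" else meta$device,
            laterality = if (is.null(meta)) "NA" else meta$laterality,
            signalStrength = if (is.null(meta)) NA_integer_
                             else meta$signal_strength)
}

#' Persist a phantom's ground truth
#'
#' Writes the rendered volumes (TIFF), the three boundary surfaces as
#' TSV grids in mm, the lumen mask voxel indices, and a JSON metadata
#' file (seed, parameters, fovea index).
#'
#' @param eye An [EyePhantom-class].
#' @param dir output directory (created).
#' @return The directory, invisibly.
#' @export
writeEyePhantom <- function(eye, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeOCTVolume(eye@reference, file.path(dir, "reference.tif"))
  if (!is.null(eye@degraded))
    writeOCTVolume(eye@degraded, file.path(dir, "input.tif"))
  for (nm in c("ilm", "rpe", "csi"))
    utils::write.table(slot(eye, nm), file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  idx <- which(eye@lumen)
  utils::write.table(data.frame(index = idx),
                     file.path(dir, "lumen_voxels.tsv"),
                     sep = "\t", row.names = FALSE)
  jsonlite::write_json(list(seed = eye@params$seed, params = eye@params,
                            fovea = eye@fovea, dim = dim(eye@scene)),
                       file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Persist / restore an aligned pair as paired PNG directories
#'
#' Writes one 8-bit PNG per B-scan under \code{input/} and
#' \code{reference/} plus a JSON sidecar with the shift, calibration and
#' provenance.
#'
#' @param pair An [AlignedPair-class].
#' @param dir output directory.
#' @return \code{writeAlignedPair}: the directory, invisibly.
#' @export
writeAlignedPair <- function(pair, dir) {
  for (sub in c("input", "reference"))
    dir.create(file.path(dir, sub), showWarnings = FALSE, recursive = TRUE)
  d <- dim(pair@input@vol)
  for (s in seq_len(d[3])) {
    fn <- sprintf("bscan_%04d.png", s)
    png::writePNG(pmin(pmax(pair@input@vol[, , s], 0), 1),
                  file.path(dir, "input", fn))
    png::writePNG(pmin(pmax(pair@reference@vol[, , s], 0), 1),
                  file.path(dir, "reference", fn))
  }
  jsonlite::write_json(list(shift = pair@shift,
                            fov_mm = as.list(pair@input@fov),
                            dim = d, provenance = pair@provenance),
                       file.path(dir, "pair.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' @rdname writeAlignedPair
#' @return \code{readAlignedPair}: the restored [AlignedPair-class].
#' @export
readAlignedPair <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "pair.json"),
                              simplifyVector = TRUE)
  readDir <- function(sub) {
    files <- sort(list.files(file.path(dir, sub), pattern = "\\.png$",
                             full.names = TRUE))
    pages <- lapply(files, png::readPNG)
    array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  }
  fov <- unlist(meta$fov_mm)
  mk <- function(arr, dev) octVolume(arr, fov = fov, device = dev)
  new("AlignedPair", input = mk(readDir("input"), "input"),
      reference = mk(readDir("reference"), "reference"),
      shift = as.numeric(meta$shift),
      provenance = list(restored_from = dir))
}
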