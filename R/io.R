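#' Write a 4D perfusion series as NIfTI with a JSON sidecar
#'
#' The internal axis order (t, z, y, x) is converted to NIfTI's (x, y, z, t)
#' layout. Frame timestamps, modality and units go to a JSON sidecar next to
#' the image (same basename, \code{.json} extension).
#'
#' @param series a [time_series_volume()].
#' @param path output path ending in \code{.nii} or \code{.nii.gz}.
#' @return invisibly, the sidecar path.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "time_series_volume"))
  if (!grepl("\\.nii(\\.gz)?$", path))
    stop_perfusim("path must end in .nii or .nii.gz")
  img <- aperm(series$data, c(4L, 3L, 2L, 1L))
  RNifti::writeNifti(RNifti::asNifti(img), path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(timestamps = series$timestamps,
                            modality = series$modality,
                            units = series$units),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a 4D perfusion series written by [write_series()]
#'
#' @param path path to a 4D NIfTI file; its JSON timestamp sidecar must sit
#'   next to it.
#' @return a [time_series_volume()].
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop_perfusim("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop_perfusim("expected a 4D series, got ", length(d),
                  " dimensions in ", path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (!file.exists(sidecar))
    stop_perfusim("missing timestamp sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (length(meta$timestamps) != d[4L])
    stop_perfusim("sidecar has ", length(meta$timestamps),
                  " timestamps but the image has ", d[4L], " frames")
  data <- aperm(array(as.numeric(img), dim = d), c(4L, 3L, 2L, 1L))
  time_series_volume(data, meta$timestamps, modality = meta$modality,
                     units = meta$units)
}

#' Write a 3D map (e.g. MTT) as NIfTI
#'
#' @param map 3D array in (z, y, x) order; NA sentinels are written as NaN.
#' @param path output path ending in \code{.nii} or \code{.nii.gz}.
#' @return invisibly, \code{path}.
#' @export
write_map <- function(map, path) {
  stopifnot(length(dim(map)) == 3L)
  if (!grepl("\\.nii(\\.gz)?$", path))
    stop_perfusim("path must end in .nii or .nii.gz")
  RNifti::writeNifti(RNifti::asNifti(aperm(map, c(3L, 2L, 1L))), path)
  invisible(path)
}
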