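#' 4D perfusion time-series volume
#'
#' The pipeline's main data container: a dynamic contrast-enhanced series of
#' 3D volumes with per-frame acquisition timestamps. Data are stored with
#' axis order \code{(t, z, y, x)}; NIfTI's \code{(x, y, z, t)} layout is
#' converted at the IO boundary ([read_series()], [write_series()]).
#'
#' @param data 4D numeric array, dimensions \code{(t, z, y, x)}.
#' @param timestamps acquisition times in seconds from the first frame,
#'   strictly increasing, one per frame.
#' @param modality \code{"conventional_hu"} or \code{"iodine_density"}.
#' @param units \code{"HU"} or \code{"mg/mL"}; defaults to the unit implied
#'   by the modality.
#' @return an object of class \code{time_series_volume}.
#' @export
time_series_volume <- function(data, timestamps,
                               modality = c("iodine_density", "conventional_hu"),
                               units = NULL) {
  modality <- match.arg(modality)
  if (!is.array(data) || length(dim(data)) != 4L)
    stop_perfusim("data must be a 4D array (t, z, y, x), got ",
                  length(dim(data)), " dimensions")
  check_increasing(timestamps, "timestamps")
  if (length(timestamps) != dim(data)[1L])
    stop_perfusim("length(timestamps) [", length(timestamps),
                  "] must equal the number of frames [", dim(data)[1L], "]")
  if (is.null(units))
    units <- if (modality == "conventional_hu") "HU" else "mg/mL"
  structure(list(data = data, timestamps = as.numeric(timestamps),
                 modality = modality, units = units),
            class = "time_series_volume")
}

#' @export
print.time_series_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Perfusion series: %d frames x (%d, %d, %d) voxels, %s [%s]\n",
              d[1], d[2], d[3], d[4], x$modality, x$units))
  cat(sprintf("  time span %.3g-%.3g s, mean interval %.3g s\n",
              x$timestamps[1], x$timestamps[length(x$timestamps)],
              mean(diff(x$timestamps))))
  invisible(x)
}

#' @export
dim.time_series_volume <- function(x) dim(x$data)

n_frames <- function(series) dim(series$data)[1L]
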