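#' Dynamic CT acquisition protocol
#'
#' Dose-relevant parameters of the dynamic perfusion protocol. Defaults
#' match the emulated scanner experiment: 120 kVp, 100 mAs per time point,
#' 9 mGy CTDIvol per scan, 4 cm detector coverage, 36 time points over
#' 26.9 s, and the thorax conversion factor 0.015 mSv/(mGy*cm).
#'
#' @param kvp tube voltage (kV).
#' @param exposure_mas tube current-time product per time point (mAs).
#' @param ctdi_per_timepoint CTDIvol per scan (mGy).
#' @param coverage_cm z coverage per scan (cm).
#' @param n_timepoints number of acquired frames.
#' @param duration_s total acquisition span (s).
#' @param conversion_factor effective-dose conversion factor
#'   (mSv/(mGy*cm)).
#' @return an object of class \code{acquisition_protocol}.
#' @export
acquisition_protocol <- function(kvp = 120, exposure_mas = 100,
                                 ctdi_per_timepoint = 9, coverage_cm = 4,
                                 n_timepoints = 36L, duration_s = 26.9,
                                 conversion_factor = 0.015) {
  vals <- c(kvp, exposure_mas, ctdi_per_timepoint, coverage_cm,
            n_timepoints, duration_s, conversion_factor)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_perfusim("all protocol parameters must be positive")
  if (n_timepoints != round(n_timepoints) || n_timepoints < 1)
    stop_perfusim("n_timepoints must be an integer >= 1")
  structure(list(kvp = kvp, exposure_mas = exposure_mas,
                 ctdi_per_timepoint = ctdi_per_timepoint,
                 coverage_cm = coverage_cm,
                 n_timepoints = as.integer(n_timepoints),
                 duration_s = duration_s,
                 conversion_factor = conversion_factor),
            class = "acquisition_protocol")
}

#' Dose-length product of a dynamic protocol
#'
#' \code{DLP = n_timepoints * CTDIvol_per_timepoint * coverage}. The default
#' protocol gives 36 x 9 x 4 = 1296 mGy*cm. (Note the accumulated CTDIvol is
#' the raw product 36 x 9 = 324 mGy.)
#'
#' @param protocol an [acquisition_protocol()].
#' @return DLP in mGy*cm.
#' @export
dlp <- function(protocol) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  protocol$n_timepoints * protocol$ctdi_per_timepoint * protocol$coverage_cm
}

#' Effective dose from DLP
#'
#' \code{dose = DLP * k}, with k the anatomical conversion factor. The full
#' 36-frame protocol yields 1296 x 0.015 = 19.44 mSv; the 8-frame reduced
#' protocol 288 x 0.015 = 4.32 mSv.
#'
#' @param dlp dose-length product (mGy*cm), \code{>= 0}.
#' @param k_factor conversion factor (mSv/(mGy*cm)), \code{>= 0}.
#' @return effective dose in mSv.
#' @export
effective_dose <- function(dlp, k_factor = 0.015) {
  if (dlp < 0 || k_factor < 0) stop_perfusim("dlp and k_factor must be >= 0")
  dlp * k_factor
}

#' Dose reduction from temporal undersampling
#'
#' \code{100 * (1 - n_reduced / n_full)} percent; 8 of 36 time points gives
#' approximately 78%.
#'
#' @param n_full number of frames of the full protocol.
#' @param n_reduced number of frames retained.
#' @return reduction in percent.
#' @export
dose_reduction_fraction <- function(n_full, n_reduced) {
  if (!(n_reduced > 0 && n_reduced <= n_full))
    stop_perfusim("need 0 < n_reduced <= n_full")
  100 * (1 - n_reduced / n_full)
}

#' Frame indices of uniform temporal undersampling
#'
#' \code{round(seq(0, n - 1, length.out = k)) + 1}: always includes the
#' first and last frames. For 8 of 36 frames this selects (1-based)
#' 1, 6, 11, 16, 21, 26, 31, 36.
#'
#' @param n number of frames available.
#' @param k number of frames to keep, \code{2 <= k <= n}.
#' @return integer vector of k strictly increasing frame indices.
#' @export
undersample_indices <- function(n, k) {
  if (k < 2) stop_perfusim("k must be >= 2")
  if (k > n) stop_perfusim("k must be <= n")
  as.integer(round(seq(0, n - 1, length.out = k))) + 1L
}

#' Temporal undersampling of a series or AIF
#'
#' Retains \code{k} of the available frames. The same index rule must be
#' applied to every TAC including the AIF, so the generic dispatches on both
#' [time_series_volume()] and [aif_curve()] objects.
#'
#' @param x a [time_series_volume()] or [aif_curve()].
#' @param k number of frames to keep, \code{>= 2}.
#' @param strategy only \code{"uniform"} (indices from
#'   [undersample_indices()]) is implemented.
#' @return object of the same class with k frames.
#' @export
undersample <- function(x, k, strategy = "uniform") {
  UseMethod("undersample")
}

#' @export
undersample.time_series_volume <- function(x, k, strategy = "uniform") {
  strategy <- match.arg(strategy, "uniform")
  idx <- undersample_indices(n_frames(x), k)
  d <- dim(x$data)
  time_series_volume(array(x$data[idx, , , , drop = FALSE],
                           dim = c(length(idx), d[2:4])),
                     x$timestamps[idx], modality = x$modality,
                     units = x$units)
}

#' @export
undersample.aif_curve <- function(x, k, strategy = "uniform") {
  strategy <- match.arg(strategy, "uniform")
  idx <- undersample_indices(length(x$times), k)
  aif_curve(x$times[idx], x$values[idx],
            source = paste0(x$source, sprintf(" [undersampled %d/%d]",
                                              k, length(x$times))))
}

#' Dose summary for a full and a reduced protocol
#'
#' @param protocol an [acquisition_protocol()] (full sampling).
#' @param n_reduced frames retained by the reduced protocol; \code{NULL}
#'   omits the reduced branch.
#' @return list with \code{dlp}, \code{effective_dose}, \code{ctdi_total}
#'   and, when requested, \code{reduced_dlp}, \code{reduced_dose},
#'   \code{reduction_pct}.
#' @export
dose_summary <- function(protocol, n_reduced = NULL) {
  full_dlp <- dlp(protocol)
  out <- list(dlp = full_dlp,
              effective_dose = effective_dose(full_dlp,
                                              protocol$conversion_factor),
              ctdi_total = protocol$n_timepoints * protocol$ctdi_per_timepoint)
  if (!is.null(n_reduced)) {
    red <- acquisition_protocol(protocol$kvp, protocol$exposure_mas,
                                protocol$ctdi_per_timepoint,
                                protocol$coverage_cm, n_reduced,
                                protocol$duration_s,
                                protocol$conversion_factor)
    rd <- dlp(red)
    out$reduced_dlp <- rd
    out$reduced_dose <- effective_dose(rd, protocol$conversion_factor)
    out$reduction_pct <- dose_reduction_fraction(protocol$n_timepoints,
                                                 n_reduced)
  }
  out
}
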