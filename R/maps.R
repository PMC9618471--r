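#' Derive perfusion parameter maps from voxel fits
#'
#' Converts the one-compartment rates into the standard perfusion quantities
#' via the central volume principle for the impulse response
#' \eqn{A e^{-\lambda t}}:
#' \itemize{
#'   \item mean transit time \code{MTT = 1 / lambda} (s),
#'   \item volume fraction \code{v = 100 * A / lambda} (mL/100 mL),
#'   \item blood flow \code{BF = 6000 * A} (mL/min/100 mL),
#' }
#' so that \code{v = BF * MTT / 60} holds identically wherever a fit exists.
#' Error maps follow by first-order propagation of \code{err_A} and
#' \code{err_lam}. Voxels without a fit keep NA sentinels; voxels whose
#' washout rate sits on the lower bound are marked unreliable.
#'
#' @param fit_maps a [fit_volume()] result.
#' @param provenance optional named list stored alongside the maps
#'   (modality, seed, ...).
#' @return an object of class \code{perfusion_maps} with 3D arrays
#'   \code{blood_flow}, \code{volume_fraction}, \code{mtt}, error maps
#'   \code{err_blood_flow}, \code{err_volume_fraction}, \code{err_mtt},
#'   logical \code{unreliable}, and \code{provenance}.
#' @export
derive_maps <- function(fit_maps, provenance = list()) {
  stopifnot(inherits(fit_maps, "fit_maps"))
  A <- fit_maps$A; lam <- fit_maps$lam
  valid <- is.finite(A) & is.finite(lam) & lam > 0
  na_map <- array(NA_real_, dim = dim(A))
  mtt <- vol <- bf <- e_bf <- e_vol <- e_mtt <- na_map
  mtt[valid] <- 1 / lam[valid]
  vol[valid] <- 100 * A[valid] / lam[valid]
  bf[valid]  <- 6000 * A[valid]
  eA <- fit_maps$err_A; eL <- fit_maps$err_lam
  e_bf[valid]  <- 6000 * eA[valid]
  e_mtt[valid] <- eL[valid] / lam[valid]^2
  e_vol[valid] <- 100 * sqrt((eA[valid] / lam[valid])^2 +
                               (A[valid] * eL[valid] / lam[valid]^2)^2)
  unreliable <- array(FALSE, dim = dim(A))
  lam_lower <- fit_maps$opts$lower[["lam"]]
  unreliable[valid & lam <= lam_lower + 1e-12] <- TRUE
  prov <- utils::modifyList(list(modality = fit_maps$modality,
                                 fit_options = fit_maps$opts), provenance)
  structure(list(blood_flow = bf, volume_fraction = vol, mtt = mtt,
                 err_blood_flow = e_bf, err_volume_fraction = e_vol,
                 err_mtt = e_mtt, unreliable = unreliable,
                 provenance = prov),
            class = "perfusion_maps")
}

#' @export
print.perfusion_maps <- function(x, ...) {
  n <- sum(is.finite(x$mtt))
  cat(sprintf("Perfusion maps (%s): %d fitted voxels\n",
              x$provenance$modality, n))
  if (n) cat(sprintf(
    "  median BF %.4g mL/min/100mL, v %.4g mL/100mL, MTT %.4g s\n",
    stats::median(x$blood_flow, na.rm = TRUE),
    stats::median(x$volume_fraction, na.rm = TRUE),
    stats::median(x$mtt, na.rm = TRUE)))
  invisible(x)
}

#' ROI signal-to-noise ratio
#'
#' Mean over the ROI divided by the standard deviation over the ROI, the
#' convention used for characterising a homogeneous blood-pool region at a
#' maximally enhanced time point.
#'
#' @param values voxel values (a frame, array or vector).
#' @param roi_mask optional logical mask selecting the ROI within
#'   \code{values}; default uses all values.
#' @return dimensionless SNR; \code{Inf} with attribute
#'   \code{zero_sd = TRUE} for a constant ROI.
#' @export
roi_snr <- function(values, roi_mask = NULL) {
  v <- if (is.null(roi_mask)) as.numeric(values) else
    as.numeric(values)[which(roi_mask)]
  if (length(v) < 2L) stop_perfusim("ROI must contain at least 2 voxels")
  s <- stats::sd(v)
  if (s == 0) {
    warning("constant ROI: SNR is infinite")
    return(structure(Inf, zero_sd = TRUE))
  }
  mean(v) / s
}

#' Row-averaged MTT line profile
#'
#' Averages MTT over each image row (left to right) of one axial slice to
#' reduce variance, producing a top-to-bottom profile through the
#' myocardium-like bands. Only voxels with a valid positive MTT enter the
#' average; rows with no such voxel are excluded.
#'
#' @param mtt_map a [derive_maps()] result or a 3D MTT array \code{(z, y, x)}.
#' @param slice_index z slice to profile; default mid-slice.
#' @return a data frame of class \code{line_profile} with columns
#'   \code{row}, \code{mean_mtt}, \code{n_averaged}.
#' @export
line_profile <- function(mtt_map, slice_index = NULL) {
  m <- if (inherits(mtt_map, "perfusion_maps")) mtt_map$mtt else mtt_map
  stopifnot(length(dim(m)) == 3L)
  if (is.null(slice_index)) slice_index <- ceiling(dim(m)[1L] / 2)
  if (slice_index < 1L || slice_index > dim(m)[1L])
    stop_perfusim("slice_index outside the volume")
  sl <- m[slice_index, , , drop = TRUE]
  if (is.null(dim(sl))) sl <- matrix(sl, nrow = dim(m)[2L])
  valid <- is.finite(sl) & sl > 0
  n_row <- rowSums(valid)
  mean_row <- ifelse(n_row > 0, rowSums(ifelse(valid, sl, 0)) / n_row, NA_real_)
  keep <- n_row > 0
  if (!any(keep)) warning("no valid voxels in slice: empty profile")
  structure(data.frame(row = which(keep), mean_mtt = mean_row[keep],
                       n_averaged = n_row[keep]),
            class = c("line_profile", "data.frame"))
}

#' Classify tissue by MTT thresholds
#'
#' Three-way rule with boundary values assigned to the lower class:
#' \code{MTT > thr_high} is highly affected,
#' \code{thr_mod < MTT <= thr_high} moderately affected,
#' \code{0 < MTT <= thr_mod} unaffected. The defaults 2.5 s and 2.0 s are the
#' empirical spectral-map thresholds of the phantom experiment.
#'
#' @param mtt_map a [derive_maps()] result or MTT array.
#' @param thr_high,thr_mod thresholds (s), \code{thr_high > thr_mod > 0}.
#' @return character array of \code{"highly"}, \code{"moderate"},
#'   \code{"unaffected"}; NA where no valid MTT.
#' @export
classify_thresholds <- function(mtt_map, thr_high = 2.5, thr_mod = 2.0) {
  if (!(thr_high > thr_mod && thr_mod > 0))
    stop_perfusim("need thr_high > thr_mod > 0")
  m <- if (inherits(mtt_map, "perfusion_maps")) mtt_map$mtt else mtt_map
  out <- array(NA_character_, dim = dim(m))
  valid <- is.finite(m) & m > 0
  out[valid & m > thr_high] <- "highly"
  out[valid & m > thr_mod & m <= thr_high] <- "moderate"
  out[valid & m <= thr_mod] <- "unaffected"
  out
}

#' Per-region summary statistics of a parameter map
#'
#' @param map a 3D parameter array (e.g. the MTT map) or [derive_maps()]
#'   result (its MTT map is used).
#' @param labels region label map aligned with the array.
#' @param regions which labels to summarise; empty regions are omitted with
#'   a warning.
#' @return data frame with \code{region}, \code{mean}, \code{sd} (sample SD,
#'   n - 1), \code{n}.
#' @export
region_stats <- function(map, labels,
                         regions = c("highly", "moderate", "unaffected")) {
  m <- if (inherits(map, "perfusion_maps")) map$mtt else map
  if (!all(dim(m) == dim(labels)))
    stop_perfusim("map and labels dimensions differ")
  rows <- lapply(regions, function(r) {
    v <- m[unclass(labels) == r]
    v <- v[is.finite(v)]
    if (!length(v)) {
      warning("region '", r, "' is empty; omitted")
      return(NULL)
    }
    data.frame(region = r, mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else 0,
               n = length(v))
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}
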