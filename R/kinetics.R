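#' Options for voxel-wise one-compartment fitting
#'
#' @param lower,upper bounds on \code{(A, lambda)} in 1/s for the
#'   bound-constrained L-BFGS-B minimisation. Defaults cover MTT from 0.1 s
#'   to 1000 s.
#' @param lam_init initial washout-rate guess (1/s). The inflow-rate guess is
#'   moment-based: \code{A0 = lam_init * area(TAC) / area(AIF)}, clipped to
#'   the bounds.
#' @param f_tol convergence tolerance of the minimiser (dimensionless,
#'   relative to the objective scale); also enters the parameter-error
#'   formula of [fit_errors()].
#' @param hessian_rel_step relative step of the central finite differences
#'   used for the error Hessian.
#' @param grid_step step (s) of the uniform auxiliary grid the convolution is
#'   evaluated on; \code{NULL} chooses
#'   \code{min(median sampling interval, 0.25 / upper["lam"])} so the fastest
#'   admissible washout is resolved.
#' @param baseline_subtract subtract the first-frame value from every TAC
#'   (and the AIF) before fitting. \code{NULL} (default) enables it for
#'   conventional-HU series only; iodine-density series already have a
#'   0 mg/mL baseline.
#' @return an object of class \code{fit_options}.
#' @export
fit_options <- function(lower = c(A = 0, lam = 1e-3),
                        upper = c(A = 10, lam = 10),
                        lam_init = 0.5,
                        f_tol = 1e-10,
                        hessian_rel_step = 1e-4,
                        grid_step = NULL,
                        baseline_subtract = NULL) {
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(upper <= lower))
    stop_perfusim("bounds must be finite with upper > lower")
  if (f_tol <= 0) stop_perfusim("f_tol must be > 0")
  if (hessian_rel_step <= 0) stop_perfusim("hessian_rel_step must be > 0")
  structure(list(lower = lower, upper = upper, lam_init = lam_init,
                 f_tol = f_tol, hessian_rel_step = hessian_rel_step,
                 grid_step = grid_step, baseline_subtract = baseline_subtract),
            class = "fit_options")
}

default_grid_step <- function(aif_times, opts) {
  if (!is.null(opts$grid_step)) return(opts$grid_step)
  min(stats::median(diff(aif_times)), 0.25 / opts$upper[["lam"]])
}

# Convolution engine: precomputes the uniform auxiliary grid, the AIF
# resampled onto it, and the linear-interpolation stencil back to the
# requested output times. The one-compartment response
#   TAC(t_i) = A * sum_{t_j <= t_i} AIF(t_j) exp(-lam (t_i - t_j)) dt
# is evaluated by the O(n) recursion S_i = exp(-lam dt) S_{i-1} + AIF_i dt
# (stats::filter), and its lambda-derivative by a second recursion on
# t_j-weighted input, so analytic gradients are available to the optimiser.
conv_engine <- function(aif, times, grid_step) {
  t0 <- aif$times[1L]
  t_end <- max(aif$times[length(aif$times)], times[length(times)])
  grid <- seq(t0, t_end + grid_step, by = grid_step)
  aifg <- stats::approx(aif$times, aif$values, xout = grid, rule = 2)$y
  # interpolation stencil for output times
  k <- pmin(pmax(floor((times - t0) / grid_step) + 1L, 1L), length(grid) - 1L)
  w <- (times - grid[k]) / grid_step
  interp <- function(v) (1 - w) * v[k] + w * v[k + 1L]
  list(grid = grid, dt = grid_step, aifg = aifg, interp = interp,
       eval = function(lam, need_grad = FALSE) {
         # recursion gives the right-endpoint Riemann sum; subtracting half
         # of both endpoint contributions turns it into the trapezoidal rule
         r <- exp(-lam * grid_step)
         E <- exp(-lam * (grid - grid[1L]))
         S <- as.numeric(stats::filter(aifg * grid_step, r,
                                       method = "recursive")) -
           0.5 * grid_step * (aifg + aifg[1L] * E)
         m <- interp(S)                    # unit-A model at output times
         if (!need_grad) return(list(m = m))
         U <- as.numeric(stats::filter(aifg * grid * grid_step, r,
                                       method = "recursive")) -
           0.5 * grid_step * (aifg * grid + aifg[1L] * grid[1L] * E)
         list(m = m, dm_dlam = interp(U - grid * S))   # d(unit model)/d lam
       })
}

#' One-compartment forward model
#'
#' Tissue time-attenuation curve of the one-compartment tracer-kinetic model
#' \deqn{\mathrm{TAC}(t) = A \,[\mathrm{AIF} \otimes e^{-\lambda t}](t),}
#' computed as a causal discrete convolution on a uniform auxiliary grid
#' (step \code{grid_step}, AIF linearly resampled, sum multiplied by the grid
#' step so \code{A} keeps units 1/s) and linearly interpolated back to the
#' requested times.
#'
#' @param aif an [aif_curve()].
#' @param A inflow rate constant (1/s), \code{>= 0}.
#' @param lam washout rate \eqn{\lambda} (1/s), \code{> 0}.
#' @param times strictly increasing output times (s) within the AIF support.
#' @param grid_step auxiliary grid step (s); default as in [fit_options()].
#' @return numeric vector of modelled concentrations at \code{times}.
#' @examples
#' tt <- seq(0, 30, by = 0.5)
#' aif <- gamma_variate_aif(solve_gamma_params(8, 10, 3), tt)
#' tac <- forward_model(aif, A = 0.1, lam = 0.5, times = tt)
#' @export
forward_model <- function(aif, A, lam, times, grid_step = NULL) {
  stopifnot(inherits(aif, "aif_curve"))
  check_increasing(times, "times")
  if (lam <= 0) stop_perfusim("lam must be > 0")
  if (is.null(grid_step)) grid_step <- default_grid_step(aif$times, fit_options())
  eng <- conv_engine(aif, times, grid_step)
  A * eng$eval(lam)$m
}

#' Fit-parameter error estimates from the objective Hessian
#'
#' Parameter errors of a bound-constrained least-squares fit,
#' \deqn{\Delta x_i = \sqrt{f_{\mathrm{tol}} \, (H^{-1})_{ii}},}
#' where \eqn{H} is the Hessian of the objective at the optimum (central
#' finite differences) and \eqn{f_{\mathrm{tol}}} the minimiser's stopping
#' bound. \code{f_tol} is interpreted relative to the objective scale: the
#' absolute tolerance entering the formula is
#' \code{f_tol * max(abs(objective(optimum)), 1)}, matching the relative
#' stopping rule of L-BFGS-B.
#'
#' @param objective function of a length-2 parameter vector \code{c(A, lam)}
#'   returning the scalar objective.
#' @param optimum parameter vector at the minimum.
#' @param f_tol relative convergence tolerance (dimensionless).
#' @param rel_step relative finite-difference step per parameter.
#' @param lower,upper optional bounds; an optimum on a bound is flagged
#'   \code{boundary} (errors are still computed from the full Hessian).
#' @param warn raise a warning when the Hessian is not positive definite;
#'   callers fitting many voxels set this to FALSE and aggregate the flag.
#' @return numeric vector \code{c(err_A, err_lam)}; attributes
#'   \code{hessian}, \code{boundary} (logical) and \code{spd} (FALSE when the
#'   Hessian is not positive definite, in which case the errors are NaN and a
#'   warning is raised).
#' @export
fit_errors <- function(objective, optimum, f_tol = 1e-10, rel_step = 1e-4,
                       lower = NULL, upper = NULL, warn = TRUE) {
  x <- as.numeric(optimum)
  p <- length(x)
  h <- rel_step * pmax(abs(x), rel_step)
  f0 <- objective(x)
  H <- matrix(0, p, p)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h[i])
    H[i, i] <- (objective(x + ei) - 2 * f0 + objective(x - ei)) / h[i]^2
    if (i < p) for (j in seq.int(i + 1L, p)) {
      ej <- replace(numeric(p), j, h[j])
      H[i, j] <- H[j, i] <-
        (objective(x + ei + ej) - objective(x + ei - ej) -
           objective(x - ei + ej) + objective(x - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  boundary <- FALSE
  if (!is.null(lower)) boundary <- boundary || any(x <= lower + 1e-12)
  if (!is.null(upper)) boundary <- boundary || any(x >= upper - 1e-12)
  ftol_abs <- f_tol * max(abs(f0), 1)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    if (warn)
      warning("objective Hessian not positive definite; errors set to NaN")
    err <- rep(NaN, p)
    spd <- FALSE
  } else {
    err <- sqrt(ftol_abs * diag(solve(H)))
    spd <- TRUE
  }
  structure(err, hessian = H, boundary = boundary, spd = spd,
            names = c("err_A", "err_lam")[seq_len(p)])
}

#' Fit the one-compartment model to a single voxel TAC
#'
#' Minimises the sum of squared residuals between the measured
#' time-attenuation curve and [forward_model()] over \code{(A, lambda)}
#' within bounds, using L-BFGS-B with analytic gradients. Parameter errors
#' come from [fit_errors()].
#'
#' A flat (e.g. all-zero) TAC yields a converged fit with \code{A} at the
#' lower bound, flagged \code{"low-signal"}; an optimum touching a bound is
#' flagged \code{"boundary"}.
#'
#' @param tac measured concentrations at \code{times} (finite).
#' @param aif an [aif_curve()].
#' @param times acquisition times (s); at least 4 points.
#' @param opts a [fit_options()].
#' @return an object of class \code{compartment_fit}: \code{A}, \code{lam},
#'   \code{err_A}, \code{err_lam}, \code{residual_sd}, \code{objective_value},
#'   \code{converged}, \code{n_iter}, \code{flags}, \code{fitted}.
#' @export
fit_voxel <- function(tac, aif, times, opts = fit_options()) {
  stopifnot(inherits(aif, "aif_curve"))
  if (length(times) < 4L) stop_perfusim("need at least 4 time points")
  if (length(tac) != length(times))
    stop_perfusim("tac and times must have equal length")
  if (any(!is.finite(tac))) stop_perfusim("tac must be finite")
  eng <- conv_engine(aif, times,
                     default_grid_step(aif$times, opts))
  fit_voxel_engine(tac, eng, times, opts)
}

# Shared worker: fits one TAC against a prebuilt convolution engine.
fit_voxel_engine <- function(tac, eng, times, opts, warn_hessian = TRUE) {
  lower <- as.numeric(opts$lower); upper <- as.numeric(opts$upper)
  area_aif <- trapz(eng$grid, eng$aifg)
  area_tac <- trapz(times, tac)
  A0 <- if (area_aif > 0) opts$lam_init * area_tac / area_aif else lower[1]
  A0 <- min(max(A0, lower[1]), upper[1])
  lam0 <- min(max(opts$lam_init, lower[2]), upper[2])

  # cache the unit model between the fn and gr calls optim makes at each p
  cache <- new.env(parent = emptyenv())
  cache$p <- c(NA_real_, NA_real_)
  get_eval <- function(p, need_grad) {
    if (!identical(p, cache$p) || (need_grad && is.null(cache$e$dm_dlam))) {
      cache$e <- eng$eval(p[2], need_grad = need_grad)
      cache$p <- p
    }
    cache$e
  }
  fn <- function(p) {
    e <- get_eval(p, FALSE)
    sum((tac - p[1] * e$m)^2)
  }
  gr <- function(p) {
    e <- get_eval(p, TRUE)
    res <- tac - p[1] * e$m
    c(-2 * sum(res * e$m), -2 * p[1] * sum(res * e$dm_dlam))
  }
  opt <- stats::optim(c(A0, lam0), fn, gr, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(factr = opts$f_tol / .Machine$double.eps,
                                     maxit = 200L))
  par <- opt$par
  fitted <- par[1] * eng$eval(par[2])$m
  res <- tac - fitted
  err <- fit_errors(fn, par, f_tol = opts$f_tol,
                    rel_step = opts$hessian_rel_step,
                    lower = lower, upper = upper, warn = warn_hessian)
  flags <- character()
  if (par[1] <= lower[1] + 1e-12) flags <- c(flags, "low-signal")
  if (attr(err, "boundary")) flags <- c(flags, "boundary")
  if (!attr(err, "spd")) flags <- c(flags, "hessian-not-spd")
  structure(list(A = par[1], lam = par[2],
                 err_A = unname(err[1]), err_lam = unname(err[2]),
                 residual_sd = stats::sd(res),
                 objective_value = opt$value,
                 converged = opt$convergence == 0L,
                 n_iter = unname(opt$counts["function"]),
                 flags = flags, fitted = fitted, residuals = res),
            class = "compartment_fit")
}

#' @export
print.compartment_fit <- function(x, ...) {
  cat(sprintf("1-compartment fit: A = %.4g +/- %.2g 1/s, lambda = %.4g +/- %.2g 1/s\n",
              x$A, x$err_A, x$lam, x$err_lam))
  cat(sprintf("  MTT = %.4g s, residual SD = %.4g, %sconverged (%d evals)%s\n",
              1 / x$lam, x$residual_sd, if (x$converged) "" else "NOT ",
              x$n_iter,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' SNR of a fitted time-attenuation curve
#'
#' Maximum of the tracer-kinetic fit function divided by the standard
#' deviation of the fit residuals.
#'
#' @param fit a [fit_voxel()] result.
#' @return dimensionless SNR; \code{Inf} with attribute
#'   \code{zero_residual = TRUE} when the residual SD is zero.
#' @export
tac_snr <- function(fit) {
  stopifnot(inherits(fit, "compartment_fit"))
  if (max(fit$fitted) == min(fit$fitted))
    warning("fitted curve is constant; SNR is not meaningful")
  if (fit$residual_sd == 0)
    return(structure(Inf, zero_residual = TRUE))
  max(fit$fitted) / fit$residual_sd
}

#' Voxel-wise fitting of a 4D perfusion series
#'
#' Applies [fit_voxel()] independently to every masked voxel of the series.
#' For conventional-HU data the first-frame value is subtracted from each
#' TAC and from the AIF before fitting (see [fit_options()]); voxels outside
#' the mask carry NA sentinels.
#'
#' @param series a [time_series_volume()].
#' @param aif an [aif_curve()] sampled at the series timestamps, in the
#'   series' units.
#' @param mask logical 3D array \code{(z, y, x)}; default all voxels.
#' @param opts a [fit_options()].
#' @return an object of class \code{fit_maps}: 3D arrays \code{A},
#'   \code{lam}, \code{err_A}, \code{err_lam}, \code{residual_sd},
#'   \code{converged}, \code{low_signal}, \code{boundary}, plus
#'   \code{n_fitted}, \code{opts}, \code{modality}.
#' @export
fit_volume <- function(series, aif, mask = NULL, opts = fit_options()) {
  stopifnot(inherits(series, "time_series_volume"),
            inherits(aif, "aif_curve"))
  d <- dim(series$data)
  vol_dim <- d[2:4]
  if (is.null(mask)) mask <- array(TRUE, dim = vol_dim)
  if (!all(dim(mask) == vol_dim))
    stop_perfusim("mask dimensions must match the series volume")
  idx <- which(mask)
  na_map <- array(NA_real_, dim = vol_dim)
  out <- list(A = na_map, lam = na_map, err_A = na_map, err_lam = na_map,
              residual_sd = na_map,
              converged = array(NA, dim = vol_dim),
              low_signal = array(NA, dim = vol_dim),
              boundary = array(NA, dim = vol_dim))
  if (!length(idx)) {
    warning("empty mask: returning empty fit maps")
    return(structure(c(out, list(n_fitted = 0L, opts = opts,
                                 modality = series$modality)),
                     class = "fit_maps"))
  }

  baseline <- opts$baseline_subtract
  if (is.null(baseline)) baseline <- series$modality == "conventional_hu"
  aif_use <- aif
  if (baseline) aif_use$values <- aif$values - aif$values[1L]

  times <- series$timestamps
  eng <- conv_engine(aif_use, times, default_grid_step(aif_use$times, opts))
  tacs <- matrix(series$data, nrow = d[1L])[, idx, drop = FALSE]
  if (baseline) tacs <- sweep(tacs, 2L, tacs[1L, ], "-")
  n_not_spd <- 0L
  for (v in seq_along(idx)) {
    f <- fit_voxel_engine(tacs[, v], eng, times, opts, warn_hessian = FALSE)
    i <- idx[v]
    out$A[i] <- f$A; out$lam[i] <- f$lam
    out$err_A[i] <- f$err_A; out$err_lam[i] <- f$err_lam
    out$residual_sd[i] <- f$residual_sd
    out$converged[i] <- f$converged
    out$low_signal[i] <- "low-signal" %in% f$flags
    out$boundary[i] <- "boundary" %in% f$flags
    if ("hessian-not-spd" %in% f$flags) n_not_spd <- n_not_spd + 1L
  }
  if (n_not_spd > 0L)
    warning(n_not_spd, " of ", length(idx),
            " voxels had a non-positive-definite error Hessian; ",
            "their error estimates are NaN")
  structure(c(out, list(n_fitted = length(idx), opts = opts,
                        modality = series$modality)),
            class = "fit_maps")
}

#' @export
print.fit_maps <- function(x, ...) {
  cat(sprintf("Voxel-wise 1-compartment fits: %d voxels (%s)\n",
              x$n_fitted, x$modality))
  if (x$n_fitted > 0) {
    ok <- x$converged[!is.na(x$converged)]
    cat(sprintf("  converged: %d/%d; median A %.4g 1/s, median lambda %.4g 1/s\n",
                sum(ok), length(ok), stats::median(x$A, na.rm = TRUE),
                stats::median(x$lam, na.rm = TRUE)))
  }
  invisible(x)
}
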