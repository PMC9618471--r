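#' Gamma-variate bolus parameters
#'
#' Container for the parameters of the gamma-variate bolus model used as the
#' synthetic arterial input function (AIF). The curve is
#' \deqn{C(t) = s \left(\frac{t - t_0}{t_p}\right)^{\alpha}
#'       \exp\left\{\alpha\left(1 - \frac{t - t_0}{t_p}\right)\right\}}
#' for \eqn{t > t_0} and 0 otherwise, with peak time \eqn{t_p = \alpha\beta}.
#' In this normalised form the maximum of the curve equals \code{scale}
#' exactly, attained at \eqn{t_0 + t_p}.
#'
#' @param t0 bolus-arrival time (s), \code{>= 0}.
#' @param alpha shape exponent (dimensionless), \code{> 0}.
#' @param beta decay time constant (s), \code{> 0}.
#' @param scale amplitude at the peak (mg/mL iodine), \code{> 0}.
#' @return an object of class \code{gamma_variate_params}.
#' @seealso [solve_gamma_params()], [gamma_variate_aif()]
#' @export
gamma_variate_params <- function(t0, alpha, beta, scale) {
  stopifnot(is.numeric(t0), is.numeric(alpha), is.numeric(beta),
            is.numeric(scale), length(t0) == 1L, length(alpha) == 1L,
            length(beta) == 1L, length(scale) == 1L)
  if (t0 < 0) stop_perfusim("t0 must be >= 0")
  if (alpha <= 0 || beta <= 0 || scale <= 0)
    stop_perfusim("alpha, beta and scale must be > 0")
  structure(list(t0 = t0, alpha = alpha, beta = beta, scale = scale),
            class = "gamma_variate_params")
}

#' @export
print.gamma_variate_params <- function(x, ...) {
  cat(sprintf(
    "Gamma-variate bolus: t0 = %.3g s, alpha = %.3g, beta = %.3g s, peak = %.3g\n",
    x$t0, x$alpha, x$beta, x$scale))
  cat(sprintf("  peak time t0 + alpha*beta = %.3g s\n", x$t0 + x$alpha * x$beta))
  invisible(x)
}

# Normalised gamma-variate shape g(x) = x^alpha * exp(alpha*(1-x)), peak g(1)=1.
gv_shape <- function(x, alpha) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- exp(alpha * (log(x[pos]) + 1 - x[pos]))
  out
}

#' Solve gamma-variate parameters from peak and FWHM
#'
#' Determines bolus parameters whose curve attains a prescribed maximum and
#' full width at half maximum (FWHM). The peak constraint fixes
#' \code{scale = peak} by construction of the normalised form; the FWHM
#' constraint is one equation in \code{(alpha, beta)}, so the shape exponent
#' \code{alpha} is held fixed (first-pass bolus curves are well described by
#' \code{alpha} around 3) and \code{beta} is obtained by root-finding the
#' half-maximum crossings of the dimensionless shape.
#'
#' @param peak curve maximum (mg/mL), \code{> 0}.
#' @param fwhm full width at half maximum (s), \code{> 0}.
#' @param t0 bolus-arrival time (s).
#' @param alpha fixed shape exponent; default 3.
#' @return a [gamma_variate_params()] object whose sampled curve has maximum
#'   \code{peak} and FWHM \code{fwhm}.
#' @examples
#' p <- solve_gamma_params(peak = 8, fwhm = 10, t0 = 3)
#' tt <- seq(0, 40, by = 0.01)
#' max(gamma_variate_aif(p, tt)$values)  # 8
#' @export
solve_gamma_params <- function(peak, fwhm, t0 = 0, alpha = 3) {
  stopifnot(length(peak) == 1L, length(fwhm) == 1L, length(t0) == 1L)
  if (peak <= 0 || fwhm <= 0) stop_perfusim("peak and fwhm must be > 0")
  if (t0 < 0) stop_perfusim("t0 must be >= 0")
  if (alpha <= 0) stop_perfusim("alpha must be > 0")
  # Half-maximum crossings of g(x) = x^alpha exp(alpha(1-x)): one in (0,1),
  # one in (1, inf). Width in x units scales to time by t_p = alpha*beta.
  g_half <- function(x) gv_shape(x, alpha) - 0.5
  x_lo <- tryCatch(
    stats::uniroot(g_half, c(1e-12, 1), tol = 1e-12)$root,
    error = function(e) stop_perfusim(
      "FWHM root-finding failed on the rising edge: ", conditionMessage(e),
      class = "perfusim_convergence_error"))
  # Bracket the falling-edge root by doubling.
  hi <- 2
  while (g_half(hi) > 0 && hi < 1e6) hi <- hi * 2
  if (g_half(hi) > 0)
    stop_perfusim("FWHM root-finding failed on the falling edge: no bracket",
                  class = "perfusim_convergence_error")
  x_hi <- stats::uniroot(g_half, c(1, hi), tol = 1e-12)$root
  width_x <- x_hi - x_lo
  tp <- fwhm / width_x          # peak time such that FWHM matches
  beta <- tp / alpha
  gamma_variate_params(t0 = t0, alpha = alpha, beta = beta, scale = peak)
}

#' Arterial input function container
#'
#' An AIF sampled at the acquisition time points, in the modality's
#' concentration units.
#'
#' @param times sample times (s), strictly increasing.
#' @param values concentration at each time (mg/mL or HU).
#' @param source free-text descriptor of the ROI or model the curve came from.
#' @return an object of class \code{aif_curve}.
#' @export
aif_curve <- function(times, values, source = "unspecified") {
  check_increasing(times, "AIF times")
  if (length(values) != length(times))
    stop_perfusim("AIF times and values must have equal length")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 source = source),
            class = "aif_curve")
}

#' @export
print.aif_curve <- function(x, ...) {
  cat(sprintf("AIF curve: %d samples over [%.3g, %.3g] s, peak %.4g (%s)\n",
              length(x$times), min(x$times), max(x$times), max(x$values),
              x$source))
  invisible(x)
}

#' Evaluate a gamma-variate AIF at given times
#'
#' @param params a [gamma_variate_params()] object.
#' @param times strictly increasing sample times (s).
#' @return an [aif_curve()] with values
#'   \eqn{s\,((t-t_0)/t_p)^\alpha e^{\alpha(1-(t-t_0)/t_p)}} for
#'   \eqn{t > t_0}, zero otherwise (\eqn{t_p = \alpha\beta}).
#' @export
gamma_variate_aif <- function(params, times) {
  stopifnot(inherits(params, "gamma_variate_params"))
  check_increasing(times, "times")
  tp <- params$alpha * params$beta
  vals <- params$scale * gv_shape((times - params$t0) / tp, params$alpha)
  aif_curve(times, vals, source = "gamma-variate model")
}
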