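# hourly collagen response to a (possibly time-varying) mRNA-sum drive,
# exact exponential update per 1-h segment with the drive frozen
.collagen_response <- function(mrna_sum, kdep, kdeg, C0, dt = 1) {
  if (kdeg > 0) {
    e <- exp(-kdeg * dt)
    inc <- (kdep * mrna_sum / kdeg) * (1 - e)
    c(C0, as.numeric(stats::filter(inc, e, method = "recursive", init = C0)))
  } else {
    c(C0, C0 + cumsum(kdep * mrna_sum * dt))
  }
}

#' Calibrate collagen deposition and degradation coefficients
#'
#' Two-stage calibration of the collagen kinetics:
#' \enumerate{
#'   \item the deposition-to-degradation ratio is solved analytically so
#'     that the baseline mRNA output sustains the healthy steady-state
#'     collagen area fraction (4\% by default):
#'     \code{kdep/kdeg = baseline_frac / baseline_mrna_sum};
#'   \item \code{kdep} is swept over a logarithmic grid with \code{kdeg}
#'     constrained to the ratio, integrating the collagen response to the
#'     stimulated mRNA trajectory from the baseline fraction and
#'     minimizing the SSE against the supplied infarct time course.
#' }
#' Ties in SSE resolve to the smallest \code{kdep}.
#'
#' @param baseline_mrna_sum steady collagen I + III mRNA activity sum of
#'   the network at baseline inputs (> 0).
#' @param infarct_curve data.frame with columns \code{time_days} and
#'   \code{area_fraction} (e.g. from [synth_infarct_timecourse()]).
#' @param stimulated_mrna_trajectory data.frame with columns
#'   \code{time_h} (hourly, starting at 0) and \code{mrna_sum}: the
#'   collagen mRNA sum of the network run under the stimulated
#'   condition.
#' @param baseline_frac healthy steady-state area fraction (default
#'   0.04).
#' @param sweep_range range of \code{kdep} candidates (per hour units).
#' @param sweep_n number of log-spaced candidates.
#' @return an object of class \code{collagen_fit}: the fitted
#'   [collagen_params()], the analytic ratio, the sweep table and fit
#'   diagnostics.
#' @export
fit_collagen_coefficients <- function(baseline_mrna_sum, infarct_curve,
                                      stimulated_mrna_trajectory,
                                      baseline_frac = 0.04,
                                      sweep_range = c(1e-4, 1e-1),
                                      sweep_n = 200) {
  if (baseline_mrna_sum <= 0)
    stop("baseline mRNA sum must be > 0: run the network to its baseline ",
         "steady state and sum the collagen I and III mRNA activities")
  if (!all(c("time_days", "area_fraction") %in% names(infarct_curve)) ||
      nrow(infarct_curve) == 0)
    stop("infarct_curve needs non-empty columns time_days and area_fraction")
  if (is.unsorted(infarct_curve$time_days, strictly = TRUE))
    stop("infarct_curve times must be strictly increasing")
  tr <- stimulated_mrna_trajectory
  if (!all(c("time_h", "mrna_sum") %in% names(tr)))
    stop("stimulated_mrna_trajectory needs columns time_h and mrna_sum")

  ratio <- baseline_frac / baseline_mrna_sum
  t_h <- infarct_curve$time_days * 24
  if (max(t_h) > max(tr$time_h))
    stop("stimulated mRNA trajectory is shorter than the infarct curve")
  # hourly drive: mrna_sum over [i-1, i) taken at the segment start
  drive <- tr$mrna_sum[-nrow(tr)]

  kdeps <- exp(seq(log(sweep_range[1]), log(sweep_range[2]),
                   length.out = sweep_n))
  sses <- vapply(kdeps, function(kd) {
    C <- .collagen_response(drive, kd, kd / ratio, C0 = baseline_frac)
    pred <- C[round(t_h) + 1L]
    sum((pred - infarct_curve$area_fraction)^2)
  }, 0)
  best <- which.min(sses)   # first minimum = smallest kdep on ties
  kdep <- kdeps[best]
  Cbest <- .collagen_response(drive, kdep, kdep / ratio, C0 = baseline_frac)

  structure(list(cparams = collagen_params(kdep = kdep, kdeg = kdep / ratio),
                 ratio = ratio, baseline_mrna_sum = baseline_mrna_sum,
                 baseline_frac = baseline_frac,
                 sweep = data.frame(kdep = kdeps, kdeg = kdeps / ratio,
                                    sse = sses),
                 curve = infarct_curve,
                 fitted = data.frame(time_h = tr$time_h,
                                     area_fraction = Cbest),
                 sse = sses[best]),
            class = "collagen_fit")
}

#' @export
print.collagen_fit <- function(x, ...) {
  cat("Collagen kinetics calibration\n")
  cat(sprintf("  analytic kdep/kdeg ratio: %.4g (baseline %.3g%% / mRNA sum %.4g)\n",
              x$ratio, 100 * x$baseline_frac, x$baseline_mrna_sum))
  cat(sprintf("  fitted kdep = %.4g, kdeg = %.4g /h (sweep SSE %.3g)\n",
              x$cparams$kdep, x$cparams$kdeg, x$sse))
  invisible(x)
}

#' @export
coef.collagen_fit <- function(object, ...) {
  c(kdep = object$cparams$kdep, kdeg = object$cparams$kdeg)
}

#' @export
plot.collagen_fit <- function(x, ...) {
  plot(x$fitted$time_h / 24, 100 * x$fitted$area_fraction, type = "l",
       xlab = "time (days)", ylab = "collagen area fraction (%)",
       main = "collagen calibration fit", ...)
  graphics::points(x$curve$time_days, 100 * x$curve$area_fraction, pch = 19)
  invisible(x)
}
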