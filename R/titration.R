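#' @include trajectory-methods.R
NULL

.baselineMean <- function(trace) {
  w <- trace@baseline
  sel <- trace@time >= w[1] & trace@time <= w[2]
  if (sum(sel) < 2)
    stop("baseline window must contain at least 2 samples", call. = FALSE)
  mean(trace@intensity[sel])
}

#' Normalize a fluorescence trace to its baseline window
#'
#' Divides the intensity by the mean over the trace's baseline window
#' (e.g. the membrane-only segment before peptide additions), so the
#' baseline plateaus at 1. Normalizing an already-normalized trace is a
#' no-op (the baseline mean is then 1).
#'
#' @param trace A \linkS4class{TitrationTrace}.
#' @return The normalized \linkS4class{TitrationTrace}.
#' @export
normalizeTrace <- function(trace) {
  b <- .baselineMean(trace)
  if (b <= 0)
    stop("baseline mean is not positive; cannot normalize", call. = FALSE)
  trace@intensity <- trace@intensity / b
  trace@normalized <- TRUE
  trace
}

#' Saturation binding curve from a titration time course
#'
#' Reads a per-addition plateau from the settled tail of each inter-event
#' interval of a normalized trace, forms the response versus cumulative
#' dose, and fits a one-site hyperbola
#' \eqn{\Delta F(D) = R_{max} D / (K_{1/2} + D)} to obtain the
#' half-saturation dose. A flat trace (zero response amplitude) is flagged
#' unidentifiable rather than fitted.
#'
#' @param trace a normalized \linkS4class{TitrationTrace}.
#' @param events data.frame of additions (default the trace's own events);
#'   needs >= 2 events with columns time and dose.
#' @param settleFraction fraction of each inter-event interval, counted
#'   from its end, averaged as the plateau (default 0.5: the last half).
#' @return A list of class \code{"SaturationCurve"}: \code{dose}
#'   (cumulative, nmol), \code{response}, \code{fraction} (response scaled
#'   to the fitted maximum), \code{halfSat}, \code{rmax},
#'   \code{identifiable}.
#' @export
saturationFromTrace <- function(trace, events = trace@events,
                                settleFraction = 0.5) {
  if (nrow(events) < 2)
    stop("at least 2 addition events are required", call. = FALSE)
  if (!trace@normalized) trace <- normalizeTrace(trace)
  ev <- events[order(events$time), ]
  bounds <- c(ev$time, max(trace@time) + 1e-9)
  plateau <- numeric(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    t0 <- bounds[i]; t1 <- bounds[i + 1]
    sel <- trace@time >= t1 - settleFraction * (t1 - t0) & trace@time < t1
    if (sum(sel) < 2)
      stop("settle windows overlap or contain too few samples between ",
           sprintf("events at %.1f and %.1f s", t0, t1), call. = FALSE)
    plateau[i] <- mean(trace@intensity[sel])
  }
  base <- .baselineMean(trace)
  dose <- cumsum(ev$dose)
  response <- plateau - base
  if (max(abs(response)) < 1e-8) {
    return(structure(list(dose = dose, response = response,
                          fraction = rep(NA_real_, length(dose)),
                          halfSat = NA_real_, rmax = NA_real_,
                          identifiable = FALSE),
                     class = "SaturationCurve"))
  }
  sgn <- sign(response[which.max(abs(response))])
  y <- sgn * response
  fit <- minpack.lm::nlsLM(y ~ rmax * dose / (k + dose),
                           start = list(rmax = max(y), k = stats::median(dose)),
                           lower = c(rmax = 0, k = 1e-6))
  co <- stats::coef(fit)
  structure(list(dose = dose, response = response,
                 fraction = y / co[["rmax"]],
                 halfSat = co[["k"]], rmax = sgn * co[["rmax"]],
                 identifiable = TRUE),
            class = "SaturationCurve")
}

#' @export
print.SaturationCurve <- function(x, ...) {
  if (x$identifiable)
    cat(sprintf("Saturation curve: half-saturation %.3g nmol, Rmax %.3g\n",
                x$halfSat, x$rmax))
  else cat("Saturation curve: flat response, fit unidentifiable\n")
  invisible(x)
}

#' Dipole-potential excitation ratio of a styryl probe scan
#'
#' The ratiometric dipole-potential readout R = I(ex 420 nm)/I(ex 520 nm)
#' at fixed emission, each intensity read as a mean over a +/- window
#' around the nominal excitation wavelength.
#'
#' @param scan data.frame with columns \code{wavelength} (nm) and
#'   \code{intensity}.
#' @param window half-width of the read window, nm (default 2).
#' @return The ratio R.
#' @export
aneppsRatio <- function(scan, window = 2) {
  readAt <- function(wl) {
    sel <- abs(scan$wavelength - wl) <= window
    if (!any(sel))
      stop("scan does not cover ", wl, " nm", call. = FALSE)
    mean(scan$intensity[sel])
  }
  num <- readAt(420); den <- readAt(520)
  if (den <= 0) stop("intensity at 520 nm is not positive", call. = FALSE)
  num / den
}

#' Fractional change of a potentiometric probe after an event
#'
#' On a normalized trace, (post-event mean - baseline mean)/baseline mean:
#' the fractional quench (negative) or rise of the probe after, e.g.,
#' mitochondria addition.
#'
#' @param trace a normalized \linkS4class{TitrationTrace}.
#' @param postWindow length-2 time window (s) after the event.
#' @return The fractional change dF/F0.
#' @export
tmrmFractionalChange <- function(trace, postWindow) {
  if (!trace@normalized) trace <- normalizeTrace(trace)
  sel <- trace@time >= postWindow[1] & trace@time <= postWindow[2]
  if (!any(sel)) stop("post-event window contains no samples", call. = FALSE)
  base <- .baselineMean(trace)
  (mean(trace@intensity[sel]) - base) / base
}

#' Hydration radius from reference-normalized diffusion coefficients
#'
#' Converts pulsed-field-gradient NMR diffusion coefficients into a
#' hydration radius via an internal reference standard: solvent viscosity
#' cancels in the ratio, giving
#' \eqn{R_h = R_{h,ref} \cdot D_{ref} / D_{analyte}}. The DSS reference
#' standard has \eqn{R_h} = 3.34 Angstrom.
#'
#' @param dRef diffusion coefficient of the reference (> 0, any unit
#'   shared with \code{dAnalyte}).
#' @param dAnalyte diffusion coefficient of the analyte (> 0).
#' @param rhRef hydration radius of the reference, Angstrom (default 3.34,
#'   DSS).
#' @return Hydration radius, Angstrom.
#' @examples
#' hydrationRadius(1.587, 1)  # ~5.3 A
#' @export
hydrationRadius <- function(dRef, dAnalyte, rhRef = 3.34) {
  stopifnot(dRef > 0, dAnalyte > 0, rhRef > 0)
  rhRef * dRef / dAnalyte
}
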