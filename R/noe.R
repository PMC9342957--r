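#' @include trajectory-methods.R
NULL

#' Instantaneous ensemble-averaged NOE distance
#'
#' Collapses the per-chain distances of a restrained ensemble into one
#' effective distance per frame using inverse-sixth-power averaging,
#' reflecting NOE intensity physics:
#' \deqn{r^*(t) = \left[\frac{1}{N}\sum_{i=1}^{N} r_i(t)^{-6}\right]^{-1/6}}
#' The result is bounded by the smallest and largest chain distances at each
#' frame and is biased toward the short ones.
#'
#' @param series A \linkS4class{DistanceSeries}, or a chains x frames
#'   numeric matrix of positive distances.
#' @return Numeric vector, one effective distance (Angstrom) per frame.
#' @examples
#' m <- rbind(rep(3, 5), rep(6, 5))
#' ensembleAvgDistance(m)  # ~3.36, dominated by the short chain
#' @export
ensembleAvgDistance <- function(series) {
  d <- if (is(series, "DistanceSeries")) distances(series) else series
  if (!is.matrix(d)) d <- matrix(d, nrow = 1)
  if (nrow(d) < 1L) stop("at least one chain is required", call. = FALSE)
  if (any(!is.finite(d)) || any(d <= 0))
    stop("all distances must be positive and finite", call. = FALSE)
  colMeans(d^-6)^(-1 / 6)
}

#' Time-averaged NOE distance over a forward window
#'
#' Applies inverse-third-power time averaging to a per-frame effective
#' distance series:
#' \deqn{\bar r^*(t) = \left[\frac{1}{W}\sum_{j=t}^{t+\tau/\Delta t}
#'   r^*(j)^{-3}\right]^{-1/3}}
#' where the forward window holds \eqn{W = \tau/\Delta t + 1} samples.
#' Terminal windows are truncated to the frames that exist and renormalized
#' by the actual sample count. Defaults are tau = 10 ps and dt = 1 ps.
#'
#' @param rstar numeric vector of per-frame effective distances (Angstrom).
#' @param tau averaging time, ps; must be an integer multiple of \code{dt}
#'   and >= \code{dt}.
#' @param dt frame spacing, ps.
#' @return Numeric vector of windowed averages, one per starting frame.
#' @examples
#' timeAvgDistance(rep(4.5, 20))        # constant in, constant out
#' timeAvgDistance(c(3, 6), tau = 1)    # (mean(c(3,6)^-3))^(-1/3)
#' @export
timeAvgDistance <- function(rstar, tau = 10, dt = 1) {
  if (tau < dt) stop("tau must be >= dt", call. = FALSE)
  w <- tau / dt
  if (abs(w - round(w)) > 1e-9)
    stop("tau must be an integer multiple of dt", call. = FALSE)
  if (any(!is.finite(rstar)) || any(rstar <= 0))
    stop("all distances must be positive and finite", call. = FALSE)
  w <- as.integer(round(w))
  n <- length(rstar)
  p <- cumsum(c(0, rstar^-3))
  t0 <- seq_len(n)
  t1 <- pmin(t0 + w, n)
  ((p[t1 + 1] - p[t0]) / (t1 - t0 + 1))^(-1 / 3)
}

#' Fraction of time windows violating a restraint
#'
#' A window counts as a violation when its time- and ensemble-averaged
#' distance exceeds the experimental upper bound plus a buffer tolerance
#' (default 0.3 Angstrom).
#'
#' @param avg numeric vector of time-averaged distances (output of
#'   \code{\link{timeAvgDistance}}).
#' @param restraint the \linkS4class{NOERestraint} supplying the upper
#'   bound.
#' @param tolerance buffer added to the upper bound, Angstrom (>= 0).
#' @return Fraction in [0, 1].
#' @export
violationFraction <- function(avg, restraint, tolerance = 0.3) {
  if (!length(avg)) stop("empty averaged-distance series", call. = FALSE)
  if (tolerance < 0) stop("tolerance must be >= 0", call. = FALSE)
  mean(avg > restraint@upper + tolerance)
}

#' Retain only medium-range restraints (i to i+2 and i to i+3)
#'
#' Sequential restraints are dropped; input order is preserved. Restrained
#' MD of the study system imposed only the i,i+2 and i,i+3 restraints so
#' that long-distance contacts are enforced without over-restraining local
#' dynamics.
#'
#' @param restraints list of \linkS4class{NOERestraint} objects.
#' @return The filtered list (possibly empty).
#' @export
filterLongRange <- function(restraints) {
  keep <- vapply(restraints,
                 function(r) (r@resJ - r@resI) %in% c(2L, 3L), logical(1))
  restraints[keep]
}

#' Restraint-compliance report for an ensemble trajectory
#'
#' Runs the ensemble (r^-6) and time (r^-3) averaging over every restraint's
#' distance series, scores per-restraint violation fractions against the
#' upper bounds plus tolerance, and summarises the share of restraints
#' violated less than \code{summaryThreshold} of the time.
#'
#' @param seriesList list of \linkS4class{DistanceSeries}; all must share
#'   the same frame spacing.
#' @param tau,dt time-averaging parameters, ps (defaults 10 and 1).
#' @param tolerance violation buffer, Angstrom (default 0.3).
#' @param summaryThreshold violation-fraction cutoff for the summary share
#'   (default 0.20).
#' @return A list of class \code{"ViolationReport"}: \code{table} (one row
#'   per restraint with residues, atoms, upper bound, class and violation
#'   fraction), \code{averaged} (list of time-averaged series),
#'   \code{shareBelowThreshold}, and the parameters used.
#' @export
complianceReport <- function(seriesList, tau = 10, dt = 1, tolerance = 0.3,
                             summaryThreshold = 0.20) {
  if (!length(seriesList))
    return(structure(list(table = data.frame(), averaged = list(),
                          shareBelowThreshold = NA_real_, tau = tau, dt = dt,
                          tolerance = tolerance), class = "ViolationReport"))
  dts <- vapply(seriesList, function(s) s@dt, numeric(1))
  if (length(unique(dts)) != 1L)
    stop("all series must share the same frame spacing dt", call. = FALSE)
  avgs <- lapply(seriesList, function(s)
    timeAvgDistance(ensembleAvgDistance(s), tau = tau, dt = dts[1]))
  fr <- mapply(function(a, s) violationFraction(a, s@restraint, tolerance),
               avgs, seriesList)
  tab <- do.call(rbind, lapply(seq_along(seriesList), function(i) {
    r <- seriesList[[i]]@restraint
    data.frame(resI = r@resI, atomI = r@atomI, resJ = r@resJ,
               atomJ = r@atomJ, upper = r@upper,
               class = restraintClass(r), violationFraction = fr[i])
  }))
  structure(list(table = tab, averaged = avgs,
                 shareBelowThreshold = mean(fr < summaryThreshold),
                 tau = tau, dt = dts[1], tolerance = tolerance,
                 summaryThreshold = summaryThreshold),
            class = "ViolationReport")
}

#' @export
print.ViolationReport <- function(x, ...) {
  cat("NOE compliance report:", nrow(x$table), "restraints",
      sprintf("(tau %.1f ps, dt %.1f ps, tolerance %.2f A)\n",
              x$tau, x$dt, x$tolerance))
  if (nrow(x$table)) {
    cat(sprintf("  share violated < %.0f%% of the time: %.2f\n",
                100 * x$summaryThreshold, x$shareBelowThreshold))
    print(x$table, row.names = FALSE)
  }
  invisible(x)
}
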