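#' @include synthetic-bilayer.R
NULL

#' Generate a synthetic fluorescence titration time course
#'
#' Emulates the three probe experiments of the electrostatics assays:
#' \describe{
#'   \item{surface-probe}{An anionic-surface probe time course: membrane
#'     present from the start, baseline window 60-120 s, then sequential
#'     peptide additions (10 nmol each, every 25 s) producing saturable
#'     plateau increases with hyperbolic dose dependence of known
#'     half-saturation dose (truth \code{halfSatDose}) and saturating
#'     fold-change (truth \code{foldChange}).}
#'   \item{dipole-scan}{The ratiometric dipole-probe readout across the
#'     same additions: the trace holds the excitation ratio R per titration
#'     step, decreasing hyperbolically by the truth \code{aneppsDrop} at
#'     saturation. Full excitation scans are available from
#'     \code{\link{makeExcitationScan}}.}
#'   \item{transmembrane}{A potentiometric quench-mode course: baseline
#'     window 40-55 s, mitochondria addition at 60 s quenching the signal
#'     by the truth \code{tmrmQuench} fraction, ionophore addition at 200 s
#'     restoring it.}
#' }
#' Gaussian noise of relative magnitude \code{truth$traceNoise} is added
#' throughout; responses settle instantly at each event.
#'
#' @param kind one of \code{"surface-probe"}, \code{"dipole-scan"},
#'   \code{"transmembrane"}.
#' @param truth a \code{\link{syntheticTruth}}.
#' @param nAdditions number of peptide additions for titration kinds
#'   (default 8).
#' @param dosePerAddition nmol per addition (default 10).
#' @return A \linkS4class{TitrationTrace} with events and provenance.
#' @export
makeTitrationTrace <- function(kind = c("surface-probe", "dipole-scan",
                                        "transmembrane"),
                               truth, nAdditions = 8, dosePerAddition = 10) {
  kind <- match.arg(kind)
  withSeed(subSeed(truth$seed, 4L), {
    noise <- truth$traceNoise
    if (kind == "surface-probe") {
      time <- seq(0, 120 + 25 * nAdditions, by = 0.5)
      evTimes <- 120 + 25 * (seq_len(nAdditions) - 1) + 5
      doses <- rep(dosePerAddition, nAdditions)
      cum <- cumsum(doses)
      amp <- truth$foldChange - 1
      level <- rep(1, length(time))
      for (i in seq_len(nAdditions))
        level[time >= evTimes[i]] <-
          1 + amp * cum[i] / (truth$halfSatDose + cum[i])
      intensity <- 200 * level
      if (noise > 0)
        intensity <- intensity + stats::rnorm(length(time), 0, noise * 200)
      events <- data.frame(time = evTimes, label = "peptide", dose = doses)
      baseline <- c(60, 120)
    } else if (kind == "dipole-scan") {
      time <- seq_len(nAdditions + 1)  # step index: 0-dose point first
      doses <- c(0, rep(dosePerAddition, nAdditions))
      cum <- cumsum(doses)
      r0 <- 1.0
      intensity <- r0 * (1 - truth$aneppsDrop * cum /
                           (truth$halfSatDose + cum))
      if (noise > 0)
        intensity <- intensity + stats::rnorm(length(time), 0, noise * r0)
      events <- data.frame(time = time[-1] - 0.5, label = "peptide",
                           dose = doses[-1])
      baseline <- c(1, 1.5)
    } else {
      time <- seq(0, 240, by = 0.5)
      level <- rep(1, length(time))
      level[time >= 60] <- 1 + truth$tmrmQuench
      level[time >= 200] <- 1
      intensity <- 400 * level
      if (noise > 0)
        intensity <- intensity + stats::rnorm(length(time), 0, noise * 400)
      events <- data.frame(time = c(60, 200),
                           label = c("mitochondria", "valinomycin"),
                           dose = c(NA, NA))
      baseline <- c(40, 55)
    }
    TitrationTrace(time, intensity, events = events, baseline = baseline,
                   provenance = list(seed = truth$seed, kind = kind,
                                     truth = truth[c("foldChange",
                                                     "halfSatDose",
                                                     "tmrmQuench",
                                                     "aneppsDrop",
                                                     "traceNoise")]))
  })
}

#' Generate synthetic dipole-probe excitation scans over a titration
#'
#' One excitation scan (380-580 nm at fixed emission) per cumulative dose,
#' with two Gaussian excitation bands at 420 and 520 nm whose amplitude
#' ratio decreases hyperbolically with dose by the truth \code{aneppsDrop}
#' at saturation, so \code{\link{aneppsRatio}} recovers a monotone
#' decreasing R sequence.
#'
#' @param truth a \code{\link{syntheticTruth}}.
#' @param doses cumulative peptide doses, nmol (default 0 to 70 by 10).
#' @return List with \code{doses} and \code{scans} (one data.frame of
#'   wavelength/intensity per dose).
#' @export
makeExcitationScan <- function(truth, doses = seq(0, 70, by = 10)) {
  withSeed(subSeed(truth$seed, 5L), {
    wl <- seq(380, 580, by = 1)
    scans <- lapply(doses, function(d) {
      r <- 1 - truth$aneppsDrop * d / (truth$halfSatDose + d)
      i420 <- 300 * r
      i520 <- 300
      intensity <- i420 * exp(-(wl - 420)^2 / (2 * 15^2)) +
        i520 * exp(-(wl - 520)^2 / (2 * 15^2)) + 5
      if (truth$traceNoise > 0)
        intensity <- intensity +
          stats::rnorm(length(wl), 0, truth$traceNoise * 30)
      data.frame(wavelength = wl, intensity = intensity)
    })
    list(doses = doses, scans = scans)
  })
}
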