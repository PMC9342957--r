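#' @include itc.R
NULL

#' Generate a synthetic single-site ITC isotherm
#'
#' Simulates a lipid-into-peptide titration under the independent identical
#' single-site model with the perfusion-cell dilution correction, then adds
#' Gaussian noise to the integrated heats. Defaults reproduce the study
#' protocol: 20 injections of 2.5 ul of 8 mM total lipid (outer-leaflet
#' fraction 0.5) into a 170 ul cell of 150 uM peptide at 25 C.
#'
#' @param truth a \code{\link{syntheticTruth}} supplying the single-site
#'   parameters (\code{itcN}, \code{itcKd} in uM, \code{itcDh} in kJ/mol)
#'   and the master seed.
#' @param injections injection volumes, ul (default 20 x 2.5).
#' @param cellConc cell peptide concentration, uM (default 150).
#' @param syringeConc syringe total lipid concentration, mM (default 8).
#' @param noiseSd Gaussian noise standard deviation on the heats, uJ
#'   (default 0; \code{relativeNoise} offers a fraction-of-largest-heat
#'   alternative).
#' @param relativeNoise if not NULL, overrides \code{noiseSd} with
#'   \code{relativeNoise * max(abs(heats))}.
#' @param outerFraction outer-leaflet fraction (default 0.5).
#' @param cellVolume ul (default 170); \code{temperature} K (default
#'   298.15).
#' @param temperature K.
#' @param seed optional seed overriding \code{truth$seed}.
#' @return An \linkS4class{ITCExperiment} whose provenance stores the truth
#'   parameters and seed.
#' @export
makeItcIsotherm <- function(truth, injections = rep(2.5, 20),
                            cellConc = 150, syringeConc = 8,
                            noiseSd = 0, relativeNoise = NULL,
                            outerFraction = 0.5, cellVolume = 170,
                            temperature = 298.15, seed = NULL) {
  stopifnot(cellConc > 0, syringeConc > 0, all(injections > 0))
  seed <- seed %||% truth$seed
  effSyr <- effectiveLipid(syringeConc, outerFraction) * 1000  # uM
  ideal <- .itcHeats(truth$itcN, truth$itcKd, truth$itcDh,
                     cellConc, effSyr, injections, cellVolume)$q
  if (!is.null(relativeNoise)) noiseSd <- relativeNoise * max(abs(ideal))
  q <- if (noiseSd > 0)
    withSeed(subSeed(seed, 3L),
             ideal + stats::rnorm(length(ideal), 0, noiseSd))
  else ideal
  ITCExperiment(cellConc = cellConc, syringeConc = syringeConc,
                injectionVolumes = injections, heats = q,
                cellVolume = cellVolume, temperature = temperature,
                outerFraction = outerFraction,
                provenance = list(seed = seed, n = truth$itcN,
                                  kd = truth$itcKd, dh = truth$itcDh,
                                  noiseSd = noiseSd))
}
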