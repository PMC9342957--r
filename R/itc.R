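#' @include trajectory-methods.R
NULL

.RGAS <- 8.314462618e-3  # kJ mol^-1 K^-1

#' Effective (outer-leaflet) lipid concentration
#'
#' Externally added peptide only reaches lipids on the outer leaflet of the
#' vesicles, so binding analysis uses the effective lipid concentration:
#' the total concentration times the outer-leaflet fraction.
#'
#' @param total total lipid concentration (any unit).
#' @param outerFraction fraction in (0, 1]; default 0.5 assumes symmetric
#'   leaflets of large unilamellar vesicles.
#' @return Effective concentration in the unit of \code{total}.
#' @examples
#' effectiveLipid(8, 0.5)  # 4 mM accessible of 8 mM total
#' @export
effectiveLipid <- function(total, outerFraction = 0.5) {
  if (outerFraction <= 0 || outerFraction > 1)
    stop("outer-leaflet fraction must be in (0, 1]", call. = FALSE)
  total * outerFraction
}

# One-site model with perfusion-cell dilution: each injection displaces an
# equal volume of mixed cell contents. Tracks total peptide and effective
# lipid in the cell; the bound lipid concentration at each step solves the
# single-site quadratic with site concentration n * [peptide]. Heat of
# injection k is dH times the newly bound lipid (displaced bound material
# releases no heat). Units: concentrations uM, volumes ul, dH kJ/mol,
# heats uJ.
.itcHeats <- function(n, kd, dh, cellConc, effSyringe_uM, vols, V0,
                      displacement = TRUE) {
  P <- cellConc; L <- 0; Bprev <- 0
  ratio <- q <- numeric(length(vols))
  for (k in seq_along(vols)) {
    fdil <- if (displacement) 1 - vols[k] / V0 else 1
    P <- P * fdil
    L <- L * fdil + effSyringe_uM * vols[k] / V0
    S <- n * P
    B <- ((S + L + kd) - sqrt((S + L + kd)^2 - 4 * S * L)) / 2
    q[k] <- dh * V0 * (B - Bprev * fdil) * 1e-3
    Bprev <- B
    ratio[k] <- L / P
  }
  list(q = q, ratio = ratio)
}

#' Fit a lipid-into-peptide isotherm to the single-site model
#'
#' Nonlinear least-squares (Levenberg-Marquardt) fit of per-injection heats
#' to a model of independent, identical single sites: each peptide in the
#' cell presents \code{n} sites for effective (outer-leaflet) lipid, with
#' dissociation constant \code{Kd} and enthalpy \code{dH} per mole of lipid
#' bound. The bound concentration after each injection follows the
#' single-site quadratic closed form; a perfusion-cell dilution correction
#' accounts for the displaced volume (switchable off). The fitted curve is
#' the classic Wiseman plot against the effective-lipid : peptide molar
#' ratio.
#'
#' A Wiseman c-value (cell peptide concentration / Kd) outside roughly
#' [1, 1000] makes parameters poorly determined; this triggers a warning,
#' not a failure.
#'
#' @param exp An \linkS4class{ITCExperiment} with at least 6 injections.
#' @param displacement logical; apply the dilution/displacement correction
#'   (default TRUE).
#' @param start optional named list of starting values (n, kd, dh).
#' @return A \linkS4class{BindingParameters} with standard errors,
#'   covariance and derived thermodynamics (see \code{\link{thermoDerive}}).
#' @export
wisemanFit <- function(exp, displacement = TRUE, start = NULL) {
  q <- heats(exp)
  if (length(q) < 6L)
    stop("at least 6 injections are required for a stable fit", call. = FALSE)
  effSyr <- effectiveLipid(exp@syringeConc, exp@outerFraction) * 1000  # uM
  vols <- exp@injectionVolumes
  V0 <- exp@cellVolume
  P0 <- exp@cellConc

  if (is.null(start)) {
    # dH from the first (far-from-saturation) injection where essentially
    # all injected lipid binds; n from the molar ratio at the half-height
    # of the cumulative heat; Kd from a generic c ~ 10.
    dL1 <- effSyr * vols[1] / V0
    dh0 <- q[1] / (V0 * dL1 * 1e-3)
    cum <- cumsum(q)
    half <- which(abs(cum) >= 0.5 * max(abs(cum)))[1]
    Lh <- sum(effSyr * vols[seq_len(half)] / V0)
    n0 <- max(0.5, Lh / P0)
    start <- list(n = n0, kd = max(P0 / 10, 1), dh = dh0)
  }
  model <- function(n, kd, dh)
    .itcHeats(n, kd, dh, P0, effSyr, vols, V0, displacement)$q
  fit <- tryCatch(
    minpack.lm::nlsLM(q ~ model(n, kd, dh),
                      start = start,
                      lower = c(n = 1e-3, kd = 1e-4, dh = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      resid <- q - do.call(model, start)
      stop("single-site fit failed to converge: ", conditionMessage(e),
           "\nlast residual range: [", sprintf("%.3g", min(resid)), ", ",
           sprintf("%.3g", max(resid)), "] uJ", call. = FALSE)
    })
  co <- stats::coef(fit)
  cval <- P0 / co[["kd"]]
  if (cval < 1 || cval > 1000)
    warning(sprintf(
      "Wiseman c-value %.3g outside the reliable range [1, 1000]; ",
      cval), "parameters may be poorly determined", call. = FALSE)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(n = NA, kd = NA, dh = NA))
  th <- thermoDerive(co[["n"]], co[["kd"]], co[["dh"]], exp@temperature)
  new("BindingParameters", n = co[["n"]], kd = co[["kd"]], dh = co[["dh"]],
      dg = th$dg, tds = th$tds,
      ratio = if (is.na(th$ratio)) NA_real_ else th$ratio,
      se = c(n = unname(se["n"]), kd = unname(se["kd"]),
             dh = unname(se["dh"])),
      covariance = tryCatch(stats::vcov(fit),
                            error = function(e) matrix(NA_real_, 0, 0)))
}

#' Thermodynamic decomposition of single-site binding
#'
#' From the fitted dissociation constant and enthalpy, derives the binding
#' free energy \eqn{\Delta G = RT \ln K_D} (Kd in molar), the entropic term
#' \eqn{T\Delta S = \Delta H - \Delta G}, and the entropy/enthalpy balance
#' \eqn{T\Delta S / |\Delta H|} used to compare how entropy- versus
#' enthalpy-driven membrane binding is.
#'
#' @param n stoichiometry (passed through, not used in the derivation).
#' @param kd dissociation constant, micromolar.
#' @param dh binding enthalpy, kJ/mol.
#' @param temperature Kelvin, default 298.15 (25 C).
#' @return List with \code{dg}, \code{tds} (kJ/mol) and \code{ratio}
#'   (NA with a message when dh == 0, where the ratio is undefined).
#' @examples
#' thermoDerive(5, 27.5, -5.1)   # dG ~ -26.0 kJ/mol
#' @export
thermoDerive <- function(n, kd, dh, temperature = 298.15) {
  stopifnot(kd > 0, temperature > 0)
  dg <- .RGAS * temperature * log(kd * 1e-6)
  tds <- dh - dg
  ratio <- if (dh == 0) {
    message("dH is zero: TdS/|dH| is undefined")
    NA_real_
  } else tds / abs(dh)
  list(dg = dg, tds = tds, ratio = ratio)
}

#' Lipid composition with cross-sectional areas
#'
#' @param fractions named mole fractions summing to 1.
#' @param areas named cross-sectional areas, Angstrom^2; defaults carry the
#'   literature values POPC = 70 and TOCL = 129.
#' @return Validated list of class \code{"LipidComposition"}.
#' @export
lipidComposition <- function(fractions = c(POPC = 0.8, TOCL = 0.2),
                             areas = c(POPC = 70, TOCL = 129)) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("mole fractions must sum to 1", call. = FALSE)
  if (!all(names(fractions) %in% names(areas)))
    stop("every species needs a cross-sectional area", call. = FALSE)
  areas <- areas[names(fractions)]
  if (any(areas <= 0)) stop("areas must be positive", call. = FALSE)
  structure(list(fractions = fractions, areas = areas),
            class = "LipidComposition")
}

#' Membrane binding footprint of a peptide
#'
#' The bilayer area occluded per bound peptide: the ITC lipid-to-peptide
#' stoichiometry times the composition-weighted mean lipid cross-sectional
#' area. For the 80:20 POPC:TOCL system the mean lipid area is
#' 0.8 x 70 + 0.2 x 129 = 81.8 Angstrom^2.
#'
#' @param n lipids (effective) bound per peptide (> 0).
#' @param comp a \code{\link{lipidComposition}}; default 80:20 POPC:TOCL.
#' @param rounded round to the nearest Angstrom^2, the report convention
#'   (default TRUE).
#' @return Footprint in Angstrom^2.
#' @examples
#' footprint(5.7)  # 466
#' footprint(3.3)  # 270
#' @export
footprint <- function(n, comp = lipidComposition(), rounded = TRUE) {
  stopifnot(n > 0)
  a <- n * sum(comp$fractions * comp$areas)
  if (rounded) round(a) else a
}
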