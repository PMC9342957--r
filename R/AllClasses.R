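#' @include AllGenerics.R
NULL

.ROLES <- c("headgroup", "acyl", "peptide", "solvent")

#' Trajectory: frames of labelled 3-D coordinates with per-frame box
#'
#' The central container for molecular coordinate data. Coordinates are held
#' as an atoms x 3 x frames array in Angstrom; each atom carries a name,
#' element, residue index/name, chain id, a role tag (one of
#' \code{"headgroup"}, \code{"acyl"}, \code{"peptide"}, \code{"solvent"})
#' and a van der Waals radius. The orthorhombic box (Lx, Ly, Lz) is recorded
#' per frame.
#'
#' The \code{"acyl"} role operationalises the acyl-chain region of a lipid:
#' the atoms below the ester carbon. The ester carbon itself belongs to the
#' headgroup region and is located by atom name when reference planes are
#' needed.
#'
#' @slot coords numeric array, atoms x 3 x frames, Angstrom.
#' @slot box numeric matrix, frames x 3, Angstrom; all entries positive.
#' @slot atoms data.frame with columns \code{name}, \code{element},
#'   \code{resid}, \code{resname}, \code{chain}, \code{role}, \code{radius}.
#' @slot provenance list; generating parameters for synthetic trajectories.
#'
#' @seealso \code{\link{makeBilayerTrajectory}}, \code{\link{readTrajectory}}
#' @export
setClass("Trajectory",
  representation(coords = "array", box = "matrix", atoms = "data.frame",
                 provenance = "list"),
  prototype(provenance = list()))

setValidity("Trajectory", function(object) {
  msg <- character()
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    msg <- c(msg, "coords must be an atoms x 3 x frames array")
  else {
    if (nrow(object@atoms) != d[1])
      msg <- c(msg, "atom table rows must match coords atom dimension")
    if (nrow(object@box) != d[3])
      msg <- c(msg, "box must have one row per frame")
  }
  if (ncol(object@box) != 3L) msg <- c(msg, "box must have 3 columns")
  if (any(!is.finite(object@box)) || any(object@box <= 0))
    msg <- c(msg, "box edges must be positive and finite")
  need <- c("name", "element", "resid", "resname", "chain", "role", "radius")
  miss <- setdiff(need, names(object@atoms))
  if (length(miss))
    msg <- c(msg, paste("atom table lacks columns:", paste(miss, collapse = ", ")))
  else if (!all(object@atoms$role %in% .ROLES))
    msg <- c(msg, paste("atom roles must be one of:", paste(.ROLES, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' NOERestraint: an atom-pair upper-bound distance restraint
#'
#' @slot resI,resJ integer residue indices with \code{resI < resJ}.
#' @slot atomI,atomJ atom names of the restrained pair.
#' @slot upper numeric upper-bound distance in Angstrom (> 0).
#'
#' @details The restraint class (\code{"sequential"}, \code{"i+2"},
#'   \code{"i+3"}) is derived from the residue separation, see
#'   \code{\link{restraintClass}}.
#' @export
setClass("NOERestraint",
  representation(resI = "integer", atomI = "character",
                 resJ = "integer", atomJ = "character", upper = "numeric"))

setValidity("NOERestraint", function(object) {
  msg <- character()
  if (object@resI >= object@resJ) msg <- c(msg, "resI must be < resJ")
  if (!is.finite(object@upper) || object@upper <= 0)
    msg <- c(msg, "upper bound must be positive")
  if (length(msg)) msg else TRUE
})

#' DistanceSeries: per-frame, per-chain distances for one restraint
#'
#' Holds the chains x frames matrix of measured distances r_i(t) for a
#' single NOE restraint across an ensemble of peptide chains, together with
#' the frame spacing.
#'
#' @slot restraint the \linkS4class{NOERestraint} the distances belong to.
#' @slot distances chains x frames numeric matrix, Angstrom, all positive.
#' @slot dt frame spacing in picoseconds (> 0).
#' @slot provenance list of generating parameters for synthetic series.
#' @export
setClass("DistanceSeries",
  representation(restraint = "NOERestraint", distances = "matrix",
                 dt = "numeric", provenance = "list"),
  prototype(dt = 1, provenance = list()))

setValidity("DistanceSeries", function(object) {
  msg <- character()
  if (any(!is.finite(object@distances)) || any(object@distances <= 0))
    msg <- c(msg, "all distances must be positive and finite")
  if (length(object@dt) != 1L || object@dt <= 0)
    msg <- c(msg, "dt must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' ITCExperiment: an injection-level calorimetry record
#'
#' A lipid-into-peptide titration: the calorimeter cell contains peptide,
#' and lipid vesicles are injected in aliquots. Heats are integrated and
#' blank-corrected, one per injection.
#'
#' @slot cellConc peptide concentration in the cell, micromolar.
#' @slot syringeConc total lipid concentration in the syringe, millimolar.
#' @slot injectionVolumes per-injection volumes, microlitre.
#' @slot heats integrated heats per injection, microjoule.
#' @slot cellVolume active cell volume, microlitre.
#' @slot temperature Kelvin.
#' @slot outerFraction fraction of total lipid on the outer leaflet and
#'   accessible to peptide, in (0, 1]; the effective lipid concentration is
#'   \code{syringeConc * outerFraction}.
#' @slot provenance list of generating parameters for synthetic isotherms.
#' @export
setClass("ITCExperiment",
  representation(cellConc = "numeric", syringeConc = "numeric",
                 injectionVolumes = "numeric", heats = "numeric",
                 cellVolume = "numeric", temperature = "numeric",
                 outerFraction = "numeric", provenance = "list"),
  prototype(cellVolume = 170, temperature = 298.15, outerFraction = 0.5,
            provenance = list()))

setValidity("ITCExperiment", function(object) {
  msg <- character()
  if (object@cellConc <= 0) msg <- c(msg, "cell concentration must be positive")
  if (object@syringeConc <= 0) msg <- c(msg, "syringe concentration must be positive")
  if (any(object@injectionVolumes <= 0)) msg <- c(msg, "injection volumes must be positive")
  if (length(object@heats) != length(object@injectionVolumes))
    msg <- c(msg, "one heat per injection required")
  if (any(!is.finite(object@heats))) msg <- c(msg, "heats must be finite")
  if (object@cellVolume <= 0) msg <- c(msg, "cell volume must be positive")
  if (object@temperature <= 0) msg <- c(msg, "temperature must be positive")
  if (object@outerFraction <= 0 || object@outerFraction > 1)
    msg <- c(msg, "outer-leaflet fraction must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' BindingParameters: fitted single-site thermodynamics
#'
#' Result of \code{\link{wisemanFit}}: the stoichiometry n (lipids per bound
#' peptide on the effective-lipid axis), dissociation constant and binding
#' enthalpy, with the derived free energy, entropy term and their ratio.
#'
#' @slot n lipids (effective) per bound peptide.
#' @slot kd dissociation constant, micromolar.
#' @slot dh binding enthalpy, kJ/mol (per mole of lipid bound).
#' @slot dg Gibbs free energy RT*ln(Kd in molar), kJ/mol.
#' @slot tds entropic term dH - dG, kJ/mol.
#' @slot ratio TdS/|dH| (NA when dH == 0).
#' @slot se named numeric vector of standard errors for n, kd, dh.
#' @slot covariance fit covariance matrix.
#' @export
setClass("BindingParameters",
  representation(n = "numeric", kd = "numeric", dh = "numeric",
                 dg = "numeric", tds = "numeric", ratio = "numeric",
                 se = "numeric", covariance = "matrix"),
  prototype(se = c(n = NA_real_, kd = NA_real_, dh = NA_real_),
            covariance = matrix(NA_real_, 0, 0)))

setValidity("BindingParameters", function(object) {
  msg <- character()
  if (object@n <= 0) msg <- c(msg, "n must be positive")
  if (object@kd <= 0) msg <- c(msg, "Kd must be positive")
  if (abs(object@dg - (object@dh - object@tds)) > 1e-9)
    msg <- c(msg, "dG must equal dH - TdS")
  if (length(msg)) msg else TRUE
})

#' TitrationTrace: a time-stamped fluorescence time course
#'
#' @slot time seconds, strictly increasing.
#' @slot intensity arbitrary fluorescence units.
#' @slot events data.frame with columns \code{time}, \code{label},
#'   \code{dose} (nmol) recording titrant additions.
#' @slot baseline length-2 numeric, the baseline window (s, s) inside the
#'   trace used by \code{\link{normalizeTrace}}.
#' @slot normalized logical; TRUE once divided by the baseline mean.
#' @slot provenance list of generating parameters for synthetic traces.
#' @export
setClass("TitrationTrace",
  representation(time = "numeric", intensity = "numeric",
                 events = "data.frame", baseline = "numeric",
                 normalized = "logical", provenance = "list"),
  prototype(events = data.frame(time = numeric(), label = character(),
                                dose = numeric()),
            normalized = FALSE, provenance = list()))

setValidity("TitrationTrace", function(object) {
  msg <- character()
  if (length(object@time) != length(object@intensity))
    msg <- c(msg, "time and intensity must have equal length")
  if (any(diff(object@time) <= 0))
    msg <- c(msg, "time must be strictly increasing")
  if (length(object@baseline) != 2L ||
      object@baseline[1] < min(object@time) ||
      object@baseline[2] > max(object@time))
    msg <- c(msg, "baseline window must lie inside the trace")
  if (length(msg)) msg else TRUE
})

#' PeptideSpec: a tetrapeptide with residue classes and termini
#'
#' A four-residue peptide with strictly alternating basic/aromatic residue
#' classes, per-residue stereochemistry metadata, a free N-terminal amine
#' and an optional C-terminal amide.
#'
#' @slot residues data.frame with columns \code{code} (three-letter),
#'   \code{class} ("basic" or "aromatic") and \code{stereo} ("L" or "D").
#' @slot amidated logical; TRUE when the C-terminus is an amide.
#' @slot name optional peptide label.
#' @export
setClass("PeptideSpec",
  representation(residues = "data.frame", amidated = "logical",
                 name = "character"),
  prototype(amidated = TRUE, name = NA_character_))

setValidity("PeptideSpec", function(object) {
  msg <- character()
  r <- object@residues
  if (nrow(r) != 4L) msg <- c(msg, "a tetrapeptide must have exactly 4 residues")
  if (!all(c("code", "class", "stereo") %in% names(r)))
    msg <- c(msg, "residues need columns code, class, stereo")
  else {
    if (!all(r$class %in% c("basic", "aromatic")))
      msg <- c(msg, "residue class must be 'basic' or 'aromatic'")
    else if (nrow(r) == 4L && any(r$class[-1] == r$class[-nrow(r)]))
      msg <- c(msg, "residue classes must strictly alternate")
    if (!all(r$stereo %in% c("L", "D")))
      msg <- c(msg, "stereo must be 'L' or 'D'")
  }
  if (length(msg)) msg else TRUE
})
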