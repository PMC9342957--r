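#' @include AllGenerics.R
NULL

#' Number of frames in a trajectory
#'
#' @param x A \linkS4class{Trajectory} object.
#' @return Integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Number of atoms in a trajectory
#'
#' @param x A \linkS4class{Trajectory} object.
#' @return Integer atom count.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Atom metadata table
#'
#' @param x A \linkS4class{Trajectory} object.
#' @return A \code{data.frame} with one row per atom (name, element, residue
#'   index, residue name, chain id, role, radius).
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' Per-frame box dimensions
#'
#' @param x A \linkS4class{Trajectory} object.
#' @return A frames-by-3 numeric matrix of orthorhombic box edges (Lx, Ly,
#'   Lz) in Angstrom.
#' @export
setGeneric("boxDims", function(x) standardGeneric("boxDims"))

#' Coordinates of one frame or all frames
#'
#' @param x A \linkS4class{Trajectory} object.
#' @param frame Frame index; if missing, the full atoms x 3 x frames array.
#' @return An atoms-by-3 matrix (single frame) or 3-d array (all frames),
#'   in Angstrom.
#' @export
setGeneric("frameCoords", function(x, frame) standardGeneric("frameCoords"))

#' Distance matrix of a restraint series
#'
#' @param x A \linkS4class{DistanceSeries} object.
#' @return A chains-by-frames numeric matrix of distances in Angstrom.
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))

#' Integrated injection heats
#'
#' @param x An \linkS4class{ITCExperiment} object.
#' @return Numeric vector of blank-corrected integrated heats, one per
#'   injection, in microjoules.
#' @export
setGeneric("heats", function(x) standardGeneric("heats"))

#' Ground-truth parameters attached to a synthetic artifact
#'
#' Synthetic generators store their generating parameters alongside the
#' artifact so that recovery tests can compare against a known truth.
#'
#' @param x A synthetic object (Trajectory, DistanceSeries list element,
#'   ITCExperiment or TitrationTrace).
#' @return A named list of generating parameters, or \code{NULL} for
#'   objects not produced by a generator.
#' @export
setGeneric("generatorTruth", function(x) standardGeneric("generatorTruth"))
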