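#' @include AllClasses.R
NULL

#' Construct a Trajectory
#'
#' @param coords atoms x 3 x frames numeric array (Angstrom). A single
#'   atoms x 3 matrix is promoted to a one-frame array.
#' @param box frames x 3 matrix of box edges (Angstrom); a length-3 vector
#'   is recycled across frames.
#' @param atoms data.frame of atom metadata; see \linkS4class{Trajectory}.
#' @param provenance optional list of generating parameters.
#' @return A validated \linkS4class{Trajectory}.
#' @export
Trajectory <- function(coords, box, atoms, provenance = list()) {
  if (is.matrix(coords)) coords <- array(coords, c(dim(coords), 1L))
  nf <- dim(coords)[3]
  if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
  atoms$role <- as.character(atoms$role)
  new("Trajectory", coords = coords, box = box, atoms = atoms,
      provenance = provenance)
}

#' @rdname nFrames
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[1])

#' @rdname atomData
#' @export
setMethod("atomData", "Trajectory", function(x) x@atoms)

#' @rdname boxDims
#' @export
setMethod("boxDims", "Trajectory", function(x) x@box)

#' @rdname frameCoords
#' @export
setMethod("frameCoords", "Trajectory", function(x, frame) {
  if (missing(frame)) return(x@coords)
  x@coords[, , frame, drop = TRUE]
})

#' @rdname generatorTruth
#' @export
setMethod("generatorTruth", "Trajectory", function(x)
  if (length(x@provenance)) x@provenance else NULL)

setMethod("show", "Trajectory", function(object) {
  tab <- table(object@atoms$role)
  cat("Trajectory:", nAtoms(object), "atoms x", nFrames(object), "frames\n")
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  box (frame 1): ",
      paste(sprintf("%.2f", object@box[1, ]), collapse = " x "), " A\n", sep = "")
  if (length(object@provenance))
    cat("  synthetic (seed ", object@provenance$seed %||% "?", ")\n", sep = "")
})

#' Select atom indices by chain / residue / atom-name pattern
#'
#' Selections are expressed as \code{"chain/resid/name"} patterns where each
#' field is a literal value, a comma-separated list, or \code{"*"} for any,
#' e.g. \code{"*/*/P"} (all phosphates) or \code{"A/2/CB"}. A missing
#' trailing field is treated as \code{"*"}.
#'
#' @param traj A \linkS4class{Trajectory}.
#' @param pattern Selection string, or a logical/integer index vector which
#'   is passed through unchanged.
#' @param role Optional role filter applied on top of the pattern.
#' @return Integer vector of atom indices; errors if nothing matches.
#' @export
selectAtoms <- function(traj, pattern = "*/*/*", role = NULL) {
  at <- atomData(traj)
  if (is.logical(pattern)) pattern <- which(pattern)
  if (is.numeric(pattern)) {
    idx <- as.integer(pattern)
  } else {
    parts <- strsplit(pattern, "/", fixed = TRUE)[[1]]
    parts <- c(parts, rep("*", max(0, 3 - length(parts))))[1:3]
    keep <- rep(TRUE, nrow(at))
    fields <- list(at$chain, at$resid, at$name)
    for (k in 1:3) {
      if (parts[k] != "*") {
        vals <- strsplit(parts[k], ",", fixed = TRUE)[[1]]
        keep <- keep & (as.character(fields[[k]]) %in% vals)
      }
    }
    idx <- which(keep)
  }
  if (!is.null(role)) idx <- idx[at$role[idx] %in% role]
  if (!length(idx))
    stop("selection '", if (is.character(pattern)) pattern else "<index>",
         "' matches no atoms", call. = FALSE)
  idx
}

#' Construct an NOERestraint
#'
#' @param resI,resJ residue indices (resI < resJ after ordering; pairs are
#'   reordered automatically).
#' @param atomI,atomJ atom names.
#' @param upper upper-bound distance, Angstrom.
#' @return An \linkS4class{NOERestraint}.
#' @export
NOERestraint <- function(resI, atomI, resJ, atomJ, upper) {
  if (resI > resJ) {
    tmp <- resI; resI <- resJ; resJ <- tmp
    tmp <- atomI; atomI <- atomJ; atomJ <- tmp
  }
  new("NOERestraint", resI = as.integer(resI), atomI = atomI,
      resJ = as.integer(resJ), atomJ = atomJ, upper = upper)
}

#' Residue-separation class of a restraint
#'
#' @param restraint An \linkS4class{NOERestraint}.
#' @return \code{"sequential"} (|j-i| = 1), \code{"i+2"}, \code{"i+3"}, or
#'   \code{"other"}.
#' @export
restraintClass <- function(restraint) {
  sep <- restraint@resJ - restraint@resI
  switch(as.character(sep), "1" = "sequential", "2" = "i+2", "3" = "i+3",
         "other")
}

setMethod("show", "NOERestraint", function(object) {
  cat(sprintf("NOERestraint %d:%s - %d:%s  upper %.2f A (%s)\n",
              object@resI, object@atomI, object@resJ, object@atomJ,
              object@upper, restraintClass(object)))
})

#' Construct a DistanceSeries
#'
#' @param restraint An \linkS4class{NOERestraint}.
#' @param distances chains x frames matrix of distances (Angstrom).
#' @param dt frame spacing, ps (default 1).
#' @param provenance optional generating-parameter list.
#' @return A \linkS4class{DistanceSeries}.
#' @export
DistanceSeries <- function(restraint, distances, dt = 1, provenance = list()) {
  if (!is.matrix(distances)) distances <- matrix(distances, nrow = 1)
  new("DistanceSeries", restraint = restraint, distances = distances,
      dt = dt, provenance = provenance)
}

#' @rdname distances
#' @export
setMethod("distances", "DistanceSeries", function(x) x@distances)

#' @rdname generatorTruth
#' @export
setMethod("generatorTruth", "DistanceSeries", function(x)
  if (length(x@provenance)) x@provenance else NULL)

setMethod("show", "DistanceSeries", function(object) {
  cat(sprintf("DistanceSeries: %d chains x %d frames (dt %.1f ps), restraint %d:%s-%d:%s\n",
              nrow(object@distances), ncol(object@distances), object@dt,
              object@restraint@resI, object@restraint@atomI,
              object@restraint@resJ, object@restraint@atomJ))
})

#' Construct an ITCExperiment
#'
#' @param cellConc peptide concentration in the cell, micromolar.
#' @param syringeConc total lipid concentration in the syringe, millimolar.
#' @param injectionVolumes per-injection volumes, microlitre.
#' @param heats integrated blank-corrected heats per injection, microjoule.
#' @param cellVolume active cell volume, microlitre (default 170).
#' @param temperature Kelvin (default 298.15).
#' @param outerFraction outer-leaflet lipid fraction in (0, 1] (default 0.5,
#'   symmetric leaflets of large unilamellar vesicles).
#' @param provenance optional generating-parameter list.
#' @return An \linkS4class{ITCExperiment}.
#' @export
ITCExperiment <- function(cellConc, syringeConc, injectionVolumes, heats,
                          cellVolume = 170, temperature = 298.15,
                          outerFraction = 0.5, provenance = list()) {
  new("ITCExperiment", cellConc = cellConc, syringeConc = syringeConc,
      injectionVolumes = injectionVolumes, heats = heats,
      cellVolume = cellVolume, temperature = temperature,
      outerFraction = outerFraction, provenance = provenance)
}

#' @rdname heats
#' @export
setMethod("heats", "ITCExperiment", function(x) x@heats)

#' @rdname generatorTruth
#' @export
setMethod("generatorTruth", "ITCExperiment", function(x)
  if (length(x@provenance)) x@provenance else NULL)

setMethod("show", "ITCExperiment", function(object) {
  cat(sprintf("ITCExperiment: %d injections, cell %.0f uM peptide / %.1f ul, syringe %.1f mM lipid (outer fraction %.2f), T %.2f K\n",
              length(object@heats), object@cellConc, object@cellVolume,
              object@syringeConc, object@outerFraction, object@temperature))
})

setMethod("show", "BindingParameters", function(object) {
  cat("Single-site binding parameters\n")
  cat(sprintf("  n   = %.3g lipids/peptide (eff.)\n", object@n))
  cat(sprintf("  Kd  = %.3g uM\n", object@kd))
  cat(sprintf("  dH  = %.3g kJ/mol\n", object@dh))
  cat(sprintf("  dG  = %.3g kJ/mol,  TdS = %.3g kJ/mol,  TdS/|dH| = %.2f\n",
              object@dg, object@tds, object@ratio))
})

#' Construct a TitrationTrace
#'
#' @param time seconds, strictly increasing.
#' @param intensity fluorescence intensities (arbitrary units).
#' @param events data.frame with columns \code{time}, \code{label},
#'   \code{dose}.
#' @param baseline length-2 window (s) used for normalization.
#' @param normalized logical, default FALSE.
#' @param provenance optional generating-parameter list.
#' @return A \linkS4class{TitrationTrace}.
#' @export
TitrationTrace <- function(time, intensity,
                           events = data.frame(time = numeric(),
                                               label = character(),
                                               dose = numeric()),
                           baseline = range(time), normalized = FALSE,
                           provenance = list()) {
  new("TitrationTrace", time = time, intensity = intensity, events = events,
      baseline = baseline, normalized = normalized, provenance = provenance)
}

#' @rdname generatorTruth
#' @export
setMethod("generatorTruth", "TitrationTrace", function(x)
  if (length(x@provenance)) x@provenance else NULL)

setMethod("show", "TitrationTrace", function(object) {
  cat(sprintf("TitrationTrace: %d samples over %.0f s, %d events%s\n",
              length(object@time), diff(range(object@time)),
              nrow(object@events),
              if (object@normalized) " (normalized)" else ""))
})
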