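#' @include utils.R
NULL

#' Ensemble RMSD to the average structure and radius of gyration
#'
#' Given a conformer ensemble, iteratively superposes every conformer onto
#' the ensemble-average structure (optimal least-squares rotation and
#' translation, reflection branch excluded) and reports each conformer's
#' RMSD to that average together with its radius of gyration (about its own
#' center of mass, unit weights) over the chosen atom scope.
#'
#' @param conformers list of n x 3 coordinate matrices with identical atom
#'   counts and ordering (>= 2 conformers).
#' @param atoms optional data.frame with \code{name} and \code{element}
#'   columns used to restrict the atom scope.
#' @param atomScope \code{"heavy"} (drop hydrogens; requires \code{atoms})
#'   or \code{"backbone"} (N, CA, C, O); \code{"all"} when \code{atoms} is
#'   NULL.
#' @return A list of class \code{"EnsembleStats"}: \code{rmsd} and
#'   \code{rg} per conformer, their means and SDs, and the \code{average}
#'   structure.
#' @export
ensembleStats <- function(conformers, atoms = NULL,
                          atomScope = c("heavy", "backbone", "all")) {
  atomScope <- match.arg(atomScope)
  if (length(conformers) < 2)
    stop("at least 2 conformers are required", call. = FALSE)
  n0 <- nrow(conformers[[1]])
  for (i in seq_along(conformers))
    if (nrow(conformers[[i]]) != n0)
      stop("conformer ", i, " has ", nrow(conformers[[i]]),
           " atoms; expected ", n0, call. = FALSE)
  keep <- seq_len(n0)
  if (!is.null(atoms)) {
    keep <- switch(atomScope,
      heavy = which(toupper(atoms$element) != "H"),
      backbone = which(atoms$name %in% c("N", "CA", "C", "O")),
      all = keep)
    if (!length(keep)) stop("atom scope matches no atoms", call. = FALSE)
  }
  confs <- lapply(conformers, function(x) x[keep, , drop = FALSE])

  # average structure: superpose all onto the first, average, then refine
  # once against the provisional average
  avg <- confs[[1]]
  for (iter in 1:2) {
    fitted <- lapply(confs, kabschFit, y = avg)
    avg <- Reduce(`+`, fitted) / length(fitted)
  }
  rmsd <- vapply(confs, superposedRmsd, numeric(1), y = avg)
  rg <- vapply(confs, radiusOfGyration, numeric(1))
  structure(list(rmsd = rmsd, rg = rg,
                 rmsdMean = mean(rmsd), rmsdSd = stats::sd(rmsd),
                 rgMean = mean(rg), rgSd = stats::sd(rg),
                 average = avg, atomScope = atomScope),
            class = "EnsembleStats")
}

#' @export
print.EnsembleStats <- function(x, ...) {
  cat(sprintf("Ensemble of %d conformers (%s atoms):\n", length(x$rmsd),
              x$atomScope))
  cat(sprintf("  RMSD to average: %.2f +/- %.2f A\n", x$rmsdMean, x$rmsdSd))
  cat(sprintf("  Rg:              %.2f +/- %.2f A\n", x$rgMean, x$rgSd))
  invisible(x)
}
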