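#' @include trajectory-methods.R
NULL

# Per-frame bilayer center of mass along z, over lipid atoms only
# (headgroup + acyl roles), unit weights.
.bilayerComZ <- function(traj) {
  lip <- which(atomData(traj)$role %in% c("headgroup", "acyl"))
  if (!length(lip))
    stop("no lipid atoms present to define the bilayer center of mass",
         call. = FALSE)
  m <- traj@coords[lip, 3, , drop = FALSE]
  colMeans(array(m, c(length(lip), dim(m)[3])))
}

# Leaflet assignment by sign of z relative to the bilayer COM at frame 1
# (no flip-flop tracking).
.leafletSign <- function(traj, idx) {
  com1 <- .bilayerComZ(traj)[1]
  sign(traj@coords[idx, 3, 1] - com1)
}

#' Per-residue peptide insertion depth
#'
#' The insertion depth of a residue is the unsigned z-distance of its
#' C-beta atom (or any selected atom) from the bilayer center of mass,
#' averaged over frames. Lower-leaflet chains are reflected so all depths
#' are positive and leaflets pool. The phosphate and ester-carbon reference
#' planes are reported the same way.
#'
#' @param traj A \linkS4class{Trajectory} containing lipid atoms (to define
#'   the bilayer COM) and the selected peptide atoms.
#' @param selection atom selection for the depth atoms (default all
#'   peptide-role atoms named CB); see \code{\link{selectAtoms}}.
#' @return A list of class \code{"DepthProfile"}: \code{perResidue}
#'   (residue, meanDepth, sd, n over chains), \code{perChain} (residues x
#'   chains matrix of chain-mean depths), \code{phosphatePlane} and
#'   \code{esterPlane} (mean unsigned plane distances from the COM).
#' @export
insertionDepth <- function(traj, selection = "*/*/CB") {
  idx <- selectAtoms(traj, selection, role = "peptide")
  at <- atomData(traj)
  comz <- .bilayerComZ(traj)
  z <- array(traj@coords[idx, 3, , drop = FALSE],
             c(length(idx), nFrames(traj)))
  depth <- abs(sweep(z, 2, comz))
  chain <- at$chain[idx]; res <- at$resid[idx]
  chains <- unique(chain); resids <- sort(unique(res))
  perChain <- matrix(NA_real_, length(resids), length(chains),
                     dimnames = list(resids, chains))
  for (i in seq_along(idx))
    perChain[as.character(res[i]), chain[i]] <- mean(depth[i, ])
  perResidue <- data.frame(
    residue = resids,
    meanDepth = rowMeans(perChain),
    sd = apply(perChain, 1, stats::sd),
    n = ncol(perChain))
  planeDepth <- function(name) {
    pid <- which(at$name == name)
    if (!length(pid)) return(NA_real_)
    zp <- array(traj@coords[pid, 3, , drop = FALSE],
                c(length(pid), nFrames(traj)))
    mean(abs(sweep(zp, 2, comz)))
  }
  structure(list(perResidue = perResidue, perChain = perChain,
                 phosphatePlane = planeDepth("P"),
                 esterPlane = planeDepth("C21")),
            class = "DepthProfile")
}

#' @export
print.DepthProfile <- function(x, ...) {
  cat("Insertion depth profile (A from bilayer COM):\n")
  print(x$perResidue, row.names = FALSE)
  cat(sprintf("  phosphate plane %.2f A, ester plane %.2f A\n",
              x$phosphatePlane, x$esterPlane))
  invisible(x)
}

#' Bilayer thickness time series
#'
#' Per-frame distance between the mean phosphate z of the upper and lower
#' leaflets (leaflets assigned at frame 1 by the sign of z relative to the
#' bilayer COM), with a block-averaged mean and uncertainty.
#'
#' @param traj A \linkS4class{Trajectory} with phosphate atoms (name "P")
#'   in both leaflets.
#' @param ... passed to \code{\link{blockAverage}} when the series is long
#'   enough (>= 8 frames); otherwise plain mean/sd are reported.
#' @return List with \code{series} (Angstrom per frame), \code{mean},
#'   \code{sd}, \code{se}, \code{blockSize}.
#' @export
bilayerThickness <- function(traj, ...) {
  at <- atomData(traj)
  pid <- which(at$name == "P" & at$role == "headgroup")
  if (!length(pid)) stop("no phosphate atoms found", call. = FALSE)
  s <- .leafletSign(traj, pid)
  if (!any(s > 0) || !any(s < 0))
    stop("a leaflet has no phosphates: cannot measure thickness",
         call. = FALSE)
  z <- array(traj@coords[pid, 3, , drop = FALSE],
             c(length(pid), nFrames(traj)))
  series <- colMeans(z[s > 0, , drop = FALSE]) -
    colMeans(z[s < 0, , drop = FALSE])
  .seriesStats(series, ...)
}

#' Area per lipid time series
#'
#' Per-frame lateral box area divided by the number of lipids in one
#' leaflet, with block-averaged statistics.
#'
#' @param traj A \linkS4class{Trajectory} with a per-frame box.
#' @param lipidsPerLeaflet lipids in one leaflet (> 0); the study system
#'   has 75.
#' @param ... passed to \code{\link{blockAverage}}.
#' @return List with \code{series} (Angstrom^2 per frame), \code{mean},
#'   \code{sd}, \code{se}, \code{blockSize}.
#' @export
areaPerLipid <- function(traj, lipidsPerLeaflet, ...) {
  stopifnot(lipidsPerLeaflet > 0)
  b <- boxDims(traj)
  if (!nrow(b) || any(!is.finite(b[, 1:2])))
    stop("trajectory has no usable per-frame box", call. = FALSE)
  series <- b[, 1] * b[, 2] / lipidsPerLeaflet
  .seriesStats(series, ...)
}

.seriesStats <- function(series, ...) {
  if (length(series) >= 8) {
    ba <- blockAverage(series, ...)
    list(series = series, mean = ba$mean, sd = ba$sd, se = ba$se,
         blockSize = ba$blockSize)
  } else {
    list(series = series, mean = mean(series),
         sd = stats::sd(series), se = stats::sd(series) / sqrt(length(series)),
         blockSize = 1L)
  }
}

#' Fraction of frames below an RMSD threshold to a reference conformer
#'
#' For each peptide chain, superposes the chain's selected atoms onto the
#' reference at every frame (optimal least-squares rotation) and reports
#' the fraction of frames with RMSD below the threshold, plus the ensemble
#' mean. The reference atom count must match each chain's selected atoms
#' one-to-one (same order).
#'
#' @param traj A \linkS4class{Trajectory}.
#' @param reference n x 3 coordinate matrix of the reference conformer.
#' @param threshold RMSD cutoff, Angstrom (default 3).
#' @param selection atom selection restricted to peptide-role atoms
#'   (default all peptide atoms).
#' @return List with \code{perChain} (named fractions) and \code{mean}.
#' @export
fractionBelowRmsd <- function(traj, reference, threshold = 3,
                              selection = "*/*/*") {
  idx <- selectAtoms(traj, selection, role = "peptide")
  at <- atomData(traj)
  chains <- unique(at$chain[idx])
  per <- vapply(chains, function(ch) {
    ci <- idx[at$chain[idx] == ch]
    if (length(ci) != nrow(reference))
      stop("reference (", nrow(reference), " atoms) does not map onto chain ",
           ch, " (", length(ci), " atoms)", call. = FALSE)
    r <- vapply(seq_len(nFrames(traj)), function(f)
      superposedRmsd(traj@coords[ci, , f], reference), numeric(1))
    mean(r < threshold)
  }, numeric(1))
  names(per) <- chains
  list(perChain = per, mean = mean(per))
}
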