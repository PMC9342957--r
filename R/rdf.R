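#' @include trajectory-methods.R
NULL

#' Lateral (x-y plane) radial distribution function
#'
#' Computes g(r) between a reference and a target atom selection in the
#' membrane plane, applying the minimum-image convention in x and y only
#' (the bilayer normal is not wrapped). Counts in each radial annulus are
#' normalized by the annulus area times the mean target surface density,
#' averaged over frames and reference atoms. When the selections share
#' atoms, self-pairs are excluded.
#'
#' @param traj A \linkS4class{Trajectory} with per-frame box.
#' @param reference,target atom selections (see \code{\link{selectAtoms}}).
#' @param breaks strictly increasing bin edges, Angstrom.
#' @param frames frame indices (default all).
#' @return A list of class \code{"RDFProfile"}: \code{r} (bin centers),
#'   \code{g}, \code{counts} (total pair counts per bin), \code{breaks},
#'   and \code{plane = "lateral-xy"}.
#' @export
lateralRdf <- function(traj, reference, target, breaks = seq(0, 30, 0.5),
                       frames = seq_len(nFrames(traj))) {
  if (any(diff(breaks) <= 0))
    stop("bin edges must be strictly increasing", call. = FALSE)
  ri <- selectAtoms(traj, reference)
  ti <- selectAtoms(traj, target)
  nb <- length(breaks) - 1
  counts <- numeric(nb)
  gsum <- numeric(nb)
  for (f in frames) {
    Lx <- traj@box[f, 1]; Ly <- traj@box[f, 2]
    xy <- traj@coords[, 1:2, f]
    dx <- outer(xy[ri, 1], xy[ti, 1], `-`)
    dy <- outer(xy[ri, 2], xy[ti, 2], `-`)
    dx <- dx - Lx * round(dx / Lx)
    dy <- dy - Ly * round(dy / Ly)
    r <- sqrt(dx^2 + dy^2)
    self <- outer(ri, ti, `==`)
    r <- r[!self]
    h <- graphics::hist(r[r >= breaks[1] & r < breaks[nb + 1]],
                        breaks = breaks, plot = FALSE)$counts
    counts <- counts + h
    # per-frame normalization: expected pairs per annulus for an ideal gas
    rho <- length(ti) / (Lx * Ly)
    annulus <- pi * diff(breaks^2)
    gsum <- gsum + h / (length(ri) * rho * annulus)
  }
  structure(list(r = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 g = gsum / length(frames), counts = counts,
                 breaks = breaks, plane = "lateral-xy",
                 nFrames = length(frames)),
            class = "RDFProfile")
}

#' @export
print.RDFProfile <- function(x, ...) {
  cat(sprintf("Lateral RDF: %d bins over [%.1f, %.1f] A, %d frame(s)\n",
              length(x$g), min(x$breaks), max(x$breaks), x$nFrames))
  invisible(x)
}
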