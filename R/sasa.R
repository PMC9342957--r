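#' @include trajectory-methods.R
NULL

# Shrake-Rupley exposed area of one coordinate set. xyz: n x 3, radius:
# length n. Returns per-atom exposed areas (A^2). Dots are a golden-spiral
# point set shared across atoms; neighbor lists cut the pairwise test to
# spheres that can actually occlude.
.shrakeRupley <- function(xyz, radius, probeRadius = 1.4, nDots = 240) {
  n <- nrow(xyz)
  dots <- sphereDots(nDots)
  rexp <- radius + probeRadius
  area <- numeric(n)
  cut <- outer(rexp, rexp, `+`)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < cut[i, ]^2)
    nb <- nb[nb != i]
    pts <- sweep(dots * rexp[i], 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, nDots)
    for (j in nb) {
      if (!any(exposed)) break
      dj <- sweep(pts[exposed, , drop = FALSE], 2, xyz[j, ])
      exposed[exposed] <- rowSums(dj^2) >= rexp[j]^2
    }
    area[i] <- 4 * pi * rexp[i]^2 * sum(exposed) / nDots
  }
  area
}

#' Solvent-accessible surface area by component
#'
#' Shrake-Rupley sphere-point SASA of the solute (all non-solvent atoms),
#' reported in total and per role group: an atom's exposed area counts
#' toward its own role (headgroup, acyl or peptide). Solvent atoms are
#' excluded from the solute set entirely -- they neither contribute area
#' nor occlude it. The dot density is a parameter; area converges as
#' O(1/nDots).
#'
#' @param traj A \linkS4class{Trajectory}; every non-solvent atom must have
#'   a finite positive radius.
#' @param probeRadius probe sphere radius, Angstrom (default 1.4, water).
#' @param nDots sphere test points per atom (default 240).
#' @param frames frame indices to analyse (default all).
#' @return A list of class \code{"SASAReport"}: \code{perFrame}
#'   (data.frame with total and per-role areas per analysed frame, A^2)
#'   and \code{mean}/\code{sd} summaries.
#' @export
sasa <- function(traj, probeRadius = 1.4, nDots = 240,
                 frames = seq_len(nFrames(traj))) {
  stopifnot(probeRadius >= 0)
  at <- atomData(traj)
  solute <- which(at$role != "solvent")
  bad <- solute[!is.finite(at$radius[solute]) | at$radius[solute] <= 0]
  if (length(bad))
    stop("atom(s) without a usable radius: ",
         paste(sprintf("%s %s/%s/%s", at$name[bad[1]], at$chain[bad[1]],
                       at$resid[bad[1]], at$name[bad[1]]), collapse = ", "),
         call. = FALSE)
  roles <- c("headgroup", "acyl", "peptide")
  perFrame <- do.call(rbind, lapply(frames, function(f) {
    xyz <- traj@coords[solute, , f, drop = FALSE][, , 1]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    a <- .shrakeRupley(xyz, at$radius[solute], probeRadius, nDots)
    out <- c(total = sum(a),
             vapply(roles, function(r) sum(a[at$role[solute] == r]),
                    numeric(1)))
    as.data.frame(as.list(out))
  }))
  structure(list(perFrame = perFrame,
                 mean = colMeans(perFrame),
                 sd = vapply(perFrame, stats::sd, numeric(1)),
                 probeRadius = probeRadius, nDots = nDots),
            class = "SASAReport")
}

#' @export
print.SASAReport <- function(x, ...) {
  cat(sprintf("SASA over %d frame(s), probe %.2f A, %d dots/atom:\n",
              nrow(x$perFrame), x$probeRadius, x$nDots))
  m <- x$mean
  cat(sprintf("  total %.1f | headgroup %.1f | acyl %.1f | peptide %.1f A^2\n",
              m["total"], m["headgroup"], m["acyl"], m["peptide"]))
  invisible(x)
}
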