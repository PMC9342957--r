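#' @include AllClasses.R
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
# Keeps generators pure functions of (parameters, seed).
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic sub-stream seed per artifact, kept below 2^31.
subSeed <- function(seed, stream) {
  (as.numeric(seed) * 2654435761 + stream * 97) %% 2147483647
}

#' van der Waals radius by element
#'
#' Bondi radii (Angstrom) for the elements that occur in peptide/lipid
#' systems; used to assign atomic radii on trajectory ingestion and by the
#' solvent-accessible surface area routines.
#'
#' @param element Character vector of element symbols.
#' @return Numeric radii in Angstrom; errors on an unknown element.
#' @examples
#' elementRadius(c("C", "N", "O"))
#' @export
elementRadius <- function(element) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80,
           F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, NA. = 2.27, K = 2.75)
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  r <- tab[key]
  if (anyNA(r))
    stop("no van der Waals radius for element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "), call. = FALSE)
  unname(r)
}

# Optimal least-squares rotation (Kabsch) mapping x onto y after centering.
# Both are n x 3 matrices; returns the rotated-and-translated x.
# The reflection branch is excluded by forcing det(U) = +1.
kabschFit <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  s <- svd(crossprod(xc, yc))
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  sweep(xc %*% t(R), 2, cy, `+`)
}

# RMSD between two n x 3 coordinate sets after optimal superposition.
superposedRmsd <- function(x, y) {
  xf <- kabschFit(x, y)
  sqrt(mean(rowSums((xf - y)^2)))
}

# n approximately evenly distributed unit-sphere points (golden spiral).
sphereDots <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Radius of gyration about the center of mass, unit weights.
radiusOfGyration <- function(x) {
  xc <- sweep(x, 2, colMeans(x))
  sqrt(mean(rowSums(xc^2)))
}
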