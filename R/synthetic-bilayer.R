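#' @include trajectory-methods.R
NULL

#' Bilayer system specification
#'
#' Describes a two-leaflet lamellar bilayer by lipids per leaflet, lipid
#' composition, the distance of the phosphate plane from the bilayer
#' midplane and the lateral box. Defaults reproduce the study system: 75
#' lipids per leaflet (150 total) at a 20:80 TOCL:POPC molar ratio.
#'
#' Each lipid species is represented by a minimal pseudo-atom template:
#' a phosphate (P), an ester carbon (C21, the lower boundary of the
#' headgroup region) and a terminal acyl bead (C2T); phosphatidylcholine
#' additionally carries a choline bead (NC). The template is sufficient for
#' every downstream metric (depth reference planes, thickness, SASA
#' components, lateral RDFs) without a force field.
#'
#' @param nLipidsPerLeaflet lipids per leaflet (default 75).
#' @param moleFractions named fractions summing to 1 (default
#'   c(TOCL = 0.2, POPC = 0.8)).
#' @param leafletZOffset phosphate-plane distance from the midplane,
#'   Angstrom (default 19, a 38 Angstrom phosphate-to-phosphate thickness).
#' @param areaPerLipid mean cross-sectional area per lipid, Angstrom^2;
#'   default 81.8, the composition-weighted mean of POPC (70) and TOCL
#'   (129).
#' @param boxZ box height, Angstrom (default 90).
#' @return A validated list of class \code{"BilayerSpec"}.
#' @export
bilayerSpec <- function(nLipidsPerLeaflet = 75,
                        moleFractions = c(TOCL = 0.2, POPC = 0.8),
                        leafletZOffset = 19,
                        areaPerLipid = 81.8,
                        boxZ = 90) {
  stopifnot(nLipidsPerLeaflet > 0, leafletZOffset > 0, areaPerLipid > 0)
  if (abs(sum(moleFractions) - 1) > 1e-9)
    stop("mole fractions must sum to 1", call. = FALSE)
  structure(list(nLipidsPerLeaflet = as.integer(nLipidsPerLeaflet),
                 moleFractions = moleFractions,
                 leafletZOffset = leafletZOffset,
                 areaPerLipid = areaPerLipid, boxZ = boxZ),
            class = "BilayerSpec")
}

#' Ground-truth parameters for the synthetic generators
#'
#' Bundles every designed quantity the generators draw from, so that each
#' emitted artifact records the truth it was built to satisfy. All noise
#' standard deviations must be non-negative; the seed is recorded in every
#' artifact's provenance.
#'
#' @param depth per-residue target insertion depths of the peptide C-beta
#'   pseudo-atoms, Angstrom (length 4). Defaults place the residues in the
#'   interfacial region between the ester-carbon and phosphate planes.
#' @param depthJitter per-frame Gaussian jitter of the depths, Angstrom.
#' @param phosphateJitter per-frame jitter of phosphate z positions,
#'   Angstrom.
#' @param areaJitter per-frame jitter of the area per lipid, Angstrom^2.
#' @param itcN,itcKd,itcDh single-site ITC truth: stoichiometry (effective
#'   lipids per peptide), dissociation constant (micromolar) and enthalpy
#'   (kJ/mol).
#' @param traceNoise relative Gaussian noise of fluorescence traces.
#' @param foldChange saturating fold-change of the surface-probe trace
#'   relative to its baseline (default 1.8).
#' @param halfSatDose half-saturation peptide dose, nmol (default 20).
#' @param tmrmQuench fractional quench of the transmembrane-potential probe
#'   on mitochondria addition (default -0.35).
#' @param aneppsDrop saturating fractional drop of the dipole-probe
#'   excitation ratio over a titration (default 0.3).
#' @param seed integer master seed; sub-streams are derived per artifact.
#' @return A list of class \code{"SyntheticTruth"}.
#' @export
syntheticTruth <- function(depth = c(16, 14, 15.5, 14.5), depthJitter = 1,
                           phosphateJitter = 0.5, areaJitter = 1.5,
                           itcN = 5, itcKd = 30, itcDh = -5,
                           traceNoise = 0.01, foldChange = 1.8,
                           halfSatDose = 20, tmrmQuench = -0.35,
                           aneppsDrop = 0.3, seed = 1L) {
  sds <- c(depthJitter, phosphateJitter, areaJitter, traceNoise)
  if (any(sds < 0)) stop("noise standard deviations must be >= 0", call. = FALSE)
  structure(list(depth = depth, depthJitter = depthJitter,
                 phosphateJitter = phosphateJitter, areaJitter = areaJitter,
                 itcN = itcN, itcKd = itcKd, itcDh = itcDh,
                 traceNoise = traceNoise, foldChange = foldChange,
                 halfSatDose = halfSatDose, tmrmQuench = tmrmQuench,
                 aneppsDrop = aneppsDrop, seed = as.integer(seed)),
            class = "SyntheticTruth")
}

#' Lipid and cardiolipin per-peptide ratios of a bilayer system
#'
#' @param spec A \code{\link{bilayerSpec}}.
#' @param nPeptides number of surface-bound peptides.
#' @return List with \code{lipidToPeptide} and \code{clToPeptide}.
#' @examples
#' compositionRatios(bilayerSpec(), 20)  # 7.5 and 1.5
#' @export
compositionRatios <- function(spec, nPeptides) {
  stopifnot(nPeptides > 0)
  total <- 2 * spec$nLipidsPerLeaflet
  cl <- total * if ("TOCL" %in% names(spec$moleFractions))
    spec$moleFractions[["TOCL"]] else 0
  list(lipidToPeptide = total / nPeptides, clToPeptide = cl / nPeptides)
}

# species -> pseudo-atom template: dz is the offset from the phosphate
# plane toward the bilayer midplane (negative = deeper).
.lipidTemplate <- function(species) {
  switch(species,
    POPC = data.frame(name = c("NC", "P", "C21", "C2T"),
                      element = c("N", "P", "C", "C"),
                      role = c("headgroup", "headgroup", "headgroup", "acyl"),
                      dz = c(2, 0, -4, -14)),
    TOCL = data.frame(name = c("P", "C21", "C2T"),
                      element = c("P", "C", "C"),
                      role = c("headgroup", "headgroup", "acyl"),
                      dz = c(0, -4, -14)),
    stop("unknown lipid species: ", species, call. = FALSE))
}

# largest-remainder apportionment of n lipids across species fractions
.apportion <- function(n, fractions) {
  raw <- fractions * n
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  k
}

#' Generate a synthetic peptide-bilayer trajectory
#'
#' Builds a two-leaflet pseudo-atom bilayer with surface-bound tetrapeptides
#' whose C-beta depths fluctuate about prescribed truth values, and emits a
#' multi-frame \linkS4class{Trajectory} with per-frame orthorhombic box.
#' Peptides are split equally across the leaflets. Phosphate pseudo-atoms
#' lie near +/- the leaflet offset; all noise is independent Gaussian
#' jitter (no force field). The generator is a pure function of its
#' arguments: identical inputs give identical trajectories.
#'
#' @param spec A \code{\link{bilayerSpec}}.
#' @param nPeptides even number of peptides (half per leaflet).
#' @param truth A \code{\link{syntheticTruth}}; supplies depths, jitters and
#'   the master seed.
#' @param nFrames number of frames (>= 1).
#' @return A \linkS4class{Trajectory} with provenance recording all
#'   generating parameters.
#' @examples
#' tr <- makeBilayerTrajectory(bilayerSpec(), 20,
#'                             syntheticTruth(seed = 7), nFrames = 5)
#' nAtoms(tr); nFrames(tr)
#' @export
makeBilayerTrajectory <- function(spec, nPeptides, truth, nFrames) {
  if (nPeptides %% 2 != 0)
    stop("nPeptides must be even: peptides are split equally across the ",
         "two leaflets", call. = FALSE)
  stopifnot(nFrames >= 1)
  withSeed(subSeed(truth$seed, 1L), {
    nl <- spec$nLipidsPerLeaflet
    counts <- .apportion(nl, spec$moleFractions)
    boxXY <- sqrt(2 * nl * spec$areaPerLipid / 2)  # per-leaflet area = Lx*Ly
    off <- spec$leafletZOffset

    atoms <- list(); base <- list()   # base: x, y, z0, leaflet sign
    resid <- 0L
    for (leaflet in c(1, -1)) {
      # lipids on a jittered grid
      grid <- ceiling(sqrt(nl))
      gx <- ((seq_len(nl) - 1) %% grid + 0.5) * boxXY / grid
      gy <- ((seq_len(nl) - 1) %/% grid + 0.5) * boxXY / grid
      species <- rep(names(counts), counts)
      k <- 0L
      for (i in seq_len(nl)) {
        k <- k + 1L; resid <- resid + 1L
        tpl <- .lipidTemplate(species[i])
        atoms[[length(atoms) + 1L]] <- data.frame(
          name = tpl$name, element = tpl$element, resid = resid,
          resname = species[i], chain = "L", role = tpl$role,
          radius = elementRadius(tpl$element))
        base[[length(base) + 1L]] <- cbind(
          x = rep(gx[k], nrow(tpl)), y = rep(gy[k], nrow(tpl)),
          z = leaflet * (off + tpl$dz), s = leaflet,
          jz = as.numeric(tpl$name == "P"))
      }
    }
    lipidAtomCount <- sum(vapply(atoms, nrow, 1L))

    # peptides: 4-residue backbones, CA + CB per residue, on their own grid
    perLeaflet <- nPeptides / 2
    pg <- max(1, ceiling(sqrt(perLeaflet)))
    for (p in seq_len(nPeptides)) {
      leaflet <- if (p <= perLeaflet) 1 else -1
      j <- (p - 1) %% perLeaflet
      px <- ((j %% pg) + 0.37) * boxXY / pg
      py <- ((j %/% pg) + 0.63) * boxXY / pg
      for (r in 1:4) {
        atoms[[length(atoms) + 1L]] <- data.frame(
          name = c("CA", "CB"), element = "C", resid = r,
          resname = "RES", chain = sprintf("p%02d", p), role = "peptide",
          radius = elementRadius("C"))
        base[[length(base) + 1L]] <- cbind(
          x = px + (r - 2.5) * 1.8, y = rep(py, 2),
          z = leaflet * c(truth$depth[r] + 1, truth$depth[r]),
          s = leaflet, jz = c(0, 1) * 2)  # jz 2 marks CB depth jitter
      }
    }
    atoms <- do.call(rbind, atoms)
    base <- do.call(rbind, base)
    na <- nrow(atoms)

    # per-frame coordinates: base + jitter streams
    coords <- array(NA_real_, c(na, 3, nFrames))
    apl <- rep(spec$areaPerLipid, nFrames) +
      if (truth$areaJitter > 0) stats::rnorm(nFrames, 0, truth$areaJitter) else 0
    box <- cbind(sqrt(nl * apl), sqrt(nl * apl), spec$boxZ)
    for (f in seq_len(nFrames)) {
      scale <- box[f, 1] / boxXY
      zj <- numeric(na)
      isP <- base[, "jz"] == 1
      isCB <- base[, "jz"] == 2
      if (truth$phosphateJitter > 0)
        zj[isP] <- stats::rnorm(sum(isP), 0, truth$phosphateJitter)
      if (truth$depthJitter > 0)
        zj[isCB] <- stats::rnorm(sum(isCB), 0, truth$depthJitter)
      coords[, 1, f] <- base[, "x"] * scale
      coords[, 2, f] <- base[, "y"] * scale
      coords[, 3, f] <- base[, "z"] + base[, "s"] * 0 + zj
    }

    Trajectory(coords, box, atoms,
               provenance = list(seed = truth$seed, truth = truth,
                                 spec = spec, nPeptides = nPeptides,
                                 nFrames = nFrames,
                                 lipidAtomCount = lipidAtomCount))
  })
}
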