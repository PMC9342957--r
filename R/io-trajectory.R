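#' @include trajectory-methods.R
NULL

.WATER <- c("HOH", "TIP3", "SOL", "WAT", "SPC")
.LIPIDS <- c("POPC", "TOCL", "POPE", "POPG", "DOPC", "CL")
.AMINO <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL", "DMT", "RES")
.LIPID_HEAD <- c("NC", "P", "C21", "N", "C1", "C2", "C3", "O21", "O22")

# assign role tags from residue/atom names; the acyl region of a lipid is
# everything below the ester carbon (here: the terminal acyl bead C2T and
# any CT*/C2T-like tail bead)
.classifyRoles <- function(atoms) {
  rn <- toupper(atoms$resname)
  role <- rep(NA_character_, nrow(atoms))
  role[rn %in% .WATER] <- "solvent"
  role[rn %in% .AMINO] <- "peptide"
  isLip <- rn %in% .LIPIDS
  nm <- toupper(atoms$name)
  role[isLip & nm %in% .LIPID_HEAD] <- "headgroup"
  role[isLip & (startsWith(nm, "C2T") | startsWith(nm, "CT"))] <- "acyl"
  if (any(isLip & is.na(role))) {
    bad <- which(isLip & is.na(role))[1]
    stop("cannot classify lipid atom '", atoms$name[bad], "' of residue ",
         atoms$resname[bad], call. = FALSE)
  }
  if (anyNA(role)) {
    bad <- which(is.na(role))[1]
    stop("unknown residue '", atoms$resname[bad],
         "': no role classification", call. = FALSE)
  }
  role
}

.elementFromName <- function(name) {
  e <- toupper(substr(gsub("^[0-9]", "", name), 1, 1))
  e[e == ""] <- "C"
  e
}

#' Write a trajectory as multi-model PDB
#'
#' Frames become MODEL/ENDMDL records; the frame-1 box is written as a
#' CRYST1 record and the generating seed as a REMARK (the plain frames
#' format, \code{\link{writeFrames}}, preserves the per-frame box).
#' Chain identifiers longer than one character go into the segment-id
#' field, with a single-character alias in the chain column.
#'
#' @param traj A \linkS4class{Trajectory}.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
writeTrajectoryPdb <- function(traj, path) {
  at <- atomData(traj)
  chains <- unique(at$chain)
  alias <- setNames(
    rep(c(LETTERS, letters, 0:9), length.out = length(chains)), chains)
  con <- file(path, "w")
  on.exit(close(con))
  prov <- traj@provenance
  if (length(prov))
    writeLines(sprintf("REMARK 300 GENERATED SEED %s", prov$seed %||% "NA"),
               con)
  b <- boxDims(traj)[1, ]
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                     b[1], b[2], b[3]), con)
  for (f in seq_len(nFrames(traj))) {
    writeLines(sprintf("MODEL %8d", f), con)
    xyz <- traj@coords[, , f]
    lines <- sprintf(
      "ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00      %-4s%2s",
      seq_len(nrow(at)) %% 100000, substr(at$name, 1, 4),
      substr(at$resname, 1, 4), alias[at$chain], at$resid %% 10000,
      xyz[, 1], xyz[, 2], xyz[, 3], substr(at$chain, 1, 4),
      .elementFromName(at$element))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a trajectory in the plain-text frames format
#'
#' A simple self-describing text format: a header with atom metadata and
#' provenance, then one block per frame holding the box edges and the
#' coordinate rows. Unlike PDB it preserves the per-frame box and full
#' coordinate precision, so write/read round-trips exactly.
#'
#' @param traj A \linkS4class{Trajectory}.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
writeFrames <- function(traj, path) {
  at <- atomData(traj)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#tetramem-frames 1", con)
  writeLines(sprintf("#natoms %d nframes %d", nAtoms(traj), nFrames(traj)),
             con)
  prov <- traj@provenance
  if (length(prov))
    writeLines(sprintf("#provenance seed=%s", prov$seed %||% "NA"), con)
  writeLines("#atoms name element resid resname chain role radius", con)
  writeLines(sprintf("%s %s %d %s %s %s %.4f", at$name, at$element,
                     at$resid, at$resname, at$chain, at$role, at$radius),
             con)
  for (f in seq_len(nFrames(traj))) {
    writeLines(sprintf("#frame %d", f), con)
    writeLines(paste(sprintf("%.10g", boxDims(traj)[f, ]), collapse = " "),
               con)
    xyz <- traj@coords[, , f]
    writeLines(sprintf("%.10g %.10g %.10g", xyz[, 1], xyz[, 2], xyz[, 3]),
               con)
  }
  invisible(path)
}

.readFramesFile <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#tetramem-frames"))
    stop("not a tetramem frames file: ", path, call. = FALSE)
  hdr <- strsplit(lines[2], " ")[[1]]
  na <- as.integer(hdr[2]); nf <- as.integer(hdr[4])
  i <- 3
  prov <- list()
  while (startsWith(lines[i], "#provenance")) {
    kv <- strsplit(sub("^#provenance ", "", lines[i]), "=")[[1]]
    prov[[kv[1]]] <- utils::type.convert(kv[2], as.is = TRUE)
    i <- i + 1
  }
  if (!startsWith(lines[i], "#atoms"))
    stop("malformed frames file at line ", i, ": expected #atoms header",
         call. = FALSE)
  atoms <- utils::read.table(text = lines[(i + 1):(i + na)],
                             col.names = c("name", "element", "resid",
                                           "resname", "chain", "role",
                                           "radius"),
                             colClasses = c("character", "character",
                                            "integer", "character",
                                            "character", "character",
                                            "numeric"))
  i <- i + na + 1
  coords <- array(NA_real_, c(na, 3, nf))
  box <- matrix(NA_real_, nf, 3)
  for (f in seq_len(nf)) {
    if (i > length(lines) || !startsWith(lines[i], "#frame"))
      stop("frame ", f, " is missing or truncated", call. = FALSE)
    if (i + 1 + na > length(lines))
      stop("frame ", f, " is truncated", call. = FALSE)
    box[f, ] <- scan(text = lines[i + 1], quiet = TRUE)
    m <- matrix(scan(text = lines[(i + 2):(i + 1 + na)], quiet = TRUE),
                ncol = 3, byrow = TRUE)
    if (nrow(m) != na) stop("frame ", f, " is truncated", call. = FALSE)
    coords[, , f] <- m
    i <- i + 2 + na
  }
  Trajectory(coords, box, atoms, provenance = prov)
}

.readPdbFile <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  a <- pdb$atom
  chain <- ifelse(!is.na(a$segid) & nzchar(a$segid), a$segid,
                  ifelse(is.na(a$chain), "A", a$chain))
  elem <- ifelse(!is.na(a$elesy) & nzchar(trimws(a$elesy)),
                 trimws(a$elesy), .elementFromName(a$elety))
  atoms <- data.frame(name = trimws(a$elety), element = elem,
                      resid = a$resno, resname = trimws(a$resid),
                      chain = trimws(chain), role = NA_character_,
                      radius = NA_real_)
  atoms$role <- .classifyRoles(atoms)
  atoms$radius <- elementRadius(atoms$element)
  nf <- nrow(pdb$xyz)
  na <- nrow(atoms)
  coords <- array(NA_real_, c(na, 3, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
  box <- if (!is.null(pdb$cryst1) && length(pdb$cryst1$abc) == 3)
    matrix(pdb$cryst1$abc, nf, 3, byrow = TRUE)
  else matrix(1e4, nf, 3)
  Trajectory(coords, box, atoms)
}

# single-configuration GROMACS .gro file; coordinates and box in nm,
# converted to Angstrom on ingestion
.readGroFile <- function(path) {
  lines <- readLines(path)
  na <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(na)) stop("malformed GRO file: bad atom count at line 2",
                      call. = FALSE)
  if (length(lines) < na + 3)
    stop("malformed GRO file: expected ", na, " atom records", call. = FALSE)
  rec <- lines[3:(na + 2)]
  resid <- as.integer(substr(rec, 1, 5))
  resname <- trimws(substr(rec, 6, 10))
  name <- trimws(substr(rec, 11, 15))
  x <- as.numeric(substr(rec, 21, 28)) * 10
  y <- as.numeric(substr(rec, 29, 36)) * 10
  z <- as.numeric(substr(rec, 37, 44)) * 10
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    bad <- which(is.na(x) | is.na(y) | is.na(z))[1]
    stop("malformed GRO coordinate record at line ", bad + 2, call. = FALSE)
  }
  boxv <- scan(text = lines[na + 3], quiet = TRUE)[1:3] * 10
  atoms <- data.frame(name = name, element = .elementFromName(name),
                      resid = resid, resname = resname, chain = "A",
                      role = NA_character_, radius = NA_real_)
  atoms$role <- .classifyRoles(atoms)
  atoms$radius <- elementRadius(atoms$element)
  Trajectory(cbind(x, y, z), boxv, atoms)
}

#' Read a trajectory from disk
#'
#' Supports multi-model PDB (read via bio3d), the package's plain-text
#' frames format, and single-configuration GRO (nm coordinates converted
#' to Angstrom on ingestion). Role tags are assigned from a residue/atom
#' classification table on formats that do not carry them; unknown
#' residues are rejected by name.
#'
#' @param path input file.
#' @param format \code{"auto"} (by extension/signature), \code{"pdb"},
#'   \code{"frames"} or \code{"gro"}.
#' @return A \linkS4class{Trajectory}.
#' @export
readTrajectory <- function(path, format = c("auto", "pdb", "frames", "gro")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "pdb") "pdb"
    else if (ext == "gro") "gro"
    else if (startsWith(readLines(path, n = 1), "#tetramem-frames")) "frames"
    else stop("cannot determine format of ", path, call. = FALSE)
  }
  switch(format,
         pdb = .readPdbFile(path),
         frames = .readFramesFile(path),
         gro = .readGroFile(path))
}
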