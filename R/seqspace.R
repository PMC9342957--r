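#' @include trajectory-methods.R
NULL

# three-letter -> one-letter codes; unnatural residues fall back to X
.AA1 <- c(Arg = "R", Lys = "K", His = "H", Phe = "F", Tyr = "Y", Trp = "W",
          Dmt = "X")

#' Construct a tetrapeptide specification from residue codes
#'
#' @param codes character vector of 4 three-letter residue codes.
#' @param basicAlphabet,aromaticAlphabet residue codes recognised as basic
#'   and aromatic; the defaults cover Arg/Lys/His and Phe/Tyr/Trp plus the
#'   unnatural 2,6-dimethyltyrosine (Dmt, aromatic). User-supplied
#'   alphabets extend the residue set.
#' @param stereo per-residue stereochemistry, \code{"L"} or \code{"D"}
#'   (recycled; default all-L). Carried as metadata only.
#' @param amidated logical; C-terminal amide (default TRUE, the class-
#'   defining modification that keeps the net charge at +3).
#' @param name optional label.
#' @return A \linkS4class{PeptideSpec}.
#' @examples
#' peptideSpec(c("Arg", "Tyr", "Lys", "Phe"), name = "SPN4")
#' @export
peptideSpec <- function(codes,
                        basicAlphabet = c("Arg", "Lys", "His"),
                        aromaticAlphabet = c("Phe", "Tyr", "Trp", "Dmt"),
                        stereo = "L", amidated = TRUE, name = NA_character_) {
  cls <- ifelse(codes %in% basicAlphabet, "basic",
                ifelse(codes %in% aromaticAlphabet, "aromatic", NA))
  if (anyNA(cls))
    stop("unknown residue code(s): ",
         paste(codes[is.na(cls)], collapse = ", "), call. = FALSE)
  new("PeptideSpec",
      residues = data.frame(code = codes, class = cls,
                            stereo = rep_len(stereo, length(codes))),
      amidated = amidated, name = name)
}

setMethod("show", "PeptideSpec", function(object) {
  r <- object@residues
  cat(sprintf("PeptideSpec%s: %s (%s)%s\n",
              if (is.na(object@name)) "" else paste0(" ", object@name),
              paste(r$code, collapse = "-"),
              classifyRegister(object),
              if (object@amidated) ", C-terminal amide" else ""))
})

#' Enumerate the alternating cationic/aromatic tetrapeptide space
#'
#' All distinct tetrapeptides with strictly alternating basic (B) and
#' aromatic (phi) residues, over both registers B-phi-B-phi and
#' phi-B-phi-B. The count is |aromatic|^2 x |basic|^2 x |registers|; the
#' two-basic (Arg, Lys) by three-aromatic (Phe, Tyr, Trp) alphabet over
#' both registers gives 3^2 x 2^2 x 2 = 72 sequences. Enumeration is over
#' L-residues; stereochemistry and unnatural residues extend the space but
#' are carried as metadata only.
#'
#' @param basicAlphabet,aromaticAlphabet disjoint, non-empty residue code
#'   sets.
#' @param registers subset of \code{c("B-phi-B-phi", "phi-B-phi-B")}.
#' @param amidated C-terminal amidation flag applied to every sequence
#'   (default TRUE).
#' @return List of \linkS4class{PeptideSpec} objects, no duplicates.
#' @examples
#' length(enumerateSpace())  # 72
#' @export
enumerateSpace <- function(basicAlphabet = c("Arg", "Lys"),
                           aromaticAlphabet = c("Phe", "Tyr", "Trp"),
                           registers = c("B-phi-B-phi", "phi-B-phi-B"),
                           amidated = TRUE) {
  if (!length(basicAlphabet) || !length(aromaticAlphabet))
    stop("alphabets must be non-empty", call. = FALSE)
  if (length(intersect(basicAlphabet, aromaticAlphabet)))
    stop("basic and aromatic alphabets must be disjoint", call. = FALSE)
  registers <- match.arg(registers, c("B-phi-B-phi", "phi-B-phi-B"),
                         several.ok = TRUE)
  out <- list()
  for (reg in registers) {
    pattern <- if (reg == "B-phi-B-phi") c("B", "A", "B", "A")
    else c("A", "B", "A", "B")
    pools <- lapply(pattern, function(p)
      if (p == "B") basicAlphabet else aromaticAlphabet)
    combos <- expand.grid(pools, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(combos)))
      out[[length(out) + 1L]] <- peptideSpec(
        unlist(combos[i, ], use.names = FALSE),
        basicAlphabet = basicAlphabet, aromaticAlphabet = aromaticAlphabet,
        amidated = amidated)
  }
  out
}

#' Register of a tetrapeptide
#'
#' @param spec A \linkS4class{PeptideSpec} with strictly alternating
#'   classes (enforced by the class validity).
#' @return \code{"B-phi-B-phi"} if position 1 is basic, else
#'   \code{"phi-B-phi-B"}.
#' @examples
#' classifyRegister(peptideSpec(c("Phe", "Arg", "Phe", "Lys")))  # phi-B-phi-B
#' @export
classifyRegister <- function(spec) {
  validObject(spec)
  if (spec@residues$class[1] == "basic") "B-phi-B-phi" else "phi-B-phi-B"
}

#' Net charge of a tetrapeptide at physiological pH
#'
#' +1 per basic side chain, +1 for the free N-terminal amine, and -1 for a
#' free-acid C-terminus (0 when amidated). The test-set tetrapeptides (two
#' basic residues, C-terminal amide) therefore carry net +3.
#'
#' @param spec A \linkS4class{PeptideSpec}.
#' @return Integer net charge.
#' @examples
#' netCharge(peptideSpec(c("Arg", "Tyr", "Lys", "Phe")))  # +3
#' @export
netCharge <- function(spec) {
  validObject(spec)
  sum(spec@residues$class == "basic") + 1L -
    (if (spec@amidated) 0L else 1L)
}

#' Write enumerated peptides as FASTA
#'
#' One-letter sequences (unnatural residues as X) with a header convention
#' \code{>name|register|amide=yes/no}.
#'
#' @param specs list of \linkS4class{PeptideSpec}.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
writePeptideFasta <- function(specs, path) {
  seqs <- vapply(specs, function(s) {
    one <- .AA1[s@residues$code]
    one[is.na(one)] <- "X"
    paste(one, collapse = "")
  }, character(1))
  headers <- vapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    nm <- if (is.na(s@name)) sprintf("pep%03d", i) else s@name
    sprintf("%s|%s|amide=%s", nm, classifyRegister(s),
            if (s@amidated) "yes" else "no")
  }, character(1))
  x <- Biostrings::AAStringSet(seqs)
  names(x) <- headers
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}
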