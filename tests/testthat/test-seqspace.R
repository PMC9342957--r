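test_that("the two-basic by three-aromatic alphabet spans 72 distinct sequences", {
  space <- enumerateSpace()
  expect_length(space, 72)
  keys <- vapply(space, function(s)
    paste(s@residues$code, collapse = "-"), character(1))
  expect_equal(anyDuplicated(keys), 0)
})

test_that("enumeration count follows the closed-form product for any alphabets", {
  cases <- list(
    list(b = c("Arg", "Lys"), a = c("Phe", "Tyr"), reg = 2, n = 32),
    list(b = "Arg", a = "Phe", reg = 1, n = 1),
    list(b = c("Arg", "Lys", "His"), a = c("Phe", "Tyr", "Trp"), reg = 2,
         n = 3^2 * 3^2 * 2))
  for (cs in cases) {
    regs <- c("B-phi-B-phi", "phi-B-phi-B")[seq_len(cs$reg)]
    sp <- enumerateSpace(cs$b, cs$a, registers = regs)
    expect_length(sp, cs$n)
  }
  expect_error(enumerateSpace(c("Arg", "Phe"), c("Phe", "Tyr")), "disjoint")
})

test_that("register classification partitions the space into equal halves", {
  space <- enumerateSpace()
  regs <- vapply(space, classifyRegister, character(1))
  expect_equal(unname(table(regs)["B-phi-B-phi"]), 36L)
  expect_equal(unname(table(regs)["phi-B-phi-B"]), 36L)
  # the study sequences classify as reported
  expect_equal(classifyRegister(peptideSpec(c("Arg", "Tyr", "Lys", "Phe"))),
               "B-phi-B-phi")   # SPN4
  expect_equal(classifyRegister(peptideSpec(c("Phe", "Arg", "Phe", "Lys"))),
               "phi-B-phi-B")   # SS-20
  expect_equal(classifyRegister(peptideSpec(c("Trp", "Arg", "Trp", "Lys"))),
               "phi-B-phi-B")   # SPN10
  expect_error(peptideSpec(c("Arg", "Lys", "Tyr", "Phe")), "alternate")
})

test_that("net charge accounts for basic side chains, termini and amidation", {
  spn4 <- peptideSpec(c("Arg", "Tyr", "Lys", "Phe"))
  expect_equal(netCharge(spn4), 3L)
  expect_true(all(vapply(enumerateSpace(), netCharge, integer(1)) == 3L))
  free <- peptideSpec(c("Arg", "Tyr", "Lys", "Phe"), amidated = FALSE)
  expect_equal(netCharge(free), 2L)
  expect_error(peptideSpec(c("Gln", "Gln", "Gln", "Gln")), "unknown residue")
})

test_that("the unnatural aromatic Dmt is representable and FASTA export round-trips headers", {
  ss31 <- peptideSpec(c("Arg", "Dmt", "Lys", "Phe"), name = "SS-31",
                      stereo = c("D", "L", "L", "L"))
  expect_equal(classifyRegister(ss31), "B-phi-B-phi")
  expect_equal(netCharge(ss31), 3L)
  path <- tempfile(fileext = ".fasta")
  writePeptideFasta(list(ss31, peptideSpec(c("Phe", "Arg", "Phe", "Lys"),
                                           name = "SS-20")), path)
  fa <- Biostrings::readAAStringSet(path)
  expect_length(fa, 2)
  expect_match(names(fa)[1], "SS-31\\|B-phi-B-phi\\|amide=yes")
  expect_equal(as.character(fa[[2]]), "FRFK")
})
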