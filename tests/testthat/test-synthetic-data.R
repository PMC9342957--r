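test_that("zero-noise bilayer geometry is exact", {
  tru <- syntheticTruth(depthJitter = 0, phosphateJitter = 0,
                        areaJitter = 0, seed = 7)
  tr <- makeBilayerTrajectory(bilayerSpec(), 20, tru, nFrames = 3)
  expect_equal(bilayerThickness(tr)$series, rep(38, 3))
  expect_equal(areaPerLipid(tr, 75)$series, rep(81.8, 3))
  dp <- insertionDepth(tr)
  expect_equal(dp$perResidue$meanDepth, tru$depth)
  expect_equal(dp$perResidue$sd, rep(0, 4))
  expect_equal(dp$phosphatePlane, 19)
  expect_equal(dp$esterPlane, 15)
})

test_that("generators are pure functions of parameters and seed", {
  spec <- bilayerSpec()
  t1 <- makeBilayerTrajectory(spec, 4, syntheticTruth(seed = 9), 5)
  t2 <- makeBilayerTrajectory(spec, 4, syntheticTruth(seed = 9), 5)
  expect_identical(t1@coords, t2@coords)
  expect_identical(t1@box, t2@box)
  t3 <- makeBilayerTrajectory(spec, 4, syntheticTruth(seed = 10), 5)
  expect_false(identical(t1@coords, t3@coords))
  tru <- syntheticTruth(seed = 3)
  expect_identical(heats(makeItcIsotherm(tru, relativeNoise = 0.01)),
                   heats(makeItcIsotherm(tru, relativeNoise = 0.01)))
  expect_identical(makeTitrationTrace("surface-probe", tru)@intensity,
                   makeTitrationTrace("surface-probe", tru)@intensity)
})

test_that("bilayer builder rejects odd peptide counts and conserves atoms across frames", {
  tru <- syntheticTruth(seed = 1)
  expect_error(makeBilayerTrajectory(bilayerSpec(), 7, tru, 2), "even")
  tr <- makeBilayerTrajectory(bilayerSpec(), 6, tru, 4)
  expect_equal(dim(tr@coords)[1], nAtoms(tr))
  expect_equal(nrow(boxDims(tr)), 4)
  expect_true(all(atomData(tr)$role %in%
                    c("headgroup", "acyl", "peptide", "solvent")))
  # provenance carries the seed
  expect_equal(generatorTruth(tr)$seed, 1L)
})

test_that("depth jitter is recovered by the sample-mean estimator within 3 SE", {
  tru <- syntheticTruth(depth = rep(12, 4), depthJitter = 1, seed = 7)
  tr <- makeBilayerTrajectory(bilayerSpec(), 20, tru, nFrames = 500)
  dp <- insertionDepth(tr)
  se <- dp$perResidue$sd / sqrt(dp$perResidue$n)
  expect_true(all(abs(dp$perResidue$meanDepth - 12) <= 3 * se))
})

test_that("NOE series generator honors constant and designed-violation modes", {
  tru <- syntheticTruth(seed = 2)
  r <- NOERestraint(1, "HA", 3, "HN", 4.0)
  # constant design at the requested level, no jitter
  s <- makeNoeSeries(3, 10, list(r), tru,
                     design = list(list(mean = 4.0, chainJitter = 0)))
  expect_true(all(distances(s[[1]]) == 4.0))
  expect_length(makeNoeSeries(3, 10, list(), tru), 0)
  # designed 30% violated windows, counted by the compliance machinery
  s2 <- makeNoeSeries(20, 3000, list(r), tru,
                      design = list(list(violationFraction = 0.3)))
  fr <- complianceReport(s2)$table$violationFraction
  expect_lt(abs(fr - 0.3), 3 * sqrt(0.3 * 0.7 / 60))
})

test_that("synthetic isotherm matches the study protocol and carries truth", {
  tru <- syntheticTruth(seed = 4)
  e <- makeItcIsotherm(tru)
  expect_length(heats(e), 20)
  expect_equal(e@injectionVolumes, rep(2.5, 20))
  expect_equal(e@cellVolume, 170)
  expect_equal(generatorTruth(e)$n, 5)
  # noiseless heats saturate toward zero at high molar ratio
  q <- heats(e)
  expect_lt(abs(q[20]), abs(q[1]) / 10)
})

test_that("titration trace generator produces the designed baseline and events", {
  tru <- syntheticTruth(traceNoise = 0, seed = 6)
  trc <- makeTitrationTrace("surface-probe", tru)
  expect_equal(nrow(trc@events), 8)
  expect_equal(trc@events$dose, rep(10, 8))
  nt <- normalizeTrace(trc)
  expect_equal(mean(nt@intensity[nt@time >= 60 & nt@time <= 120]), 1)
  # zero response amplitude: flat normalized trace
  flat <- makeTitrationTrace("surface-probe",
                             syntheticTruth(foldChange = 1, traceNoise = 0,
                                            seed = 6))
  expect_equal(unique(normalizeTrace(flat)@intensity), 1)
  expect_error(makeTitrationTrace("unknown-kind", tru))
})
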