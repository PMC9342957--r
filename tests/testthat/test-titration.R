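test_that("baseline normalization is exact and idempotent", {
  t <- seq(0, 100, 0.5)
  trc <- TitrationTrace(t, ifelse(t < 50, 200, 500), baseline = c(10, 40))
  nt <- normalizeTrace(trc)
  expect_equal(unique(nt@intensity), c(1, 2.5))
  expect_equal(normalizeTrace(nt)@intensity, nt@intensity)
  # constant trace normalizes to all ones
  cst <- TitrationTrace(t, rep(7, length(t)), baseline = c(0, 100))
  expect_equal(unique(normalizeTrace(cst)@intensity), 1)
  neg <- TitrationTrace(t, rep(-1, length(t)), baseline = c(0, 100))
  expect_error(normalizeTrace(neg), "not positive")
})

test_that("saturation analysis recovers the designed half-saturation dose", {
  tru <- syntheticTruth(traceNoise = 0.002, seed = 11)
  trc <- normalizeTrace(makeTitrationTrace("surface-probe", tru))
  sat <- saturationFromTrace(trc)
  expect_true(sat$identifiable)
  expect_lt(abs(sat$halfSat - 20) / 20, 0.1)
  expect_true(all(diff(sat$dose) > 0))
  # scaling all doses doubles the fitted half-saturation dose
  ev2 <- trc@events
  ev2$dose <- ev2$dose * 2
  sat2 <- saturationFromTrace(trc, events = ev2)
  expect_equal(sat2$halfSat, 2 * sat$halfSat, tolerance = 1e-8)
})

test_that("flat traces are flagged unidentifiable, not fitted", {
  tru <- syntheticTruth(foldChange = 1, traceNoise = 0, seed = 2)
  trc <- normalizeTrace(makeTitrationTrace("surface-probe", tru))
  sat <- saturationFromTrace(trc)
  expect_false(sat$identifiable)
  expect_true(is.na(sat$halfSat))
  expect_error(saturationFromTrace(trc, events = trc@events[1, , drop = FALSE]),
               "at least 2")
})

test_that("plateau means are invariant to uniform intensity rescaling", {
  tru <- syntheticTruth(traceNoise = 0, seed = 4)
  trc <- makeTitrationTrace("surface-probe", tru)
  s1 <- saturationFromTrace(normalizeTrace(trc))
  trc@intensity <- trc@intensity * 37.5
  s2 <- saturationFromTrace(normalizeTrace(trc))
  expect_equal(s1$response, s2$response, tolerance = 1e-12)
})

test_that("excitation-ratio readout follows its arithmetic and recovers a monotone titration", {
  wl <- 380:580
  flat <- data.frame(wavelength = wl, intensity = rep(100, length(wl)))
  expect_equal(aneppsRatio(flat), 1)
  scan <- data.frame(wavelength = wl,
                     intensity = ifelse(abs(wl - 420) <= 2, 300,
                                        ifelse(abs(wl - 520) <= 2, 400, 10)))
  expect_equal(aneppsRatio(scan), 0.75)
  expect_error(aneppsRatio(data.frame(wavelength = 430:600,
                                      intensity = 1)), "420")
  sc <- makeExcitationScan(syntheticTruth(traceNoise = 0, seed = 5))
  rr <- vapply(sc$scans, aneppsRatio, numeric(1))
  expect_true(all(diff(rr) < 0))
})

test_that("fractional probe change reads quench depth from the normalized trace", {
  tru <- syntheticTruth(tmrmQuench = -0.35, traceNoise = 0.002, seed = 6)
  trc <- normalizeTrace(makeTitrationTrace("transmembrane", tru))
  expect_equal(tmrmFractionalChange(trc, c(100, 190)), -0.35,
               tolerance = 0.01)
  # no quench -> 0
  trc0 <- normalizeTrace(makeTitrationTrace(
    "transmembrane", syntheticTruth(tmrmQuench = 0, traceNoise = 0,
                                    seed = 6)))
  expect_equal(tmrmFractionalChange(trc0, c(100, 190)), 0)
  expect_error(tmrmFractionalChange(trc, c(500, 600)), "no samples")
})

test_that("hydration radius conversion is a homogeneous reference ratio", {
  expect_equal(hydrationRadius(1, 1), 3.34)
  expect_equal(hydrationRadius(2, 1), 6.68)
  # the printed peptide radius corresponds to a diffusion ratio of ~1.587
  expect_equal(hydrationRadius(5.3 / 3.34, 1), 5.3, tolerance = 1e-12)
  # homogeneity: degree 1 in the reference radius, degree -1 in D_analyte
  expect_equal(hydrationRadius(1.3, 0.9, rhRef = 2 * 3.34),
               2 * hydrationRadius(1.3, 0.9))
  expect_equal(hydrationRadius(1.3, 2 * 0.9),
               hydrationRadius(1.3, 0.9) / 2)
})
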