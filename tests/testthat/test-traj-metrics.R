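test_that("insertion depth folds leaflets and handles the COM reference", {
  # one lipid-ish pair of phosphate planes plus peptide atoms at known z
  atoms <- data.frame(
    name = c("P", "P", "CB", "CB"),
    element = c("P", "P", "C", "C"),
    resid = c(1, 2, 1, 1), resname = c("POPC", "POPC", "RES", "RES"),
    chain = c("L", "L", "p01", "p02"),
    role = c("headgroup", "headgroup", "peptide", "peptide"),
    radius = 1.8)
  xyz <- rbind(c(0, 0, 19), c(0, 0, -19),   # COM at z = 0
               c(5, 5, 0),                  # at the COM -> depth 0
               c(8, 2, -15))                # lower leaflet -> folded to 15
  tr <- Trajectory(xyz, c(50, 50, 80), atoms)
  dp <- insertionDepth(tr)
  expect_equal(dp$perChain["1", "p01"], 0)
  expect_equal(dp$perChain["1", "p02"], 15)
  expect_error(insertionDepth(tr, "*/*/CZ"), "matches no atoms")
})

test_that("thickness is exact on frozen planes and invariant to rigid z-translation", {
  tru <- syntheticTruth(depthJitter = 0, phosphateJitter = 0,
                        areaJitter = 0, seed = 1)
  tr <- makeBilayerTrajectory(bilayerSpec(), 4, tru, nFrames = 3)
  expect_equal(bilayerThickness(tr)$series, rep(38, 3))
  shifted <- tr
  shifted@coords[, 3, ] <- shifted@coords[, 3, ] + 7.3
  expect_equal(bilayerThickness(shifted)$series,
               bilayerThickness(tr)$series)
  # depths are also translation invariant (COM moves with the system)
  expect_equal(insertionDepth(shifted)$perResidue$meanDepth,
               insertionDepth(tr)$perResidue$meanDepth)
})

test_that("noisy thickness and area fixtures recover generator truth", {
  tru <- syntheticTruth(phosphateJitter = 0.5, seed = 13)
  spec <- bilayerSpec(leafletZOffset = 19.5)  # 39 A truth
  tr <- makeBilayerTrajectory(spec, 20, tru, nFrames = 300)
  th <- bilayerThickness(tr)
  expect_lt(abs(th$mean - 39), 3 * max(th$se, 1e-3))
  ap <- areaPerLipid(tr, 75)
  expect_lt(abs(ap$mean - 81.8), max(ap$sd, 3 * ap$se))
})

test_that("area per lipid follows the box arithmetic and scaling law", {
  atoms <- data.frame(name = "P", element = "P", resid = 1,
                      resname = "POPC", chain = "L", role = "headgroup",
                      radius = 1.8)
  tr <- Trajectory(matrix(0, 1, 3), c(78, 78, 90), atoms)
  expect_equal(areaPerLipid(tr, 75)$series, 78 * 78 / 75)
  expect_equal(78^2 / 75, 81.12)
  tr2 <- Trajectory(matrix(0, 1, 3), c(156, 156, 90), atoms)
  expect_equal(areaPerLipid(tr2, 75)$series,
               4 * areaPerLipid(tr, 75)$series)
  expect_error(areaPerLipid(tr, 0))
})

test_that("ensemble statistics: identical copies, rigid motions, closed-form Rg", {
  set.seed(5)
  p <- matrix(rnorm(30), 10, 3)
  es <- ensembleStats(list(p, p, p), atomScope = "all")
  expect_equal(es$rmsd, rep(0, 3), tolerance = 1e-10)
  # rigidly moved copy superposes to zero RMSD
  R <- randomRotation()
  es2 <- ensembleStats(list(p, p %*% R + 3), atomScope = "all")
  expect_equal(es2$rmsd, rep(0, 2), tolerance = 1e-8)
  # two unit-mass points 2 A apart
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  es3 <- ensembleStats(list(two, two), atomScope = "all")
  expect_equal(es3$rg, c(1, 1))
  expect_error(ensembleStats(list(p, p[1:5, ]), atomScope = "all"),
               "conformer 2")
})

test_that("superposed RMSD agrees with an established structural-biology fitter", {
  set.seed(8)
  for (k in 1:5) {
    a <- matrix(rnorm(24), 8, 3)
    b <- a + matrix(rnorm(24, 0, 0.5), 8, 3)
    mine <- tetramem:::superposedRmsd(a, b)
    ref <- bio3d::rmsd(as.vector(t(a)), as.vector(t(b)), fit = TRUE)
    expect_equal(mine, ref, tolerance = 1e-3)
  }
})

test_that("fraction below RMSD threshold counts conformer states and is monotone", {
  ref <- matrix(rnorm(24, sd = 3), 8, 3)
  near <- ref + 0.1                     # rigid shift: RMSD ~ 0
  far <- ref %*% diag(c(3, 1, 1))       # internal stretch: RMSD >> 3
  frames <- rep(list(near, far), 5)
  tr <- peptideTraj(frames)
  fb <- fractionBelowRmsd(tr, ref)
  expect_equal(fb$mean, 0.5)
  # frozen copies of the reference give fraction 1
  tr1 <- peptideTraj(rep(list(ref), 4))
  expect_equal(fractionBelowRmsd(tr1, ref)$mean, 1)
  # monotone non-decreasing in threshold
  fr <- vapply(c(0.5, 1, 3, 10, 100),
               function(th) fractionBelowRmsd(tr, ref, threshold = th)$mean,
               numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_error(fractionBelowRmsd(tr, ref[1:5, ]), "does not map")
})
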