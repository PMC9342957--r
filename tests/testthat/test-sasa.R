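test_that("single isolated sphere matches the closed form exactly", {
  at <- data.frame(name = "S", element = "C", resid = 1, resname = "RES",
                   chain = "p01", role = "peptide", radius = 1.9)
  tr <- Trajectory(matrix(0, 1, 3), c(100, 100, 100), at)
  s <- sasa(tr, probeRadius = 1.4, nDots = 500)
  # all dots exposed -> the sum is exactly 4*pi*(r+probe)^2
  expect_equal(s$perFrame$total, 4 * pi * 3.3^2)
  expect_equal(s$perFrame$peptide, s$perFrame$total)
})

test_that("a fully enclosed atom contributes zero area", {
  shell <- tetramem:::sphereDots(40) * 3.0
  xyz <- rbind(c(0, 0, 0), shell)
  a <- tetramem:::.shrakeRupley(xyz, rep(1.9, 41), 1.4, 300)
  expect_equal(a[1], 0)
})

test_that("random clusters agree with the grid-quadrature oracle within 2 percent", {
  set.seed(21)
  for (k in 1:20) {
    n <- sample(3:10, 1)
    xyz <- matrix(rnorm(n * 3, sd = 2.2), n, 3)
    radius <- runif(n, 1.2, 2.0)
    mine <- sum(tetramem:::.shrakeRupley(xyz, radius, 1.4, nDots = 960))
    oracle <- gridSasaOracle(xyz, radius, 1.4)
    expect_lt(abs(mine - oracle) / oracle, 0.02)
  }
})

test_that("well-separated groups are additive and contact never increases total area", {
  set.seed(9)
  g1 <- matrix(rnorm(15, sd = 1.5), 5, 3)
  g2 <- matrix(rnorm(15, sd = 1.5), 5, 3)
  r <- rep(1.7, 5)
  sep <- sum(tetramem:::.shrakeRupley(rbind(g1, g2 + 100), rep(1.7, 10),
                                      1.4, 960))
  apart <- sum(tetramem:::.shrakeRupley(g1, r, 1.4, 960)) +
    sum(tetramem:::.shrakeRupley(g2, r, 1.4, 960))
  expect_equal(sep, apart, tolerance = 1e-9)
  for (d in c(6, 3, 1)) {
    close <- sum(tetramem:::.shrakeRupley(rbind(g1, g2 + d), rep(1.7, 10),
                                          1.4, 960))
    expect_lte(close, apart + 1e-9)
  }
})

test_that("component report partitions by role and excludes solvent", {
  at <- data.frame(
    name = c("P", "C2T", "CB", "OW"),
    element = c("P", "C", "C", "O"),
    resid = 1:4, resname = c("POPC", "POPC", "RES", "HOH"),
    chain = c("L", "L", "p01", "W"),
    role = c("headgroup", "acyl", "peptide", "solvent"),
    radius = c(1.8, 1.7, 1.7, 1.52))
  xyz <- rbind(c(0, 0, 0), c(40, 0, 0), c(0, 40, 0), c(0, 0, 1))
  tr <- Trajectory(xyz, c(100, 100, 100), at)
  s <- sasa(tr, nDots = 400)
  # solvent neither contributes nor occludes: headgroup sphere is full
  expect_equal(s$perFrame$headgroup, 4 * pi * 3.2^2)
  expect_equal(s$perFrame$total,
               s$perFrame$headgroup + s$perFrame$acyl + s$perFrame$peptide)
  at$radius[1] <- NA
  tr2 <- Trajectory(xyz, c(100, 100, 100), at)
  expect_error(sasa(tr2), "radius")
})
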