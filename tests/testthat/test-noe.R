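test_that("ensemble averaging reduces to identity on constant input and is r^-6 weighted", {
  expect_equal(ensembleAvgDistance(matrix(4, 20, 10)), rep(4, 10))
  # split ensemble: biased toward the short distance
  m <- rbind(matrix(3, 10, 4), matrix(6, 10, 4))
  expect_equal(ensembleAvgDistance(m),
               rep(((3^-6 + 6^-6) / 2)^(-1 / 6), 4))
  # single chain passes through
  expect_equal(ensembleAvgDistance(matrix(c(3.2, 4.1), 1)), c(3.2, 4.1))
})

test_that("ensemble average is bounded by chain extremes and monotone in each distance", {
  set.seed(42)
  for (rep in 1:20) {
    m <- matrix(runif(20 * 15, 2, 8), 20, 15)
    r <- ensembleAvgDistance(m)
    expect_true(all(r >= apply(m, 2, min) - 1e-12))
    expect_true(all(r <= apply(m, 2, max) + 1e-12))
    m2 <- m
    m2[3, 5] <- m2[3, 5] + 1
    expect_gte(ensembleAvgDistance(m2)[5], r[5])
  }
})

test_that("time averaging matches the closed form and degenerates correctly", {
  expect_equal(timeAvgDistance(rep(4.5, 50)), rep(4.5, 50))
  # alternating series, window covering equal counts of each level
  r <- rep(c(3, 6), 10)
  expect_equal(timeAvgDistance(r, tau = 1, dt = 1)[1],
               ((3^-3 + 6^-3) / 2)^(-1 / 3))
  expect_equal(((3^-3 + 6^-3) / 2)^(-1 / 3), 48^(1 / 3))
  # tau == dt is the smallest admissible window (two samples, t and t+1)
  expect_equal(timeAvgDistance(c(3, 5, 4), tau = 2, dt = 2),
               bruteTimeAvg(c(3, 5, 4), 2, 2))
  expect_error(timeAvgDistance(1:5, tau = 2.5, dt = 1), "multiple")
  expect_error(timeAvgDistance(1:5, tau = 0.5, dt = 1), ">= dt")
})

test_that("ensemble and time averaging agree with brute-force arithmetic", {
  set.seed(7)
  for (k in 1:25) {
    m <- matrix(runif(20 * 200, 2, 9), 20, 200)
    r <- ensembleAvgDistance(m)
    expect_equal(r, bruteEnsembleAvg(m), tolerance = 1e-12)
    expect_equal(timeAvgDistance(r, 10, 1), bruteTimeAvg(r, 10, 1),
                 tolerance = 1e-12)
  }
})

test_that("composing the two averages on time-constant input equals the ensemble average alone", {
  set.seed(3)
  chains <- runif(20, 2, 8)
  m <- matrix(chains, 20, 100)
  r <- ensembleAvgDistance(m)
  expect_equal(timeAvgDistance(r, 10, 1), r)
})

test_that("violation scoring honors the buffer tolerance rule", {
  r <- NOERestraint(1, "HA", 3, "HN", 4.0)
  expect_equal(violationFraction(rep(4.25, 10), r), 0)   # inside buffer
  expect_equal(violationFraction(rep(4.35, 10), r), 1)   # beyond buffer
  expect_equal(violationFraction(c(3, 3.9, 4.2), r), 0)
  expect_error(violationFraction(numeric(0), r), "empty")
  # monotone in tolerance
  avg <- runif(200, 3.5, 5)
  f <- vapply(seq(0, 1, 0.1), function(tol) violationFraction(avg, r, tol),
              numeric(1))
  expect_true(all(diff(f) <= 0))
  expect_equal(violationFraction(avg, r, tolerance = 1e9), 0)
})

test_that("medium-range filtering keeps only i+2 and i+3 restraints in order", {
  rs <- list(NOERestraint(1, "HA", 2, "HN", 4),
             NOERestraint(1, "HA", 3, "HN", 4),
             NOERestraint(1, "HA", 4, "HN", 4),
             NOERestraint(2, "HA", 3, "HN", 4))
  kept <- filterLongRange(rs)
  expect_length(kept, 2)
  expect_equal(vapply(kept, function(r) r@resJ, integer(1)), c(3L, 4L))
  expect_length(filterLongRange(list()), 0)
  expect_length(filterLongRange(rs[c(1, 4)]), 0)
})

test_that("compliance report recovers designed violation behavior", {
  tru <- syntheticTruth(seed = 5)
  rs <- list(NOERestraint(1, "HA", 3, "HN", 4.0),
             NOERestraint(1, "HB", 4, "HN", 5.0),
             NOERestraint(2, "HA", 4, "HN", 4.5))
  des <- list(list(violationFraction = 0),
              list(violationFraction = 0.3),
              list(violationFraction = 1))
  series <- makeNoeSeries(20, 2000, rs, tru, design = des)
  rep <- complianceReport(series)
  fr <- rep$table$violationFraction
  expect_equal(fr[1], 0)
  expect_equal(fr[3], 1)
  # binomial error over ~40 independent blocks
  expect_lt(abs(fr[2] - 0.3), 3 * sqrt(0.3 * 0.7 / 40))
  expect_error(
    complianceReport(list(series[[1]],
                          DistanceSeries(rs[[1]], matrix(4, 2, 5), dt = 2))),
    "frame spacing")
})

test_that("twenty-chain ensembles are accepted and the summary share is exact on a deterministic fixture", {
  tru <- syntheticTruth(seed = 11)
  rs <- lapply(1:10, function(i) NOERestraint(1, "HA", 3, "HN", 4.0))
  des <- lapply(1:10, function(i)
    list(violationFraction = as.numeric(i > 7)))
  expect_no_warning(series <- makeNoeSeries(20, 300, rs, tru, design = des))
  expect_equal(nrow(distances(series[[1]])), 20)
  expect_equal(complianceReport(series)$shareBelowThreshold, 0.7)
})
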