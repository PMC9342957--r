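test_that("uniform points give g(r) ~ 1 in the ideal-gas limit", {
  set.seed(1)
  n <- 400
  tr <- pointTraj(cbind(runif(n, 0, 50), runif(n, 0, 50)))
  g <- lateralRdf(tr, "*/*/*", "*/*/*", breaks = seq(2, 20, 1))
  expect_true(all(abs(g$g - 1) < 0.12))
  expect_lt(abs(mean(g$g) - 1), 0.02)
})

test_that("a square lattice excludes pairs below the spacing", {
  d <- 5
  xy <- as.matrix(expand.grid(x = d * 0:7, y = d * 0:7)) + d / 2
  tr <- pointTraj(xy, box = c(40, 40, 40))
  g <- lateralRdf(tr, "*/*/*", "*/*/*", breaks = seq(0.5, 4.5, 0.5))
  expect_true(all(g$g == 0))
  expect_true(all(g$counts == 0))
})

test_that("a 6-point configuration matches a hand-enumerated pair histogram", {
  xy <- rbind(c(1, 1), c(4, 1), c(1, 5), c(9, 9), c(9.5, 9), c(19, 19))
  tr <- pointTraj(xy, box = c(20, 20, 20))
  breaks <- seq(0, 10, 1)
  g <- lateralRdf(tr, "*/*/*", "*/*/*", breaks = breaks)
  # brute-force double loop with minimum image in x and y
  cnt <- numeric(length(breaks) - 1)
  for (i in 1:6) for (j in 1:6) {
    if (i == j) next
    dx <- xy[i, 1] - xy[j, 1]; dx <- dx - 20 * round(dx / 20)
    dy <- xy[i, 2] - xy[j, 2]; dy <- dy - 20 * round(dy / 20)
    r <- sqrt(dx^2 + dy^2)
    b <- findInterval(r, breaks, left.open = TRUE)
    if (b >= 1 && b <= length(cnt) && r < max(breaks)) cnt[b] <- cnt[b] + 1
  }
  expect_equal(g$counts, cnt)
})

test_that("bin counts integrate to the total pair count over the covering range", {
  set.seed(3)
  n <- 60
  tr <- pointTraj(cbind(runif(n, 0, 30), runif(n, 0, 30)),
                  box = c(30, 30, 30))
  # minimum-image lateral distances cannot exceed sqrt(2)*L/2
  breaks <- seq(0, 30 * sqrt(2) / 2 + 1, 0.5)
  g <- lateralRdf(tr, "*/*/*", "*/*/*", breaks = breaks)
  expect_equal(sum(g$counts), n * (n - 1))
})

test_that("bad bin edges and empty selections are rejected", {
  tr <- pointTraj(cbind(1:4, 1:4))
  expect_error(lateralRdf(tr, "*/*/*", "*/*/*", breaks = c(1, 1, 2)),
               "strictly increasing")
  expect_error(lateralRdf(tr, "*/*/NOPE", "*/*/*"), "matches no atoms")
})
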