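# Shared fixtures and independent oracles, built in code at test time.

# minimal single-chain peptide trajectory from a list of per-frame
# coordinate matrices (n x 3)
peptideTraj <- function(frames, box = c(100, 100, 100),
                        chain = "p01") {
  n <- nrow(frames[[1]])
  atoms <- data.frame(name = rep(c("CA", "CB"), length.out = n),
                      element = "C", resid = rep(seq_len(ceiling(n / 2)),
                                                 each = 2)[seq_len(n)],
                      resname = "RES", chain = chain, role = "peptide",
                      radius = 1.7)
  coords <- array(NA_real_, c(n, 3, length(frames)))
  for (f in seq_along(frames)) coords[, , f] <- frames[[f]]
  Trajectory(coords, matrix(box, length(frames), 3, byrow = TRUE), atoms)
}

# flat point set wrapped as a one-frame headgroup-only trajectory
pointTraj <- function(xy, box = c(50, 50, 50), z = 0) {
  n <- nrow(xy)
  atoms <- data.frame(name = paste0("U", seq_len(n)), element = "C",
                      resid = seq_len(n), resname = "POPC", chain = "L",
                      role = "headgroup", radius = 1.7)
  Trajectory(cbind(xy, z), box, atoms)
}

# Independent brute-force evaluation of the r^-6 ensemble average,
# written as plain loops so it shares nothing with the implementation.
bruteEnsembleAvg <- function(m) {
  out <- numeric(ncol(m))
  for (t in seq_len(ncol(m))) {
    s <- 0
    for (i in seq_len(nrow(m))) s <- s + m[i, t]^(-6)
    out[t] <- (s / nrow(m))^(-1 / 6)
  }
  out
}

# Independent brute-force r^-3 forward-window time average.
bruteTimeAvg <- function(r, tau, dt) {
  w <- as.integer(round(tau / dt))
  n <- length(r)
  out <- numeric(n)
  for (t in seq_len(n)) {
    hi <- min(t + w, n)
    s <- 0
    for (j in t:hi) s <- s + r[j]^(-3)
    out[t] <- (s / (hi - t + 1))^(-1 / 3)
  }
  out
}

# Independent SASA oracle: latitude-longitude quadrature of each expanded
# sphere, counting quadrature area where the surface point lies outside
# every other expanded sphere. Different point set and weighting scheme
# from the golden-spiral Shrake-Rupley implementation.
gridSasaOracle <- function(xyz, radius, probe = 1.4, nTheta = 90,
                           nPhi = 180) {
  rexp <- radius + probe
  theta <- (seq_len(nTheta) - 0.5) * pi / nTheta
  phi <- (seq_len(nPhi) - 0.5) * 2 * pi / nPhi
  grid <- expand.grid(theta = theta, phi = phi)
  dirs <- cbind(sin(grid$theta) * cos(grid$phi),
                sin(grid$theta) * sin(grid$phi),
                cos(grid$theta))
  wBase <- sin(grid$theta) * (pi / nTheta) * (2 * pi / nPhi)
  total <- 0
  for (i in seq_len(nrow(xyz))) {
    pts <- sweep(dirs * rexp[i], 2, xyz[i, ], `+`)
    outside <- rep(TRUE, nrow(pts))
    for (j in seq_len(nrow(xyz))) {
      if (j == i) next
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      outside <- outside & d2 >= rexp[j]^2
    }
    total <- total + rexp[i]^2 * sum(wBase[outside])
  }
  total
}

# random rigid rotation matrix (det +1)
randomRotation <- function() {
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
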