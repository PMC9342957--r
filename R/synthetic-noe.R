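#' @include trajectory-methods.R
NULL

#' Generate per-restraint ensemble distance series with designed violations
#'
#' For each restraint, builds a chains x frames matrix of distances whose
#' time- and ensemble-averaged value violates the upper bound (plus the 0.3
#' Angstrom buffer) in a designed fraction of time windows. The ensemble
#' dimension carries small inter-chain Gaussian jitter; the time dimension
#' switches between a satisfied level and a violating level.
#'
#' Violation designs per restraint:
#' \itemize{
#'   \item fraction 0 or 1: the series is held at a constant level one full
#'     Angstrom below (or 0.7 above) the violation threshold, so the
#'     recovered fraction is exactly 0 or 1 -- a deterministic fixture.
#'   \item fraction in (0, 1): frames are grouped into contiguous blocks of
#'     \code{blockLength} frames, each independently violating with the
#'     designed probability, so the recovered window fraction matches the
#'     design within binomial error.
#' }
#'
#' @param nChains ensemble size (>= 1); the study used 20 chains.
#' @param nFrames frames per chain.
#' @param restraints list of \linkS4class{NOERestraint}; an empty list
#'   yields an empty result.
#' @param truth a \code{\link{syntheticTruth}} (supplies the seed).
#' @param design optional list, one element per restraint, each a list with
#'   any of \code{violationFraction} (default 0), \code{mean} (satisfied
#'   level, default upper - 1), \code{blockLength} (default 50 frames) and
#'   \code{chainJitter} (default 0.05 Angstrom).
#' @param dt frame spacing, ps (default 1).
#' @param tolerance violation buffer the design is laid out against
#'   (default 0.3 Angstrom).
#' @return List of \linkS4class{DistanceSeries}, one per restraint, each
#'   carrying its design in \code{generatorTruth()}.
#' @export
makeNoeSeries <- function(nChains, nFrames, restraints, truth,
                          design = NULL, dt = 1, tolerance = 0.3) {
  stopifnot(nChains >= 1, nFrames >= 1)
  if (!length(restraints)) return(list())
  withSeed(subSeed(truth$seed, 2L), {
    lapply(seq_along(restraints), function(k) {
      r <- restraints[[k]]
      d <- if (!is.null(design) && length(design) >= k) design[[k]] else list()
      f <- d$violationFraction %||% 0
      lo <- d$mean %||% (r@upper - 1)
      hi <- r@upper + tolerance + 0.7
      blockLength <- d$blockLength %||% 50L
      jitter <- d$chainJitter %||% 0.05
      level <- if (f <= 0) rep(lo, nFrames)
      else if (f >= 1) rep(hi, nFrames)
      else {
        nb <- ceiling(nFrames / blockLength)
        states <- stats::rbinom(nb, 1L, f)
        rep(ifelse(states == 1L, hi, lo), each = blockLength)[seq_len(nFrames)]
      }
      m <- matrix(rep(level, each = nChains), nrow = nChains)
      if (jitter > 0 && nChains > 1)
        m <- m + matrix(stats::rnorm(nChains * nFrames, 0, jitter),
                        nrow = nChains)
      m[m <= 0.1] <- 0.1
      DistanceSeries(r, m, dt = dt,
                     provenance = list(seed = truth$seed,
                                       violationFraction = f,
                                       mean = lo, blockLength = blockLength,
                                       chainJitter = jitter,
                                       tolerance = tolerance))
    })
  })
}
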