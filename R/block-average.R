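#' @include trajectory-methods.R
NULL

#' Block-averaged standard error of a correlated time series
#'
#' Groups the series into non-overlapping blocks of increasing size and
#' computes the standard error of the mean from the block means,
#' \code{sd(blockMeans)/sqrt(nBlocks)}. For correlated data the estimate
#' grows with block size until blocks decorrelate, then plateaus; the chosen
#' block size is the smallest at which the relative change to the next size
#' falls below \code{tol} (default 5\%).
#'
#' @param series numeric time series; must be at least twice the largest
#'   block.
#' @param blockSizes increasing integer block sizes; by default a
#'   near-geometric ladder from 1 to length(series)/4.
#' @param tol relative-change plateau tolerance (default 0.05).
#' @return A list of class \code{"BlockAverage"}: \code{mean}, \code{se}
#'   (at the chosen block size), \code{sd} (of block means at the chosen
#'   size), \code{blockSize}, and the full \code{blockSizes}/\code{seCurve}
#'   profile.
#' @examples
#' x <- rnorm(4000)
#' blockAverage(x)$se  # ~ 1/sqrt(4000)
#' @export
blockAverage <- function(series, blockSizes = NULL, tol = 0.05) {
  n <- length(series)
  if (is.null(blockSizes)) {
    blockSizes <- unique(round(exp(seq(0, log(max(1, n / 4)),
                                       length.out = 12))))
  }
  blockSizes <- sort(unique(as.integer(blockSizes)))
  if (n < 2 * max(blockSizes))
    stop("series too short: need length >= 2 x the largest block (",
         2 * max(blockSizes), ")", call. = FALSE)
  prof <- vapply(blockSizes, function(b) {
    nb <- n %/% b
    bm <- colMeans(matrix(series[seq_len(nb * b)], nrow = b))
    c(se = stats::sd(bm) / sqrt(nb), sd = stats::sd(bm))
  }, numeric(2))
  se <- prof["se", ]
  chosen <- length(blockSizes)
  for (i in seq_len(length(blockSizes) - 1)) {
    if (se[i] == 0 || abs(se[i + 1] - se[i]) / max(se[i], .Machine$double.eps)
        < tol) { chosen <- i; break }
  }
  structure(list(mean = mean(series), se = se[chosen],
                 sd = prof["sd", chosen], blockSize = blockSizes[chosen],
                 blockSizes = blockSizes, seCurve = unname(se), tol = tol),
            class = "BlockAverage")
}

#' @export
print.BlockAverage <- function(x, ...) {
  cat(sprintf("Block average: mean %.4g +/- %.3g (SE), block size %d\n",
              x$mean, x$se, x$blockSize))
  invisible(x)
}
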