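#' Effective sample size of an autocorrelated series
#'
#' Estimates the integrated autocorrelation time with Geyer's
#' initial-positive-sequence rule on the empirical autocorrelation function
#' (consecutive lag pairs are summed and the sum truncated at the first
#' non-positive pair), and returns n divided by that time. A constant series
#' has no autocorrelation information; its ESS is reported as n with a
#' warning.
#'
#' @param series numeric vector, length >= 10.
#' @return effective sample size, capped at \code{length(series)}.
#' @examples
#' ess(rnorm(1000))  # close to 1000
#' @export
ess <- function(series) {
  n <- length(series)
  if (n < 10L) stop("need at least 10 samples")
  if (stats::var(series) == 0) {
    warning("degenerate series: all values identical")
    return(n)
  }
  maxLag <- min(n - 1L, 2000L)
  rho <- stats::acf(series, lag.max = maxLag, plot = FALSE,
                    demean = TRUE)$acf[-1L]
  nPair <- floor(length(rho) / 2)
  tau <- 1
  if (nPair >= 1L) {
    pair <- rho[seq(1L, by = 2L, length.out = nPair)] +
      rho[seq(2L, by = 2L, length.out = nPair)]
    m <- which(pair <= 0)
    keep <- if (length(m)) m[1L] - 1L else nPair
    if (keep > 0L) {
      # initial monotone sequence: enforce nonincreasing pair sums to damp
      # accumulation of autocorrelation noise at long lags
      tau <- 1 + 2 * sum(cummin(pair[seq_len(keep)]))
    } else if (rho[1L] > 0) {
      tau <- 1 + 2 * rho[1L]  # first unpaired lag
    }
  }
  min(n, n / max(tau, 1e-12))
}

#' Highest posterior density interval
#'
#' The shortest interval containing \code{ceiling(level * n)} of the sorted
#' samples.
#'
#' @param series numeric samples.
#' @param level coverage level in (0, 1).
#' @return numeric c(low, high).
#' @examples
#' hpdInterval(rnorm(1e4))  # roughly (-1.96, 1.96)
#' @export
hpdInterval <- function(series, level = 0.95) {
  if (level <= 0 || level >= 1) stop("domain error: level must be in (0, 1)")
  n <- length(series)
  s <- sort(series)
  m <- ceiling(level * n)
  if (m >= n) return(c(s[1L], s[n]))
  width <- s[seq(m, n)] - s[seq(1L, n - m + 1L)]
  i <- which.min(width)
  c(s[i], s[i + m - 1L])
}

#' Summarise an MCMC trace
#'
#' Per-column mean, 95% HPD bounds and ESS, after discarding burn-in.
#'
#' @param trace an \code{\linkS4class{MCMCTrace}}.
#' @param level HPD level.
#' @return data.frame with one row per sampled quantity.
#' @export
traceSummary <- function(trace, level = 0.95) {
  stopifnot(is(trace, "MCMCTrace"))
  s <- traceSamples(trace, dropBurnin = TRUE)
  cols <- setdiff(names(s), "iteration")
  out <- lapply(cols, function(cn) {
    x <- s[[cn]]
    h <- hpdInterval(x, level)
    e <- suppressWarnings(ess(x))
    data.frame(parameter = cn, mean = mean(x), hpdLow = h[1L],
               hpdHigh = h[2L], ess = e)
  })
  do.call(rbind, out)
}
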