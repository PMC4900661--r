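# Chain-quality diagnostics and posterior summarization.
#
# Conventions: Geweke windows default to the first 10% vs the last 50% of
# the chain, with the window spectral density at frequency zero estimated
# by an autoregressive fit; ESS uses the integrated autocorrelation time
# truncated by Geyer's initial-positive-sequence rule; the HPD interval is
# the shortest contiguous window of sorted draws (unimodal posteriors
# assumed, as for variance components).

check_chain <- function(chain, min_n = 20L) {
  chain <- as.numeric(chain)
  if (anyNA(chain)) stop("chain contains missing values", call. = FALSE)
  if (length(chain) < min_n)
    stop(sprintf("chain too short (need at least %d draws)", min_n), call. = FALSE)
  chain
}

# spectral density at frequency zero via an AR fit (AIC order selection);
# a zero-variance window is the caller's error to raise
spectrum0_ar <- function(x) {
  v <- stats::var(x)
  if (v == 0) return(0)
  ord_max <- min(length(x) - 1L, floor(10 * log10(length(x))))
  fit <- try(stats::ar(x, aic = TRUE, order.max = ord_max), silent = TRUE)
  if (inherits(fit, "try-error")) return(v)
  if (fit$order == 0L) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke convergence statistic
#'
#' Compares the mean of an early window of the chain with the mean of a
#' late window, standardized by the windows' spectral variances at
#' frequency zero: a stationary chain gives an asymptotically standard
#' normal Z.
#'
#' @param chain Numeric vector of MCMC draws (length >= 20).
#' @param frac_first Fraction of the chain in the early window (default 0.1).
#' @param frac_last Fraction in the late window (default 0.5); the windows
#'   must not overlap.
#' @return The Z statistic (sign positive when the early mean exceeds the
#'   late mean).
#' @examples
#' set.seed(1)
#' geweke_z(rnorm(2000))
#' @export
geweke_z <- function(chain, frac_first = 0.1, frac_last = 0.5) {
  chain <- check_chain(chain)
  if (!(frac_first > 0 && frac_first < 1 && frac_last > 0 && frac_last < 1))
    stop("window fractions must lie in (0, 1)", call. = FALSE)
  if (frac_first + frac_last > 1)
    stop("Geweke windows overlap: frac_first + frac_last must be <= 1", call. = FALSE)
  n <- length(chain)
  if (stats::var(chain) == 0)
    stop("chain has zero variance; Geweke statistic undefined", call. = FALSE)
  n1 <- max(2L, floor(frac_first * n))
  n2 <- max(2L, floor(frac_last * n))
  x1 <- chain[seq_len(n1)]
  x2 <- chain[seq.int(n - n2 + 1L, n)]
  s1 <- spectrum0_ar(x1)
  s2 <- spectrum0_ar(x2)
  denom <- s1 / n1 + s2 / n2
  if (denom == 0)
    stop("both Geweke windows have zero variance", call. = FALSE)
  (mean(x1) - mean(x2)) / sqrt(denom)
}

#' Effective sample size
#'
#' Chain length divided by the integrated autocorrelation time
#' `tau = 1 + 2 * sum(rho_k)`, with the autocorrelation sum truncated by
#' the initial-positive-sequence rule: successive pair sums
#' `rho_(2m) + rho_(2m+1)` are accumulated while they stay positive.
#' The estimate is capped at the chain length.
#'
#' @param chain Numeric vector of MCMC draws (length >= 20).
#' @return Estimated number of effectively independent draws.
#' @examples
#' set.seed(1)
#' effective_sample_size(rnorm(2000))
#' @export
effective_sample_size <- function(chain) {
  chain <- check_chain(chain)
  n <- length(chain)
  if (stats::var(chain) == 0)
    stop("chain has zero variance; ESS undefined", call. = FALSE)
  # grow the acf window until the initial positive sequence terminates
  lag_max <- min(n - 1L, 200L)
  repeat {
    rho <- as.vector(stats::acf(chain, lag.max = lag_max, plot = FALSE,
                                demean = TRUE)$acf)
    m_max <- (length(rho) - length(rho) %% 2L) / 2L  # complete pairs
    pair <- rho[2 * seq_len(m_max) - 1L] + rho[2 * seq_len(m_max)]
    cut <- which(pair <= 0)
    if (length(cut) || lag_max >= n - 1L) break
    lag_max <- min(n - 1L, lag_max * 4L)
  }
  keep <- if (length(cut)) seq_len(cut[1L] - 1L) else seq_len(m_max)
  tau <- max(-1 + 2 * sum(pair[keep]), 1e-8)
  min(n / tau, n)
}

#' Highest-posterior-density interval
#'
#' Shortest interval containing `mass` of the draws, found by scanning
#' every contiguous window of `ceiling(mass * n)` sorted draws.
#'
#' @param chain Numeric vector of draws.
#' @param mass Probability mass of the interval, in (0, 1); default 0.95.
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' set.seed(1)
#' hpd_interval(rexp(5000))  # left edge near 0
#' @export
hpd_interval <- function(chain, mass = 0.95) {
  if (!(is.numeric(mass) && length(mass) == 1L && mass > 0 && mass < 1))
    stop("hpd mass must be a single number in (0, 1)", call. = FALSE)
  x <- sort(as.numeric(chain))
  n <- length(x)
  m <- min(n, max(2L, ceiling(mass * n)))
  widths <- x[m:n] - x[1:(n - m + 1L)]
  i <- which.min(widths)
  c(x[i], x[i + m - 1L])
}

#' Posterior summary of a scalar chain
#'
#' One row with the posterior mean (PM), median (PMD), mode (PMO,
#' maximizer of a Gaussian kernel density on a 512-point grid), standard
#' deviation (PSD), bounds of the highest-posterior-density interval, the
#' Geweke Z statistic and the effective sample size. A constant chain is
#' summarized with a degenerate interval and flagged rather than rejected.
#'
#' @param chain Numeric vector of MCMC draws (length >= 20).
#' @param hpd_mass Mass of the HPD interval, in (0, 1).
#' @return A one-row `data.frame` with columns `PM`, `PMD`, `PMO`, `PSD`,
#'   `HPD_low`, `HPD_high`, `Z`, `ESS` and logical `degenerate`.
#' @examples
#' set.seed(1)
#' summarize_chain(rnorm(1000, mean = 5))
#' @export
summarize_chain <- function(chain, hpd_mass = 0.95) {
  chain <- check_chain(chain)
  if (!(hpd_mass > 0 && hpd_mass < 1))
    stop("hpd mass must lie in (0, 1)", call. = FALSE)
  psd <- stats::sd(chain)
  if (psd == 0) {
    v <- chain[1L]
    return(data.frame(PM = v, PMD = v, PMO = v, PSD = 0,
                      HPD_low = v, HPD_high = v,
                      Z = NA_real_, ESS = NA_real_, degenerate = TRUE))
  }
  dens <- suppressWarnings(try(stats::density(chain, bw = "SJ", n = 512L),
                               silent = TRUE))
  if (inherits(dens, "try-error"))
    dens <- suppressWarnings(stats::density(chain, bw = "nrd0", n = 512L))
  hpd <- hpd_interval(chain, hpd_mass)
  data.frame(PM = mean(chain), PMD = stats::median(chain),
             PMO = dens$x[which.max(dens$y)], PSD = psd,
             HPD_low = hpd[1L], HPD_high = hpd[2L],
             Z = geweke_z(chain), ESS = effective_sample_size(chain),
             degenerate = FALSE)
}
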