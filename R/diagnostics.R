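# Posterior summarisation and convergence diagnostics.

#' Highest posterior density interval
#'
#' Shortest contiguous interval of the sorted draws containing
#' `ceiling(mass * n)` draws. Assumes a unimodal marginal; multimodal draws
#' are summarised by the same rule with a warning.
#'
#' @param draws Numeric vector of posterior draws (>= 2).
#' @param mass Target probability mass, in (0, 1); default 0.90.
#' @param warn_multimodal Emit a warning when a crude bimodality check
#'   (a deep internal density dip) fires.
#' @return A one-row tibble with `lower`, `upper`, `mass`.
#' @examples
#' hpd_interval(rnorm(10000), mass = 0.9) # about [-1.645, 1.645]
#' @export
hpd_interval <- function(draws, mass = 0.90, warn_multimodal = FALSE) {
  n <- length(draws)
  if (n < 2) abort("Need at least 2 draws for an HPD interval.")
  if (mass <= 0 || mass >= 1) abort("`mass` must be in (0, 1).")
  x <- sort(draws)
  m <- ceiling(mass * n)
  if (m >= n) {
    lo <- x[1]; hi <- x[n]
  } else {
    widths <- x[m:n] - x[1:(n - m + 1)]
    i <- which.min(widths)
    lo <- x[i]; hi <- x[i + m - 1]
  }
  if (warn_multimodal) {
    d <- stats::density(draws)
    peak <- max(d$y)
    inner <- d$y[d$x > stats::quantile(draws, 0.1) &
                   d$x < stats::quantile(draws, 0.9)]
    if (length(inner) > 0 && min(inner) < 0.1 * peak) {
      warn("Draws look multimodal; the contiguous HPD interval may be misleading.")
    }
  }
  tibble(lower = lo, upper = hi, mass = mass)
}

as_chain_list <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)),
                                          function(j) chains[, j])
  if (is.data.frame(chains)) chains <- as.list(chains)
  if (!is.list(chains)) abort("`chains` must be a list, matrix, or data frame.")
  chains
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Two-variance PSRF: with m chains of length n, W the mean within-chain
#' variance and B/n the variance of the chain means,
#' Rhat = sqrt((W + B/n) / W) — the factor by which between-chain spread
#' inflates the within-chain estimate, exactly 1 when the chains coincide.
#' Values near 1 indicate convergence; the conventional threshold here is
#' 1.001. A split-chain variant (halving each chain first, which also
#' detects within-chain trend) is available via `split = TRUE`.
#'
#' @param chains List of >= 2 equal-length numeric chains (or a matrix with
#'   one chain per column).
#' @param split Split each chain in half first (detects within-chain trend).
#' @return Rhat as a single number.
#' @export
gelman_rubin <- function(chains, split = FALSE) {
  chains <- as_chain_list(chains)
  if (split) {
    chains <- unlist(lapply(chains, function(x) {
      h <- floor(length(x) / 2)
      list(x[1:h], x[(h + 1):(2 * h)])
    }), recursive = FALSE)
  }
  m <- length(chains)
  if (m < 2) abort("Gelman-Rubin needs at least 2 chains.")
  lens <- lengths(chains)
  if (length(unique(lens)) != 1 || lens[1] < 2) {
    abort("Chains must have equal length >= 2.")
  }
  n <- lens[1]
  means <- vapply(chains, mean, numeric(1))
  W <- mean(vapply(chains, var, numeric(1)))
  B_over_n <- var(means)
  sqrt((W + B_over_n) / W)
}

#' Effective sample size of an MCMC chain
#'
#' n / (1 + 2 sum_k rho_k), with the empirical autocorrelations summed until
#' the first nonpositive pair rho_(2m) + rho_(2m+1) (Geyer's
#' initial-positive-sequence truncation), which is stable on thinned chains.
#'
#' @param draws Numeric vector of >= 10 draws.
#' @return The effective sample size.
#' @export
effective_sample_size <- function(draws) {
  n <- length(draws)
  if (n < 10) abort("Need at least 10 draws for an ESS estimate.")
  if (sd(draws) == 0) abort("ESS is undefined for a constant sequence.")
  # FFT-based autocovariance, normalised to autocorrelation
  x <- draws - mean(draws)
  npad <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(x, rep(0, npad - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[1:n] / npad
  rho <- ac / ac[1]
  # sum pairs (rho_1 + rho_2), (rho_3 + rho_4), ... while positive
  s <- 0
  k <- 1
  while (k + 1 < n) {
    pair <- rho[k + 1] + rho[k + 2] # rho[1] is lag 0
    if (!is.finite(pair) || pair <= 0) break
    s <- s + pair
    k <- k + 2
  }
  n / (1 + 2 * s)
}
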