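# Shared fixtures, all generated in code.

# identity curve: mu(t) = t, constant error; calibration becomes a
# discretised Normal, which many tests use as an analytic oracle
identity_curve <- function(a = 6000, b = 4000, tau0 = 0) {
  synth_curve("identity", a, b, tau0 = tau0)
}

# simulate a date table from a growth pmf through the full generative chain
simulate_dates <- function(pmf, n, curve, lab_error = 20, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  theta <- sample_calendar_dates(pmf, n)
  tibble::tibble(
    labcode = sprintf("SIM-%04d", seq_len(n)),
    c14age = uncalibrate(theta, curve, lab_error),
    error = lab_error,
    true_calbp = theta
  )
}

# brute-force shortest contiguous interval containing >= mass of the draws
hpd_oracle <- function(draws, mass = 0.9) {
  x <- sort(draws)
  n <- length(x)
  m <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - m + 1)) {
    j <- i + m - 1
    if (x[j] - x[i] < best[2] - best[1]) best <- c(x[i], x[j])
  }
  best
}

# discretised-Normal calibration oracle on the identity curve (tau = 0)
discretized_normal <- function(x, sigma, grid) {
  d <- stats::dnorm(x, mean = grid, sd = sigma)
  d / sum(d)
}
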