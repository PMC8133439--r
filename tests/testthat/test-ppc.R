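# minimal fit-like object with a degenerate posterior at fixed parameters
degenerate_fit <- function(model, a, b, params, dates, n_rows = 100) {
  draws <- tibble::as_tibble(c(list(.chain = 1L, .iteration = seq_len(n_rows)),
                               lapply(params, rep, n_rows)))
  structure(list(draws = draws, model = model, window = c(a = a, b = b),
                 dates = dates, logistic_exponent = "boundary",
                 free = names(params)),
            class = "c14_fit")
}

test_that("the simulated SPD ensemble averages to the generating pmf", {
  a <- 4100; b <- 4000
  g <- identity_curve(a = a, b = b, tau0 = 0)
  pmf <- pmf_exponential(a, b, 0.01)
  dates <- tibble::tibble(c14age = rep(4050, 5), error = rep(1, 5))
  fit <- degenerate_fit("exponential", a, b, list(r = 0.01), dates)
  env <- posterior_predictive_spd(fit, g, n_sim = 500, n_dates = 1000,
                                  observed_errors = 1, seed = 61)
  expect_s3_class(env, "ppc_envelope")
  expect_true(all(env$lo <= env$hi))
  # pointwise mean of simulated SPDs converges on the model pmf
  expect_lt(max(abs(attr(env, "mean_sim") - pmf$p)), 0.01)
})

test_that("each simulated curve lies inside its own ensemble's envelope on average", {
  a <- 4200; b <- 4000
  g <- identity_curve(a = a, b = b, tau0 = 0)
  dates <- tibble::tibble(c14age = rep(4100, 20), error = rep(20, 20))
  fit <- degenerate_fit("exponential", a, b, list(r = 0.003), dates)
  env <- posterior_predictive_spd(fit, g, n_sim = 200, seed = 62)
  cov <- envelope_coverage(env)
  # the observed dates came from a different process; just check structure
  expect_true(cov$coverage >= 0 && cov$coverage <= 1)
  expect_error(posterior_predictive_spd(fit, g, n_sim = 1), "n_sim")
})

test_that("envelope_coverage splits deviations by sign with inclusive bounds", {
  env <- tibble::tibble(calbp = 4100:4000,
                        lo = rep(0.1, 101), hi = rep(0.2, 101),
                        observed = rep(0.1, 101))
  class(env) <- c("ppc_envelope", class(env))
  expect_equal(envelope_coverage(env)$coverage, 1) # observed == lo counts
  cov_hi <- envelope_coverage(env, observed = rep(0.3, 101))
  expect_equal(cov_hi$coverage, 0)
  expect_equal(cov_hi$above, 4100:4000)
  expect_length(cov_hi$below, 0)
  expect_error(envelope_coverage(env, observed = 1:5), "mismatch")
})

test_that("well-specified data fall inside the envelope in most replicates", {
  # observed data drawn from the very model the envelope simulates; sharp
  # lab errors keep neighbouring grid years close to independent so the
  # per-replicate coverage fraction concentrates near the pointwise level
  a <- 4500; b <- 4000
  g <- identity_curve(a = a, b = b, tau0 = 0)
  pmf <- pmf_exponential(a, b, 0.003)
  withr::local_seed(63)
  ok <- 0
  for (rep in 1:20) {
    dates <- simulate_dates(pmf, 200, g, lab_error = 1)
    fit <- degenerate_fit("exponential", a, b, list(r = 0.003), dates)
    env <- posterior_predictive_spd(fit, g, n_sim = 400)
    if (envelope_coverage(env)$coverage >= 0.9) ok <- ok + 1
  }
  expect_gte(ok, 18)
})

test_that("envelopes narrow as the simulated sample size grows", {
  a <- 4200; b <- 4000
  g <- identity_curve(a = a, b = b, tau0 = 0)
  dates <- tibble::tibble(c14age = rep(4100, 10), error = rep(20, 10))
  fit <- degenerate_fit("exponential", a, b, list(r = 0.003), dates)
  env_small <- posterior_predictive_spd(fit, g, n_sim = 150, n_dates = 100,
                                        seed = 64)
  env_big <- posterior_predictive_spd(fit, g, n_sim = 150, n_dates = 1000,
                                      seed = 64)
  expect_lt(mean(env_big$hi - env_big$lo), mean(env_small$hi - env_small$lo))
})

test_that("every simulated SPD is normalised before quantiling", {
  # with a degenerate posterior and uncalsample, mean_sim integrates to 1
  a <- 4100; b <- 4000
  g <- identity_curve(a = a, b = b, tau0 = 5)
  dates <- tibble::tibble(c14age = rep(4050, 8), error = rep(15, 8))
  fit <- degenerate_fit("exponential", a, b, list(r = 0), dates)
  for (method in c("uncalsample", "calsample")) {
    env <- posterior_predictive_spd(fit, g, n_sim = 50, method = method,
                                    seed = 65)
    expect_equal(sum(attr(env, "mean_sim")), 1, tolerance = 1e-9)
  }
})
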