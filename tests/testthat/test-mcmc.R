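test_that("fit_mcmc validates its inputs", {
  g <- identity_curve()
  dates <- tibble::tibble(c14age = 5000, error = 20)
  expect_error(
    fit_mcmc(dates, "exponential", 6000, 4000, priors = list(), curve = g),
    "Missing prior"
  )
  expect_error(mcmc_config(n_iter = 100, burnin = 100), "n_iter")
  expect_error(mcmc_config(thin = 0), "thin")
})

test_that("the latent-date Gibbs step samples the exact categorical full conditional", {
  # fixed growth parameters: successive theta draws for a single date are
  # iid from p(theta = t | .) proportional to p_t N(x; mu(t), sigma)
  a <- 5019; b <- 5000 # 20-year toy grid
  g <- identity_curve(a = a, b = b, tau0 = 0)
  r <- 0.05
  x <- 5011; err <- 6
  dates <- tibble::tibble(c14age = x, error = err)
  fit <- fit_mcmc(dates, "exponential", a, b,
                  priors = list(r = prior_fixed(r)), curve = g,
                  config = mcmc_config(n_iter = 101000, burnin = 1000,
                                       seed = 8, store_theta = TRUE))
  draws <- g$calbp[fit$theta[[1]][, 1] + 1L]
  # enumerated conditional on the same grid
  p <- pmf_exponential(a, b, r)$p
  w <- p * dnorm(x, g$calbp, err)
  w <- w / sum(w)
  emp <- tabulate(a + 1 - draws, nbins = a - b + 1) / length(draws)
  tv <- 0.5 * sum(abs(emp - w))
  expect_lt(tv, 0.01)
})

test_that("with no data the sampler recovers each prior", {
  g <- identity_curve()
  empty <- tibble::tibble(c14age = numeric(0), error = numeric(0))
  cfg <- mcmc_config(n_iter = 23000, burnin = 3000, seed = 21)
  fit <- fit_mcmc(empty, "double_exponential", 6000, 4000,
                  priors = list(r1 = prior_normal(0, 0.1),
                                r2 = prior_normal(0.002, 0.05),
                                c = prior_uniform(4001, 5999)),
                  curve = g, config = cfg)
  n_eff <- sapply(fit$free, function(p)
    effective_sample_size(fit$draws[[p]]))
  truth <- list(r1 = c(0, 0.1), r2 = c(0.002, 0.05),
                c = c(5000, (5999 - 4001) / sqrt(12)))
  for (p in names(truth)) {
    mc_se <- truth[[p]][2] / sqrt(n_eff[[p]])
    expect_lt(abs(mean(fit$draws[[p]]) - truth[[p]][1]), 3 * mc_se)
    expect_lt(abs(sd(fit$draws[[p]]) - truth[[p]][2]),
              3 * truth[[p]][2] / sqrt(n_eff[[p]]))
  }
})

test_that("identical seed and config give bitwise-identical chains", {
  g <- identity_curve(a = 4600, b = 4400)
  pmf <- pmf_exponential(4600, 4400, 0.003)
  dates <- simulate_dates(pmf, 50, g, seed = 4)
  cfg <- mcmc_config(n_iter = 1500, burnin = 500, n_chains = 2, seed = 31)
  f1 <- fit_mcmc(dates, "exponential", 4600, 4400,
                 priors = list(r = prior_exponential(500)), curve = g,
                 config = cfg)
  f2 <- fit_mcmc(dates, "exponential", 4600, 4400,
                 priors = list(r = prior_exponential(500)), curve = g,
                 config = cfg)
  expect_identical(f1$draws, f2$draws)
  # chains differ from each other
  expect_false(identical(f1$draws$r[f1$draws$.chain == 1],
                         f1$draws$r[f1$draws$.chain == 2]))
})

test_that("adapted acceptance rates settle in a workable band", {
  g <- identity_curve()
  pmf <- pmf_double_exponential(6000, 4000, 0.002, -0.001, 4500)
  dates <- simulate_dates(pmf, 288, g, seed = 17)
  fit <- fit_mcmc(dates, "double_exponential", 6000, 4000,
                  priors = list(r1 = prior_normal(0, 0.1),
                                r2 = prior_normal(0, 0.1),
                                c = prior_uniform(4001, 5999)),
                  curve = g, config = mcmc_config(seed = 5))
  rates <- fit$acceptance_rates[1, fit$free]
  expect_true(all(rates >= 0.2 & rates <= 0.6))
})

test_that("posterior recovers a known growth rate (identity curve)", {
  g <- identity_curve()
  pmf <- pmf_exponential(6000, 4000, 0.003)
  dates <- simulate_dates(pmf, 500, g, seed = 29)
  fit <- fit_mcmc(dates, "exponential", 6000, 4000,
                  priors = list(r = prior_exponential(500)), curve = g,
                  config = mcmc_config(seed = 30))
  sm <- tidy(fit)
  expect_gt(sm$hpd_upper, 0.003 - 0.001)
  expect_lt(sm$hpd_lower, 0.003 + 0.001)
  expect_equal(sm$median, 0.003, tolerance = 0.25)
})

test_that("one nearly-uninformative date leaves the prior unchanged (KS check)", {
  g <- identity_curve(a = 4200, b = 4000, tau0 = 0)
  # an error of 5000 14C years makes the likelihood flat over the window
  dates <- tibble::tibble(c14age = 4100, error = 5000)
  fit <- fit_mcmc(dates, "exponential", 4200, 4000,
                  priors = list(r = prior_exponential(500)), curve = g,
                  config = mcmc_config(n_iter = 103000, burnin = 3000,
                                       thin = 10, seed = 12))
  withr::local_seed(13)
  ref <- prior_sample(prior_exponential(500), 10000)
  ks <- suppressWarnings(stats::ks.test(fit$draws$r, ref))
  expect_lt(unname(ks$statistic), 0.05)
})
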