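test_that("exponential pmf follows the closed form and normalises", {
  unif <- pmf_exponential(6000, 4000, r = 0)
  expect_equal(nrow(unif), 2001)
  expect_equal(unif$p, rep(1 / 2001, 2001), tolerance = 1e-12)

  pmf <- pmf_exponential(6000, 4000, r = 0.001)
  expect_equal(sum(pmf$p), 1, tolerance = 1e-9)
  # p_b / p_a = (1 + r)^(a - b)
  expect_equal(pmf$p[pmf$calbp == 4000] / pmf$p[pmf$calbp == 6000],
               1.001^2000, tolerance = 1e-9)
  # strictly increasing toward the present iff r > 0
  expect_true(all(diff(pmf$p) > 0)) # calbp descending = toward present
  neg <- pmf_exponential(6000, 4000, r = -0.001)
  expect_true(all(diff(neg$p) < 0))

  expect_error(pmf_exponential(6000, 4000, r = -1), "domain")
})

test_that("pmf builders normalise across randomised parameter sweeps", {
  withr::local_seed(11)
  for (i in 1:20) {
    a <- sample(3000:7000, 1)
    b <- a - sample(200:2500, 1)
    r1 <- runif(1, -0.005, 0.005)
    r2 <- runif(1, -0.005, 0.005)
    cc <- runif(1, b + 1, a - 1)
    p1 <- pmf_exponential(a, b, runif(1, -0.005, 0.008))
    p2 <- pmf_double_exponential(a, b, r1, r2, cc)
    k <- runif(1, 0.01, 0.3)
    p3 <- try(pmf_exp_logistic(a, b, r1, r2, cc, k), silent = TRUE)
    expect_equal(sum(p1$p), 1, tolerance = 1e-9)
    expect_equal(length(p1$p), a - b + 1)
    expect_equal(sum(p2$p), 1, tolerance = 1e-9)
    if (!inherits(p3, "try-error")) {
      expect_equal(sum(p3$p), 1, tolerance = 1e-9)
    }
  }
})

test_that("double exponential collapses to the single exponential when r1 = r2", {
  pe <- pmf_exponential(6000, 4000, 0.002)
  pd <- pmf_double_exponential(6000, 4000, 0.002, 0.002, c = 4500)
  expect_equal(pd$p, pe$p, tolerance = 1e-12)

  pu <- pmf_double_exponential(6000, 4000, 0, 0, c = 5000)
  expect_equal(pu$p, rep(1 / 2001, 2001), tolerance = 1e-12)

  # |r2 - r1| -> 0 converges in sup-norm
  pd2 <- pmf_double_exponential(6000, 4000, 0.002, 0.002 + 1e-9, c = 4500)
  expect_lt(max(abs(pd2$p - pe$p)), 1e-6)
})

test_that("rise-then-fall double exponential peaks at the changepoint", {
  # experiment-3b parameters
  pmf <- pmf_double_exponential(6000, 4000, r1 = 0.002, r2 = -0.001, c = 4500)
  expect_equal(pmf$calbp[which.max(pmf$p)], 4500)
  expect_error(pmf_double_exponential(6000, 4000, 0.002, -0.001, c = 6000),
               "domain")
})

test_that("exp-logistic matches a direct term-by-term transliteration", {
  # independent brute-force evaluation of the printed formula on a toy window
  a <- 3450; b <- 3400; cc <- 3430; r1 <- 0.004; r2 <- 0.03; k <- 0.3
  i <- 0:(a - b)
  t <- a - i
  K <- k * (1 + r1)^(a - cc)
  num <- ifelse(t > cc,
                k * (1 + r1)^i,
                1 / (1 + ((1 - K) / K) * exp(-r2 * i)))
  oracle <- num / sum(num)
  pmf <- pmf_exp_logistic(a, b, r1, r2, cc, k)
  expect_equal(pmf$p, oracle, tolerance = 1e-12)

  # exponential region is proportional to k (1+r1)^i exactly
  expo <- pmf$p[t > cc]
  expect_equal(expo / expo[1], (1 + r1)^(i[t > cc]), tolerance = 1e-12)

  # changepoint-relative exponent variant
  num2 <- ifelse(t > cc,
                 k * (1 + r1)^i,
                 1 / (1 + ((1 - K) / K) * exp(-r2 * (i - (a - cc)))))
  pmf2 <- pmf_exp_logistic(a, b, r1, r2, cc, k,
                           logistic_exponent = "changepoint")
  expect_equal(pmf2$p, num2 / sum(num2), tolerance = 1e-12)

  # case-study-scale parameters still normalise
  p3 <- pmf_exp_logistic(3400, 1850, -0.0003, 0.003, 2650, 0.08)
  expect_equal(sum(p3$p), 1, tolerance = 1e-9)

  # ill-defined logistic fraction: k (1+r1)^(a-c) >= 1
  expect_error(pmf_exp_logistic(3400, 1850, 0.01, 0.003, 2650, 0.9),
               "domain")
})

test_that("log-space evaluation survives large windows and rates", {
  pmf <- pmf_exponential(12000, 2000, r = 0.01) # T = 10,000
  expect_equal(sum(pmf$p), 1, tolerance = 1e-9)
  expect_true(all(is.finite(pmf$p)))
  pmf2 <- pmf_double_exponential(12000, 2000, 0.01, -0.01, c = 7000)
  expect_equal(sum(pmf2$p), 1, tolerance = 1e-9)
})

test_that("trajectory pmfs are plain normalisation, rejecting nonpositive sizes", {
  p <- pmf_from_trajectory(4002, 4000, c(1, 1, 1))
  expect_equal(p$p, rep(1 / 3, 3))
  p2 <- pmf_from_trajectory(4002, 4000, c(1, 2, 3))
  expect_equal(p2$p, c(1 / 6, 1 / 3, 1 / 2))
  expect_error(pmf_from_trajectory(4002, 4000, c(1, 0, 3)), "positive")
  expect_error(pmf_from_trajectory(4002, 4000, c(1, 2)), "length")
})

test_that("sample_calendar_dates draws from the pmf reproducibly", {
  pmf <- pmf_exponential(4100, 4000, 0)
  expect_identical(sample_calendar_dates(pmf, 0), integer(0))

  degenerate <- pmf_from_trajectory(4002, 4000, c(1e-12, 1, 1e-12))
  draws <- sample_calendar_dates(degenerate, 50, seed = 5)
  expect_true(all(draws == 4001))

  d1 <- sample_calendar_dates(pmf, 100, seed = 9)
  d2 <- sample_calendar_dates(pmf, 100, seed = 9)
  expect_identical(d1, d2)

  # uniform pmf: every year's empirical frequency within 5 binomial SEs
  n <- 200000
  T1 <- nrow(pmf)
  draws <- sample_calendar_dates(pmf, n, seed = 13)
  freq <- tabulate(4101 - draws, nbins = T1) / n
  se <- sqrt((1 / T1) * (1 - 1 / T1) / n)
  expect_true(all(abs(freq - 1 / T1) <= 5 * se))
})
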