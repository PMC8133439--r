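test_that("combined_sigma adds lab and curve error in quadrature", {
  g0 <- identity_curve(tau0 = 0)
  expect_equal(combined_sigma(g0, 5000, 20), 20)
  g34 <- identity_curve(tau0 = 4)
  expect_equal(combined_sigma(g34, 5000, 3), 5)
  g20 <- identity_curve(tau0 = 20)
  expect_equal(combined_sigma(g20, 5000, 20), sqrt(800))
  expect_error(combined_sigma(g0, 5000.5, 20), "on the curve grid")
})

test_that("calibrate_date equals the discretised-Normal oracle on the identity curve", {
  g <- identity_curve(tau0 = 0)
  d <- calibrate_date(5000, 20, g)
  expect_equal(sum(d$mass), 1, tolerance = 1e-12)
  oracle <- discretized_normal(5000, 20, g$calbp)
  expect_equal(d$mass, oracle, tolerance = 1e-12)
  expect_equal(d$calbp[which.max(d$mass)], 5000)
  # ~95.45% of mass within 2 sigma of the mode (value from the same oracle)
  within2 <- sum(oracle[g$calbp >= 4960 & g$calbp <= 5040])
  expect_equal(sum(d$mass[d$calbp >= 4960 & d$calbp <= 5040]), within2,
               tolerance = 1e-12)
  # continuous-Normal 2-sigma mass is 0.9545; the yearly discretisation
  # shifts it by under 0.003
  expect_lt(abs(within2 - 0.9545), 0.003)

  d1 <- calibrate_date(5000, 1, g)
  expect_gt(sum(d1$mass[d1$calbp >= 4998 & d1$calbp <= 5002]), 0.99)
})

test_that("a steeper curve slope shrinks the calendar posterior", {
  # mu(t) = 2t: a 14C error of 20 maps to ~10 calendar years
  lin <- synth_curve("linear", 6000, 4000, tau0 = 0,
                     params = list(alpha = 0, beta = 2))
  d <- calibrate_date(10000, 20, lin)
  post_sd <- sqrt(sum(d$mass * (d$calbp - sum(d$mass * d$calbp))^2))
  expect_equal(post_sd, 10, tolerance = 0.05)
})

test_that("calibration errors on degenerate support", {
  g <- identity_curve(a = 4200, b = 4000, tau0 = 0)
  expect_error(calibrate_date(20000, 10, g), "underflow")
})

test_that("uncalibrate is seeded, unbiased, and noiseless in the zero-error limit", {
  g <- identity_curve(tau0 = 0)
  expect_equal(uncalibrate(5000, g, sigma_lab = 1e-12, seed = 1), 5000,
               tolerance = 1e-9)
  x1 <- uncalibrate(rep(5000, 10), g, 20, seed = 42)
  x2 <- uncalibrate(rep(5000, 10), g, 20, seed = 42)
  expect_identical(x1, x2)
  draws <- uncalibrate(rep(5000, 10000), g, 20, seed = 7)
  se <- 20 / sqrt(10000)
  expect_lt(abs(mean(draws) - 5000), 3 * se)
})

test_that("spd sums calibrated masses and normalises on request", {
  g <- identity_curve(tau0 = 0)
  dates <- tibble::tibble(c14age = c(4500, 4500, 5500), error = 20)
  cal <- calibrate(dates, g)
  s <- spd(cal)
  expect_equal(sum(s$density), 3, tolerance = 1e-9) # n dates exactly
  sn <- spd(cal, normalize = TRUE)
  expect_equal(sum(sn$density), 1, tolerance = 1e-9)

  one <- calibrate_date(4500, 20, g)
  s1 <- spd(list(one))
  expect_equal(s1$density, one$mass)
  s2 <- spd(list(one, one), normalize = TRUE)
  expect_equal(s2$density, one$mass, tolerance = 1e-12)

  other <- calibrate_date(4500, 20, g, a = 5000, b = 4000)
  expect_error(spd(list(one, other)), "share one calendar grid")
})

test_that("window_filter keeps dates by full-curve in-window mass, inclusive threshold", {
  curve <- synth_curve("identity", 6500, 3500, tau0 = 0)
  dates <- tibble::tibble(
    labcode = c("inside", "outside", "edge"),
    c14age = c(5000, 3600, 4000),
    error = c(20, 20, 20)
  )
  wf <- window_filter(dates, curve, a = 6000, b = 4000)
  expect_equal(wf$in_window[1], 1, tolerance = 1e-9)
  expect_true(wf$kept[1])
  expect_equal(wf$in_window[2], 0, tolerance = 1e-9)
  expect_false(wf$kept[2])
  # date centred on the window edge: slightly over half its mass inside
  expect_gt(wf$in_window[3], 0.5)
  expect_true(wf$kept[3])
  # the threshold comparison is inclusive: a date with exactly the threshold
  # mass is kept
  wf_eq <- window_filter(dates, curve, a = 6000, b = 4000,
                         threshold = wf$in_window[3])
  expect_true(wf_eq$kept[3])
  wf_above <- window_filter(dates, curve, a = 6000, b = 4000,
                            threshold = min(1, wf$in_window[3] + 1e-6))
  expect_false(wf_above$kept[3])
  expect_error(window_filter(dates, curve, 6000, 4000, threshold = 0), "0, 1")
})

test_that("back-calibrated dates re-calibrate around the truth at nominal coverage", {
  g <- identity_curve(a = 5200, b = 4800, tau0 = 0)
  t_true <- 5000
  n_trial <- 1000
  withr::local_seed(99)
  x <- uncalibrate(rep(t_true, n_trial), g, 20)
  ll <- outer(x, g$calbp, function(xx, tt) dnorm(xx, tt, 20))
  mass <- ll / rowSums(ll)
  # central 95% interval per trial from the cumulative mass
  cum <- t(apply(mass, 1, cumsum))
  lo_idx <- apply(cum, 1, function(z) which(z >= 0.025)[1])
  hi_idx <- apply(cum, 1, function(z) which(z >= 0.975)[1])
  covered <- g$calbp[lo_idx] >= t_true & g$calbp[hi_idx] <= t_true
  expect_gte(mean(covered), 0.93)
})
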