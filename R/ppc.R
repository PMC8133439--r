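# Posterior-predictive checks: SPD ensembles simulated from posterior
# parameter draws, compared pointwise against the observed SPD.

#' Posterior-predictive SPD envelope
#'
#' For each of `n_sim` iterations: draw one posterior parameter combination,
#' build its growth PMF, sample `n_dates` calendar dates from it,
#' back-calibrate each into a 14C age, attach a lab error resampled with
#' replacement from the observed errors, calibrate, and aggregate into a
#' normalised SPD. The envelope is the pointwise 2.5% and 97.5% quantile
#' (for `level = 0.95`) across the simulated SPDs.
#'
#' `method = "calsample"` is a variant in which the back-calibration noise
#' uses only the curve error and the resampled lab error enters at the
#' calibration stage; the default `"uncalsample"` is the five-step recipe
#' above, with curve and lab error combined in one Normal draw.
#'
#' @param fit A `c14_fit` (its own dates provide the default observed SPD
#'   and error pool), or a draws tibble via `posterior =`.
#' @param curve Calibration curve used for back-calibration and calibration.
#' @param n_sim Number of simulated SPDs (>= 2); default 500.
#' @param n_dates Dates per simulation; defaults to the observed count.
#' @param observed_errors Lab-error pool to resample; defaults to the fit's.
#' @param level Pointwise envelope coverage (default 0.95).
#' @param method `"uncalsample"` (default) or `"calsample"`.
#' @param seed Optional seed applied locally.
#' @return A `ppc_envelope` tibble with columns `calbp`, `lo`, `hi`,
#'   `observed` (and attribute `n_sim`). Supports [autoplot()] and
#'   [envelope_coverage()].
#' @export
posterior_predictive_spd <- function(fit, curve, n_sim = 500,
                                     n_dates = NULL, observed_errors = NULL,
                                     level = 0.95,
                                     method = c("uncalsample", "calsample"),
                                     seed = NULL) {
  method <- match.arg(method)
  if (n_sim < 2) abort("`n_sim` must be >= 2.")
  if (!is.null(seed)) withr::local_seed(seed)
  a <- fit$window[["a"]]; b <- fit$window[["b"]]
  g <- ensure_grid(curve, a, b)
  observed_errors <- observed_errors %||% fit$dates$error
  if (length(observed_errors) == 0) abort("`observed_errors` must be non-empty.")
  n_dates <- n_dates %||% nrow(fit$dates)
  if (is.null(n_dates) || n_dates < 1) abort("`n_dates` must be >= 1.")

  pars <- as.matrix(fit$draws[, model_par_names(fit$model), drop = FALSE])
  pick <- sample.int(nrow(pars), n_sim, replace = TRUE)
  variant <- match(fit$logistic_exponent, c("boundary", "changepoint")) - 1L

  sims <- matrix(NA_real_, n_sim, nrow(g))
  for (s in seq_len(n_sim)) {
    logp <- cpp_growth_logpmf(model_code(fit$model), pars[pick[s], ],
                              a, b, variant)
    theta <- sample(g$calbp, n_dates, replace = TRUE, prob = exp(logp))
    err <- sample(observed_errors, n_dates, replace = TRUE)
    i <- match(theta, g$calbp)
    if (method == "uncalsample") {
      x <- rnorm(n_dates, g$mu[i], sqrt(g$tau[i]^2 + err^2))
    } else {
      x <- rnorm(n_dates, g$mu[i], g$tau[i])
    }
    ll <- loglik_grid_matrix(x, err, g)
    mx <- apply(ll, 1, max)
    w <- exp(ll - mx)
    tot <- rowSums(w)
    ok <- is.finite(mx) & tot > 0
    sims[s, ] <- colSums(w[ok, , drop = FALSE] / tot[ok]) / sum(ok)
  }

  alpha <- (1 - level) / 2
  qs <- apply(sims, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  observed <- if (nrow(fit$dates) > 0) {
    spd(calibrate(fit$dates, g), normalize = TRUE)$density
  } else {
    rep(NA_real_, nrow(g))
  }
  out <- tibble(calbp = g$calbp, lo = qs[1, ], hi = qs[2, ],
                observed = observed)
  class(out) <- c("ppc_envelope", class(out))
  attr(out, "n_sim") <- n_sim
  attr(out, "level") <- level
  attr(out, "mean_sim") <- colMeans(sims)
  out
}

#' Envelope coverage of the observed SPD
#'
#' Fraction of grid years where the observed SPD lies inside the pointwise
#' envelope (bounds inclusive), plus the years deviating above (positive
#' anomalies) and below (negative anomalies).
#'
#' @param envelope A `ppc_envelope`.
#' @param observed Optional replacement observed density (same grid).
#' @return List with `coverage`, `above` (years where observed > hi), and
#'   `below` (years where observed < lo).
#' @export
envelope_coverage <- function(envelope, observed = NULL) {
  obs <- observed %||% envelope$observed
  if (length(obs) != nrow(envelope)) abort("Observed SPD grid mismatch.")
  if (anyNA(obs)) abort("Observed SPD has missing values.")
  inside <- obs >= envelope$lo & obs <= envelope$hi
  list(coverage = mean(inside),
       above = envelope$calbp[obs > envelope$hi],
       below = envelope$calbp[obs < envelope$lo])
}

#' @export
autoplot.ppc_envelope <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$calbp)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed), colour = "black") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "cal BP", y = "summed probability",
                  title = sprintf("Posterior predictive check (%d simulations)",
                                  attr(object, "n_sim")))
}

#' @export
autoplot.spd_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$calbp, y = .data$density)) +
    ggplot2::geom_area(fill = "grey70") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "cal BP", y = "summed probability")
}
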