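# Hierarchical model fitting.
#
# The model couples a bounded growth PMF over calendar years to the observed
# 14C ages:
#   theta_j ~ BoundedGrowth(a, b, params)     (discrete, yearly)
#   X_j     ~ Normal(mu(theta_j), sigma_j),   sigma_j^2 = error_j^2 + tau^2
# Growth parameters are updated one at a time by adaptive Gaussian
# random-walk Metropolis-Hastings; the latent calendar dates theta_j are
# updated by exact discrete Gibbs draws from their categorical full
# conditional. The compiled core lives in src/sampler.cpp.

#' MCMC configuration
#'
#' @param n_chains Number of independent chains.
#' @param n_iter Iterations per chain (including burn-in).
#' @param burnin Burn-in iterations discarded from the front of each chain.
#' @param thin Keep every `thin`-th post-burn-in iteration.
#' @param target_accept Target acceptance rate for the adaptive random-walk
#'   proposals (0.44 is the standard univariate target).
#' @param adapt_interval Proposal scales are nudged toward `target_accept`
#'   every `adapt_interval` iterations, with Robbins-Monro decay.
#' @param seed Integer seed making the whole run reproducible.
#' @param store_theta Keep the latent calendar-date draws (memory-hungry;
#'   off by default).
#' @return An `mcmc_config` list.
#' @examples
#' mcmc_config()                       # the experiment protocol
#' mcmc_config_case_study()            # 3 chains x 100k, 15k retained draws
#' @export
mcmc_config <- function(n_chains = 1, n_iter = 10000, burnin = 3000,
                        thin = 1, target_accept = 0.44, adapt_interval = 200,
                        seed = NULL, store_theta = FALSE) {
  if (n_iter <= burnin || burnin < 0) abort("Need `n_iter` > `burnin` >= 0.")
  if (thin < 1) abort("`thin` must be >= 1.")
  structure(list(n_chains = n_chains, n_iter = n_iter, burnin = burnin,
                 thin = thin, target_accept = target_accept,
                 adapt_interval = adapt_interval, seed = seed,
                 store_theta = store_theta),
            class = "mcmc_config")
}

#' @rdname mcmc_config
#' @details `mcmc_config_case_study()` is the heavier protocol used for
#'   empirical analyses: 3 chains of 100,000 iterations with 10,000 burn-in,
#'   thinned by 18 so that 3 x 90,000 / 18 = 15,000 draws are retained.
#' @export
mcmc_config_case_study <- function(seed = NULL) {
  mcmc_config(n_chains = 3, n_iter = 1e5, burnin = 1e4, thin = 18,
              seed = seed)
}

#' Marginal log likelihood of one date under a growth model
#'
#' The per-observation likelihood with the latent calendar date summed out:
#' log sum_t p_t N(x; mu(t), sqrt(error^2 + tau(t)^2)), evaluated by
#' log-sum-exp over the window grid.
#'
#' @param c14age Observed 14C age (BP).
#' @param error 1-sigma lab error.
#' @param curve A `cal_curve` gridded over the PMF window.
#' @param pmf A `growth_pmf`.
#' @return A single log probability; `-Inf` when every term underflows.
#' @export
log_marginal_likelihood_date <- function(c14age, error, curve, pmf) {
  w <- attr(pmf, "window")
  g <- ensure_grid(curve, w[["a"]], w[["b"]])
  ll <- dnorm(c14age, g$mu, sqrt(error^2 + g$tau^2), log = TRUE)
  log_sum_exp(ll + attr(pmf, "logp"))
}

# numeric encoding of a named prior list, in canonical parameter order
encode_priors <- function(priors, par_names) {
  missing <- setdiff(par_names, names(priors))
  if (length(missing) > 0) {
    abort(sprintf("Missing prior(s) for parameter(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  specs <- priors[par_names]
  ok <- vapply(specs, inherits, logical(1), what = "prior_spec")
  if (!all(ok)) abort("All priors must be prior_spec objects.")
  list(
    type = vapply(specs, `[[`, integer(1), "code"),
    hp = vapply(specs, `[[`, numeric(4), "hp"), # 4 x P, one column each
    specs = specs
  )
}

draw_init <- function(specs, model, a, b, variant, max_tries = 200) {
  for (try in seq_len(max_tries)) {
    init <- vapply(specs, prior_sample, numeric(1))
    ok <- tryCatch({
      cpp_growth_logpmf(model_code(model), init, a, b, variant)
      TRUE
    }, error = function(e) FALSE)
    if (ok && all(is.finite(mapply(prior_logpdf, specs, init)))) return(init)
  }
  abort("Could not find an initial parameter vector with finite posterior density.")
}

#' Fit a growth model to radiocarbon dates by MCMC
#'
#' Draws from the joint posterior of the growth parameters and the latent
#' calendar dates given observed 14C ages, a calibration curve, and priors.
#' Growth parameters move by univariate adaptive random-walk
#' Metropolis-Hastings; latent dates move by exact discrete Gibbs updates
#' from their categorical full conditional. Samples should first pass
#' [window_filter()] so the fixed window boundaries are defensible.
#'
#' @param dates Tibble with columns `c14age`, `error` (optionally `labcode`).
#'   May have zero rows, in which case the sampler targets the prior.
#' @param model `"exponential"`, `"double_exponential"`, or
#'   `"exp_logistic"`.
#' @param a,b Window boundaries in cal BP (`a` older), treated as fixed
#'   constants.
#' @param priors Named list of [prior_exponential()]-style specs covering
#'   every model parameter (`r`; or `r1`, `r2`, `c`; plus `k`). Use
#'   [prior_fixed()] to pin a parameter.
#' @param curve A `cal_curve` spanning the window.
#' @param config An [mcmc_config()].
#' @param logistic_exponent See [pmf_exp_logistic()].
#' @return A `c14_fit` object: `draws` (tibble with `.chain`, `.iteration`
#'   and one column per parameter), `acceptance_rates`, the model, window,
#'   priors and config, and (optionally) latent-date draws. Supports
#'   [tidy()], [glance()], and [autoplot()].
#' @examples
#' curve <- synth_curve("identity", 6000, 4000, tau0 = 0)
#' pmf <- pmf_exponential(6000, 4000, r = 0.003)
#' theta <- sample_calendar_dates(pmf, 100, seed = 1)
#' dates <- tibble::tibble(c14age = uncalibrate(theta, curve, 20, seed = 2),
#'                         error = 20)
#' fit <- fit_mcmc(dates, "exponential", a = 6000, b = 4000,
#'                 priors = list(r = prior_exponential(500)), curve = curve,
#'                 config = mcmc_config(n_iter = 2000, burnin = 500, seed = 3))
#' tidy(fit)
#' @export
fit_mcmc <- function(dates, model, a, b, priors, curve,
                     config = mcmc_config(),
                     logistic_exponent = c("boundary", "changepoint")) {
  model <- match.arg(model, c("exponential", "double_exponential",
                              "exp_logistic"))
  variant <- match(match.arg(logistic_exponent),
                   c("boundary", "changepoint")) - 1L
  par_names <- model_par_names(model)
  enc <- encode_priors(priors, par_names)
  g <- ensure_grid(curve, a, b)
  n <- nrow(dates)

  if (n > 0) {
    dates <- check_dates_df(dates)
    ll <- loglik_grid_matrix(dates$c14age, dates$error, g)
    mx <- apply(ll, 1, max)
    dens <- exp(ll - mx)
    # per-date band outside which the scaled likelihood is numerically zero;
    # passed as contiguous segments so the Gibbs scan stays cache-friendly
    keep <- dens > 1e-14
    band_lo <- apply(keep, 1, function(z) which(z)[1]) - 1L
    band_hi <- apply(keep, 1, function(z) tail(which(z), 1)) - 1L
    segs <- lapply(seq_len(n), function(j) dens[j, (band_lo[j] + 1):(band_hi[j] + 1)])
    band_vals <- unlist(segs, use.names = FALSE)
    band_off <- c(0L, cumsum(lengths(segs)))[seq_len(n)]
    theta_init <- max.col(dens, ties.method = "first") - 1L
  } else {
    band_vals <- numeric(0)
    band_off <- band_lo <- band_hi <- theta_init <- integer(0)
  }

  if (!is.null(config$seed)) withr::local_seed(config$seed)
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    init <- draw_init(enc$specs, model, a, b, variant)
    res <- cpp_run_chain(band_vals, band_off, band_lo, band_hi,
                         model_code(model), variant,
                         init, enc$type, enc$hp, a, b,
                         config$n_iter, config$burnin, config$thin,
                         config$target_accept, config$adapt_interval,
                         config$store_theta, theta_init)
    colnames(res$draws) <- par_names
    chains[[ch]] <- res
  }

  draws <- purrr::map_dfr(seq_along(chains), function(ch) {
    d <- as_tibble(as.data.frame(chains[[ch]]$draws))
    dplyr::bind_cols(tibble(.chain = ch, .iteration = seq_len(nrow(d))), d)
  })
  acc <- do.call(rbind, lapply(chains, `[[`, "acceptance_rate"))
  colnames(acc) <- par_names
  theta <- if (config$store_theta) {
    lapply(chains, function(x) x$theta + 0L)
  }

  structure(
    list(draws = draws, acceptance_rates = acc, model = model,
         window = c(a = a, b = b), priors = enc$specs, config = config,
         logistic_exponent = c("boundary", "changepoint")[variant + 1L],
         dates = if (n > 0) as_tibble(dates) else tibble(),
         grid = g$calbp, theta = theta,
         free = names(enc$specs)[enc$type != 5L]),
    class = "c14_fit"
  )
}

#' @export
print.c14_fit <- function(x, ...) {
  cat(sprintf("<c14_fit> %s model on [%s, %s] cal BP; %d dates; %d draws (%d chain%s)\n",
              x$model, x$window["b"], x$window["a"], nrow(x$dates),
              nrow(x$draws), x$config$n_chains,
              if (x$config$n_chains > 1) "s" else ""))
  print(tidy(x))
  invisible(x)
}

#' Posterior parameter draws as a matrix, one column per free parameter
#' @param fit A `c14_fit`.
#' @return Numeric matrix of draws.
#' @export
posterior_matrix <- function(fit) {
  as.matrix(fit$draws[, fit$free, drop = FALSE])
}

#' @export
tidy.c14_fit <- function(x, mass = 0.90, ...) {
  purrr::map_dfr(x$free, function(par) {
    per_chain <- split(x$draws[[par]], x$draws$.chain)
    h <- hpd_interval(x$draws[[par]], mass = mass)
    rhat <- if (length(per_chain) >= 2) gelman_rubin(per_chain) else NA_real_
    ess <- tryCatch(sum(vapply(per_chain, effective_sample_size, numeric(1))),
                    error = function(e) NA_real_)
    tibble(parameter = par, rhat = rhat, ess = ess,
           median = median(x$draws[[par]]),
           hpd_lower = h$lower, hpd_upper = h$upper, hpd_mass = mass)
  })
}

#' @export
glance.c14_fit <- function(x, ...) {
  tibble(model = x$model, n_dates = nrow(x$dates),
         n_chains = x$config$n_chains, n_draws = nrow(x$draws),
         a = unname(x$window["a"]), b = unname(x$window["b"]),
         mean_acceptance = mean(colMeans(x$acceptance_rates)[x$free]))
}

#' @export
autoplot.c14_fit <- function(object, type = c("trace", "density"), ...) {
  type <- match.arg(type)
  long <- tidyr::pivot_longer(object$draws, cols = dplyr::all_of(object$free),
                              names_to = "parameter", values_to = "value")
  if (type == "trace") {
    ggplot2::ggplot(long, ggplot2::aes(x = .data$.iteration, y = .data$value,
                                       colour = factor(.data$.chain))) +
      ggplot2::geom_line(alpha = 0.7) +
      ggplot2::facet_wrap(~parameter, scales = "free_y") +
      ggplot2::labs(x = "iteration", y = NULL, colour = "chain")
  } else {
    ggplot2::ggplot(long, ggplot2::aes(x = .data$value,
                                       colour = factor(.data$.chain))) +
      ggplot2::geom_density() +
      ggplot2::facet_wrap(~parameter, scales = "free") +
      ggplot2::labs(x = NULL, colour = "chain")
  }
}

#' Growth PMF at given parameter values
#'
#' Rebuilds the growth model PMF of a fit at one parameter combination
#' (e.g. one posterior draw).
#'
#' @param fit A `c14_fit`.
#' @param params Named list/vector of parameter values; defaults to the
#'   posterior medians.
#' @return A `growth_pmf`.
#' @export
fitted_pmf <- function(fit, params = NULL) {
  if (is.null(params)) {
    params <- lapply(fit$draws[, model_par_names(fit$model), drop = FALSE],
                     median)
  }
  growth_pmf(fit$model, fit$window[["a"]], fit$window[["b"]],
             as.list(params), logistic_exponent = fit$logistic_exponent)
}

#' Pointwise marginal log-likelihood matrix for WAIC
#'
#' Evaluates, for every retained posterior draw s and every date j, the
#' marginal per-date log likelihood log sum_t p_t(s) N(x_j; mu(t), s_j(t))
#' (latent calendar dates summed out over the window grid). Rows are draws,
#' columns observations — the input [waic()] expects.
#'
#' @param fit A `c14_fit` fitted to at least one date.
#' @param curve The calibration curve used in the fit.
#' @param draw_indices Optional subset of draw rows (e.g. for thinning the
#'   WAIC computation).
#' @return An S x J matrix of log likelihoods.
#' @export
loglik_matrix <- function(fit, curve, draw_indices = NULL) {
  if (nrow(fit$dates) == 0) abort("Fit has no dates; WAIC is undefined.")
  g <- ensure_grid(curve, fit$window[["a"]], fit$window[["b"]])
  ll <- loglik_grid_matrix(fit$dates$c14age, fit$dates$error, g)
  mx <- apply(ll, 1, max)
  M <- exp(ll - mx) # n x G
  pars <- as.matrix(fit$draws[, model_par_names(fit$model), drop = FALSE])
  if (!is.null(draw_indices)) pars <- pars[draw_indices, , drop = FALSE]
  S <- nrow(pars)
  variant <- match(fit$logistic_exponent, c("boundary", "changepoint")) - 1L
  P <- vapply(seq_len(S), function(s) {
    exp(cpp_growth_logpmf(model_code(fit$model), pars[s, ],
                          fit$window[["a"]], fit$window[["b"]], variant))
  }, numeric(ncol(M)))               # G x S
  out <- t(log(M %*% P) + mx)        # S x n
  dimnames(out) <- NULL
  out
}
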