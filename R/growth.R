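# Bounded growth models as probability masses over calendar years.
#
# A bounded growth model is a generalised Bernoulli (categorical) distribution
# over the calendar years of a window [b, a]: the probability of sampling a
# calendar date t is p_t, with p_t = 0 outside [b, a]. Years are indexed
# i = 0..T from the OLDER boundary (t = a - i, T = a - b), so a positive
# growth rate means growth toward the present. All masses are computed in log
# space and normalised by log-sum-exp (src/growth.cpp), so large windows and
# rates up to ~0.01 at T = 10,000 do not overflow.

model_code <- function(model) {
  switch(model,
    exponential = 1L,
    double_exponential = 2L,
    exp_logistic = 3L,
    abort(sprintf("Unknown growth model '%s'.", model))
  )
}

model_par_names <- function(model) {
  switch(model,
    exponential = "r",
    double_exponential = c("r1", "r2", "c"),
    exp_logistic = c("r1", "r2", "c", "k")
  )
}

new_growth_pmf <- function(a, b, logp, model, params) {
  out <- tibble(calbp = seq(a, b, by = -1), p = exp(logp))
  class(out) <- c("growth_pmf", class(out))
  attr(out, "window") <- c(a = a, b = b)
  attr(out, "model") <- model
  attr(out, "params") <- params
  attr(out, "logp") <- logp
  out
}

growth_pmf <- function(model, a, b, params,
                       logistic_exponent = c("boundary", "changepoint")) {
  if (a <= b) abort("`a` must be older (larger) than `b`.")
  variant <- match(match.arg(logistic_exponent), c("boundary", "changepoint")) - 1L
  pars <- unlist(params[model_par_names(model)])
  if (anyNA(pars)) abort("Missing growth-model parameters.")
  logp <- cpp_growth_logpmf(model_code(model), pars, a, b, variant)
  new_growth_pmf(a, b, logp, model, as.list(pars))
}

#' Bounded exponential growth model
#'
#' p at year t = a - i is proportional to (1 + r)^i: the yearly share of a
#' population growing (r > 0) or declining (r < 0) at a constant rate,
#' truncated to the window and normalised to sum to 1.
#'
#' @param a,b Window in cal BP (`a` older); integers.
#' @param r Annual growth rate, > -1; zero gives the uniform phase model.
#' @return A `growth_pmf` tibble with columns `calbp` (descending from `a`)
#'   and `p`.
#' @examples
#' pmf <- pmf_exponential(6000, 4000, r = 0.001)
#' sum(pmf$p)
#' @export
pmf_exponential <- function(a, b, r) {
  growth_pmf("exponential", a, b, list(r = r))
}

#' Double-exponential growth model with a changepoint
#'
#' Growth proceeds at rate `r1` while the calendar year is older than the
#' changepoint `c` and at `r2` from `c` onwards: the yearly step into year t
#' uses `r1` while the year being left is older than `c`, so the trajectory
#' is continuous, collapses to [pmf_exponential()] when `r1 == r2`, and for
#' rise-then-fall parameters peaks exactly at `t = c`.
#'
#' @inheritParams pmf_exponential
#' @param r1,r2 Annual growth rates before (older than) and after the
#'   changepoint, each > -1.
#' @param c Changepoint in cal BP, strictly inside `(b, a)`; may be
#'   non-integer (the piecewise rule compares integer years to `c` directly,
#'   keeping the likelihood usable for continuous MCMC proposals).
#' @export
pmf_double_exponential <- function(a, b, r1, r2, c) {
  growth_pmf("double_exponential", a, b, list(r1 = r1, r2 = r2, c = c))
}

#' Exponential-logistic growth model
#'
#' Exponential growth at rate `r1` down to the changepoint `c`, then logistic
#' growth with intrinsic rate `r2` toward a carrying capacity; `k` is the
#' population at the older boundary `a` as a proportion of that capacity.
#' For years t > c the unnormalised mass is k (1 + r1)^i; for t <= c it is
#' 1 / (1 + ((1 - K)/K) exp(-r2 x)) with K = k (1 + r1)^(a - c).
#'
#' The published formulation measures the logistic exponent x by the global
#' year index i (counted from `a`), which leaves the trajectory discontinuous
#' at the changepoint; `logistic_exponent = "changepoint"` instead measures
#' it from the changepoint (x = i - (a - c)), making the handover continuous.
#' The default is the published form.
#'
#' @inheritParams pmf_double_exponential
#' @param k Initial proportion of carrying capacity, in (0, 1); the model
#'   requires k (1 + r1)^(a - c) < 1.
#' @param logistic_exponent `"boundary"` (as published) or `"changepoint"`.
#' @export
pmf_exp_logistic <- function(a, b, r1, r2, c, k,
                             logistic_exponent = c("boundary", "changepoint")) {
  growth_pmf("exp_logistic", a, b, list(r1 = r1, r2 = r2, c = c, k = k),
             logistic_exponent = logistic_exponent)
}

#' Growth model from an arbitrary population trajectory
#'
#' Any numerical model producing a vector of population sizes N_t per
#' calendar year translates into a bounded growth model by normalisation:
#' p = N / sum(N).
#'
#' @inheritParams pmf_exponential
#' @param N Positive population sizes, one per year from `a` down to `b`
#'   (length `a - b + 1`).
#' @export
pmf_from_trajectory <- function(a, b, N) {
  if (a <= b) abort("`a` must be older (larger) than `b`.")
  if (length(N) != a - b + 1) {
    abort(sprintf("`N` must have length a - b + 1 = %d.", a - b + 1))
  }
  if (any(!is.finite(N)) || any(N <= 0)) {
    abort("All population sizes `N` must be positive and finite.")
  }
  logp <- log(N) - log_sum_exp(log(N))
  new_growth_pmf(a, b, logp, "trajectory", list())
}

#' Sample calendar dates from a growth model
#'
#' Independent draws from the categorical distribution defined by the PMF.
#'
#' @param pmf A `growth_pmf`.
#' @param n Number of dates to draw (>= 0).
#' @param seed Optional seed applied locally for reproducible draws.
#' @return Integer vector of `n` calendar years (cal BP).
#' @export
sample_calendar_dates <- function(pmf, n, seed = NULL) {
  if (n < 0) abort("`n` must be >= 0.")
  if (!is.null(seed)) withr::local_seed(seed)
  if (n == 0) return(integer(0))
  sample(pmf$calbp, size = n, replace = TRUE, prob = pmf$p)
}

#' @export
print.growth_pmf <- function(x, ...) {
  w <- attr(x, "window")
  cat(sprintf("<growth_pmf> %s over [%s, %s] cal BP\n",
              attr(x, "model"), w["b"], w["a"]))
  NextMethod()
}

#' @export
autoplot.growth_pmf <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$calbp, y = .data$p)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "cal BP", y = "probability mass",
                  title = sprintf("%s growth model", attr(object, "model")))
}
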