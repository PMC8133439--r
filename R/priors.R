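# Prior specifications for growth-model parameters.
#
# Each prior is a small tagged list; `prior_logpdf()` evaluates the exact log
# density (returning -Inf outside the support, never an error) and
# `prior_sample()` draws from it. The same specifications are encoded
# numerically for the compiled sampler (src/sampler.cpp).

new_prior <- function(type, code, hp) {
  structure(list(type = type, code = code, hp = hp), class = "prior_spec")
}

#' Prior distributions for growth-model parameters
#'
#' Constructors for the prior families used by [fit_mcmc()]:
#' exponential (parameterised by RATE, so `prior_exponential(2500)` has mean
#' 1/2500 = 0.0004), normal, truncated normal (renormalised over
#' `[lower, upper]`), uniform, and point mass (`prior_fixed()`, which pins a
#' parameter at a constant and excludes it from sampling).
#'
#' @param rate Exponential rate lambda > 0 (mean = 1/lambda).
#' @param mean,sd Normal location and spread; `sd > 0`.
#' @param lower,upper Support bounds; `lower < upper`.
#' @param value Constant for a fixed parameter.
#' @return A `prior_spec` object.
#' @examples
#' prior_exponential(2500)            # mean growth rate 0.0004
#' prior_truncated_normal(2625, 200, 1850, 3400)
#' @export
prior_exponential <- function(rate) {
  if (rate <= 0) abort("Exponential prior needs `rate` > 0.")
  new_prior("exponential", 1L, c(rate, 0, 0, 0))
}

#' @rdname prior_exponential
#' @export
prior_normal <- function(mean, sd) {
  if (sd <= 0) abort("Normal prior needs `sd` > 0.")
  new_prior("normal", 2L, c(mean, sd, 0, 0))
}

#' @rdname prior_exponential
#' @export
prior_truncated_normal <- function(mean, sd, lower, upper) {
  if (sd <= 0) abort("Truncated normal prior needs `sd` > 0.")
  if (lower >= upper) abort("Truncated normal prior needs `lower` < `upper`.")
  new_prior("truncated_normal", 3L, c(mean, sd, lower, upper))
}

#' @rdname prior_exponential
#' @export
prior_uniform <- function(lower, upper) {
  if (lower >= upper) abort("Uniform prior needs `lower` < `upper`.")
  new_prior("uniform", 4L, c(lower, upper, 0, 0))
}

#' @rdname prior_exponential
#' @export
prior_fixed <- function(value) {
  new_prior("fixed", 5L, c(value, 0, 0, 0))
}

#' @export
print.prior_spec <- function(x, ...) {
  hp <- switch(x$type,
    exponential = sprintf("rate = %g", x$hp[1]),
    normal = sprintf("mean = %g, sd = %g", x$hp[1], x$hp[2]),
    truncated_normal = sprintf("mean = %g, sd = %g, bounds [%g, %g]",
                               x$hp[1], x$hp[2], x$hp[3], x$hp[4]),
    uniform = sprintf("[%g, %g]", x$hp[1], x$hp[2]),
    fixed = sprintf("value = %g", x$hp[1])
  )
  cat(sprintf("<prior> %s(%s)\n", x$type, hp))
  invisible(x)
}

#' Evaluate a prior log density
#'
#' Exact log density of a `prior_spec` at `value`; values outside the support
#' return `-Inf` (not an error). Truncated normals are renormalised by the
#' in-bounds mass.
#'
#' @param spec A `prior_spec`.
#' @param value Numeric vector of evaluation points.
#' @return Log densities, vectorised over `value`.
#' @export
prior_logpdf <- function(spec, value) {
  if (!inherits(spec, "prior_spec")) abort("`spec` must be a prior_spec.")
  hp <- spec$hp
  switch(spec$type,
    exponential = ifelse(value < 0, -Inf, log(hp[1]) - hp[1] * value),
    normal = dnorm(value, hp[1], hp[2], log = TRUE),
    truncated_normal = {
      z <- pnorm(hp[4], hp[1], hp[2]) - pnorm(hp[3], hp[1], hp[2])
      ifelse(value < hp[3] | value > hp[4], -Inf,
             dnorm(value, hp[1], hp[2], log = TRUE) - log(z))
    },
    uniform = ifelse(value < hp[1] | value > hp[2], -Inf,
                     -log(hp[2] - hp[1])),
    fixed = ifelse(value == hp[1], 0, -Inf)
  )
}

#' Draw from a prior
#'
#' @param spec A `prior_spec`.
#' @param n Number of draws.
#' @return Numeric vector of `n` draws.
#' @export
prior_sample <- function(spec, n = 1) {
  hp <- spec$hp
  switch(spec$type,
    exponential = stats::rexp(n, rate = hp[1]),
    normal = rnorm(n, hp[1], hp[2]),
    truncated_normal = {
      # inverse-CDF sampling restricted to the bounds
      plo <- pnorm(hp[3], hp[1], hp[2])
      phi <- pnorm(hp[4], hp[1], hp[2])
      qnorm(runif(n, plo, phi), hp[1], hp[2])
    },
    uniform = runif(n, hp[1], hp[2]),
    fixed = rep(hp[1], n)
  )
}
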