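# WAIC model comparison from pointwise posterior log likelihoods.

#' Widely Applicable Information Criterion
#'
#' From an S x J matrix of pointwise log likelihoods (S posterior draws, J
#' observations): lppd = sum_j log(mean_s exp ll_sj) (log column means of
#' the exponentiated entries, computed stably), the effective-parameter
#' penalty p_waic = sum_j var_s(ll_sj), and waic = -2 (lppd - p_waic).
#' Lower WAIC indicates better expected predictive performance.
#'
#' For fitted growth models the pointwise likelihood is the MARGINAL
#' per-date likelihood produced by [loglik_matrix()] (latent calendar dates
#' summed out), so the observation-level predictive density is well defined.
#'
#' @param loglik S x J matrix of log likelihoods; all entries finite.
#' @param model Optional model label carried into comparisons.
#' @return A `c14_waic` object with fields `lppd`, `p_waic`, `waic`, `n_obs`,
#'   `n_draws`, `model`.
#' @examples
#' ll <- matrix(rnorm(20, -2), nrow = 5) # 5 draws x 4 observations
#' waic(ll)
#' @export
waic <- function(loglik, model = NULL) {
  loglik <- as.matrix(loglik)
  if (nrow(loglik) < 2) abort("WAIC needs at least 2 posterior draws.")
  if (ncol(loglik) < 1) abort("WAIC needs at least 1 observation.")
  if (any(!is.finite(loglik))) abort("Non-finite entries in `loglik`.")
  S <- nrow(loglik)
  mx <- apply(loglik, 2, max)
  lppd_j <- mx + log(colMeans(exp(sweep(loglik, 2, mx)))) # log mean exp
  p_j <- apply(loglik, 2, var)
  lppd <- sum(lppd_j)
  p_waic <- sum(p_j)
  structure(
    list(lppd = lppd, p_waic = p_waic, waic = -2 * (lppd - p_waic),
         n_obs = ncol(loglik), n_draws = S,
         model = model %||% NA_character_,
         pointwise = tibble(lppd = lppd_j, p_waic = p_j)),
    class = "c14_waic"
  )
}

#' @export
print.c14_waic <- function(x, ...) {
  cat(sprintf("<c14_waic> %swaic = %.3f (lppd = %.3f, p_waic = %.3f; %d obs, %d draws)\n",
              if (is.na(x$model)) "" else paste0(x$model, ": "),
              x$waic, x$lppd, x$p_waic, x$n_obs, x$n_draws))
  invisible(x)
}

#' @export
glance.c14_waic <- function(x, ...) {
  tibble(model = x$model, waic = x$waic, lppd = x$lppd, p_waic = x$p_waic,
         n_obs = x$n_obs, n_draws = x$n_draws)
}

#' Compare models by WAIC
#'
#' Computes differences to the best (lowest-WAIC) model and Akaike-style
#' weights w_i = exp(-dWAIC_i / 2) / sum_k exp(-dWAIC_k / 2). Weights are
#' invariant to adding a constant to every log-likelihood entry of every
#' model.
#'
#' @param ... `c14_waic` objects, or a single list of them, or a named
#'   numeric vector of WAIC values.
#' @param model_names Optional labels overriding the objects' own.
#' @return A tibble with columns `model`, `waic`, `delta_waic`, `weight`
#'   (and `lppd`, `p_waic` where available), sorted by WAIC; the best model
#'   has `delta_waic` 0, and weights sum to 1.
#' @examples
#' waic_compare(c(m3 = 3036.756, m2 = 3036.933, m1 = 3038.307))
#' @export
waic_compare <- function(..., model_names = NULL) {
  dots <- list(...)
  if (length(dots) == 1 && is.list(dots[[1]]) &&
      !inherits(dots[[1]], "c14_waic")) {
    dots <- dots[[1]]
  }
  if (length(dots) == 1 && is.numeric(dots[[1]])) {
    vals <- dots[[1]]
    out <- tibble(
      model = model_names %||% names(vals) %||%
        paste0("model", seq_along(vals)),
      waic = as.numeric(vals)
    )
  } else {
    ok <- vapply(dots, inherits, logical(1), what = "c14_waic")
    if (!all(ok)) abort("Inputs must be c14_waic objects or a numeric vector of WAIC values.")
    out <- purrr::map_dfr(dots, glance)
    out <- dplyr::select(out, "model", "waic", "lppd", "p_waic")
    if (!is.null(model_names)) out$model <- model_names
    if (all(is.na(out$model))) out$model <- paste0("model", seq_len(nrow(out)))
  }
  out <- dplyr::mutate(out, delta_waic = .data$waic - min(.data$waic))
  w <- exp(-out$delta_waic / 2)
  out$weight <- w / sum(w)
  dplyr::arrange(out, .data$waic)
}
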