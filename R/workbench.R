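# Simulation workbench: parameter-recovery experiments (simulate calendar
# dates from a known growth model, back-calibrate, refit, check HPD
# coverage) and the empirical case-study pipeline (data-hygiene filters,
# m1/m2/m3 fits, diagnostics, WAIC, posterior-predictive checks).

#' Define a parameter-recovery experiment
#'
#' An experiment draws `n_rep` replicate samples of calendar dates from a
#' known growth model, converts each into 14C ages with a fixed lab error,
#' refits the model by MCMC, and records whether each true parameter falls
#' inside its 90% HPD interval. `settings` holds one row per condition
#' (true parameter values, and optionally a per-condition `n_dates`), so a
#' single design expresses sweeps over rates or sample sizes.
#'
#' @param model Growth model name (see [fit_mcmc()]).
#' @param a,b Window in cal BP.
#' @param settings Tibble of true parameter values, one condition per row
#'   (columns named after the model parameters; optional `n_dates` column).
#' @param n_dates Default sample size per replicate.
#' @param lab_error Fixed 1-sigma lab error attached to simulated ages
#'   (14C yr).
#' @param n_rep Replicates per condition.
#' @param priors Named prior list for the refit.
#' @param config [mcmc_config()] for the refit.
#' @return An `experiment_design` list.
#' @export
experiment_design <- function(model, a, b, settings, n_dates = 500,
                              lab_error = 20, n_rep = 20, priors,
                              config = mcmc_config()) {
  settings <- as_tibble(settings)
  if (n_rep < 1) abort("`n_rep` must be >= 1.")
  missing <- setdiff(model_par_names(model), names(settings))
  if (length(missing) > 0) {
    abort(sprintf("`settings` lacks column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  if (model %in% c("double_exponential", "exp_logistic") &&
      any(settings$c <= b | settings$c >= a)) {
    abort("Changepoint `c` must lie strictly inside (b, a).")
  }
  structure(list(model = model, a = a, b = b, settings = settings,
                 n_dates = n_dates, lab_error = lab_error, n_rep = n_rep,
                 priors = priors, config = config),
            class = "experiment_design")
}

#' The four published experiment designs
#'
#' Returns the standard battery of parameter-recovery experiments as a named
#' list of [experiment_design()] objects:
#'
#' 1. exponential growth, window 6000-4000 cal BP, r in
#'    \{0.001, 0.003, 0.005\}, 500 dates, prior r ~ Exponential(rate 500);
#' 2. exponential r = 0.003, 300 dates, on two windows chosen for their
#'    calibration-curve character (a steep stretch, 7000-6400, and a
#'    plateau, 2800-2200);
#' 3. (a) exponential r = 0.005 on 6000-4000 at sample sizes 250/100/50;
#'    (b) double-exponential r1 = 0.002, r2 = -0.001, c = 4500 at sample
#'    sizes 500/250/100/50, priors r1, r2 ~ Normal(0, 0.1) and
#'    c ~ Uniform(4001, 5999);
#' 4. double-exponential on the case-study window 3400-1850, c = 2800,
#'    r1 in \{-0.001, -0.002, -0.003\} crossed with r2 in
#'    \{0.001, 0.002, 0.003\}, 288 dates; the changepoint prior is
#'    Uniform(1851, 3399), i.e. bounded by the experiment's own window.
#'
#' All use a fixed lab error of 20 14C years, 20 replicates per condition,
#' and a single chain of 10,000 iterations with 3,000 burn-in.
#'
#' @return Named list of designs (`exp1`, `exp2_steep`, `exp2_plateau`,
#'   `exp3a`, `exp3b`, `exp4`).
#' @export
experiment_designs <- function() {
  cfg <- mcmc_config(n_chains = 1, n_iter = 10000, burnin = 3000)
  exp_prior <- list(r = prior_exponential(500))
  dexp_priors <- function(c_lo, c_hi) {
    list(r1 = prior_normal(0, 0.1), r2 = prior_normal(0, 0.1),
         c = prior_uniform(c_lo, c_hi))
  }
  list(
    exp1 = experiment_design(
      "exponential", a = 6000, b = 4000,
      settings = tibble(r = c(0.001, 0.003, 0.005)),
      n_dates = 500, n_rep = 20, priors = exp_prior, config = cfg),
    exp2_steep = experiment_design(
      "exponential", a = 7000, b = 6400,
      settings = tibble(r = 0.003),
      n_dates = 300, n_rep = 20, priors = exp_prior, config = cfg),
    exp2_plateau = experiment_design(
      "exponential", a = 2800, b = 2200,
      settings = tibble(r = 0.003),
      n_dates = 300, n_rep = 20, priors = exp_prior, config = cfg),
    exp3a = experiment_design(
      "exponential", a = 6000, b = 4000,
      settings = tibble(r = 0.005, n_dates = c(250, 100, 50)),
      n_rep = 20, priors = exp_prior, config = cfg),
    exp3b = experiment_design(
      "double_exponential", a = 6000, b = 4000,
      settings = tibble(r1 = 0.002, r2 = -0.001, c = 4500,
                        n_dates = c(500, 250, 100, 50)),
      n_rep = 20, priors = dexp_priors(4001, 5999), config = cfg),
    exp4 = experiment_design(
      "double_exponential", a = 3400, b = 1850,
      settings = tidyr::expand_grid(r1 = c(-0.001, -0.002, -0.003),
                                    r2 = c(0.001, 0.002, 0.003),
                                    c = 2800),
      n_dates = 288, n_rep = 20, priors = dexp_priors(1851, 3399),
      config = cfg)
  )
}

# deterministic per-replicate substreams from one master seed
replicate_seeds <- function(seed, n) {
  withr::local_seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run a parameter-recovery experiment
#'
#' Executes every (condition, replicate) cell of a design: sample calendar
#' dates from the true growth model, back-calibrate them with the design's
#' lab error, refit by MCMC, and compare each true parameter against its
#' 90% HPD interval. Each replicate's RNG stream derives from
#' (`seed`, condition, replicate), so results do not depend on execution
#' order.
#'
#' @param design An [experiment_design()].
#' @param curve Calibration curve for back-calibration and refitting.
#' @param seed Master seed.
#' @param scale Replicate multiplier in (0, 1]: `scale = 0.5` runs half the
#'   replicates (at least one), for desk-scale runs.
#' @param hpd_mass HPD mass used for the coverage flag (default 0.90).
#' @param verbose Print one line per replicate.
#' @return A `recovery_report` tibble, one row per condition x replicate x
#'   parameter: true value, posterior median, HPD bounds, `covered` flag.
#'   `attr(, "manifest")` records seed, design and curve checksum.
#' @export
run_experiment <- function(design, curve, seed = 1, scale = 1,
                           hpd_mass = 0.90, verbose = FALSE) {
  if (scale <= 0 || scale > 1) abort("`scale` must be in (0, 1].")
  curve <- ensure_grid(curve, design$a, design$b)
  n_rep <- max(1L, as.integer(round(design$n_rep * scale)))
  par_names <- model_par_names(design$model)
  conds <- design$settings
  seeds <- matrix(replicate_seeds(seed, nrow(conds) * n_rep),
                  nrow(conds), n_rep)

  rows <- purrr::map_dfr(seq_len(nrow(conds)), function(ci) {
    truth <- as.list(conds[ci, par_names])
    n_dates <- if ("n_dates" %in% names(conds)) conds$n_dates[ci] else design$n_dates
    pmf <- growth_pmf(design$model, design$a, design$b, truth)
    purrr::map_dfr(seq_len(n_rep), function(rep) {
      rs <- seeds[ci, rep]
      withr::local_seed(rs)
      theta <- sample_calendar_dates(pmf, n_dates)
      dates <- tibble(c14age = uncalibrate(theta, curve, design$lab_error),
                      error = design$lab_error)
      cfg <- design$config
      cfg$seed <- NULL # replicate stream already seeded
      fit <- fit_mcmc(dates, design$model, design$a, design$b,
                      design$priors, curve, cfg)
      sm <- tidy(fit, mass = hpd_mass)
      if (verbose) {
        message(sprintf("condition %d rep %d: %s", ci, rep,
                        paste(sprintf("%s=%.4g", sm$parameter, sm$median),
                              collapse = " ")))
      }
      truth_vec <- unlist(truth)[sm$parameter]
      tibble(condition = ci, replicate = rep, n_dates = n_dates,
             parameter = sm$parameter, true = truth_vec,
             median = sm$median, hpd_lower = sm$hpd_lower,
             hpd_upper = sm$hpd_upper,
             covered = truth_vec >= sm$hpd_lower & truth_vec <= sm$hpd_upper)
    })
  })
  class(rows) <- c("recovery_report", class(rows))
  attr(rows, "manifest") <- list(
    seed = seed, scale = scale, model = design$model,
    window = c(a = design$a, b = design$b), n_rep = n_rep,
    curve_checksum = rlang::hash(list(curve$calbp, curve$mu, curve$tau)),
    config = unclass(design$config)
  )
  rows
}

#' Aggregate HPD coverage of a recovery report
#'
#' @param report A `recovery_report`.
#' @return Tibble with per condition and parameter: replicates, number
#'   covered, coverage fraction.
#' @export
coverage_summary <- function(report) {
  dplyr::summarise(
    dplyr::group_by(as_tibble(report), .data$condition, .data$parameter),
    n_rep = dplyr::n(), n_covered = sum(.data$covered),
    coverage = mean(.data$covered), .groups = "drop"
  )
}

#' @export
autoplot.recovery_report <- function(object, ...) {
  df <- dplyr::mutate(as_tibble(object),
                      status = ifelse(.data$covered, "covered", "missed"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$replicate, y = .data$median,
                                   colour = .data$status)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$hpd_lower,
                                        ymax = .data$hpd_upper),
                           width = 0.2) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$true),
                        linetype = "dashed") +
    ggplot2::facet_grid(parameter ~ condition, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(covered = "grey30",
                                            missed = "orange")) +
    ggplot2::labs(x = "replicate", y = "posterior median and 90% HPD")
}

#' Data-hygiene filters for a date table
#'
#' Applies, in an order-independent way, the standard exclusions: rows with
#' a missing 14C age, rows with a missing lab code, rows whose lab error
#' exceeds `max_error` (default 100 14C yr), and rows whose full-curve
#' calibrated mass inside the analysis window falls below `threshold`
#' (see [window_filter()]).
#'
#' @param dates Tibble with `labcode`, `c14age`, `error` columns.
#' @param curve Calibration curve.
#' @param a,b Analysis window (cal BP).
#' @param max_error Maximum admissible lab error.
#' @param threshold Minimum in-window calibrated mass.
#' @return List with `kept` (the retained tibble) and `report` (all rows
#'   with `reason` for exclusion, or NA when retained, and `in_window`).
#' @export
preprocess_dates <- function(dates, curve, a, b, max_error = 100,
                             threshold = 0.5) {
  dates <- as_tibble(dates)
  if (is.null(dates$labcode)) dates$labcode <- NA_character_
  reason <- rep(NA_character_, nrow(dates))
  bad_age <- !is.finite(suppressWarnings(as.numeric(dates$c14age)))
  bad_lab <- is.na(dates$labcode) | !nzchar(trimws(as.character(dates$labcode)))
  bad_err <- !is.finite(dates$error) | dates$error <= 0 |
    dates$error > max_error
  reason[bad_err] <- "error > max_error"
  reason[bad_lab] <- "missing lab code"
  reason[bad_age] <- "missing 14C age"
  usable <- !(bad_age | bad_lab | bad_err)
  in_window <- rep(NA_real_, nrow(dates))
  if (any(usable)) {
    wf <- window_filter(dates[usable, ], curve, a, b, threshold = threshold)
    in_window[usable] <- wf$in_window
    out_win <- usable
    out_win[usable] <- !wf$kept
    reason[out_win] <- "in-window mass below threshold"
  }
  report <- dplyr::mutate(dates, in_window = in_window, reason = reason,
                          kept = is.na(reason))
  list(kept = dplyr::filter(report, .data$kept), report = report)
}

#' Run the full case-study pipeline on a date table
#'
#' Applies the data-hygiene filters ([preprocess_dates()]), fits the three
#' growth models — exponential (m1), double-exponential (m2), and
#' exponential-logistic (m3) — with their standard weakly-informative
#' priors, and produces the parameter summary table, WAIC comparison, and
#' posterior-predictive SPD envelopes.
#'
#' Default priors: m1 r ~ Exponential(rate 2500) (mean 0.0004, the
#' cross-cultural mean prehistoric growth rate); m2 adds
#' r1 ~ Normal(0, 0.0004), r2 ~ Exponential(rate 2500),
#' c ~ TruncatedNormal(2625, 200, b, a); m3 further adds
#' k ~ TruncatedNormal(0.1, 0.1, 0.0001, 0.5).
#'
#' @param dates Tibble with `labcode`, `c14age`, `error` columns.
#' @param curve Calibration curve spanning the window.
#' @param a,b Analysis window (cal BP); default 3400-1850.
#' @param config [mcmc_config()]; defaults to the heavy
#'   [mcmc_config_case_study()] protocol.
#' @param models Subset of `c("m1", "m2", "m3")` to fit.
#' @param n_sim Simulations per posterior-predictive envelope; set to 0 to
#'   skip the PPC stage.
#' @param waic_draws Number of posterior draws used in the WAIC pointwise
#'   log-likelihood matrix (evenly thinned); `NULL` uses all draws.
#' @param seed Master seed.
#' @return A `case_study` list: `filter` (preprocessing report), `fits`
#'   (named `c14_fit`s), `summary` (per-parameter Rhat/ESS/median/HPD
#'   table), `waic` (comparison tibble), `ppc` (named envelopes), and a
#'   reproducibility `manifest`.
#' @export
case_study_pipeline <- function(dates, curve, a = 3400, b = 1850,
                                config = mcmc_config_case_study(),
                                models = c("m1", "m2", "m3"),
                                n_sim = 500, waic_draws = 1000, seed = 1) {
  models <- match.arg(models, several.ok = TRUE)
  pre <- preprocess_dates(dates, curve, a, b)
  if (nrow(pre$kept) == 0) abort("No dates survive the hygiene filters.")
  kept <- pre$kept

  prior_sets <- list(
    m1 = list(r = prior_exponential(2500)),
    m2 = list(r1 = prior_normal(0, 0.0004), r2 = prior_exponential(2500),
              c = prior_truncated_normal(2625, 200, b, a)),
    m3 = list(r1 = prior_normal(0, 0.0004), r2 = prior_exponential(2500),
              c = prior_truncated_normal(2625, 200, b, a),
              k = prior_truncated_normal(0.1, 0.1, 0.0001, 0.5))
  )
  model_map <- c(m1 = "exponential", m2 = "double_exponential",
                 m3 = "exp_logistic")

  seeds <- replicate_seeds(seed, length(models) * 2)
  fits <- list()
  for (i in seq_along(models)) {
    m <- models[i]
    cfg <- config
    cfg$seed <- seeds[i]
    fits[[m]] <- fit_mcmc(kept, model_map[[m]], a, b, prior_sets[[m]],
                          curve, cfg)
  }

  summary_tbl <- purrr::map_dfr(models, function(m) {
    dplyr::mutate(tidy(fits[[m]]), model = m, .before = 1)
  })

  waic_tbl <- if (length(models) >= 1) {
    ws <- purrr::map(models, function(m) {
      idx <- if (!is.null(waic_draws) && waic_draws < nrow(fits[[m]]$draws)) {
        unique(round(seq(1, nrow(fits[[m]]$draws), length.out = waic_draws)))
      }
      waic(loglik_matrix(fits[[m]], curve, draw_indices = idx), model = m)
    })
    waic_compare(ws)
  }

  ppc <- if (n_sim >= 2) {
    out <- purrr::imap(fits, function(f, m) {
      posterior_predictive_spd(f, curve, n_sim = n_sim,
                               seed = seeds[length(models) + match(m, models)])
    })
    out
  }

  structure(
    list(filter = pre$report, fits = fits, summary = summary_tbl,
         waic = waic_tbl, ppc = ppc,
         manifest = list(
           seed = seed, window = c(a = a, b = b), models = models,
           n_dates = nrow(kept),
           curve_checksum = rlang::hash(list(curve$calbp, curve$mu,
                                             curve$tau)),
           config = unclass(config))),
    class = "case_study"
  )
}

#' @export
print.case_study <- function(x, ...) {
  cat(sprintf("<case_study> %d dates on [%s, %s] cal BP; models: %s\n",
              x$manifest$n_dates, x$manifest$window["b"],
              x$manifest$window["a"],
              paste(x$manifest$models, collapse = ", ")))
  print(x$summary)
  if (!is.null(x$waic)) print(x$waic)
  invisible(x)
}

# ---- design serialisation (YAML round trip) --------------------------------

prior_to_list <- function(spec) {
  hp <- switch(spec$type,
    exponential = list(rate = spec$hp[1]),
    normal = list(mean = spec$hp[1], sd = spec$hp[2]),
    truncated_normal = list(mean = spec$hp[1], sd = spec$hp[2],
                            lower = spec$hp[3], upper = spec$hp[4]),
    uniform = list(lower = spec$hp[1], upper = spec$hp[2]),
    fixed = list(value = spec$hp[1])
  )
  c(list(distribution = spec$type), hp)
}

prior_from_list <- function(x) {
  switch(x$distribution,
    exponential = prior_exponential(x$rate),
    normal = prior_normal(x$mean, x$sd),
    truncated_normal = prior_truncated_normal(x$mean, x$sd, x$lower, x$upper),
    uniform = prior_uniform(x$lower, x$upper),
    fixed = prior_fixed(x$value),
    abort(sprintf("Unknown prior distribution '%s'.", x$distribution))
  )
}

#' Write / read an experiment design as YAML
#'
#' Serialises every field of an [experiment_design()] (model, window,
#' condition table, priors, MCMC settings) to a plain hierarchical text
#' file and reads it back; the round trip reproduces the design.
#'
#' @param design An `experiment_design`.
#' @param path File path.
#' @return `write_design()` returns `path` invisibly; `read_design()`
#'   returns the design.
#' @export
write_design <- function(design, path) {
  obj <- list(
    model = design$model, a = design$a, b = design$b,
    settings = lapply(seq_len(nrow(design$settings)), function(i)
      as.list(design$settings[i, ])),
    n_dates = design$n_dates, lab_error = design$lab_error,
    n_rep = design$n_rep,
    priors = lapply(design$priors, prior_to_list),
    config = unclass(design$config)[c("n_chains", "n_iter", "burnin",
                                      "thin", "target_accept",
                                      "adapt_interval")]
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  obj <- yaml::read_yaml(path)
  experiment_design(
    model = obj$model, a = obj$a, b = obj$b,
    settings = purrr::map_dfr(obj$settings, as_tibble),
    n_dates = obj$n_dates, lab_error = obj$lab_error, n_rep = obj$n_rep,
    priors = lapply(obj$priors, prior_from_list),
    config = do.call(mcmc_config, obj$config)
  )
}
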