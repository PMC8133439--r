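# Calibration of radiocarbon determinations to probability masses on the
# calendar grid, back-calibration (simulating 14C ages from calendar dates),
# SPD aggregation, and the window-membership filter used for sample selection.

check_dates_df <- function(dates) {
  need <- c("c14age", "error")
  if (!all(need %in% names(dates))) {
    abort("`dates` needs columns `c14age` and `error` (optionally `labcode`, `site`).")
  }
  if (any(!is.finite(dates$c14age))) abort("`c14age` must be finite.")
  if (any(dates$error <= 0)) abort("`error` (1-sigma lab error) must be > 0.")
  if (!("labcode" %in% names(dates))) {
    dates$labcode <- paste0("S", seq_len(nrow(dates)))
  }
  dates
}

#' Read a table of radiocarbon determinations from CSV
#'
#' Expects a header with columns `labcode`, `c14age`, `error` and optionally
#' `site`.
#'
#' @param path CSV file path.
#' @return A tibble with one row per determination.
#' @export
read_c14_csv <- function(path) {
  dates <- readr::read_csv(path, show_col_types = FALSE)
  check_dates_df(dates)
}

#' Combined measurement error at a calendar year
#'
#' The standard deviation in Eq. X_j ~ Normal(mu(theta_j), sigma_j) combines
#' the lab error and the calibration-curve error in quadrature:
#' sqrt(sigma_lab^2 + tau(t)^2).
#'
#' @param curve A gridded `cal_curve`.
#' @param t Calendar year(s) on the curve grid (cal BP).
#' @param sigma_lab 1-sigma lab error (14C yr).
#' @return Combined sigma in 14C years, vectorised over `t`.
#' @examples
#' g <- synth_curve("identity", 6000, 4000, tau0 = 4)
#' combined_sigma(g, 5000, sigma_lab = 3) # 5
#' @export
combined_sigma <- function(curve, t, sigma_lab) {
  i <- match(t, curve$calbp)
  if (anyNA(i)) abort("`t` must lie on the curve grid.")
  sqrt(sigma_lab^2 + curve$tau[i]^2)
}

# log-density matrix of observed ages x (length n) over the grid of `curve`
# rows = dates, cols = grid years (descending calbp)
loglik_grid_matrix <- function(x, sigma_lab, curve) {
  s2 <- outer(sigma_lab^2, curve$tau^2, "+")
  dnorm(x, mean = matrix(curve$mu, length(x), nrow(curve), byrow = TRUE),
        sd = sqrt(s2), log = TRUE)
}

#' Calibrate a radiocarbon determination
#'
#' Converts an observed 14C age and lab error into a probability mass over
#' calendar years in `[b, a]`: mass(t) is proportional to the Normal density
#' of `c14age` at mean mu(t) and standard deviation
#' sqrt(error^2 + tau(t)^2), normalised to sum to 1 over the window.
#'
#' @param c14age Observed 14C age (BP).
#' @param error 1-sigma lab error (14C yr), > 0.
#' @param curve A `cal_curve` (gridded over the window if already at 1-yr
#'   resolution, otherwise gridded internally).
#' @param a,b Analysis window in cal BP (`a` older). Defaults to the curve
#'   span when the curve is already gridded.
#' @return A `cal_date` tibble with columns `calbp` (descending) and `mass`.
#' @examples
#' g <- synth_curve("identity", 6000, 4000, tau0 = 0)
#' d <- calibrate_date(5000, 20, g)
#' sum(d$mass) # 1
#' @export
calibrate_date <- function(c14age, error, curve, a = NULL, b = NULL) {
  if (length(c14age) != 1) abort("`calibrate_date` calibrates one date; see `calibrate()`.")
  if (error <= 0) abort("`error` must be > 0.")
  a <- a %||% max(curve$calbp)
  b <- b %||% min(curve$calbp)
  g <- ensure_grid(curve, a, b)
  dens <- dnorm(c14age, mean = g$mu, sd = sqrt(error^2 + g$tau^2))
  tot <- sum(dens)
  if (tot == 0) {
    abort("All calibrated densities underflow to 0: date lies far outside the window.")
  }
  out <- tibble(calbp = g$calbp, mass = dens / tot)
  class(out) <- c("cal_date", class(out))
  out
}

#' Calibrate a table of determinations on a shared grid
#'
#' Data-frame-first companion to [calibrate_date()]: calibrates every row of
#' `dates` over one shared calendar grid, which is what SPDs and the
#' likelihood machinery need.
#'
#' @param dates Tibble with columns `c14age`, `error` (and optionally
#'   `labcode`, `site`).
#' @param curve A `cal_curve`.
#' @param a,b Analysis window in cal BP.
#' @return A `cal_dates` object: list with the shared `grid` (cal BP,
#'   descending), a dates-by-years `mass` matrix (rows sum to 1), and the
#'   input `meta`. `tidy()` returns it in long form.
#' @export
calibrate <- function(dates, curve, a = NULL, b = NULL) {
  dates <- check_dates_df(dates)
  a <- a %||% max(curve$calbp)
  b <- b %||% min(curve$calbp)
  g <- ensure_grid(curve, a, b)
  ll <- loglik_grid_matrix(dates$c14age, dates$error, g)
  mx <- apply(ll, 1, max)
  w <- exp(ll - mx)
  tot <- rowSums(w)
  bad <- !is.finite(mx) | tot == 0
  if (any(bad)) {
    abort(sprintf("Date(s) %s: calibrated mass underflows over the window.",
                  paste(dates$labcode[bad], collapse = ", ")))
  }
  structure(
    list(grid = g$calbp, mass = w / tot, meta = as_tibble(dates), curve = g),
    class = "cal_dates"
  )
}

#' @export
print.cal_dates <- function(x, ...) {
  cat(sprintf("<cal_dates> %d dates on %s to %s cal BP\n",
              nrow(x$mass), max(x$grid), min(x$grid)))
  invisible(x)
}

#' @export
tidy.cal_dates <- function(x, ...) {
  n <- nrow(x$mass)
  tibble(
    labcode = rep(x$meta$labcode, each = length(x$grid)),
    calbp = rep(x$grid, times = n),
    mass = as.vector(t(x$mass))
  )
}

#' Simulate a 14C age from a calendar date (back-calibration)
#'
#' Draws X ~ Normal(mu(t), sqrt(tau(t)^2 + sigma_lab^2)) — the single-Normal
#' equivalent of drawing the curve value first and adding measurement noise.
#'
#' @param t Calendar year(s) on the curve grid (cal BP).
#' @param curve A gridded `cal_curve`.
#' @param sigma_lab 1-sigma lab error, recycled against `t`.
#' @param seed Optional seed applied locally for a reproducible draw.
#' @return Simulated 14C age(s), one per element of `t`.
#' @export
uncalibrate <- function(t, curve, sigma_lab, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  i <- match(t, curve$calbp)
  if (anyNA(i)) abort("`t` must lie on the curve grid.")
  rnorm(length(t), mean = curve$mu[i], sd = sqrt(curve$tau[i]^2 + sigma_lab^2))
}

#' Summed probability distribution of calibrated dates
#'
#' @param dates A `cal_dates` object ([calibrate()]) or a list of `cal_date`
#'   tibbles sharing one grid.
#' @param normalize If `TRUE` the summed density is divided by the number of
#'   dates so it integrates to 1; otherwise it integrates to n.
#' @return An `spd_grid` tibble with columns `calbp`, `density`; the number
#'   of aggregated dates is in `attr(, "n")`.
#' @export
spd <- function(dates, normalize = FALSE) {
  if (inherits(dates, "cal_dates")) {
    grid <- dates$grid
    dens <- colSums(dates$mass)
    n <- nrow(dates$mass)
  } else {
    grids <- lapply(dates, `[[`, "calbp")
    if (!all(vapply(grids, identical, logical(1), y = grids[[1]]))) {
      abort("All calibrated dates must share one calendar grid.")
    }
    grid <- grids[[1]]
    dens <- Reduce(`+`, lapply(dates, `[[`, "mass"))
    n <- length(dates)
  }
  if (normalize) dens <- dens / n
  out <- tibble(calbp = grid, density = dens)
  class(out) <- c("spd_grid", class(out))
  attr(out, "n") <- n
  attr(out, "normalized") <- normalize
  out
}

#' Window-membership filter for sample selection
#'
#' Treating the analysis window as fixed boundaries means only samples whose
#' true calendar date plausibly falls inside `[b, a]` should enter the
#' likelihood. Each date is calibrated over the FULL span of the calibration
#' curve and kept when its cumulative calibrated probability inside the
#' window is at least `threshold` (dates strictly below the threshold are
#' excluded).
#'
#' @param dates Tibble with columns `c14age`, `error` (optionally `labcode`).
#' @param curve A `cal_curve` spanning at least the window.
#' @param a,b Window in cal BP (`a` older).
#' @param threshold Minimum in-window calibrated mass, in (0, 1]; default 0.5.
#' @return The input tibble with added columns `in_window` (cumulative mass
#'   inside the window) and `kept`; filter on `kept` to obtain the analysis
#'   set.
#' @export
window_filter <- function(dates, curve, a, b, threshold = 0.5) {
  if (threshold <= 0 || threshold > 1) abort("`threshold` must be in (0, 1].")
  dates <- check_dates_df(dates)
  full <- ensure_grid(curve, max(curve$calbp), min(curve$calbp))
  cal <- calibrate(dates, full)
  inside <- full$calbp <= a & full$calbp >= b
  in_window <- as.vector(cal$mass %*% as.numeric(inside))
  dplyr::mutate(as_tibble(dates),
                in_window = in_window,
                kept = in_window >= threshold)
}
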