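# Calibration curves: reading the standard .14c distribution format, gridding
# to yearly resolution, and synthesising curves for simulation studies.

new_cal_curve <- function(calbp, mu, tau, gridded = FALSE) {
  out <- tibble(calbp = calbp, mu = mu, tau = tau)
  class(out) <- c("cal_curve", class(out))
  attr(out, "gridded") <- gridded
  out
}

validate_cal_curve <- function(curve) {
  if (!all(c("calbp", "mu", "tau") %in% names(curve))) {
    abort("A calibration curve needs columns `calbp`, `mu`, `tau`.")
  }
  if (nrow(curve) < 2) abort("A calibration curve needs at least 2 rows.")
  if (anyDuplicated(curve$calbp)) abort("Duplicated `calbp` values in curve.")
  if (any(curve$tau < 0)) abort("Curve errors `tau` must be >= 0.")
  invisible(curve)
}

#' Read a calibration curve in the `.14c` distribution format
#'
#' Parses the comma-separated format in which radiocarbon calibration curves
#' (e.g. IntCal20) are distributed: `#`-prefixed comment header, then data
#' lines with at least three numeric columns (CAL BP, 14C age BP, 1-sigma
#' curve error); any further columns are ignored.
#'
#' @param source Path to a `.14c` file, or a character vector of lines.
#' @return A `cal_curve` tibble with columns `calbp`, `mu`, `tau`, sorted
#'   oldest-first (decreasing `calbp`).
#' @examples
#' lines <- c("# toy curve", "6000,5200,20", "4000,3600,15")
#' read_calcurve(lines)
#' @seealso [grid_curve()], [synth_curve()], [write_calcurve()]
#' @export
read_calcurve <- function(source) {
  lines <- if (length(source) == 1L && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    as.character(source)
  }
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) < 2) {
    abort("Calibration curve has fewer than 2 data rows.")
  }
  parse_row <- function(i) {
    fields <- strsplit(trimws(lines[i]), "\\s*,\\s*")[[1]]
    if (length(fields) < 3) {
      abort(sprintf("Line %d: expected at least 3 comma-separated fields.", i))
    }
    vals <- suppressWarnings(as.numeric(fields[1:3]))
    if (anyNA(vals)) {
      abort(sprintf("Line %d: malformed numeric field in '%s'.", i, lines[i]))
    }
    vals
  }
  m <- vapply(idx, parse_row, numeric(3))
  curve <- new_cal_curve(calbp = m[1, ], mu = m[2, ], tau = m[3, ])
  validate_cal_curve(curve)
  dplyr::arrange(curve, dplyr::desc(.data$calbp))
}

#' Write a calibration curve in the `.14c` dialect
#'
#' @param curve A `cal_curve`.
#' @param path Output file path.
#' @param comment Header comment line(s), written with a `#` prefix.
#' @return `path`, invisibly.
#' @export
write_calcurve <- function(curve, path, comment = "calibration curve") {
  validate_cal_curve(curve)
  hdr <- paste0("# ", comment)
  rows <- sprintf("%.15g,%.15g,%.15g", curve$calbp, curve$mu, curve$tau)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Interpolate a calibration curve to a yearly grid
#'
#' Linearly interpolates both the 14C age `mu` and the curve error `tau`
#' between the published knots, returning one row per calendar year from `a`
#' (older) down to `b` (younger). The discrete-time likelihood works on this
#' 1-year grid.
#'
#' @param curve A `cal_curve`.
#' @param a,b Window bounds in cal BP, `a > b`; both must lie within the
#'   span of `curve`.
#' @return A gridded `cal_curve` with `a - b + 1` rows, `calbp` descending.
#' @examples
#' curve <- read_calcurve(c("#", "6000,5200,20", "4000,3600,15"))
#' g <- grid_curve(curve, 6000, 4000)
#' g[g$calbp == 5000, ] # mu 4400, tau 17.5
#' @export
grid_curve <- function(curve, a, b) {
  validate_cal_curve(curve)
  if (a <= b) abort("`a` must be older (larger) than `b`.")
  span <- range(curve$calbp)
  if (a > span[2] || b < span[1]) {
    abort(sprintf("Window [%s, %s] outside curve span [%s, %s].",
                  b, a, span[1], span[2]))
  }
  grid <- seq(a, b, by = -1)
  ord <- order(curve$calbp)
  mu <- stats::approx(curve$calbp[ord], curve$mu[ord], xout = grid)$y
  tau <- stats::approx(curve$calbp[ord], curve$tau[ord], xout = grid)$y
  new_cal_curve(calbp = grid, mu = mu, tau = tau, gridded = TRUE)
}

is_gridded <- function(curve) isTRUE(attr(curve, "gridded"))

# grid a curve over [b, a] unless it already is that exact grid
ensure_grid <- function(curve, a, b) {
  if (is_gridded(curve) &&
      nrow(curve) == a - b + 1 &&
      curve$calbp[1] == a && curve$calbp[nrow(curve)] == b) {
    return(curve)
  }
  grid_curve(curve, a, b)
}

#' Synthesise a calibration curve for simulation studies
#'
#' Generates deterministic synthetic calibration curves used in place of a
#' published curve for download-free tests and simulation experiments. Shapes:
#'
#' * `identity`: mu(t) = t — calibration becomes analytically tractable.
#' * `linear`: mu(t) = alpha + beta * t.
#' * `plateau`: identity outside `[from, to]`, constant `level` inside —
#'   emulates a calibration plateau (information loss).
#' * `steep`: identity outside `[from, to]`, slope `slope` (> 1) inside,
#'   with continuous matching at the boundaries.
#' * `wiggle`: identity plus a smooth oscillation of amplitude `amplitude`
#'   and period `period` years.
#'
#' All shapes carry a constant curve error `tau0`.
#'
#' @param kind One of `"identity"`, `"linear"`, `"plateau"`, `"steep"`,
#'   `"wiggle"`.
#' @param a,b Span in cal BP (`a` older).
#' @param tau0 Constant 1-sigma curve error (14C yr), >= 0.
#' @param params Named list of shape parameters: `alpha`, `beta` (linear);
#'   `from`, `to`, `level` (plateau); `from`, `to`, `slope` (steep);
#'   `amplitude`, `period` (wiggle).
#' @param seed Optional seed; the curves are deterministic in their
#'   parameters, so this only fixes the RNG state for API symmetry with the
#'   samplers.
#' @return A gridded `cal_curve` at 1-year resolution over `[b, a]`.
#' @examples
#' synth_curve("identity", 6000, 4000, tau0 = 0)
#' @export
synth_curve <- function(kind, a, b, tau0 = 20, params = list(), seed = NULL) {
  if (a <= b) abort("`a` must be older (larger) than `b`.")
  if (tau0 < 0) abort("`tau0` must be >= 0.")
  if (!is.null(seed)) withr::local_seed(seed)
  t <- seq(a, b, by = -1)
  mu <- switch(kind,
    identity = t,
    linear = {
      alpha <- params$alpha %||% 0
      beta <- params$beta %||% 1
      alpha + beta * t
    },
    plateau = {
      from <- params$from %||% abort("plateau needs `from`.")
      to <- params$to %||% abort("plateau needs `to`.")
      level <- params$level %||% mean(c(from, to))
      out <- as.numeric(t)
      inside <- t >= min(from, to) & t <= max(from, to)
      out[inside] <- level
      out
    },
    steep = {
      from <- params$from %||% abort("steep needs `from`.")
      to <- params$to %||% abort("steep needs `to`.")
      slope <- params$slope %||% 3
      if (abs(slope) <= 1) abort("steep segment needs |slope| > 1.")
      lo <- min(from, to); hi <- max(from, to)
      out <- as.numeric(t)
      inside <- t >= lo & t <= hi
      out[inside] <- hi + slope * (t[inside] - hi)
      below <- t < lo
      out[below] <- t[below] + (hi + slope * (lo - hi) - lo)
      out
    },
    wiggle = {
      amplitude <- params$amplitude %||% 30
      period <- params$period %||% 200
      t + amplitude * sin(2 * pi * t / period)
    },
    abort(sprintf("Unknown curve kind '%s'.", kind))
  )
  new_cal_curve(calbp = t, mu = mu, tau = rep(tau0, length(t)), gridded = TRUE)
}

#' @export
print.cal_curve <- function(x, ...) {
  cat(sprintf("<cal_curve> %d knots, %s to %s cal BP%s\n",
              nrow(x), max(x$calbp), min(x$calbp),
              if (is_gridded(x)) " (1-yr grid)" else ""))
  NextMethod()
}
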