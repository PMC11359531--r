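#' Ordered time-value profile
#'
#' The backbone container for dissolution and plasma concentration data: an
#' ordered series of sampling times with one value per time, a declared value
#' kind and a declared time unit. Times must be strictly increasing and
#' non-negative; values must be finite. Fraction-kind profiles (cumulative
#' dissolution, cumulative absorption) may overshoot 1 slightly because of
#' assay noise; values above 1.05 are flagged with a warning rather than
#' rejected.
#'
#' @param times numeric vector of sampling times, non-negative, strictly
#'   increasing.
#' @param values numeric vector, same length as `times`. Finite.
#' @param kind one of `"fraction"` (unitless cumulative fraction),
#'   `"concentration"` (ng/mL), `"amount"` (ug).
#' @param unit time unit, `"minutes"` or `"hours"`. The package works in
#'   minutes internally; hours appear at I/O and in reported dissolution
#'   parameters.
#' @param label free-text label (component name, medium, route, ...).
#' @return An object of class `time_profile`: a list with elements `times`,
#'   `values`, `kind`, `unit`, `label`.
#' @examples
#' tp <- time_profile(c(0, 30, 60), c(0, 0.4, 0.8), kind = "fraction")
#' resample(tp, 15)
#' @export
time_profile <- function(times, values,
                         kind = c("concentration", "fraction", "amount"),
                         unit = c("minutes", "hours"),
                         label = "") {
  kind <- match.arg(kind)
  unit <- match.arg(unit)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("`times` and `values` must have the same length", call. = FALSE)
  }
  if (anyNA(times) || any(times < 0)) {
    stop("times must be non-negative and non-missing", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("values must be finite", call. = FALSE)
  }
  if (kind == "fraction" && any(values > 1.05)) {
    warning("fraction-kind profile '", label, "' exceeds 1.05 (max ",
            format(max(values), digits = 4), "); check assay scaling",
            call. = FALSE)
  }
  structure(list(times = times, values = values, kind = kind,
                 unit = unit, label = label),
            class = "time_profile")
}

#' @export
print.time_profile <- function(x, ...) {
  cat(sprintf("<time_profile> %s [%s, %s], %d points, t in [%g, %g]\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              x$kind, x$unit, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' @export
as.data.frame.time_profile <- function(x, ...) {
  data.frame(time = x$times, value = x$values)
}

#' Interpolate a profile onto a new time grid
#'
#' Interpolation never extrapolates: every requested time must lie inside the
#' observed range. Monotone piecewise-cubic interpolation (`pchip`) is the
#' default for cumulative (fraction) profiles because it cannot overshoot and
#' preserves monotonicity; linear is the default for concentration profiles.
#' Input knots are reproduced exactly by both methods.
#'
#' @param profile a [time_profile()].
#' @param grid numeric vector of times (same unit as `profile`) within
#'   `range(profile$times)`.
#' @param method `"linear"` or `"pchip"`; if missing, chosen from the profile
#'   kind (`pchip` for fractions, linear otherwise).
#' @return A [time_profile()] on `grid`.
#' @export
resample <- function(profile, grid, method = NULL) {
  stopifnot(inherits(profile, "time_profile"))
  if (length(profile$times) < 2) {
    stop("resample needs a profile with at least 2 points", call. = FALSE)
  }
  if (is.null(method)) {
    method <- if (profile$kind == "fraction") "pchip" else "linear"
  }
  method <- match.arg(method, c("linear", "pchip"))
  grid <- as.numeric(grid)
  lo <- min(profile$times); hi <- max(profile$times)
  bad <- grid < lo | grid > hi
  if (any(bad)) {
    stop(sprintf(
      "resample: time %g outside observed range [%g, %g]; extrapolation is not supported",
      grid[which(bad)[1]], lo, hi), call. = FALSE)
  }
  if (length(profile$times) < 3) method <- "linear"  # pchip needs 3 knots
  vals <- if (method == "linear") {
    stats::approx(profile$times, profile$values, xout = grid, ties = "ordered")$y
  } else {
    pracma::pchip(profile$times, profile$values, grid)
  }
  # exactness on knots regardless of interpolant arithmetic
  knot <- match(grid, profile$times)
  hit <- !is.na(knot)
  vals[hit] <- profile$values[knot[hit]]
  time_profile(grid, vals, kind = profile$kind, unit = profile$unit,
               label = profile$label)
}

#' Convert the time unit of a profile
#'
#' @param profile a [time_profile()].
#' @param to `"minutes"` or `"hours"`.
#' @return The profile with times rescaled (values untouched). A no-op when
#'   already in the requested unit.
#' @export
convert_time_units <- function(profile, to = c("minutes", "hours")) {
  stopifnot(inherits(profile, "time_profile"))
  to <- match.arg(to)
  if (identical(profile$unit, to)) return(profile)
  f <- if (to == "hours") 1 / 60 else 60
  out <- profile
  out$times <- profile$times * f
  out$unit <- to
  out
}

# trapezoidal AUC over observed points; shared by NCA and deconvolution
trapz_auc <- function(times, values) {
  if (length(times) < 2) return(0)
  sum(diff(times) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}
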