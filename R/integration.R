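#' Content-based weight coefficients
#'
#' For components sharing a BCS class, the integration weight of each
#' component is its tablet content over the total content:
#' Wi = Ni / sum(N). Weights sum to 1.
#'
#' @param contents named numeric vector/map of per-tablet contents, mg; all
#'   positive.
#' @return Named numeric vector of weights.
#' @examples
#' weight_coefficients(c(protopin = 0.1742, thp = 0.3017))
#' @export
weight_coefficients <- function(contents) {
  contents <- unlist(contents)
  if (length(contents) == 0) stop("empty contents map", call. = FALSE)
  if (any(contents <= 0)) stop("contents must be > 0", call. = FALSE)
  contents / sum(contents)
}

#' Integrate dissolution profiles of one BCS class
#'
#' The class-level cumulative dissolution is the pointwise convex combination
#' Ct = sum_i Wi * Ci(t) on a shared time grid.
#'
#' @param profiles named list of fraction-kind [time_profile()]s on the same
#'   grid (use [resample()] first if needed).
#' @param weights named weights from [weight_coefficients()]; must cover
#'   every profile and sum to 1.
#' @return A fraction-kind [time_profile()].
#' @export
integrate_dissolution <- function(profiles, weights) {
  check_shared_grid(profiles)
  if (!all(names(profiles) %in% names(weights))) {
    stop("weights missing for: ",
         paste(setdiff(names(profiles), names(weights)), collapse = ", "),
         call. = FALSE)
  }
  w <- weights[names(profiles)]
  if (abs(sum(w) - 1) > 1e-12) stop("weights must sum to 1", call. = FALSE)
  vals <- Reduce(`+`, Map(function(p, wi) wi * p$values, profiles, w))
  time_profile(profiles[[1]]$times, vals, kind = "fraction",
               unit = profiles[[1]]$unit, label = "integrated dissolution")
}

#' Integrate plasma concentrations of one BCS class
#'
#' The class-level plasma profile is the unweighted pointwise sum
#' CT = sum_j Cj(t) of the member components' concentrations at each sampling
#' time. An optional weights argument (defaulting to 1 per member) is
#' provided for custom weighting schemes.
#'
#' @param profiles named list of concentration-kind [time_profile()]s on the
#'   same grid.
#' @param weights optional named multipliers (default 1 for each member).
#' @return A concentration-kind [time_profile()].
#' @export
integrate_concentrations <- function(profiles, weights = NULL) {
  check_shared_grid(profiles)
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, length(profiles)), names(profiles))
  }
  w <- weights[names(profiles)]
  vals <- Reduce(`+`, Map(function(p, wi) wi * p$values, profiles, w))
  time_profile(profiles[[1]]$times, vals, kind = "concentration",
               unit = profiles[[1]]$unit, label = "integrated concentration")
}

check_shared_grid <- function(profiles) {
  if (length(profiles) == 0) stop("no profiles supplied", call. = FALSE)
  ref <- profiles[[1]]$times
  for (nm in names(profiles)) {
    if (!isTRUE(all.equal(profiles[[nm]]$times, ref, tolerance = 1e-9))) {
      stop("profile '", nm, "' is not on the shared time grid; resample first",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}
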