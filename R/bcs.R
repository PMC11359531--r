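#' Dose number
#'
#' The dose number D0 relates the highest single-administration dose to
#' aqueous solubility: D0 = (M0/V0)/Cs, where M0 is the maximum dose, V0 the
#' volume of water taken with the dose (250 mL by convention), and Cs the
#' solubility in the medium of interest. A compound with D0 <= 1 in all
#' required media is classified highly soluble.
#'
#' @param m0 maximum dose, mg.
#' @param v0 volume, mL (default 250).
#' @param cs solubility, mg/mL; must be > 0.
#' @return Unitless dose number.
#' @examples
#' dose_number(m0 = 0.00418 * 250, cs = 0.535)  # 0.007813
#' @export
dose_number <- function(m0, v0 = 250, cs) {
  if (any(m0 <= 0) || any(v0 <= 0)) stop("m0 and v0 must be > 0", call. = FALSE)
  if (any(cs <= 0)) stop("cs must be > 0 (insoluble input)", call. = FALSE)
  (m0 / v0) / cs
}

#' Apparent permeability coefficient from transwell transport data
#'
#' Peff = (dQ/dt) / (A * C0), with dQ/dt the slope of cumulative amount
#' transported to the receiver side versus time (replacement-corrected),
#' A the insert membrane area and C0 the initial donor concentration.
#' Permeability above 1e-6 cm/s is counted as high.
#'
#' Either pass a precomputed slope `dq_dt`, or receiver-side observations
#' `times`/`amounts` from which the slope is estimated by ordinary least
#' squares.
#'
#' @param dq_dt amount transported per unit time (amount/min). Optional if
#'   `times` and `amounts` are given.
#' @param times,amounts receiver-side sampling times (min) and cumulative
#'   transported amounts; at least 2 points.
#' @param area membrane area, cm^2 (0.33 for the 24-well insert used here).
#' @param c0 initial donor concentration, amount/mL; must be > 0.
#' @return List with `peff` (cm/s, using seconds in the denominator when
#'   `times` are minutes) and `class` (`"high"`/`"low"`).
#' @export
apparent_permeability <- function(dq_dt = NULL, times = NULL, amounts = NULL,
                                  area = 0.33, c0) {
  if (area <= 0) stop("area must be > 0", call. = FALSE)
  if (c0 <= 0) stop("c0 must be > 0", call. = FALSE)
  if (is.null(dq_dt)) {
    if (is.null(times) || length(times) < 2) {
      stop("need at least 2 receiver time points to estimate dQ/dt",
           call. = FALSE)
    }
    dq_dt <- unname(stats::coef(stats::lm(amounts ~ times))[2])
  }
  peff <- dq_dt / (area * c0) / 60  # per-minute slope -> cm/s
  list(peff = peff, class = if (peff > 1e-6) "high" else "low")
}

#' BCS class from solubility and permeability
#'
#' Computes the dose number per medium (phosphate pH 6.8, acetate pH 4.5,
#' 0.1 M HCl pH 1.2) and against the minimum solubility across those media
#' (the conservative rule used for the final class), then crosses the
#' solubility class with the permeability class:
#' I = high/high, II = low solubility/high permeability,
#' III = high solubility/low permeability, IV = low/low.
#'
#' @param spec a [component_spec()] with solubilities for `HCl_0.1M`,
#'   `acetate_pH4.5` and `phosphate_pH6.8`, and a `peff`.
#' @param peff_threshold high-permeability cutoff, cm/s (default 1e-6).
#' @return An object of class `bcs_result`: list with `d0_by_medium`,
#'   `d0_min_solubility`, `peff`, `solubility_class`, `permeability_class`,
#'   `bcs_class`, and `censored` flags carried through from the spec.
#' @export
classify_bcs <- function(spec, peff_threshold = 1e-6) {
  stopifnot(inherits(spec, "component_spec"))
  required <- c("HCl_0.1M", "acetate_pH4.5", "phosphate_pH6.8")
  missing <- setdiff(required, names(spec$solubilities))
  if (length(missing)) {
    stop("missing solubilities for media: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sol <- spec$solubilities[required]
  d0 <- (spec$m0_over_v0) / sol
  d0_min <- spec$m0_over_v0 / min(sol)
  sol_class <- if (all(d0 <= 1)) "high" else "low"
  perm_class <- if (spec$peff > peff_threshold) "high" else "low"
  bcs <- if (sol_class == "high" && perm_class == "high") "I"
  else if (sol_class == "low" && perm_class == "high") "II"
  else if (sol_class == "high") "III"
  else "IV"
  structure(list(component = spec$name, d0_by_medium = d0,
                 d0_min_solubility = d0_min, peff = spec$peff,
                 solubility_class = sol_class,
                 permeability_class = perm_class, bcs_class = bcs,
                 censored = intersect(spec$censored, required)),
            class = "bcs_result")
}

#' @export
print.bcs_result <- function(x, ...) {
  cat(sprintf("<bcs_result> %s: BCS %s (solubility %s, permeability %s); D0(min Cs) = %.4g%s\n",
              x$component, x$bcs_class, x$solubility_class,
              x$permeability_class, x$d0_min_solubility,
              if (length(x$censored)) " [censored solubility bound used]" else ""))
  invisible(x)
}
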