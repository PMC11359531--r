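#' Non-compartmental analysis of a concentration-time profile
#'
#' Model-free PK metrics: Cmax/Tmax read off the observed points, AUC0-t by
#' the linear trapezoidal rule, the terminal rate constant lambda_z by
#' log-linear regression over the terminal window (chosen among candidate
#' windows of >= 3 post-Tmax points by best adjusted R-squared),
#' t1/2 = ln(2)/lambda_z, and AUC0-inf = AUC0-t + Clast/lambda_z. When no
#' terminal window is estimable the extrapolated quantities are reported as
#' `NA` rather than guessed.
#'
#' When the first sample is taken after time zero, the AUC is anchored at
#' t = 0 in the conventional way: an oral profile starts at C(0) = 0, an IV
#' bolus profile is back-extrapolated to C0 from the log-linear slope of the
#' first two positive samples. Cmax and Tmax are always read off the observed
#' samples, never the anchor point.
#'
#' @param profile concentration-kind [time_profile()] in minutes, with at
#'   least 3 positive concentrations.
#' @param dose administered dose, ug (carried into the result for
#'   dose-normalised comparisons).
#' @param route `"oral"` or `"iv"`.
#' @return Object of class `nca_result`: `cmax` (ng/mL), `tmax` (min),
#'   `auc_0_t`, `auc_0_inf` (ng*min/mL), `lambda_z` (1/min), `t_half` (min),
#'   `dose`, `route`, `n_lambda_points`.
#' @export
nca <- function(profile, dose = NA_real_, route = c("oral", "iv")) {
  stopifnot(inherits(profile, "time_profile"))
  route <- match.arg(route)
  t <- profile$times; y <- profile$values
  if (sum(y > 0) < 3) {
    stop("NCA needs at least 3 positive concentrations", call. = FALSE)
  }
  imax <- which.max(y)
  cmax <- y[imax]; tmax <- t[imax]
  ta <- t; ya <- y
  if (min(t) > 0) {
    c0 <- 0
    if (route == "iv") {
      ip <- which(y > 0)[1:2]
      c0 <- if (y[ip[2]] < y[ip[1]]) {
        sl <- (log(y[ip[2]]) - log(y[ip[1]])) / (t[ip[2]] - t[ip[1]])
        y[ip[1]] * exp(-sl * t[ip[1]])
      } else y[ip[1]]
    }
    ta <- c(0, t); ya <- c(c0, y)
  }
  auc_t <- trapz_auc(ta, ya)

  lz <- lambda_z(t, y, imax)
  auc_inf <- if (is.na(lz$lambda)) NA_real_ else auc_t + y[length(y)] / lz$lambda
  structure(list(cmax = cmax, tmax = tmax, auc_0_t = auc_t,
                 auc_0_inf = auc_inf, lambda_z = lz$lambda,
                 t_half = if (is.na(lz$lambda)) NA_real_ else log(2) / lz$lambda,
                 n_lambda_points = lz$n, dose = dose, route = route),
            class = "nca_result")
}

# terminal slope: best adjusted R^2 over windows of >=3 points after Cmax
lambda_z <- function(t, y, imax) {
  cand <- which(seq_along(t) > imax & y > 0)
  if (length(cand) < 3) return(list(lambda = NA_real_, n = 0L))
  best <- list(lambda = NA_real_, n = 0L)
  best_ar2 <- -Inf
  for (k in 3:length(cand)) {
    idx <- utils::tail(cand, k)
    fit <- stats::lm(log(y[idx]) ~ t[idx])
    sl <- stats::coef(fit)[2]
    ar2 <- suppressWarnings(summary(fit)$adj.r.squared)
    if (!is.na(sl) && sl < 0 && ar2 > best_ar2) {
      best_ar2 <- ar2
      best <- list(lambda = unname(-sl), n = k)
    }
  }
  best
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf(
    "<nca_result> %s: Cmax %.4g ng/mL at %g min; AUC0-t %.5g; AUC0-inf %s; t1/2 %s min\n",
    x$route, x$cmax, x$tmax, x$auc_0_t,
    if (is.na(x$auc_0_inf)) "NA" else sprintf("%.5g", x$auc_0_inf),
    if (is.na(x$t_half)) "NA" else sprintf("%.4g", x$t_half)))
  invisible(x)
}

#' Absolute oral bioavailability
#'
#' F% = 100 * (AUC_po / Dose_po) / (AUC_iv / Dose_iv). Dose-corrected
#' AUC0-t values are used: that convention reproduces the study's printed
#' bioavailability figures, whereas AUC0-inf does not.
#'
#' @param auc_po,auc_iv areas under the oral and IV curves, ng*min/mL.
#' @param dose_po,dose_iv administered doses, ug; must be > 0.
#' @return Bioavailability in percent.
#' @examples
#' bioavailability(8130.23, 2500, 592.23, 19.75)  # 10.85
#' @export
bioavailability <- function(auc_po, dose_po, auc_iv, dose_iv) {
  if (any(c(dose_po, dose_iv) <= 0)) stop("doses must be > 0", call. = FALSE)
  if (any(c(auc_po, auc_iv) <= 0)) stop("AUCs must be > 0", call. = FALSE)
  100 * (auc_po / dose_po) / (auc_iv / dose_iv)
}
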