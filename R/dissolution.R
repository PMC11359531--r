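#' Cumulative dissolution from sampled concentrations
#'
#' Paddle-method sampling withdraws a volume V2 at each time point and
#' replaces it with fresh medium, so drug removed in earlier samples must be
#' added back. The cumulative dissolved fraction at the n-th sampling is
#'
#'   D_n = (C_n * V1 + V2 * sum_{i=1..n-1} C_i) / M
#'
#' with C_i the measured concentrations (mg/mL), V1 the vessel volume (mL),
#' V2 the sample volume (mL) and M the total drug content (mg). Returned as a
#' fraction; multiply by 100 at report time.
#'
#' @param times sampling times, minutes, strictly increasing.
#' @param concs measured concentrations at `times`, mg/mL, non-negative.
#' @param v1 vessel volume, mL.
#' @param v2 withdrawn/replaced volume per sample, mL.
#' @param m total drug content in the vessel, mg.
#' @param label label for the returned profile.
#' @return A fraction-kind [time_profile()]. Values above 1.05 trigger a
#'   warning (assay overshoot flag).
#' @export
cumulative_dissolution <- function(times, concs, v1, v2 = 0, m, label = "") {
  if (any(concs < 0)) stop("negative concentration", call. = FALSE)
  if (m <= 0) stop("total content m must be > 0", call. = FALSE)
  if (v2 < 0) stop("v2 must be >= 0", call. = FALSE)
  prior <- c(0, cumsum(concs)[-length(concs)])
  d <- (concs * v1 + v2 * prior) / m
  time_profile(times, d, kind = "fraction", unit = "minutes", label = label)
}

# invert cumulative fractions back to sampled concentrations (synthetic data)
concentrations_from_dissolution <- function(frac, v1, v2, m) {
  n <- length(frac)
  concs <- numeric(n)
  run <- 0
  for (i in seq_len(n)) {
    concs[i] <- (m * frac[i] - v2 * run) / v1
    run <- run + concs[i]
  }
  concs
}

#' Fit a dissolution model to a mean profile
#'
#' Least-squares fit of one of the three model families by
#' Levenberg-Marquardt with a deterministic multi-start grid:
#' time-scale starts at the empirical 25/50/75% crossing times, shape
#' starts b in {0.5, 1, 2, 4}, plateau start at the maximum observed value.
#' Parameters are reported on the hour scale (mean dissolution time MDT in
#' hours) regardless of the profile's unit.
#'
#' Diagnostics: `r` is by default the Pearson correlation of fitted versus
#' observed values (`r_method = "pearson"`); `r_method = "rsq"` gives
#' sqrt(1 - SSR/SST) instead. AIC uses the least-squares form
#' n*log(SSR/n) + 2k.
#'
#' @param profile fraction-kind [time_profile()], >= 4 points.
#' @param model `"hill"`, `"weibull"` or `"makoid_banakar"`.
#' @param finf_fixed fix the plateau at 1 instead of estimating it
#'   (default `FALSE`: observed plateaus of partially-dissolving components
#'   sit well below 1).
#' @param r_method `"pearson"` or `"rsq"`.
#' @return Object of class `dissolution_fit`: `model`, `params` (named list),
#'   `r`, `aic`, `n`, `ssr`, `finf_fixed`, plus the fitting data.
#' @export
fit_dissolution_model <- function(profile,
                                  model = c("hill", "weibull", "makoid_banakar"),
                                  finf_fixed = FALSE,
                                  r_method = c("pearson", "rsq")) {
  stopifnot(inherits(profile, "time_profile"))
  model <- match.arg(model)
  r_method <- match.arg(r_method)
  if (length(profile$times) < 4) {
    stop("need at least 4 points to fit a dissolution model", call. = FALSE)
  }
  ph <- convert_time_units(profile, "hours")
  t <- ph$times; y <- ph$values
  plateau0 <- max(y)
  # empirical times at which the curve crosses 25/50/75% of its plateau
  tq <- vapply(c(0.25, 0.5, 0.75), function(q) {
    i <- which(y >= q * plateau0)[1]
    if (is.na(i)) max(t) else t[max(i, 2)]
  }, numeric(1))
  tq <- unique(pmax(tq, 1e-3))
  b0s <- c(0.5, 1, 2, 4)

  best <- NULL
  best_ssr <- Inf
  for (t0 in tq) for (b0 in b0s) {
    start <- switch(model,
      hill = list(finf = plateau0, mdt = t0, b = b0),
      weibull = list(finf = plateau0, mdt = t0, b = b0, tlag = 0),
      makoid_banakar = list(fmax = plateau0, tmax = max(t) * 0.8, b = b0))
    lower <- switch(model,
      hill = c(finf = 1e-6, mdt = 1e-4, b = 1e-2),
      weibull = c(finf = 1e-6, mdt = 1e-4, b = 1e-2, tlag = 0),
      makoid_banakar = c(fmax = 1e-6, tmax = 1e-4, b = 1e-2))
    upper <- switch(model,
      hill = c(finf = 1.2, mdt = 100, b = 50),
      weibull = c(finf = 1.2, mdt = 100, b = 50, tlag = max(t)),
      makoid_banakar = c(fmax = 1.2, tmax = 10 * max(t), b = 50))
    if (finf_fixed && model != "makoid_banakar") {
      start$finf <- NULL
      lower <- lower[names(lower) != "finf"]
      upper <- upper[names(upper) != "finf"]
    }
    fn <- function(p) {
      pl <- as.list(p)
      if (finf_fixed && model != "makoid_banakar") pl$finf <- 1
      eval_dissolution(model, pl, t) - y
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = unlist(start), lower = lower, upper = upper,
                         fn = fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (ssr < best_ssr) { best_ssr <- ssr; best <- fit }
  }
  if (is.null(best)) {
    stop("dissolution model fit failed to converge for model '", model, "'",
         call. = FALSE)
  }
  params <- as.list(stats::coef(best))
  if (finf_fixed && model != "makoid_banakar") params$finf <- 1
  fitted <- eval_dissolution(model, params, t)
  n <- length(y)
  k <- length(stats::coef(best))
  r <- if (r_method == "pearson") {
    stats::cor(fitted, y)
  } else {
    sst <- sum((y - mean(y))^2)
    sqrt(max(0, 1 - best_ssr / sst))
  }
  structure(list(model = model, params = params, r = r,
                 aic = n * log(best_ssr / n) + 2 * k,
                 ssr = best_ssr, n = n, k = k,
                 finf_fixed = finf_fixed, r_method = r_method,
                 times_h = t, observed = y, fitted = fitted,
                 label = profile$label),
            class = "dissolution_fit")
}

#' @export
print.dissolution_fit <- function(x, ...) {
  p <- unlist(x$params)
  cat(sprintf("<dissolution_fit> %s%s: %s | R = %.4f, AIC = %.2f\n",
              x$model, if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              paste(sprintf("%s = %.4g", names(p), p), collapse = ", "),
              x$r, x$aic))
  invisible(x)
}

#' @param object a `dissolution_fit`.
#' @param t times in hours at which to evaluate the fitted model.
#' @rdname fit_dissolution_model
#' @param ... unused.
#' @export
predict.dissolution_fit <- function(object, t, ...) {
  eval_dissolution(object$model, object$params, t)
}

#' Select the best dissolution model
#'
#' The winner has the highest correlation coefficient; near-ties
#' (|delta r| < 1e-4) are broken by the smaller AIC. Deterministic.
#'
#' @param fits list of `dissolution_fit` objects on identical data.
#' @return The selected `dissolution_fit`.
#' @export
select_dissolution_model <- function(fits) {
  if (length(fits) == 0) stop("no candidate fits supplied", call. = FALSE)
  if (length(fits) == 1) return(fits[[1]])
  r <- vapply(fits, `[[`, numeric(1), "r")
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  top <- which(r > max(r) - 1e-4)
  fits[[top[which.min(aic[top])]]]
}

#' Fit all three families and select the best
#'
#' @inheritParams fit_dissolution_model
#' @param models families to try.
#' @return The winning `dissolution_fit` with an extra `candidates` attribute.
#' @export
fit_best_dissolution <- function(profile,
                                 models = c("hill", "weibull", "makoid_banakar"),
                                 finf_fixed = FALSE) {
  fits <- lapply(models, function(m)
    tryCatch(fit_dissolution_model(profile, m, finf_fixed = finf_fixed),
             error = function(e) NULL))
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("no dissolution model converged", call. = FALSE)
  best <- select_dissolution_model(fits)
  attr(best, "candidates") <- fits
  best
}
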