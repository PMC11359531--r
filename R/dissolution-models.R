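# Dissolution model families (time argument in hours).
#
# hill:            F(t) = Finf * t^b / (MDT^b + t^b)
# weibull:         F(t) = Finf * (1 - exp(-((t - tlag)/MDT)^b)),  0 for t <= tlag
# makoid_banakar:  F(t) = Fmax * (t/Tmax)^b * exp(b*(1 - t/Tmax)) for t <= Tmax,
#                  Fmax for t > Tmax
#
# All families are 0 at t = 0 and bounded by their plateau parameter
# (Finf resp. Fmax).

#' Evaluate a dissolution model
#'
#' @param model `"hill"`, `"weibull"` or `"makoid_banakar"`.
#' @param params named list/vector: `finf`, `mdt`, `b` (+ `tlag` for Weibull);
#'   `fmax`, `tmax`, `b` for Makoid-Banakar.
#' @param t times in hours; values at `t <= 0` (or before the lag) are 0.
#' @return Numeric vector of dissolved fractions.
#' @export
eval_dissolution <- function(model, params, t) {
  p <- as.list(params)
  t <- as.numeric(t)
  out <- numeric(length(t))
  pos <- t > 0
  switch(model,
    hill = {
      tb <- t[pos]^p$b
      out[pos] <- p$finf * tb / (p$mdt^p$b + tb)
    },
    weibull = {
      tlag <- if (is.null(p$tlag)) 0 else p$tlag
      on <- t > tlag
      out[on] <- p$finf * (1 - exp(-((t[on] - tlag) / p$mdt)^p$b))
    },
    makoid_banakar = {
      u <- t[pos] / p$tmax
      v <- p$fmax * u^p$b * exp(p$b * (1 - u))
      v[u > 1] <- p$fmax
      out[pos] <- v
    },
    stop("unknown dissolution model '", model, "'", call. = FALSE)
  )
  out
}

#' Analytic time-derivative of a dissolution model
#'
#' Used to form the absorption input rate for convolution-based prediction;
#' analytic rather than finite-difference so the predicted profile carries no
#' differentiation error.
#'
#' @inheritParams eval_dissolution
#' @return dF/dt in 1/hour.
#' @export
eval_dissolution_rate <- function(model, params, t) {
  p <- as.list(params)
  t <- as.numeric(t)
  out <- numeric(length(t))
  pos <- t > 0
  switch(model,
    hill = {
      tb <- t[pos]^p$b
      mb <- p$mdt^p$b
      out[pos] <- p$finf * p$b * mb * t[pos]^(p$b - 1) / (mb + tb)^2
    },
    weibull = {
      tlag <- if (is.null(p$tlag)) 0 else p$tlag
      on <- t > tlag
      u <- (t[on] - tlag) / p$mdt
      out[on] <- p$finf * (p$b / p$mdt) * u^(p$b - 1) * exp(-u^p$b)
    },
    makoid_banakar = {
      u <- t[pos] / p$tmax
      v <- p$fmax * (p$b / p$tmax) * u^(p$b - 1) * (1 - u) * exp(p$b * (1 - u))
      v[u >= 1] <- 0
      out[pos] <- v
    },
    stop("unknown dissolution model '", model, "'", call. = FALSE)
  )
  out
}
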