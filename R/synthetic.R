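#' Standard sampling grids
#'
#' Dissolution sampling grid (min): 15, 30, 45, 60, 90, 120, 180, 240, 360;
#' truncated at 180 min in gastric-residence-limited media (0.1 M HCl).
#' PK sampling grid (min): 15, 30, 45, 60, 90, 120, 150, 180, 240, 360, 480,
#' 720, 1440.
#' @name sampling_grids
NULL

#' @rdname sampling_grids
#' @param medium medium name; `HCl_0.1M` truncates the grid at 180 min.
#' @return Numeric vector of minutes.
#' @export
dissolution_grid <- function(medium = "water") {
  g <- c(15, 30, 45, 60, 90, 120, 180, 240, 360)
  if (identical(medium, "HCl_0.1M")) g[g <= 180] else g
}

#' @rdname sampling_grids
#' @export
pk_grid <- function() c(15, 30, 45, 60, 90, 120, 150, 180, 240, 360, 480,
                        720, 1440)

#' Synthetic study scenario
#'
#' Bundles the ground truth for one simulated component: a dissolution model
#' per medium, a polyexponential disposition, first-order absorption with
#' lag, absolute bioavailability, doses and tablet content, plus a
#' proportional log-normal noise model. All rates are per minute; dissolution
#' parameters are on the hour scale as reported.
#'
#' @param name component name.
#' @param dissolution named list: per-medium `list(model =, params =)`
#'   ground-truth dissolution curves (params on the hour scale).
#' @param A,alpha disposition amplitudes (ng/mL per ug) and rates (1/min).
#' @param ka first-order absorption rate, 1/min.
#' @param tlag absorption lag, min.
#' @param f absolute bioavailability, fraction.
#' @param oral_dose,iv_dose ug.
#' @param content_per_tablet mg.
#' @param cv proportional noise coefficient of variation (natural scale);
#'   assay precision in this class of UPLC-MS/MS methods runs about 1-11%,
#'   so the default is 0.10.
#' @param floor additive noise floor (value units).
#' @param n_vessels dissolution vessels (default 6).
#' @param n_subjects PK subjects (default 6).
#' @param absorption `"first_order"` (rate `ka`, lag `tlag`) or
#'   `"dissolution_limited"` (oral input rate proportional to the derivative
#'   of the ground-truth dissolution curve in `absorption_medium`, so the
#'   in vivo fraction absorbed tracks the in vitro curve with unit time
#'   scale).
#' @param absorption_medium medium whose dissolution curve drives
#'   dissolution-limited absorption (defaults to the first one).
#' @param seed integer RNG seed; every simulation from the scenario is
#'   reproducible given this seed.
#' @return Object of class `ivivc_scenario`.
#' @export
ivivc_scenario <- function(name, dissolution, A, alpha, ka, tlag = 0,
                           f = 0.1, oral_dose, iv_dose,
                           content_per_tablet = 1, cv = 0.10, floor = 0,
                           n_vessels = 6, n_subjects = 6,
                           absorption = c("first_order", "dissolution_limited"),
                           absorption_medium = NULL, seed = 1L) {
  stopifnot(all(alpha > 0), ka > 0, tlag >= 0, cv >= 0, f > 0, f <= 1)
  absorption <- match.arg(absorption)
  if (is.null(absorption_medium)) absorption_medium <- names(dissolution)[1]
  structure(list(name = name, dissolution = dissolution, A = A,
                 alpha = alpha, ka = ka, tlag = tlag, f = f,
                 oral_dose = oral_dose, iv_dose = iv_dose,
                 content_per_tablet = content_per_tablet,
                 cv = cv, floor = floor, n_vessels = n_vessels,
                 n_subjects = n_subjects, absorption = absorption,
                 absorption_medium = absorption_medium,
                 seed = as.integer(seed)),
            class = "ivivc_scenario")
}

# stable small offset so each medium/route stream is distinct but seeded
seed_offset <- function(...) {
  s <- paste(..., collapse = "|")
  sum(utf8ToInt(s)) %% 10000L
}

lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Simulate a dissolution run
#'
#' Per-vessel noisy samples of the scenario's ground-truth dissolution curve
#' on the standard sampling grid, reported as measured concentrations that
#' are consistent with the replacement-corrected cumulative-dissolution
#' formula (V1 = 900 mL, V2 = 3 mL): in the noise-free limit,
#' [cumulative_dissolution()] on the output reproduces the generating curve
#' exactly.
#'
#' @param scenario an [ivivc_scenario()] with a dissolution entry for
#'   `medium`.
#' @param medium medium name.
#' @param v1,v2 vessel and sample volumes, mL.
#' @param tablets_per_vessel tablets per vessel (default 6).
#' @return Object of class `dissolution_run`: `medium`, `component`,
#'   `m` (vessel drug content, mg), `vessels` (list of concentration
#'   [time_profile()]s), `fractions` (per-vessel cumulative fractions),
#'   `mean_profile` (fraction-kind [time_profile()]).
#' @export
simulate_dissolution <- function(scenario, medium, v1 = 900, v2 = 3,
                                 tablets_per_vessel = 6) {
  stopifnot(inherits(scenario, "ivivc_scenario"))
  gt <- scenario$dissolution[[medium]]
  if (is.null(gt)) stop("scenario has no dissolution model for medium '",
                        medium, "'", call. = FALSE)
  set.seed(scenario$seed + seed_offset("diss", scenario$name, medium))
  grid <- dissolution_grid(medium)
  truth <- eval_dissolution(gt$model, gt$params, grid / 60)
  m <- scenario$content_per_tablet * tablets_per_vessel
  vessels <- vector("list", scenario$n_vessels)
  fracs <- matrix(0, scenario$n_vessels, length(grid))
  for (v in seq_len(scenario$n_vessels)) {
    fr <- truth * lognormal_noise(length(grid), scenario$cv) +
      scenario$floor * stats::rnorm(length(grid))
    fr <- pmin(cummax(pmax(fr, 0)), 1.05)  # cumulative data are monotone
    fracs[v, ] <- fr
    vessels[[v]] <- time_profile(
      grid, concentrations_from_dissolution(fr, v1, v2, m),
      kind = "concentration",
      label = sprintf("%s/%s vessel %d", scenario$name, medium, v))
  }
  mean_fr <- colMeans(fracs)
  structure(list(medium = medium, component = scenario$name, m = m,
                 v1 = v1, v2 = v2, vessels = vessels, fractions = fracs,
                 mean_profile = time_profile(
                   grid, mean_fr, kind = "fraction",
                   label = sprintf("%s/%s mean", scenario$name, medium))),
            class = "dissolution_run")
}

#' @export
print.dissolution_run <- function(x, ...) {
  cat(sprintf("<dissolution_run> %s in %s: %d vessels, %d time points\n",
              x$component, x$medium, length(x$vessels),
              length(x$mean_profile$times)))
  invisible(x)
}

# Bateman superposition: first-order input (ka, tlag) into a polyexponential
# disposition; exact closed form, with the ka ~ alpha confluent limit
bateman <- function(t, dose_f, A, alpha, ka, tlag) {
  tau <- pmax(t - tlag, 0)
  out <- numeric(length(t))
  for (i in seq_along(A)) {
    if (is.infinite(ka)) {
      term <- A[i] * exp(-alpha[i] * tau)
    } else if (abs(ka - alpha[i]) < 1e-12 * ka) {
      term <- A[i] * ka * tau * exp(-ka * tau)
    } else {
      term <- A[i] * ka / (ka - alpha[i]) *
        (exp(-alpha[i] * tau) - exp(-ka * tau))
    }
    out <- out + term
  }
  out[t <= tlag] <- 0
  dose_f * out
}

#' Simulate plasma concentration profiles
#'
#' IV profiles are the dose-scaled polyexponential disposition; oral profiles
#' are the exact first-order-absorption (Bateman) convolution of the
#' disposition with rate `ka` and lag `tlag`, scaled by dose and absolute
#' bioavailability. Proportional log-normal noise per subject.
#'
#' @param scenario an [ivivc_scenario()].
#' @param route `"oral"` or `"iv"`.
#' @param times sampling grid, min (defaults to [pk_grid()]).
#' @return List with `subjects` (list of concentration [time_profile()]s),
#'   `mean_profile`, `truth` (noise-free profile), and `route`.
#' @export
simulate_pk <- function(scenario, route = c("oral", "iv"), times = pk_grid()) {
  stopifnot(inherits(scenario, "ivivc_scenario"))
  route <- match.arg(route)
  set.seed(scenario$seed + seed_offset("pk", scenario$name, route))
  truth <- if (route == "iv") {
    scenario$iv_dose * bateman(times, 1, scenario$A, scenario$alpha,
                               Inf, 0)
  } else if (identical(scenario$absorption, "dissolution_limited")) {
    gt <- scenario$dissolution[[scenario$absorption_medium]]
    h <- 1
    n <- ceiling(max(times) / h)
    mid <- (seq_len(n) - 0.5) * h
    plateau <- if (gt$model == "makoid_banakar") gt$params$fmax else
      gt$params$finf
    rate <- scenario$oral_dose * scenario$f / plateau / 60 *
      eval_dissolution_rate(gt$model, gt$params, mid / 60)
    convolve_staircase(rate, h, uir(scenario$A, scenario$alpha, 0), times)
  } else {
    bateman(times, scenario$oral_dose * scenario$f, scenario$A,
            scenario$alpha, scenario$ka, scenario$tlag)
  }
  subjects <- lapply(seq_len(scenario$n_subjects), function(s) {
    y <- truth * lognormal_noise(length(times), scenario$cv) +
      scenario$floor * abs(stats::rnorm(length(times)))
    time_profile(times, pmax(y, 0), kind = "concentration",
                 label = sprintf("%s %s subject %d", scenario$name, route, s))
  })
  mean_y <- Reduce(`+`, lapply(subjects, `[[`, "values")) / length(subjects)
  list(subjects = subjects,
       mean_profile = time_profile(times, mean_y, kind = "concentration",
                                   label = paste(scenario$name, route, "mean")),
       truth = time_profile(times, truth, kind = "concentration",
                            label = paste(scenario$name, route, "truth")),
       route = route)
}

#' A study-shaped default scenario set
#'
#' Five components whose ground-truth dissolution curves, disposition
#' magnitudes, doses and tablet contents follow the motivating
#' five-marker tablet study (dissolution plateaus 0.15-0.9, MDT ~1-3 h,
#' Cmax ~1-50 ng/mL,
#' biexponential disposition with rates around 0.5/0.015 per hour).
#'
#' @param seed integer seed.
#' @param cv proportional noise CV (default 0.10).
#' @return Named list of [ivivc_scenario()] objects.
#' @export
default_scenarios <- function(seed = 1L, cv = 0.10) {
  per_min <- function(x) x / 60  # rates tabulated per hour
  defs <- list(
    protopin = list(
      diss = list(
        HCl_0.1M = list(model = "weibull",
                        params = list(finf = 0.70, mdt = 1.10, b = 2.06, tlag = 0)),
        acetate_pH4.5 = list(model = "hill",
                             params = list(finf = 0.78, mdt = 1.10, b = 2.71)),
        FaSSGF = list(model = "weibull",
                      params = list(finf = 0.82, mdt = 1.00, b = 1.01, tlag = 0))),
      A = 12.44 / 168.062, alpha = per_min(1.35), ka = per_min(1.36),
      tlag = 26, f = 0.0135, oral = 1896, iv = 168.062, content = 0.1742),
    alloc = list(
      diss = list(
        HCl_0.1M = list(model = "hill",
                        params = list(finf = 0.90, mdt = 0.90, b = 5.14)),
        acetate_pH4.5 = list(model = "weibull",
                             params = list(finf = 0.86, mdt = 1.26, b = 1.97, tlag = 0)),
        FaSSGF = list(model = "hill",
                      params = list(finf = 0.76, mdt = 1.84, b = 1.38))),
      A = 32.8 / 297.16, alpha = per_min(1.13), ka = per_min(5.65),
      tlag = 40, f = 0.075, oral = 917, iv = 297.16, content = 1.1042),
    byak = list(
      diss = list(
        HCl_0.1M = list(model = "hill",
                        params = list(finf = 0.45, mdt = 1.17, b = 2.74)),
        acetate_pH4.5 = list(model = "hill",
                             params = list(finf = 0.35, mdt = 1.12, b = 2.79)),
        FaSSGF = list(model = "hill",
                      params = list(finf = 1.0, mdt = 1.68, b = 2.00))),
      A = 11.81 / 78.68, alpha = per_min(1.18), ka = per_min(2.23),
      tlag = 27, f = 0.15, oral = 2783, iv = 78.68, content = 0.0975),
    thp = list(
      diss = list(
        HCl_0.1M = list(model = "hill",
                        params = list(finf = 0.72, mdt = 0.97, b = 4.77)),
        acetate_pH4.5 = list(model = "hill",
                             params = list(finf = 0.79, mdt = 1.07, b = 2.93)),
        FaSSGF = list(model = "hill",
                      params = list(finf = 0.81, mdt = 2.27, b = 1.12))),
      A = 11.36 / 19.75, alpha = per_min(1.30), ka = per_min(1.28),
      tlag = 24, f = 0.1085, oral = 2500, iv = 19.75, content = 0.3017),
    coryd = list(
      diss = list(
        HCl_0.1M = list(model = "weibull",
                        params = list(finf = 0.79, mdt = 1.06, b = 2.00, tlag = 0)),
        acetate_pH4.5 = list(model = "weibull",
                             params = list(finf = 0.71, mdt = 1.23, b = 2.04, tlag = 0)),
        FaSSGF = list(model = "hill",
                      params = list(finf = 0.44, mdt = 3.25, b = 0.98))),
      A = 5.01 / 4.54, alpha = per_min(1.42), ka = per_min(1.46),
      tlag = 26, f = 0.0538, oral = 963, iv = 4.54, content = 0.2871))
  out <- lapply(names(defs), function(nm) {
    d <- defs[[nm]]
    ivivc_scenario(nm, d$diss, A = d$A, alpha = d$alpha, ka = d$ka,
                   tlag = d$tlag, f = d$f, oral_dose = d$oral,
                   iv_dose = d$iv, content_per_tablet = d$content,
                   cv = cv, seed = seed)
  })
  stats::setNames(out, names(defs))
}
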