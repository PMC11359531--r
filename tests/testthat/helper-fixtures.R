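# Shared fixtures, all generated in code.

# published best-fit dissolution functions used as ground truths in tests
# (time in hours, fraction dissolved)
tbl_weibull_protopin_hcl <- list(model = "weibull",
  params = list(finf = 0.70, mdt = 1.10, b = 2.06, tlag = 0))
tbl_hill_protopin_acetate <- list(model = "hill",
  params = list(finf = 0.78, mdt = 1.10, b = 2.71))
tbl_weibull_protopin_fassgf <- list(model = "weibull",
  params = list(finf = 0.82, mdt = 1.00, b = 1.01, tlag = 0))
tbl_hill_thp_acetate <- list(model = "hill",
  params = list(finf = 0.79, mdt = 1.07, b = 2.93))

diss_grid_min <- c(15, 30, 45, 60, 90, 120, 180, 240, 360)

sample_model <- function(gt, grid_min = diss_grid_min) {
  time_profile(grid_min,
               eval_dissolution(gt$model, gt$params, grid_min / 60),
               kind = "fraction")
}

# minimal dissolution_fit wrapper around known parameters (for IVIVC tests
# that start from a printed model rather than a data fit)
as_diss_fit <- function(gt, label = "") {
  structure(list(model = gt$model, params = gt$params, r = NA_real_,
                 aic = NA_real_, label = label),
            class = "dissolution_fit")
}

# one-compartment oral fixture: UIR = exp(-ke t)/V, first-order absorption
one_compartment <- function(ke = 0.01, ka = 0.03, V = 1, f_dose = 1,
                            times = seq(1, 720, by = 1)) {
  u <- uir(A = 1 / V, alpha = ke, tlag = 0)
  conc <- ivivctk:::bateman(times, f_dose, 1 / V, ke, ka, 0)
  list(u = u, ke = ke, ka = ka,
       oral = time_profile(times, conc, kind = "concentration"),
       fabs_true = function(t) 1 - exp(-ka * t))
}

# scenario whose oral absorption tracks its own dissolution curve (true
# correlation is form F2 with unit time scale)
pipeline_scenario <- function(seed, cv = 0.10) {
  ivivc_scenario(
    "pipe",
    dissolution = list(acetate_pH4.5 = list(
      model = "weibull",
      params = list(finf = 0.80, mdt = 1.2, b = 2.0, tlag = 0))),
    A = 0.5, alpha = 1.3 / 60, ka = 1.3 / 60, f = 0.10,
    oral_dose = 2500, iv_dose = 100, content_per_tablet = 0.3,
    cv = cv, absorption = "dissolution_limited",
    absorption_medium = "acetate_pH4.5", seed = seed)
}
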