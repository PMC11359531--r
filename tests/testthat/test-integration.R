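test_that("weight coefficients are content fractions that sum to one", {
  contents <- c(protopin = 0.1742, alloc = 1.1042, byak = 0.0975,
                thp = 0.3017, coryd = 0.2871)
  w <- weight_coefficients(contents)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(unname(w["protopin"]), 0.1742 / sum(contents),
               tolerance = 1e-12)
  expect_equal(round(unname(w["protopin"]), 4), 0.0887)
  expect_equal(weight_coefficients(c(a = 3)), c(a = 1))
  expect_equal(unname(weight_coefficients(setNames(rep(2, 5), letters[1:5]))),
               rep(0.2, 5))
  expect_error(weight_coefficients(numeric()), "empty")
  expect_error(weight_coefficients(c(a = 1, b = 0)), "> 0")
})

test_that("dissolution integration is a pointwise convex combination", {
  t <- diss_grid_min
  p <- time_profile(t, seq(0.1, 0.9, length.out = length(t)),
                    kind = "fraction")
  same <- integrate_dissolution(list(a = p, b = p, c = p),
                                weight_coefficients(c(a = 1, b = 2, c = 3)))
  expect_equal(same$values, p$values)
  z <- time_profile(t, rep(0, length(t)), kind = "fraction")
  o <- time_profile(t, rep(1, length(t)), kind = "fraction")
  mix <- integrate_dissolution(list(lo = z, hi = o), c(lo = 0.3, hi = 0.7))
  expect_equal(mix$values, rep(0.7, length(t)))
  # bounded by the member envelope for random members and weights
  set.seed(41)
  for (i in 1:10) {
    ps <- lapply(1:4, function(j)
      time_profile(t, cummax(runif(length(t), 0, 1)), kind = "fraction"))
    names(ps) <- letters[1:4]
    w <- weight_coefficients(setNames(runif(4, 0.1, 2), letters[1:4]))
    out <- integrate_dissolution(ps, w)
    env <- sapply(ps, `[[`, "values")
    expect_true(all(out$values <= apply(env, 1, max) + 1e-12))
    expect_true(all(out$values >= apply(env, 1, min) - 1e-12))
  }
})

test_that("the plateau of an integrated curve is the weighted plateau sum", {
  # class-level plateau from the published acetate-buffer best fits
  gts <- list(
    protopin = list(model = "hill", params = list(finf = 0.78, mdt = 1.10, b = 2.71)),
    alloc = list(model = "weibull", params = list(finf = 0.86, mdt = 1.26, b = 1.97, tlag = 0)),
    byak = list(model = "hill", params = list(finf = 0.35, mdt = 1.12, b = 2.79)),
    thp = list(model = "hill", params = list(finf = 0.79, mdt = 1.07, b = 2.93)),
    coryd = list(model = "weibull", params = list(finf = 0.71, mdt = 1.23, b = 2.04, tlag = 0)))
  w <- weight_coefficients(c(protopin = 0.1742, alloc = 1.1042,
                             byak = 0.0975, thp = 0.3017, coryd = 0.2871))
  t_long <- c(diss_grid_min, 1e5)  # push far onto the plateau
  profs <- lapply(gts, function(g)
    time_profile(t_long, eval_dissolution(g$model, g$params, t_long / 60),
                 kind = "fraction"))
  out <- integrate_dissolution(profs, w)
  plateau <- sum(w * vapply(gts, function(g) g$params$finf, numeric(1)))
  expect_equal(out$values[length(t_long)], plateau, tolerance = 1e-6)
})

test_that("concentration integration is the pointwise sum with additive AUC", {
  t <- pk_grid()
  c1 <- time_profile(t, 10 * exp(-0.005 * t), kind = "concentration")
  c2 <- time_profile(t, 4 * exp(-0.002 * t), kind = "concentration")
  z <- time_profile(t, rep(0, length(t)), kind = "concentration")
  both <- integrate_concentrations(list(a = c1, b = c1))
  expect_equal(both$values, 2 * c1$values)
  keep <- integrate_concentrations(list(a = c1, b = z))
  expect_equal(keep$values, c1$values)
  tot <- integrate_concentrations(list(a = c1, b = c2))
  expect_equal(ivivctk:::trapz_auc(t, tot$values),
               ivivctk:::trapz_auc(t, c1$values) +
                 ivivctk:::trapz_auc(t, c2$values), tolerance = 1e-12)
})

test_that("grid mismatches are rejected with the offending series named", {
  a <- time_profile(c(15, 30, 60), c(0.1, 0.2, 0.3), kind = "fraction")
  b <- time_profile(c(15, 30, 90), c(0.1, 0.2, 0.3), kind = "fraction")
  expect_error(integrate_dissolution(list(ok = a, off = b),
                                     c(ok = 0.5, off = 0.5)), "off")
  expect_error(integrate_concentrations(list(ok = a, off = b)), "off")
})

test_that("a single-member class reduces exactly to the member itself", {
  t <- diss_grid_min
  p <- time_profile(t, cummax(runif(length(t))), kind = "fraction")
  out <- integrate_dissolution(list(solo = p), weight_coefficients(c(solo = 5)))
  expect_equal(out$values, p$values)
  c1 <- time_profile(t, runif(length(t), 0, 10), kind = "concentration")
  expect_equal(integrate_concentrations(list(solo = c1))$values, c1$values)
})
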