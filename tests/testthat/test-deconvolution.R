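test_that("deconvolution recovers first-order absorption against the Bateman oracle", {
  fx <- one_compartment()
  ac <- deconvolve(fx$oral, fx$u, grid_step = 1)
  truth <- fx$fabs_true(ac$times)
  expect_lt(max(abs(ac$fabs - truth / max(truth))), 0.01)
  expect_equal(ac$fabs[1], 0)
  expect_true(all(diff(ac$fabs) >= -1e-12))
})

test_that("deconvolution and Wagner-Nelson agree on one-compartment data", {
  fx <- one_compartment()
  ac <- deconvolve(fx$oral, fx$u, grid_step = 1)
  wn <- wagner_nelson(fx$oral, fx$ke)
  wn_on_grid <- pracma::pchip(wn$times, wn$fabs, ac$times)
  expect_lt(max(abs(wn_on_grid - ac$fabs)), 0.01)
})

test_that("an oral profile equal to the dose-scaled UIR deconvolves to a bolus", {
  u <- uir(0.4, 0.005, tlag = 0)
  tt <- seq(5, 720, by = 5)
  oral <- time_profile(tt, 100 * uir_eval(u, tt), kind = "concentration")
  ac <- deconvolve(oral, u, grid_step = 5)
  # all input lands in the first grid interval
  expect_equal(ac$fabs[-1], rep(1, length(ac$fabs) - 1), tolerance = 1e-6)
  # recovered mass approximates the bolus dose (the true input is an impulse,
  # the estimate a 5-min staircase)
  expect_equal(max(ac$cum_amount), 100, tolerance = 0.02)
})

test_that("zero concentrations deconvolve to an identically zero curve", {
  u <- uir(0.4, 0.005)
  oral <- time_profile(c(15, 60, 360), c(0, 0, 0), kind = "concentration")
  ac <- deconvolve(oral, u, grid_step = 5)
  expect_true(all(ac$fabs == 0))
})

test_that("convolving the estimated input back reproduces the observations", {
  fx <- one_compartment(times = seq(5, 720, by = 5))
  ac <- deconvolve(fx$oral, fx$u, grid_step = 5)
  expect_lt(attr(ac, "residual_rms"), 0.02)
  rate <- attr(ac, "rate")
  rebuilt <- ivivctk:::convolve_staircase(rate, 5, fx$u, fx$oral$times)
  expect_lt(sqrt(mean((rebuilt - fx$oral$values)^2)) / max(fx$oral$values),
            0.02)
})

test_that("fabs is invariant to a joint concentration-unit rescale", {
  fx <- one_compartment(times = seq(5, 720, by = 5))
  k <- 1000  # e.g. ng/mL -> pg/mL on both sides
  u2 <- uir(fx$u$A * k, fx$u$alpha, fx$u$tlag)
  oral2 <- time_profile(fx$oral$times, fx$oral$values * k,
                        kind = "concentration")
  a1 <- deconvolve(fx$oral, fx$u, grid_step = 5)
  a2 <- deconvolve(oral2, u2, grid_step = 5)
  expect_equal(a1$fabs, a2$fabs, tolerance = 1e-9)
})

test_that("Wagner-Nelson normalization is robust to a mis-specified ke", {
  fx <- one_compartment(times = seq(1, 2880, by = 1))
  wn_right <- wagner_nelson(fx$oral, fx$ke)
  wn_wrong <- wagner_nelson(fx$oral, 2 * fx$ke)
  expect_equal(max(wn_right$fabs), 1, tolerance = 1e-9)
  expect_equal(max(wn_wrong$fabs), 1, tolerance = 1e-9)
  # with the right ke the curve tends to 1 well before the last sample
  at_5halves <- pracma::pchip(wn_right$times, wn_right$fabs,
                              5 * log(2) / fx$ka)
  expect_gt(at_5halves, 0.95)
  expect_error(wagner_nelson(fx$oral, 0), "ke")
})

test_that("deconvolution rejects a grid that does not tile the window", {
  fx <- one_compartment(times = seq(5, 715, by = 5))
  expect_error(deconvolve(fx$oral, fx$u, grid_step = 7), "divide")
})
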