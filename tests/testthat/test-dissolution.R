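test_that("cumulative dissolution applies the sampling-replacement correction", {
  # single point, no replacement: D1 = C1 V1 / M
  d <- cumulative_dissolution(15, 0.1, v1 = 900, v2 = 0, m = 100)
  expect_equal(d$values, 0.90)
  # V2 = 0 collapses to Cn V1 / M at every point
  cc <- c(0.01, 0.03, 0.05)
  d0 <- cumulative_dissolution(c(15, 30, 45), cc, 900, 0, m = 100)
  expect_equal(d0$values, cc * 900 / 100)
  # constant concentration, hand-expanded third sample
  c3 <- 0.02; m <- 60
  d3 <- cumulative_dissolution(c(15, 30, 45), rep(c3, 3), 900, 3, m)
  expect_equal(d3$values[3], (900 * c3 + 2 * 3 * c3) / m)
  expect_error(cumulative_dissolution(c(15, 30), c(0.1, -0.1), 900, 3, 100),
               "negative")
})

test_that("cumulative dissolution is non-decreasing for monotone sampling data", {
  set.seed(5)
  for (i in 1:20) {
    concs <- sort(runif(9, 0, 0.08))
    d <- cumulative_dissolution(diss_grid_min, concs, 900, 3, m = 100)
    expect_true(all(diff(d$values) >= -1e-12))
  }
})

test_that("model families vanish at t = 0 and are bounded by their plateau", {
  set.seed(9)
  for (i in 1:10) {
    pars <- list(finf = runif(1, 0.2, 1), mdt = runif(1, 0.5, 3),
                 b = runif(1, 0.5, 5), tlag = runif(1, 0, 0.3))
    mb <- list(fmax = pars$finf, tmax = runif(1, 1, 5), b = pars$b)
    tt <- seq(0, 12, by = 0.1)
    for (m in c("hill", "weibull")) {
      y <- eval_dissolution(m, pars, tt)
      expect_equal(y[1], 0)
      expect_true(all(y <= pars$finf + 1e-12))
    }
    y <- eval_dissolution("makoid_banakar", mb, tt)
    expect_equal(y[1], 0)
    expect_true(all(y <= mb$fmax + 1e-12))
  }
})

test_that("closed-form identities: Hill half-maximum and Makoid-Banakar plateau", {
  expect_equal(eval_dissolution("hill", list(finf = 0.78, mdt = 1.1, b = 2.71),
                                1.1), 0.78 / 2)
  mb <- list(fmax = 0.6, tmax = 2, b = 1.5)
  expect_equal(eval_dissolution("makoid_banakar", mb, 2), 0.6)
  expect_equal(eval_dissolution("makoid_banakar", mb, c(2.5, 7)), c(0.6, 0.6))
})

test_that("fits on noise-free curves recover the generating parameters", {
  # Weibull ground truth from the published protopin/HCl best fit
  prof <- sample_model(tbl_weibull_protopin_hcl)
  f <- fit_dissolution_model(prof, "weibull")
  expect_equal(f$params$finf, 0.70, tolerance = 1e-4)
  expect_equal(f$params$mdt, 1.10, tolerance = 1e-4)
  expect_equal(f$params$b, 2.06, tolerance = 1e-4)
  expect_equal(f$r, 1, tolerance = 1e-6)

  prof2 <- sample_model(tbl_hill_thp_acetate)
  f2 <- fit_dissolution_model(prof2, "hill")
  expect_equal(unlist(f2$params[c("finf", "mdt", "b")]),
               c(finf = 0.79, mdt = 1.07, b = 2.93), tolerance = 1e-4)

  gt_mb <- list(model = "makoid_banakar",
                params = list(fmax = 0.55, tmax = 3.0, b = 1.8))
  f3 <- fit_dissolution_model(sample_model(gt_mb), "makoid_banakar")
  expect_equal(unlist(f3$params[c("fmax", "tmax", "b")]),
               c(fmax = 0.55, tmax = 3.0, b = 1.8), tolerance = 1e-4)
})

test_that("fixing the plateau at 1 constrains the Weibull asymptote", {
  gt <- list(model = "weibull", params = list(finf = 1, mdt = 1.4, b = 1.7,
                                              tlag = 0))
  f <- fit_dissolution_model(sample_model(gt), "weibull", finf_fixed = TRUE)
  expect_equal(f$params$finf, 1)
  expect_equal(f$params$mdt, 1.4, tolerance = 1e-4)
})

test_that("model selection ranks by correlation with an AIC tie-break", {
  mk <- function(r, aic) structure(list(model = "hill", r = r, aic = aic),
                                   class = "dissolution_fit")
  picked <- select_dissolution_model(list(mk(0.9909, -25.65), mk(0.9981, -39.54)))
  expect_equal(picked$r, 0.9981)
  expect_equal(select_dissolution_model(list(mk(0.99, -10)))$aic, -10)
  tie <- select_dissolution_model(list(mk(0.995, -25), mk(0.995, -40)))
  expect_equal(tie$aic, -40)
  expect_error(select_dissolution_model(list()), "no candidate")
})
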