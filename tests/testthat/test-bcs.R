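test_that("dose number matches the published worked examples", {
  expect_equal(round(dose_number(0.00418 * 250, 250, 0.535), 6), 0.007813)
  expect_equal(round(dose_number(0.0265 * 250, 250, 0.0447), 6), 0.592841)
  expect_equal(dose_number(m0 = 100, v0 = 250, cs = 100 / 250), 1)
  expect_error(dose_number(1, 250, 0), "insoluble")
})

test_that("dose number is invariant to joint rescaling of dose and solubility", {
  set.seed(11)
  for (i in 1:20) {
    m0 <- runif(1, 0.1, 100); cs <- runif(1, 0.001, 5); k <- runif(1, 0.1, 50)
    expect_equal(dose_number(k * m0, 250, k * cs), dose_number(m0, 250, cs))
  }
})

test_that("apparent permeability is slope over area times donor concentration", {
  expect_equal(apparent_permeability(dq_dt = 0.5, area = 0.33, c0 = 10)$peff,
               0.5 / (0.33 * 10) / 60)
  # slope recovered from exactly linear receiver data
  s <- 0.004; c0 <- 2.5
  tt <- c(30, 60, 120)
  p <- apparent_permeability(times = tt, amounts = s * tt, area = 0.33, c0 = c0)
  expect_equal(p$peff, s / (0.33 * c0) / 60, tolerance = 1e-10)
  expect_equal(apparent_permeability(dq_dt = 0, area = 0.33, c0 = 1)$class, "low")
  expect_equal(apparent_permeability(dq_dt = 1.34e-5 * 60 * 0.33 * 1,
                                     area = 0.33, c0 = 1)$class, "high")
  expect_error(apparent_permeability(times = 30, amounts = 1, c0 = 1),
               "at least 2")
})

test_that("all five study components classify as BCS I from the shipped config", {
  comps <- read_components_json(
    system.file("extdata", "components.json", package = "ivivctk"))
  expect_length(comps, 5)
  for (cs in comps) {
    b <- classify_bcs(cs)
    expect_equal(b$bcs_class, "I")
    expect_true(all(b$d0_by_medium <= 1))
  }
  # per-medium dose numbers reproduce the tabulated worked values
  b <- classify_bcs(comps$protopin)
  expect_equal(round(unname(b$d0_by_medium["phosphate_pH6.8"]), 6), 0.007813)
  b2 <- classify_bcs(comps$`alpha-allocryptopine`)
  expect_equal(round(unname(b2$d0_by_medium["phosphate_pH6.8"]), 6), 0.592841)
  # censored solubility bound carried through for corydaline
  expect_true("acetate_pH4.5" %in% classify_bcs(comps$corydaline)$censored)
})

test_that("BCS classes partition the solubility x permeability plane", {
  mk <- function(sol, peff) component_spec(
    "x", content_per_tablet = 1, oral_dose = 1, iv_dose = 1,
    solubilities = c(HCl_0.1M = sol, acetate_pH4.5 = sol,
                     phosphate_pH6.8 = sol),
    peff = peff, m0_over_v0 = 0.01)
  expect_equal(classify_bcs(mk(1, 1e-5))$bcs_class, "I")
  expect_equal(classify_bcs(mk(0.005, 1e-5))$bcs_class, "II")  # D0 = 2
  expect_equal(classify_bcs(mk(1, 5e-7))$bcs_class, "III")
  expect_equal(classify_bcs(mk(0.005, 5e-7))$bcs_class, "IV")
  # exhaustive and mutually exclusive over random specs
  set.seed(3)
  for (i in 1:25) {
    b <- classify_bcs(mk(10^runif(1, -4, 1), 10^runif(1, -8, -4)))
    expect_true(b$bcs_class %in% c("I", "II", "III", "IV"))
    expect_equal(b$bcs_class == "I",
                 b$solubility_class == "high" && b$permeability_class == "high")
  }
  expect_error(classify_bcs(component_spec(
    "y", 1, 1, 1, solubilities = c(HCl_0.1M = 1), peff = 1e-5)),
    "phosphate_pH6.8")
})
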