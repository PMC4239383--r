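test_that("ionic strength is half the charge-weighted sum", {
  expect_equal(ionic_strength(c(0.1, 0.1), c(1, -1)), 0.1)
  expect_equal(ionic_strength(0.1, -2), 0.2)
  expect_equal(ionic_strength(numeric(0), numeric(0)), 0)
  expect_error(ionic_strength(-0.1, 1), ">= 0")
})

test_that("Davies coefficients: unity limits, divalent value, monotone decay", {
  expect_equal(davies_activity(1, 0), 1)
  expect_equal(davies_activity(0, 0.3), 1)
  expect_equal(davies_activity(2, 0.3), 0.29, tolerance = 0.01)
  # monotone decay holds up to the Davies turning point (~0.39 mol/L,
  # where the linear 0.3 I term overtakes the limiting-law term)
  I <- seq(0, 0.35, by = 0.05)
  for (z in 1:3) {
    g <- davies_activity(z, I)
    expect_true(all(g > 0 & g <= 1))
    expect_true(all(diff(g) < 0))
  }
  # gamma decreases with |z| at fixed I
  expect_true(all(diff(davies_activity(1:3, 0.2)) < 0))
})

test_that("pure water speciates to neutrality", {
  sp <- speciate(pulp_composition())
  expect_equal(sp$pH_vac, 7, tolerance = 1e-4)
  expect_lt(abs(sp$charge_residual), 1e-9)
})

test_that("potassium raises the solved pH monotonically", {
  ks <- seq(0.01, 0.06, by = 0.01)
  ph <- vapply(ks, function(k) speciate(pulp_composition(
    K = k, citrate = 0.02, malate = 0.02, oxalate = 0.005,
    Cl = 0.004))$pH_vac, 1)
  expect_true(all(diff(ph) > 0))
})

test_that("speciation matches the 1-D grid-scan oracle", {
  # fixed 3-species toy medium (needs an extended bracket: it is alkaline)
  comp <- pulp_composition(K = 0.03, malate = 0.01, Cl = 0.005)
  cfg <- speciation_config(pH_range = c(2, 13))
  sp <- speciate(comp, cfg = cfg)
  grid <- seq(2, 13, by = 1e-4)
  res <- oracle_state(comp, grid)$residual
  expect_lt(abs(sp$pH_vac - grid[which.min(abs(res))]), 1e-4 + 1e-8)

  set.seed(101)
  for (i in 1:50) {
    comp <- random_composition()
    sp <- speciate(comp)
    expect_lt(abs(sp$pH_vac - oracle_spec_ph(comp)), 0.01)
    expect_lt(abs(sp$charge_residual), 1e-9)
    expect_gt(sp$K1_app, sp$K2_app)
    expect_true(sp$a_mal2 > 0 && sp$a_mal2 <= 1)
  }
})

test_that("speciation is vectorized consistently across samples", {
  set.seed(5)
  comps <- replicate(8, random_composition(), simplify = FALSE)
  fields <- lapply(names(comps[[1]]), function(f) vapply(comps, `[[`, 1, f))
  names(fields) <- names(comps[[1]])
  spv <- speciate(do.call(pulp_composition, fields))
  for (i in seq_along(comps))
    expect_equal(spv$pH_vac[i], speciate(comps[[i]])$pH_vac,
                 tolerance = 1e-10)
})

test_that("errors are raised when no charge-balance root exists in range", {
  expect_error(speciate(pulp_composition(K = 0.1, Cl = 0.001)),
               "no root")
})

test_that("measured-pH medium is a passthrough with composition-driven
           constants", {
  comp <- pulp_composition(K = 0.05, malate = 0.02, citrate = 0.02,
                           oxalate = 0.005, Cl = 0.004)
  med <- measured_ph_medium(4.6, comp)
  expect_equal(med$pH_vac, 4.6)
  med2 <- measured_ph_medium(5.2, comp)
  # same composition: constants move only through the (pH-dependent) ionic
  # strength, so they stay close while the pH is exactly the measurement
  expect_equal(med$K1_app, med2$K1_app, tolerance = 0.1)
  expect_equal(med$a_mal2, med2$a_mal2, tolerance = 0.1)
  # degenerate zero composition: infinite dilution, gamma = 1
  med0 <- measured_ph_medium(7, pulp_composition())
  expect_equal(med0$a_mal2, 1, tolerance = 5e-3)
  expect_equal(med0$K1_app, 10^-3.40, tolerance = 5e-3)
  expect_error(measured_ph_medium(9.5, comp), "\\[2, 8\\]")
})
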