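test_that("coupling ratio follows its pH dependence and rejects n <= 0", {
  pump <- pump_parameters()
  expect_equal(coupling_ratio(7, pump), 3.88)
  expect_equal(coupling_ratio(5, pump), 3.28)
  # constant-stoichiometry limit
  p0 <- pump_parameters(alpha = 0, beta = 0)
  for (ph in c(3, 4.5, 6, 7.5)) expect_equal(coupling_ratio(ph, p0), 4)
  # strongly negative alpha drives n <= 0 at acid pH
  expect_error(coupling_ratio(3, pump_parameters(alpha = 2)),
               "stoichiometry")
})

test_that("ATPase-equilibrium potential matches hand evaluations and zeroes
           the chemiosmotic free energy", {
  pump <- pump_parameters()
  expect_equal(delta_psi_atpase(7, pump, -45200, 291.15),
               45200 / (3.88 * 96500), tolerance = 1e-10)
  expect_equal(delta_psi_atpase(5, pump, -45200, 291.15), 0.0273,
               tolerance = 1e-2)
  expect_error(delta_psi_atpase(7, pump, 500, 291.15), "negative")
  # residual of the chemiosmotic relation is zero at the returned potential
  set.seed(42)
  for (i in 1:100) {
    ph <- runif(1, 3, 7)
    pmp <- pump_parameters(pH_cyt = runif(1, 6.5, 7.5))
    g <- runif(1, -55e3, -25e3)
    temp <- runif(1, 285, 305)
    dpsi <- delta_psi_atpase(ph, pmp, g, temp)
    expect_lt(abs(delta_g_atpase(dpsi, ph, pmp, g, temp)), 1e-6)
  }
})

test_that("di-anion fraction spans its limits", {
  med <- vacuolar_medium(4.6, 10^-3.40, 10^-5.11, 0.3)
  expect_equal(dianion_fraction(14, med), 1, tolerance = 1e-3)
  expect_equal(dianion_fraction(-2, med), 0, tolerance = 1e-6)
  # at pH = pK'2 the second dissociation is half complete (h^2 term small)
  expect_equal(dianion_fraction(5.11, med), 0.5, tolerance = 0.02)
})

test_that("di-anion electrochemical gradient matches direct arithmetic", {
  expect_equal(delta_g_mal(0, 0.01, 0.01, 298.15), 0)
  expect_equal(delta_g_mal(0.01, 0.01, 0.01, 298.15), -1930)
  expect_equal(delta_g_mal(0, 0.001 * exp(1), 0.001, 298.15),
               8.3144621 * 298.15, tolerance = 1e-10)
  expect_error(delta_g_mal(0, -1, 0.001, 298.15), "> 0")
})

test_that("equilibrium vacuolar malate: limits, linearity and zero gradient", {
  pump <- pump_parameters()
  med_high_ph <- vacuolar_medium(8, 10^-3.40, 10^-5.11, 0.3)
  expect_equal(
    vacuolar_malate_equilibrium(med_high_ph, pump, 0, 291.15),
    0.001 / 0.3, tolerance = 1e-2)
  med <- vacuolar_medium(4.6, 10^-3.40, 10^-5.11, 0.3)
  m1 <- vacuolar_malate_equilibrium(med, pump, 0.012, 291.15)
  m2 <- vacuolar_malate_equilibrium(
    med, pump_parameters(mal2_cyt = 0.002), 0.012, 291.15)
  expect_equal(m2, 2 * m1, tolerance = 1e-12)
  # returned concentration puts the di-anion at zero electrochemical gradient
  set.seed(7)
  for (i in 1:100) {
    medr <- vacuolar_medium(runif(1, 3, 6), 10^-3.40, 10^-5.11,
                            runif(1, 0.2, 0.9))
    dpsi <- runif(1, -0.02, 0.05)
    temp <- runif(1, 285, 305)
    mal <- vacuolar_malate_equilibrium(medr, pump, dpsi, temp)
    act_vac <- medr$a_mal2 * mal * dianion_fraction(medr$pH_vac, medr)
    expect_lt(abs(delta_g_mal(dpsi, act_vac, pump$mal2_cyt, temp)), 1e-6)
  }
  expect_error(
    vacuolar_malate_equilibrium(med, pump, 5, 291.15), "exponent guard")
})

test_that("monotonicity: deeper dG_ATP raises the potential and the stored
           malate; higher cytosolic pH lowers it", {
  pump <- pump_parameters()
  med <- vacuolar_medium(4.6, 10^-3.40, 10^-5.11, 0.3)
  gs <- seq(-55e3, -30e3, by = 5e3)
  psi <- delta_psi_atpase(4.6, pump, gs, 291.15)
  expect_true(all(diff(psi) < 0))  # less negative dG -> lower potential
  mals <- vapply(gs, function(g) vacuolar_malate_equilibrium(
    med, pump, delta_psi_atpase(4.6, pump, g, 291.15), 291.15), 1)
  expect_true(all(diff(mals) < 0))
  phc <- seq(6.6, 7.4, by = 0.2)
  mals_ph <- vapply(phc, function(p) {
    pm <- pump_parameters(pH_cyt = p)
    vacuolar_malate_equilibrium(
      med, pm, delta_psi_atpase(4.6, pm, -45e3, 291.15), 291.15)
  }, 1)
  expect_true(all(diff(mals_ph) < 0))
})

test_that("pulp malate conversion and its guards", {
  expect_equal(pulp_malate(0, 100, 25), 0)
  expect_equal(pulp_malate(0.02, 100, 25), 15)
  expect_equal(pulp_malate(0.02, 100, 1e-9), 20, tolerance = 1e-6)
  expect_error(pulp_malate(0.02, 100, 100), "FW > DW")
})

test_that("ripening energy polynomial reproduces the published arithmetic", {
  idn <- energy_polynomial(75, -1176, -45.2e3)
  pl <- energy_polynomial(110, -1959, -46.3e3)
  expect_equal(dg_atp_at(0, idn), -45200)
  expect_equal(dg_atp_at(13, idn), -47813)
  expect_equal(dg_atp_at(13, pl), -53177)
  expect_error(dg_atp_at(5, energy_constant(-40e3)), "polynomial")
  expect_error(energy_polynomial(5000, 0, -1e3), "negative")
})

test_that("dG_ATP inversion round-trips the forward model and matches a
           brute-force bisection", {
  pump <- pump_parameters()
  set.seed(11)
  for (i in 1:100) {
    med <- vacuolar_medium(runif(1, 3.5, 6), 10^-3.40 / runif(1, 1, 2),
                           10^-5.11 / runif(1, 1, 2), runif(1, 0.2, 0.8))
    g <- runif(1, -55e3, -30e3)
    temp <- runif(1, 285, 305)
    mal <- vacuolar_malate_equilibrium(
      med, pump, delta_psi_atpase(med$pH_vac, pump, g, temp), temp)
    expect_equal(invert_dg_atp(mal, med, pump, temp), g,
                 tolerance = 1e-9)
  }
  # independent numerical inversion on the documented assumption set
  med <- measured_ph_medium(4.6, pulp_composition(K = 0.05, malate = 0.02,
                                                  citrate = 0.02,
                                                  temperature = 291.15))
  g_alg <- invert_dg_atp(0.02, med, pump, 291.15)
  g_num <- oracle_invert_dg(0.02, med, pump, 291.15)
  expect_equal(g_alg, g_num, tolerance = 1e-6)
  expect_error(invert_dg_atp(0, med, pump, 291.15), "> 0")
})

test_that("potential required by an observed malate inverts the equilibrium
           and vanishes with no gradient", {
  pump <- pump_parameters()
  med <- vacuolar_medium(4.8, 10^-3.40, 10^-5.11, 0.35)
  for (dpsi in c(-0.01, 0, 0.005, 0.02)) {
    mal <- vacuolar_malate_equilibrium(med, pump, dpsi, 295)
    expect_equal(delta_psi_from_malate(mal, med, pump, 295), dpsi,
                 tolerance = 1e-12)
  }
  # vacuolar activity equal to cytosolic -> zero potential
  frac <- dianion_fraction(med$pH_vac, med)
  mal0 <- pump$mal2_cyt / (med$a_mal2 * frac)
  expect_equal(delta_psi_from_malate(mal0, med, pump, 295), 0,
               tolerance = 1e-12)
})
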