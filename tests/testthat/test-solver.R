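test_that("solver recovers a state constructed from the forward equations", {
  # build a sample, solve it, then feed the solved malate back through the
  # independent equations: speciation of the full medium must return the
  # solved pH, and the equilibrium malate at that pH must match.
  s <- toy_sample()
  sol <- solve_state(s, pump_parameters(), energy_constant(-39e3))
  expect_true(sol$converged)
  sp <- speciate(samples_comp <- malvac:::samples_composition(s, sol$mal_vac))
  expect_equal(sp$pH_vac, sol$pH_vac, tolerance = 1e-8)
  med <- as_medium(sp)
  mal_eq <- vacuolar_malate_equilibrium(
    med, pump_parameters(),
    delta_psi_atpase(sol$pH_vac, pump_parameters(), -39e3, s$temperature),
    s$temperature)
  expect_equal(mal_eq, sol$mal_vac, tolerance = 1e-7)
  expect_lt(abs(sol$charge_residual), 1e-9)
  expect_lt(sol$eq_residual, 1e-7)
})

test_that("solution matches the 2-D brute-force grid oracle", {
  pump <- pump_parameters()
  # fixed toy case at the published IDN growth energy and 18 degC
  s0 <- toy_sample(temperature = 291.15)
  sol0 <- solve_state(s0, pump, energy_constant(-36.9e3))
  or0 <- oracle_solve_grid(malvac:::samples_composition(s0),
                           291.15, -36.9e3, pump)
  expect_lt(abs(sol0$pH_vac - or0$pH), or0$ph_step)
  expect_lt(abs(sol0$mal_vac - or0$mal), or0$mal_step)

  set.seed(202)
  for (i in 1:10) {
    s <- random_sample()
    g <- runif(1, -50e3, -33e3)
    sol <- solve_state(s, pump, energy_constant(g))
    expect_true(sol$converged)
    orc <- oracle_solve_grid(malvac:::samples_composition(s),
                             s$temperature, g, pump)
    expect_lt(abs(sol$pH_vac - orc$pH), orc$ph_step)
    expect_lt(abs(sol$mal_vac - orc$mal), orc$mal_step)
  }
})

test_that("solution is independent of initialization", {
  set.seed(303)
  pump <- pump_parameters()
  for (i in 1:50) {
    s <- random_sample()
    g <- runif(1, -50e3, -33e3)
    a <- solve_state(s, pump, energy_constant(g),
                     solve_settings(mal_init = 0.0005))
    s$observed_malate <- 40  # warm start far away, via the observed column
    b <- solve_state(s, pump, energy_constant(g),
                     solve_settings(mal_init = 0.5))
    expect_lt(abs(a$pH_vac - b$pH_vac), 1e-9)
    expect_lt(abs(a$mal_vac - b$mal_vac) / a$mal_vac, 1e-9)
  }
})

test_that("joint quasi-Newton solve (independent route) lands on the same
           state", {
  # cross-check the bracketing engine against a Broyden solve of the raw
  # two-unknown system (pH, log malate)
  pump <- pump_parameters()
  cfg <- speciation_config()
  cn <- tonoplast_constants()
  set.seed(404)
  for (i in 1:5) {
    s <- random_sample()
    g <- runif(1, -48e3, -35e3)
    sol <- solve_state(s, pump, energy_constant(g))
    fsys <- function(x) {
      pH <- x[1]; mal <- exp(x[2])
      st <- malvac:::spec_core(
        malvac:::samples_composition(s, mal), pH, cfg)
      dPsi <- delta_psi_atpase(pH, pump, g, s$temperature)
      k12 <- st$K1_app * st$K2_app
      h <- 10^(-pH)
      mal_eq <- (1 / st$a_mal2) * ((h^2 + h * st$K1_app + k12) / k12) *
        pump$mal2_cyt * exp(2 * cn$Faraday * dPsi / (cn$R * s$temperature))
      c(st$charge_residual * 1e3, x[2] - log(mal_eq))
    }
    br <- pracma::broyden(fsys, c(4.5, log(0.01)))
    expect_equal(br$zero[1], sol$pH_vac, tolerance = 1e-5)
    expect_equal(exp(br$zero[2]), sol$mal_vac, tolerance = 1e-4)
  }
})

test_that("series solving is per-date independent and aggregates failures", {
  expect_equal(nrow(simulate_series(toy_sample()[0, ], pump_parameters(),
                                    energy = energy_constant(-40e3))), 0)
  # constant composition in constant-energy mode: identical solutions
  s <- toy_sample()[rep(1, 4), ]
  s$time <- c(10, 30, 50, 70)
  out <- simulate_series(s, pump_parameters(), energy_constant(-40e3))
  expect_equal(length(unique(round(out$mal_fruit, 9))), 1L)
  # an unsolvable sample (acid excess: charge balance cannot close even at
  # the acid end of the bracket) is flagged, others still solve
  s2 <- rbind(toy_sample(), toy_sample(K = 0, Mg = 0, Ca = 0, oxalate = 0.3))
  out2 <- simulate_series(s2, pump_parameters(), energy_constant(-40e3))
  expect_true(out2$converged[1])
  expect_false(out2$converged[2])
  expect_true(is.na(out2$mal_fruit[2]))
})

test_that("ripening series follows the quadratic energy course", {
  pl <- banana_parameters()[3, ]
  s <- toy_sample(stage = "ripening", temperature = 291.15)[rep(1, 5), ]
  s$time <- c(0, 3, 6, 9, 13)
  out <- simulate_series(s, pump_parameters(),
                         energy_polynomial(pl$G1, pl$G2, pl$G3))
  expect_true(all(out$converged))
  expect_equal(out$dG_ATP, pl$G1 * s$time^2 + pl$G2 * s$time + pl$G3)
  # deeper dG over the window -> malate rises from day 0 toward the minimum
  expect_true(all(diff(out$mal_fruit[1:4]) > 0))
  # vertex of the PL parabola is near day 9; the tail flattens or declines
  expect_lt(out$mal_fruit[5] - out$mal_fruit[4],
            out$mal_fruit[4] - out$mal_fruit[3])
})

test_that("predictions respond continuously to small input perturbations", {
  s <- toy_sample()
  base <- solve_state(s, pump_parameters(), energy_constant(-40e3))$mal_fruit
  for (col in c("K", "Mg", "Ca", "P", "Cl", "citrate", "oxalate",
                "temperature")) {
    s2 <- s
    s2[[col]] <- s2[[col]] * 1.001
    m <- solve_state(s2, pump_parameters(), energy_constant(-40e3))$mal_fruit
    expect_lt(abs(m - base) / base, 0.05)
  }
})
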