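test_that("a single self-consistent observation is fitted exactly", {
  s <- toy_sample()
  g_true <- -41e3
  s$observed_malate <- solve_state(s, pump_parameters(),
                                   energy_constant(g_true))$mal_fruit
  fit <- fit_growth_dg(s, seed = 3,
                       swarm = pso_settings(n_particles = 16L, n_iter = 80L))
  expect_lt(abs(fit$par$dG_ATP - g_true) / abs(g_true), 1e-4)
  expect_lt(fit$sse, 1e-6)
  expect_lt(fit$rmse, 1e-3)
})

test_that("ripening inversion recovers per-sample energies that round-trip", {
  pl <- banana_parameters()[3, ]
  s <- toy_sample(stage = "ripening", temperature = 291.15)[rep(1, 5), ]
  s$time <- c(0, 3, 6, 9, 13)
  out <- simulate_series(s, pump_parameters(),
                         energy_polynomial(pl$G1, pl$G2, pl$G3))
  s$observed_malate <- out$mal_fruit
  dgs <- ripening_dg_series(s)
  expect_equal(dgs$dG_ATP, out$dG_ATP, tolerance = 1e-6)
})

test_that("quadratic coefficients are recovered exactly from exact data and
           match the least-squares closed form under noise", {
  # exact quadratic -> exact recovery (interpolation)
  pl <- banana_parameters()[3, ]
  s <- toy_sample(stage = "ripening", temperature = 291.15)[rep(1, 10), ]
  s$time <- rep(c(0, 3, 6, 9, 13), 2)
  out <- simulate_series(s, pump_parameters(),
                         energy_polynomial(pl$G1, pl$G2, pl$G3))
  s$observed_malate <- out$mal_fruit
  fit <- fit_ripening_G(s, seed = 5)
  expect_lt(abs(fit$par$G1 - pl$G1) / abs(pl$G1), 5e-3)
  expect_lt(abs(fit$par$G2 - pl$G2) / abs(pl$G2), 5e-3)
  expect_lt(abs(fit$par$G3 - pl$G3) / abs(pl$G3), 5e-3)

  # PSO agrees with the normal-equations oracle on noisy quadratic data
  set.seed(6)
  dae <- rep(c(0, 3, 6, 9, 13), each = 6)
  y <- 90 * dae^2 - 1300 * dae - 46e3 + rnorm(length(dae), 0, 400)
  pso <- pso_minimize(function(p) sum((y - p[1] * dae^2 - p[2] * dae -
                                         p[3])^2),
                      c(0, -5000, -60e3), c(500, 0, -30e3),
                      n_particles = 40, n_iter = 300, seed = 8)
  ls <- unname(coef(lm(y ~ I(dae^2) + dae)))  # (intercept, G1, G2)
  expect_lt(abs(pso$par[1] - ls[2]) / abs(ls[2]), 1e-3)
  expect_lt(abs(pso$par[2] - ls[3]) / abs(ls[3]), 1e-3)
  expect_lt(abs(pso$par[3] - ls[1]) / abs(ls[1]), 1e-3)
})

test_that("fewer than three distinct ripening dates is an error", {
  s <- toy_sample(stage = "ripening")[rep(1, 4), ]
  s$time <- c(0, 0, 3, 3)
  s$observed_malate <- 20
  expect_error(fit_ripening_G(s, seed = 1), "3 distinct")
})

test_that("objective at the fitted parameter does not exceed the truth's
           objective on noisy data", {
  p <- generate_profiles(1, seed = 21)[[1]]
  d <- forward_dataset(p, "growth")
  fit <- fit_growth_dg(d, seed = 22)
  sse_true <- {
    out <- simulate_series(d, pump_parameters(), energy_constant(p$dG_ATP))
    sse(d$observed_malate, out$mal_fruit)
  }
  expect_lte(fit$sse, sse_true + 1e-9)
})

test_that("fit serialization records parameters, metrics and seed", {
  s <- toy_sample()
  s$observed_malate <- solve_state(s, pump_parameters(),
                                   energy_constant(-40e3))$mal_fruit
  fit <- fit_growth_dg(s, seed = 4,
                       swarm = pso_settings(n_particles = 8L, n_iter = 15L))
  path <- tempfile(fileext = ".json")
  write_fit(fit, path)
  x <- jsonlite::read_json(path)
  expect_equal(x$par$dG_ATP, fit$par$dG_ATP)
  expect_equal(x$seed, 4)
  expect_equal(x$pso_settings$n_particles, 8)
})
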