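# Independent brute-force oracles. These re-derive the speciation arithmetic
# with their own generic code (cumulative-product species terms, explicit
# Davies law) and locate solutions by grid scanning, so they share no solve
# path with the package's bracketing/fixed-point engine.

oracle_pka <- list(malate = c(3.40, 5.11), citrate = c(3.13, 4.76, 6.40),
                   oxalate = c(1.25, 4.27), phosphate = c(2.15, 7.21, 12.35))

oracle_gamma <- function(z, I) {
  10^(-0.509 * z^2 * (sqrt(I) / (1 + sqrt(I)) - 0.3 * I))
}

# charge-balance residual (cations - anions) and medium constants at given
# pH (vectorized) for one scalar composition, iterating ionic strength.
oracle_state <- function(comp, pH, n_iter = 25) {
  h <- 10^(-pH)
  I <- rep(0.05, length(pH))
  for (it in seq_len(n_iter)) {
    g <- lapply(0:3, function(z) oracle_gamma(z, I))
    Hc <- h / g[[2]]
    OHc <- 10^(pH - 14) / g[[2]]
    chg <- 0
    iz2 <- 0
    kap_mal <- NULL
    for (a in names(oracle_pka)) {
      pk <- oracle_pka[[a]]
      n <- length(pk)
      kap <- lapply(seq_len(n),
                    function(j) 10^(-pk[j]) * g[[j]] / g[[j + 1]])
      terms <- list(h^n)
      for (j in seq_len(n)) terms[[j + 1]] <- terms[[j]] / h * kap[[j]]
      den <- Reduce(`+`, terms)
      tot <- comp[[c(malate = "malate", citrate = "citrate",
                     oxalate = "oxalate", phosphate = "P")[[a]]]]
      for (j in seq_len(n)) {
        cj <- tot * terms[[j + 1]] / den
        chg <- chg + j * cj
        iz2 <- iz2 + j^2 * cj
      }
      if (a == "malate") kap_mal <- kap
    }
    I <- 0.5 * (comp$K + 4 * comp$Mg + 4 * comp$Ca + comp$Cl +
                  Hc + OHc + iz2)
  }
  list(residual = comp$K + 2 * comp$Mg + 2 * comp$Ca + Hc -
         comp$Cl - OHc - chg,
       K1_app = kap_mal[[1]], K2_app = kap_mal[[2]],
       a_mal2 = g[[3]], I = I)
}

# 1-D grid scan for the electroneutral pH at fixed composition
oracle_spec_ph <- function(comp, ph_range = c(2, 8), step = 1e-4) {
  grid <- seq(ph_range[1], ph_range[2], by = step)
  res <- oracle_state(comp, grid)$residual
  grid[which.min(abs(res))]
}

# 2-D grid search for the coupled stationary state: minimizes a scaled norm
# of (charge residual, malate-equilibrium log-residual) over a coarse full
# grid, then over a refined local grid.
oracle_solve_grid <- function(comp0, temperature, dG, pump,
                              FW = NULL, DW = NULL) {
  Rg <- 8.3144621; Fc <- 9.65e4
  norm_at <- function(pH, mal) {
    comp <- comp0
    comp$malate <- mal
    st <- oracle_state(comp, pH)
    n <- pump$n0 + pump$alpha * (pH - 7) + pump$beta * 10^(pump$pH_cyt - 7)
    dPsi <- -dG / (n * Fc) +
      (Rg * temperature / Fc) * log(10) * (pH - pump$pH_cyt)
    h <- 10^(-pH)
    k12 <- st$K1_app * st$K2_app
    mal_eq <- (1 / st$a_mal2) * ((h^2 + h * st$K1_app + k12) / k12) *
      pump$mal2_cyt * exp(2 * Fc * dPsi / (Rg * temperature))
    (st$residual / 1e-3)^2 + log(mal / mal_eq)^2
  }
  scan <- function(ph_seq, mal_seq) {
    g <- expand.grid(pH = ph_seq, mal = mal_seq)
    v <- norm_at(g$pH, g$mal)
    g[which.min(v), ]
  }
  coarse <- scan(seq(2, 8, by = 0.02), seq(1e-4, 0.1, by = 1e-3))
  fine <- scan(seq(max(2, coarse$pH - 0.05), min(8, coarse$pH + 0.05),
                   by = 0.002),
               seq(max(1e-5, coarse$mal - 2e-3), coarse$mal + 2e-3,
                   by = 1e-4))
  list(pH = fine$pH, mal = fine$mal, ph_step = 0.002, mal_step = 1e-4)
}

# brute-force inversion of the coupled equilibria for dG_ATP by bisection:
# the forward map dG -> equilibrium malate is monotone decreasing in dG.
oracle_invert_dg <- function(observed_mal, medium, pump, temperature,
                             lo = -9e4, hi = -1e3, iter = 200) {
  fwd <- function(g) {
    vacuolar_malate_equilibrium(
      medium, pump, delta_psi_atpase(medium$pH_vac, pump, g, temperature),
      temperature, exponent_guard = 200) - observed_mal
  }
  for (i in seq_len(iter)) {
    mid <- 0.5 * (lo + hi)
    if (fwd(mid) > 0) lo <- mid else hi <- mid
  }
  0.5 * (lo + hi)
}

# random but always-solvable pulp media (acid pool dominates the strong
# cations so a charge-balance root exists below pH 8)
random_composition <- function() {
  pulp_composition(
    K = runif(1, 0.012, 0.03), Mg = runif(1, 0, 0.005),
    Ca = runif(1, 0, 0.002), P = runif(1, 0.001, 0.006),
    Cl = runif(1, 0.001, 0.004), citrate = runif(1, 0.015, 0.04),
    oxalate = runif(1, 0.002, 0.008), malate = runif(1, 0.01, 0.05),
    temperature = runif(1, 288, 303)
  )
}
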