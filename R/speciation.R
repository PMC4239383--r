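#' Speciation configuration
#'
#' Thermodynamic dissociation constants (25 degC, infinite dilution), the
#' Davies coefficient, and numerical tolerances used by the vacuolar pH
#' model. The pKa set covers the acids the model tracks in banana pulp:
#' malate, citrate, oxalate and phosphate, plus the water ion product.
#'
#' @param pka Named list of pKa vectors, one per acid (successive proton
#'   dissociations, increasing).
#' @param pKw Water ion product, -log10 Kw.
#' @param davies_A Davies coefficient A at the reference temperature.
#' @param davies_dAdT Optional linear temperature correction dA/dT (K^-1)
#'   about 298.15 K; 0 disables it.
#' @param I_tol Convergence tolerance on the ionic-strength fixed point,
#'   mol L^-1.
#' @param I_maxit Maximum ionic-strength iterations.
#' @param pH_range pH bracket for the charge-balance root.
#' @param bisect_iter Bisection iterations for the pH root.
#' @return A list of class `speciation_config`.
#' @examples
#' cfg <- speciation_config()
#' cfg$pka$malate
#' @export
speciation_config <- function(pka = list(malate    = c(3.40, 5.11),
                                         citrate   = c(3.13, 4.76, 6.40),
                                         oxalate   = c(1.25, 4.27),
                                         phosphate = c(2.15, 7.21, 12.35)),
                              pKw = 14.0,
                              davies_A = 0.509,
                              davies_dAdT = 0,
                              I_tol = 1e-10,
                              I_maxit = 100L,
                              pH_range = c(2, 8),
                              bisect_iter = 60L) {
  stopifnot(is.list(pka), all(c("malate", "citrate", "oxalate", "phosphate")
                              %in% names(pka)),
            I_tol > 0, pH_range[1] < pH_range[2])
  structure(list(pka = pka, pKw = pKw, davies_A = davies_A,
                 davies_dAdT = davies_dAdT, I_tol = I_tol,
                 I_maxit = as.integer(I_maxit), pH_range = pH_range,
                 bisect_iter = as.integer(bisect_iter)),
            class = "speciation_config")
}

#' Pulp composition (per litre of pulp water)
#'
#' Soluble composition of the pulp expressed in mol per litre of pulp water
#' — the concentration scale on which vacuolar speciation is computed. The
#' cations K+, Mg2+ and Ca2+ and the anion Cl- are treated as fully
#' dissociated spectator charges; P enters as total phosphate; citrate,
#' oxalate and malate as total weak acid.
#'
#' All arguments are vectorized over samples (recycled to a common length).
#'
#' @param K,Mg,Ca,P,Cl,citrate,oxalate,malate Concentrations, mol L^-1
#'   (>= 0).
#' @param temperature Temperature, K.
#' @return An object of class `pulp_composition` (list of aligned vectors).
#' @examples
#' pulp_composition(K = 0.03, citrate = 0, oxalate = 0, malate = 0.01,
#'                  Cl = 0.005)
#' @export
pulp_composition <- function(K = 0, Mg = 0, Ca = 0, P = 0, Cl = 0,
                             citrate = 0, oxalate = 0, malate = 0,
                             temperature = 298.15) {
  m <- max(lengths(list(K, Mg, Ca, P, Cl, citrate, oxalate, malate,
                        temperature)))
  comp <- list(K = rep_len(K, m), Mg = rep_len(Mg, m), Ca = rep_len(Ca, m),
               P = rep_len(P, m), Cl = rep_len(Cl, m),
               citrate = rep_len(citrate, m), oxalate = rep_len(oxalate, m),
               malate = rep_len(malate, m),
               temperature = rep_len(temperature, m))
  conc <- unlist(comp[setdiff(names(comp), "temperature")])
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("all concentrations must be finite and >= 0", call. = FALSE)
  if (any(comp$temperature < 250) || any(comp$temperature > 340))
    stop("temperature must be in kelvin (250-340 K)", call. = FALSE)
  structure(comp, class = "pulp_composition")
}

#' Ionic strength
#'
#' I = 1/2 sum(c_i z_i^2) over all charged species.
#'
#' @param concentration Species concentrations, mol L^-1 (>= 0).
#' @param charge Corresponding signed charges.
#' @return Ionic strength, mol L^-1.
#' @examples
#' ionic_strength(c(0.1, 0.1), c(1, -1))
#' @export
ionic_strength <- function(concentration, charge) {
  stopifnot(length(concentration) == length(charge))
  if (any(concentration < 0)) stop("concentrations must be >= 0",
                                   call. = FALSE)
  0.5 * sum(concentration * charge^2)
}

#' Davies activity coefficient
#'
#' log10(gamma) = -A z^2 (sqrt(I)/(1 + sqrt(I)) - 0.3 I). Neutral species
#' and infinite dilution give gamma = 1.
#'
#' @param charge Signed species charge (integer-valued); vectorized.
#' @param I Ionic strength, mol L^-1 (>= 0); vectorized.
#' @param temperature Temperature, K (used only when the configuration
#'   enables a linear A(T) correction).
#' @param cfg A [speciation_config()].
#' @return Activity coefficient gamma (dimensionless).
#' @examples
#' davies_activity(2, 0.3)
#' @export
davies_activity <- function(charge, I, temperature = 298.15,
                            cfg = speciation_config()) {
  if (any(I < 0)) stop("ionic strength must be >= 0", call. = FALSE)
  A <- cfg$davies_A + cfg$davies_dAdT * (temperature - 298.15)
  s <- sqrt(I)
  10^(-A * charge^2 * (s / (1 + s) - 0.3 * I))
}

# --- internal speciation engine -------------------------------------------
#
# Everything below is vectorized across samples: `pH`, the composition
# vectors and the returned fields are parallel vectors of one common length.
# This is what makes series solving and PSO calibration affordable: one
# bisection runs for all samples of a dataset at once.

# species distribution of one polyprotic acid (1-3 protons) at hydrogen-ion
# activity h, given per-sample activity coefficients gam[[z]] for |z| = 1..3.
# Apparent constants on the concentration scale are K'_j = K_j g_{j-1}/g_j.
# Returns charge = total anion charge conc., iz2 = sum(c z^2) for I.
acid_contrib <- function(total, pk, h, gam) {
  n <- length(pk)
  K1 <- 10^(-pk[1L]) / gam[[1L]]
  if (n == 1L) {
    t1 <- K1
    den <- h + t1
    f1 <- t1 / den
    return(list(charge = total * f1, iz2 = total * f1,
                K1_app = K1, K2_app = NULL))
  }
  K2 <- 10^(-pk[2L]) * gam[[1L]] / gam[[2L]]
  if (n == 2L) {
    t1 <- h * K1
    t2 <- K1 * K2
    den <- h * h + t1 + t2
    chg <- total * (t1 + 2 * t2) / den
    iz2 <- total * (t1 + 4 * t2) / den
    return(list(charge = chg, iz2 = iz2, K1_app = K1, K2_app = K2))
  }
  K3 <- 10^(-pk[3L]) * gam[[2L]] / gam[[3L]]
  h2 <- h * h
  t1 <- h2 * K1
  t2 <- h * K1 * K2
  t3 <- K1 * K2 * K3
  den <- h2 * h + t1 + t2 + t3
  chg <- total * (t1 + 2 * t2 + 3 * t3) / den
  iz2 <- total * (t1 + 4 * t2 + 9 * t3) / den
  list(charge = chg, iz2 = iz2, K1_app = K1, K2_app = K2)
}

# one vectorized pass of the speciation arithmetic at fixed pH and fixed
# ionic-strength estimate. The Davies law scales log(gamma) with z^2, so
# gamma_z = gamma_1^(z^2). Returns species charge totals, the updated ionic
# strength, the malate apparent constants and the charge-balance residual.
core_pass <- function(comp, pH, I, cfg) {
  h <- 10^(-pH)                      # hydrogen-ion activity
  A <- cfg$davies_A + cfg$davies_dAdT * (comp$temperature - 298.15)
  s <- sqrt(I)
  g1 <- 10^(-A * (s / (1 + s) - 0.3 * I))
  gam <- list(g1, g1^4, g1^9)
  Hc  <- h / g1
  OHc <- 10^(pH - cfg$pKw) / g1
  chg <- 0
  iz2 <- 0
  mal_k <- NULL
  # pKa-set name -> composition field
  acids <- c(malate = "malate", citrate = "citrate", oxalate = "oxalate",
             phosphate = "P")
  for (a in names(acids)) {
    ac <- acid_contrib(comp[[acids[[a]]]], cfg$pka[[a]], h, gam)
    chg <- chg + ac$charge
    iz2 <- iz2 + ac$iz2
    if (a == "malate") mal_k <- ac
  }
  I_new <- 0.5 * (comp$K + 4 * comp$Mg + 4 * comp$Ca + comp$Cl +
                    Hc + OHc + iz2)
  res <- comp$K + 2 * comp$Mg + 2 * comp$Ca + Hc - comp$Cl - OHc - chg
  list(pH = pH, I = I_new, charge_residual = res,
       K1_app = mal_k$K1_app, K2_app = mal_k$K2_app,
       a_mal2 = gam[[2L]], gamma1 = gam[[1L]], gamma2 = gam[[2L]],
       gamma3 = gam[[3L]])
}

# ionic-strength/activity fixed point at fixed pH. comp fields and pH are
# parallel vectors. Returns per-sample medium constants and the
# charge-balance residual (cations - anions, mol/L).
spec_core <- function(comp, pH, cfg, I_init = NULL) {
  m <- length(pH)
  I <- if (is.null(I_init)) rep_len(0, m) else rep_len(I_init, m)
  for (it in seq_len(cfg$I_maxit)) {
    st <- core_pass(comp, pH, I, cfg)
    done <- max(abs(st$I - I)) < cfg$I_tol
    I <- st$I
    if (done) break
  }
  st
}

# vectorized bisection for the pH at which the charge balance closes.
# Residual (cations - anions) decreases with pH; each sample keeps its own
# bracket. Errors if any sample has no sign change over cfg$pH_range.
spec_solve_ph <- function(comp, cfg) {
  m <- length(comp$K)
  lo <- rep_len(cfg$pH_range[1], m)
  hi <- rep_len(cfg$pH_range[2], m)
  rlo <- spec_core(comp, lo, cfg)$charge_residual
  rhi <- spec_core(comp, hi, cfg)$charge_residual
  bad <- rlo < 0 | rhi > 0
  if (any(bad))
    stop("charge balance has no root in pH range [", cfg$pH_range[1], ", ",
         cfg$pH_range[2], "] for ", sum(bad), " sample(s)", call. = FALSE)
  I_warm <- NULL
  for (it in seq_len(cfg$bisect_iter)) {
    mid <- 0.5 * (lo + hi)
    st <- spec_core(comp, mid, cfg, I_init = I_warm)
    I_warm <- st$I
    up <- st$charge_residual > 0
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  spec_core(comp, 0.5 * (lo + hi), cfg)
}

#' Solve the vacuolar acid-base speciation
#'
#' Finds the vacuolar pH at which the medium is electroneutral: fully
#' dissociated K+, Mg2+, Ca2+ and Cl- against the pH-dependent anion charge
#' of malate, citrate, oxalate and phosphate, plus H+ and OH-. Apparent
#' acidity constants and the di-anion malate activity coefficient are
#' corrected for ionic strength by the Davies equation, and ionic strength
#' and pH are iterated to joint convergence.
#'
#' @param comp A [pulp_composition()]; when `trial_mal_vac` is supplied it
#'   replaces the composition's malate entry (the stationary-state solver
#'   iterates on this argument).
#' @param trial_mal_vac Optional total vacuolar malate, mol L^-1.
#' @param cfg A [speciation_config()].
#' @return An object of class `speciation_result`: parallel vectors
#'   `pH_vac`, `K1_app`, `K2_app`, `a_mal2`, `ionic_strength`,
#'   `charge_residual` (mol L^-1), plus the activity coefficients
#'   `gamma1`..`gamma3`.
#' @examples
#' sp <- speciate(pulp_composition(K = 0.03, malate = 0.01, Cl = 0.005))
#' sp$pH_vac
#' @export
speciate <- function(comp, trial_mal_vac = NULL, cfg = speciation_config()) {
  stopifnot(inherits(comp, "pulp_composition"))
  if (!is.null(trial_mal_vac)) {
    if (any(trial_mal_vac < 0)) stop("trial_mal_vac must be >= 0",
                                     call. = FALSE)
    comp$malate <- rep_len(trial_mal_vac, length(comp$malate))
  }
  st <- spec_solve_ph(comp, cfg)
  structure(list(pH_vac = st$pH, K1_app = st$K1_app, K2_app = st$K2_app,
                 a_mal2 = st$a_mal2, ionic_strength = st$I,
                 charge_residual = st$charge_residual,
                 gamma1 = st$gamma1, gamma2 = st$gamma2, gamma3 = st$gamma3),
            class = "speciation_result")
}

#' Vacuolar medium with a measured pH
#'
#' Builds the vacuolar medium used by the malate equations with the pH fixed
#' at a measurement (pulp pH as a proxy for vacuolar pH) while the apparent
#' acidity constants and the di-anion activity coefficient are still
#' computed from the composition at that pH. This is the "pH known" mode of
#' the sensitivity analysis.
#'
#' @param measured_pH Measured pulp pH, in \[2, 8\]; scalar.
#' @param comp A [pulp_composition()] (single sample).
#' @param cfg A [speciation_config()].
#' @return A [vacuolar_medium()].
#' @export
measured_ph_medium <- function(measured_pH, comp, cfg = speciation_config()) {
  stopifnot(inherits(comp, "pulp_composition"))
  if (!is.finite(measured_pH) || measured_pH < 2 || measured_pH > 8)
    stop("measured_pH must lie in [2, 8]", call. = FALSE)
  st <- spec_core(comp, rep_len(measured_pH, length(comp$K)), cfg)
  vacuolar_medium(measured_pH, st$K1_app[1], st$K2_app[1], st$a_mal2[1])
}

#' Extract a vacuolar medium from a speciation result
#'
#' @param x A `speciation_result`.
#' @param i Sample index.
#' @return A [vacuolar_medium()].
#' @export
as_medium <- function(x, i = 1L) {
  stopifnot(inherits(x, "speciation_result"))
  vacuolar_medium(x$pH_vac[i], x$K1_app[i], x$K2_app[i], x$a_mal2[i])
}
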