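#' Solver settings
#'
#' Numerical controls for the coupled stationary-state solve of
#' (vacuolar malate, vacuolar pH).
#'
#' @param tol Relative tolerance on the malate equilibrium residual.
#' @param charge_tol Absolute tolerance on the charge-balance residual,
#'   mol L^-1.
#' @param mal_init Starting vacuolar malate, mol L^-1, used when a sample
#'   carries no observed malate.
#' @param mal_cap Upper cap on malate iterates, mol L^-1; iterates beyond it
#'   only occur at bracketing extremes and are flagged if final.
#' @param inner_maxit Maximum fixed-point iterations for malate at fixed pH.
#' @param bisect_iter Bisection iterations on pH.
#' @param method Solver family identifier (`"bracketing"`; kept for
#'   provenance in outputs).
#' @return A list of class `solve_settings`.
#' @export
solve_settings <- function(tol = 1e-10, charge_tol = 1e-9,
                           mal_init = 0.01, mal_cap = 2,
                           inner_maxit = 40L, bisect_iter = 48L,
                           method = "bracketing") {
  stopifnot(tol > 0, charge_tol > 0, mal_init > 0, mal_cap > mal_init)
  structure(list(tol = tol, charge_tol = charge_tol, mal_init = mal_init,
                 mal_cap = mal_cap, inner_maxit = as.integer(inner_maxit),
                 bisect_iter = as.integer(bisect_iter), method = method),
            class = "solve_settings")
}

#' Convert between fresh-weight and molar concentration scales
#'
#' Solute measurements on fruit pulp are reported per kg fresh weight; the
#' speciation and transport equations work in mol per litre of pulp water,
#' taking the water mass as FW - DW (and vacuolar water volume equal to the
#' pulp water mass).
#'
#' @param x Concentration in mmol kg FW^-1.
#' @param conc Concentration in mol L^-1 of pulp water.
#' @param FW,DW Pulp fresh and dry weight, g.
#' @return The concentration on the other scale.
#' @examples
#' conc_fw_to_molar(15, FW = 100, DW = 25)
#' conc_molar_to_fw(0.02, FW = 100, DW = 25)
#' @export
conc_fw_to_molar <- function(x, FW, DW) {
  if (any(DW <= 0) || any(DW >= FW))
    stop("weights must satisfy FW > DW > 0", call. = FALSE)
  x * FW / (1000 * (FW - DW))
}

#' @rdname conc_fw_to_molar
#' @export
conc_molar_to_fw <- function(conc, FW, DW) pulp_malate(conc, FW, DW)

# composition list (solutes other than solved malate) from a samples
# data.frame; malate slot is filled by the solver.
samples_composition <- function(samples, malate = 0) {
  pulp_composition(K = samples$K, Mg = samples$Mg, Ca = samples$Ca,
                   P = samples$P, Cl = samples$Cl,
                   citrate = samples$citrate, oxalate = samples$oxalate,
                   malate = malate, temperature = samples$temperature)
}

required_sample_cols <- function() {
  c("stage", "time", "temperature", "FW", "DW",
    "K", "Mg", "Ca", "P", "Cl", "citrate", "oxalate")
}

check_samples <- function(samples) {
  miss <- setdiff(required_sample_cols(), names(samples))
  if (length(miss))
    stop("samples are missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(samples$stage %in% c("growth", "ripening")))
    stop("stage must be 'growth' or 'ripening'", call. = FALSE)
  if (any(samples$time < 0)) stop("time must be >= 0", call. = FALSE)
  if (any(samples$DW <= 0) || any(samples$DW >= samples$FW))
    stop("weights must satisfy FW > DW > 0", call. = FALSE)
  invisible(samples)
}

# joint fixed point for (malate, ionic strength) at fixed pH, vectorized
# across samples. dPsi depends on pH only; the malate iterate feeds back
# through ionic strength into the apparent constants and the di-anion
# activity, a weak coupling, so plain iteration converges fast. Each
# iteration is a single speciation pass.
inner_malate <- function(comp, pH, dPsi, temp, pump, settings, cfg,
                         mal0, I_warm = NULL, tol = settings$tol) {
  cn <- tonoplast_constants()
  expo <- exp(pmin(50, pmax(-50, 2 * cn$Faraday * dPsi / (cn$R * temp))))
  h <- 10^(-pH)
  mal <- mal0
  if (is.null(I_warm)) I_warm <- rep_len(0.05, length(pH))
  st <- NULL
  for (k in seq_len(settings$inner_maxit)) {
    comp$malate <- mal
    st <- core_pass(comp, pH, I_warm, cfg)
    k12 <- st$K1_app * st$K2_app
    dfac <- (h^2 + h * st$K1_app + k12) / k12
    mal_new <- pmin(settings$mal_cap,
                    (1 / st$a_mal2) * dfac * pump$mal2_cyt * expo)
    done <- max(abs(mal_new - mal) / pmax(mal_new, 1e-12)) < tol &&
      max(abs(st$I - I_warm)) < cfg$I_tol
    mal <- mal_new
    I_warm <- st$I
    if (done) break
  }
  comp$malate <- mal
  st <- core_pass(comp, pH, I_warm, cfg)
  list(mal = mal, st = st, dPsi = dPsi)
}

# vectorized coupled solve over a set of samples. Returns parallel vectors;
# samples whose charge balance has no root in the pH range come back with
# NA and ok = FALSE instead of aborting the series.
solve_engine <- function(samples, pump, energy, settings, cfg) {
  check_samples(samples)
  m <- nrow(samples)
  comp <- samples_composition(samples)
  temp <- samples$temperature
  dG <- dg_atp_for(energy, samples$stage, samples$time)

  mal0 <- rep_len(settings$mal_init, m)
  if ("observed_malate" %in% names(samples)) {
    obs <- conc_fw_to_molar(samples$observed_malate, samples$FW, samples$DW)
    use <- !is.na(obs) & obs > 0
    mal0[use] <- obs[use]
  }

  lo <- rep_len(cfg$pH_range[1], m)
  hi <- rep_len(cfg$pH_range[2], m)
  # bracketing runs at a loose inner tolerance (only the residual sign
  # matters); the final state is polished at the full tolerance.
  res_at <- function(pH, mal_start, I_warm = NULL, tol = 1e-7) {
    dPsi <- delta_psi_atpase(pH, pump, dG, temp)
    inner_malate(comp, pH, dPsi, temp, pump, settings, cfg,
                 mal0 = mal_start, I_warm = I_warm, tol = tol)
  }
  st_lo <- res_at(lo, mal0)
  st_hi <- res_at(hi, st_lo$mal)
  ok <- st_lo$st$charge_residual >= 0 & st_hi$st$charge_residual <= 0

  mal_warm <- st_lo$mal
  I_warm <- NULL
  for (it in seq_len(settings$bisect_iter)) {
    mid <- 0.5 * (lo + hi)
    fp <- res_at(mid, mal_warm, I_warm)
    mal_warm <- fp$mal
    I_warm <- fp$st$I
    up <- fp$st$charge_residual > 0
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  pH <- 0.5 * (lo + hi)
  fin <- res_at(pH, mal_warm, I_warm, tol = settings$tol)
  # Newton polish on pH: the loose bracketing tolerance biases the bisection
  # root by O(tol); two damped Newton steps at full tolerance remove it.
  for (j in 1:2) {
    r0 <- fin$st$charge_residual
    dpH <- 1e-6
    r1 <- res_at(pH + dpH, fin$mal, fin$st$I,
                 tol = settings$tol)$st$charge_residual
    slope <- (r1 - r0) / dpH
    step <- ifelse(is.finite(slope) & slope != 0, -r0 / slope, 0)
    step <- pmin(pmax(step, -0.02), 0.02)
    pH <- pH + step
    fin <- res_at(pH, fin$mal, fin$st$I, tol = settings$tol)
  }

  cn <- tonoplast_constants()
  dPsi <- delta_psi_atpase(pH, pump, dG, temp)
  n <- coupling_ratio(pH, pump)
  h <- 10^(-pH)
  k12 <- fin$st$K1_app * fin$st$K2_app
  dfac <- (h^2 + h * fin$st$K1_app + k12) / k12
  mal_eq <- (1 / fin$st$a_mal2) * dfac * pump$mal2_cyt *
    exp(2 * cn$Faraday * dPsi / (cn$R * temp))
  eq_res <- abs(fin$mal - mal_eq) / pmax(mal_eq, 1e-12)
  conv <- ok & eq_res < 1e3 * settings$tol &
    abs(fin$st$charge_residual) < settings$charge_tol &
    fin$mal < settings$mal_cap

  out <- data.frame(
    mal_vac = fin$mal, pH_vac = pH, delta_psi = dPsi, n = n,
    mal_fruit = pulp_malate(fin$mal, samples$FW, samples$DW),
    dG_ATP = dG,
    a_mal2 = fin$st$a_mal2, K1_app = fin$st$K1_app, K2_app = fin$st$K2_app,
    ionic_strength = fin$st$I,
    charge_residual = fin$st$charge_residual, eq_residual = eq_res,
    converged = conv
  )
  out[!ok, c("mal_vac", "pH_vac", "delta_psi", "n", "mal_fruit")] <- NA_real_
  out
}

#' Solve one stationary vacuolar state
#'
#' Finds the pair (vacuolar malate, vacuolar pH) at which (i) the vacuolar
#' medium including the solved malate is electroneutral (the speciation
#' model) and (ii) total malate satisfies di-anion transport equilibrium at
#' the membrane potential set by the ATPase equilibrium. Each sampling date
#' is an independent stationary state.
#'
#' @param sample A single-row data.frame (or coercible list) with columns
#'   `stage`, `time` (days after bloom, or days after ethylene),
#'   `temperature` (K), `FW`, `DW` (g) and solute concentrations `K`, `Mg`,
#'   `Ca`, `P`, `Cl`, `citrate`, `oxalate` in mol per litre of pulp water;
#'   optional `observed_malate` (mmol kg FW^-1) seeds the iteration.
#' @param pump A [pump_parameters()].
#' @param energy An [energy_constant()] or [energy_polynomial()] model.
#' @param settings A [solve_settings()].
#' @param cfg A [speciation_config()].
#' @return A list of class `vacuole_solution`: `mal_vac` (mol L^-1),
#'   `pH_vac`, `delta_psi` (V), `n`, `mal_fruit` (mmol kg FW^-1), the medium
#'   constants, residual diagnostics and a `converged` flag.
#' @examples
#' s <- data.frame(stage = "growth", time = 60, temperature = 300.15,
#'                 FW = 80, DW = 20, K = 0.08, Mg = 0.008, Ca = 0.002,
#'                 P = 0.008, Cl = 0.004, citrate = 0.02, oxalate = 0.01)
#' sol <- solve_state(s, pump_parameters(), energy_constant(-39e3))
#' sol$mal_fruit
#' @export
solve_state <- function(sample, pump = pump_parameters(), energy,
                        settings = solve_settings(),
                        cfg = speciation_config()) {
  sample <- as.data.frame(sample)
  if (nrow(sample) != 1L)
    stop("solve_state() expects a single sample; use simulate_series() for ",
         "several", call. = FALSE)
  out <- solve_engine(sample, pump, energy, settings, cfg)
  sol <- as.list(out[1L, ])
  if (!sol$converged && is.na(sol$pH_vac))
    warning("no stationary state in the configured pH range", call. = FALSE)
  structure(sol, class = "vacuole_solution")
}

#' @export
print.vacuole_solution <- function(x, ...) {
  cat("Stationary vacuolar state\n")
  cat(sprintf("  [Mal_vac] = %.5g mol/L   pH_vac = %.4f\n",
              x$mal_vac, x$pH_vac))
  cat(sprintf("  dPsi = %.4g mV   n = %.3f\n", 1000 * x$delta_psi, x$n))
  cat(sprintf("  [Mal_fruit] = %.4g mmol/kg FW   (converged: %s)\n",
              x$mal_fruit, x$converged))
  invisible(x)
}

#' Simulate a time series of stationary states
#'
#' Solves every sample of a dataset independently (no state is carried
#' between dates): the model treats development as a succession of
#' stationary states. In ripening mode the ATP-hydrolysis energy is
#' evaluated per sample from its days-after-ethylene via the quadratic
#' energy model. Per-sample failures are reported in the `converged` column
#' rather than aborting the series.
#'
#' @param samples Data.frame of samples (see [solve_state()] for columns);
#'   zero rows give a zero-row result.
#' @inheritParams solve_state
#' @return A data.frame, one row per sample, binding the sample identifiers
#'   (`stage`, `time`, plus `cultivar` and `observed_malate` when present)
#'   to the solution columns of [solve_state()].
#' @export
simulate_series <- function(samples, pump = pump_parameters(), energy,
                            settings = solve_settings(),
                            cfg = speciation_config()) {
  samples <- as.data.frame(samples)
  if (nrow(samples) == 0L) {
    return(data.frame(stage = character(), time = numeric(),
                      mal_vac = numeric(), pH_vac = numeric(),
                      delta_psi = numeric(), n = numeric(),
                      mal_fruit = numeric(), converged = logical()))
  }
  out <- solve_engine(samples, pump, energy, settings, cfg)
  id_cols <- intersect(c("cultivar", "stage", "time", "observed_malate",
                         "measured_pH"),
                       names(samples))
  cbind(samples[id_cols], out)
}
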