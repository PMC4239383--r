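#' Physical constants of the tonoplast model
#'
#' Gas constant and Faraday constant used throughout the thermodynamic
#' equations. Values are fixed to the conventions of the model; temperature
#' is not a constant here — it is carried on each sample, in kelvin.
#'
#' @return A list with elements `R` (gas constant, J mol^-1 K^-1) and
#'   `Faraday` (Faraday constant, C mol^-1).
#' @examples
#' tonoplast_constants()$R
#' @export
tonoplast_constants <- function() {
  list(R = 8.3144621, Faraday = 9.65e4)
}

#' Proton-pump parameters
#'
#' Container for the cytosolic-side parameters of the vacuolar H+-ATPase
#' model: cytosolic pH, the (constant) activity of di-anion malate in the
#' cytosol, and the three constants of the pH-dependent coupling ratio
#' n = n0 + alpha * (pH_vac - 7) + beta * 10^(pH_cyt - 7).
#'
#' Defaults are the literature values used for banana: pH_cyt = 7,
#' (Mal2-cyt) = 0.001 mol L^-1, n0 = 4, alpha = 0.3, beta = -0.12.
#'
#' @param pH_cyt Cytosolic pH (must lie in \[6, 8\]).
#' @param mal2_cyt Activity of cytosolic di-anion malate, mol L^-1 (> 0).
#' @param n0,alpha,beta Dimensionless coupling-ratio constants.
#' @return An object of class `pump_parameters`.
#' @examples
#' pump_parameters()
#' pump_parameters(pH_cyt = 7.2)
#' @export
pump_parameters <- function(pH_cyt = 7, mal2_cyt = 0.001,
                            n0 = 4, alpha = 0.3, beta = -0.12) {
  if (!is.finite(pH_cyt) || pH_cyt < 6 || pH_cyt > 8)
    stop("pH_cyt must be a finite value in [6, 8]", call. = FALSE)
  if (!is.finite(mal2_cyt) || mal2_cyt <= 0)
    stop("mal2_cyt (cytosolic di-anion malate activity) must be > 0",
         call. = FALSE)
  structure(list(pH_cyt = pH_cyt, mal2_cyt = mal2_cyt,
                 n0 = n0, alpha = alpha, beta = beta),
            class = "pump_parameters")
}

#' @export
print.pump_parameters <- function(x, ...) {
  cat("Proton-pump parameters\n")
  cat(sprintf("  pH_cyt   = %g\n", x$pH_cyt))
  cat(sprintf("  (Mal2-cyt) = %g mol/L\n", x$mal2_cyt))
  cat(sprintf("  n0 = %g, alpha = %g, beta = %g\n", x$n0, x$alpha, x$beta))
  invisible(x)
}

#' ATP-hydrolysis energy models
#'
#' The free energy of ATP hydrolysis, dG_ATP (J mol^-1), is treated as a
#' constant during fruit growth and as a quadratic function of days after
#' ethylene treatment (DAE) during post-harvest ripening:
#' dG_ATP(DAE) = G1 * DAE^2 + G2 * DAE + G3.
#'
#' @param dG_ATP Constant free energy of ATP hydrolysis, J mol^-1 (< 0).
#' @return An object of class `energy_model`.
#' @examples
#' energy_constant(-36.9e3)
#' energy_polynomial(75, -1176, -45.2e3)
#' @export
energy_constant <- function(dG_ATP) {
  if (!is.finite(dG_ATP) || dG_ATP >= 0)
    stop("dG_ATP must be negative (ATP hydrolysis releases free energy)",
         call. = FALSE)
  structure(list(mode = "constant", dG_ATP = dG_ATP),
            class = "energy_model")
}

#' @rdname energy_constant
#' @param G1 Quadratic coefficient, J mol^-1 day^-2.
#' @param G2 Linear coefficient, J mol^-1 day^-1.
#' @param G3 Intercept, J mol^-1.
#' @param dae_window Days-after-ethylene window over which the polynomial
#'   must stay negative; checked at construction.
#' @export
energy_polynomial <- function(G1, G2, G3, dae_window = c(0, 13)) {
  stopifnot(length(dae_window) == 2L, dae_window[1] <= dae_window[2])
  dae <- seq(dae_window[1], dae_window[2], length.out = 200L)
  vals <- G1 * dae^2 + G2 * dae + G3
  if (any(!is.finite(vals)) || any(vals >= 0))
    stop("dG_ATP polynomial must remain negative over the DAE window",
         call. = FALSE)
  structure(list(mode = "ripening_polynomial",
                 G1 = G1, G2 = G2, G3 = G3, dae_window = dae_window),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  if (x$mode == "constant") {
    cat(sprintf("Energy model: constant dG_ATP = %g J/mol\n", x$dG_ATP))
  } else {
    cat(sprintf(
      "Energy model: dG_ATP(DAE) = %g*DAE^2 + %g*DAE + %g J/mol (DAE in [%g, %g])\n",
      x$G1, x$G2, x$G3, x$dae_window[1], x$dae_window[2]))
  }
  invisible(x)
}

#' Evaluate the ATP-hydrolysis free energy at a ripening date
#'
#' @param dae Days after ethylene treatment (>= 0); vectorized.
#' @param energy An `energy_model` in `ripening_polynomial` mode.
#' @return dG_ATP in J mol^-1.
#' @examples
#' pl <- energy_polynomial(110, -1959, -46.3e3)
#' dg_atp_at(13, pl)
#' @export
dg_atp_at <- function(dae, energy) {
  stopifnot(inherits(energy, "energy_model"))
  if (energy$mode != "ripening_polynomial")
    stop("dg_atp_at() requires an energy model in 'ripening_polynomial' mode",
         call. = FALSE)
  if (any(dae < 0)) stop("dae must be >= 0", call. = FALSE)
  energy$G1 * dae^2 + energy$G2 * dae + energy$G3
}

# dG_ATP for any energy model at a sample's time point (internal)
dg_atp_for <- function(energy, stage, time) {
  if (energy$mode == "constant") {
    rep_len(energy$dG_ATP, length(time))
  } else {
    if (!all(stage == "ripening"))
      stop("ripening_polynomial energy model requires stage == 'ripening'",
           call. = FALSE)
    dg_atp_at(time, energy)
  }
}

#' Published banana model parameters
#'
#' Calibrated per-cultivar parameters of the banana malate model for the
#' three dessert cultivars IDN (Indonesia 110), PJB (Pisang Jari Buaya) and
#' PL (Pisang Lilin): the constant dG_ATP during fruit growth and the
#' quadratic coefficients G1-G3 driving dG_ATP during post-harvest ripening.
#'
#' @return A data.frame with columns `cultivar`, `dG_ATP_growth` (J mol^-1),
#'   `G1` (J mol^-1 day^-2), `G2` (J mol^-1 day^-1), `G3` (J mol^-1).
#' @examples
#' banana_parameters()
#' @export
banana_parameters <- function() {
  data.frame(
    cultivar      = c("IDN", "PJB", "PL"),
    dG_ATP_growth = c(-36.9e3, -39.1e3, -47.4e3),
    G1            = c(75, 69, 110),
    G2            = c(-1176, -1108, -1959),
    G3            = c(-45.2e3, -48.9e3, -46.3e3),
    stringsAsFactors = FALSE
  )
}

#' Vacuolar medium descriptor
#'
#' The acid-base state of the vacuole as seen by the malate equations:
#' vacuolar pH, the apparent (ionic-strength corrected) acidity constants of
#' malate, and the activity coefficient of the di-anion.
#'
#' Usually produced by [speciate()] or [measured_ph_medium()]; the
#' constructor is exported for direct use with known constants.
#'
#' @param pH_vac Vacuolar pH, in \[2, 8\].
#' @param K1_app,K2_app Apparent first and second acidity constants of
#'   malate, mol L^-1; must satisfy K1_app > K2_app > 0.
#' @param a_mal2 Activity coefficient of vacuolar di-anion malate, in (0, 1].
#' @return An object of class `vacuolar_medium`.
#' @examples
#' vacuolar_medium(4.6, 10^-3.40, 10^-5.11, 0.3)
#' @export
vacuolar_medium <- function(pH_vac, K1_app, K2_app, a_mal2) {
  if (!is.finite(pH_vac) || pH_vac < 2 || pH_vac > 8)
    stop("pH_vac must lie in [2, 8]", call. = FALSE)
  if (!(K1_app > K2_app && K2_app > 0))
    stop("apparent acidity constants must satisfy K1_app > K2_app > 0",
         call. = FALSE)
  if (!(a_mal2 > 0 && a_mal2 <= 1))
    stop("a_mal2 must lie in (0, 1]", call. = FALSE)
  structure(list(pH_vac = pH_vac, K1_app = K1_app, K2_app = K2_app,
                 a_mal2 = a_mal2),
            class = "vacuolar_medium")
}
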