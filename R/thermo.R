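#' Coupling ratio of the vacuolar H+-ATPase
#'
#' Number of protons pumped into the vacuole per ATP hydrolyzed, modeled as
#' a linear function of vacuolar pH with an exponential cytosolic-pH term:
#' n = n0 + alpha * (pH_vac - 7) + beta * 10^(pH_cyt - 7).
#'
#' @param pH_vac Vacuolar pH; vectorized.
#' @param pump A [pump_parameters()] object.
#' @return The coupling ratio n (dimensionless, > 0).
#' @examples
#' coupling_ratio(5, pump_parameters())
#' @export
coupling_ratio <- function(pH_vac, pump = pump_parameters()) {
  n <- pump$n0 + pump$alpha * (pH_vac - 7) + pump$beta * 10^(pump$pH_cyt - 7)
  if (any(!is.finite(n)) || any(n <= 0))
    stop("coupling ratio n <= 0: pump stoichiometry is meaningless in this ",
         "parameter region", call. = FALSE)
  n
}

#' Free energy of the chemiosmotic ATPase reaction
#'
#' dG_ATPase = dG_ATP + n F dPsi - n R T ln(10) (pH_vac - pH_cyt).
#' Proton pumping can proceed only while this is negative; the model assumes
#' operation at dG_ATPase = 0 (see [delta_psi_atpase()]). Exposed as a
#' diagnostic.
#'
#' @param delta_psi Tonoplast membrane potential, psi_vac - psi_cyt, V.
#' @param pH_vac Vacuolar pH.
#' @param pump A [pump_parameters()] object.
#' @param dG_ATP Free energy of ATP hydrolysis, J mol^-1 (< 0).
#' @param temperature Temperature, K.
#' @return dG_ATPase in J mol^-1.
#' @export
delta_g_atpase <- function(delta_psi, pH_vac, pump, dG_ATP, temperature) {
  cn <- tonoplast_constants()
  n <- coupling_ratio(pH_vac, pump)
  dG_ATP + n * cn$Faraday * delta_psi -
    n * cn$R * temperature * log(10) * (pH_vac - pump$pH_cyt)
}

#' Membrane potential at ATPase thermodynamic equilibrium
#'
#' Solves dG_ATPase = 0 for the tonoplast potential:
#' dPsi = -dG_ATP / (n F) + (R T / F) ln(10) (pH_vac - pH_cyt),
#' with n the pH-dependent coupling ratio.
#'
#' @inheritParams delta_g_atpase
#' @return dPsi = psi_vac - psi_cyt, in volts.
#' @examples
#' delta_psi_atpase(5, pump_parameters(), dG_ATP = -45200, temperature = 291.15)
#' @export
delta_psi_atpase <- function(pH_vac, pump, dG_ATP, temperature) {
  if (any(!is.finite(dG_ATP)) || any(dG_ATP >= 0))
    stop("dG_ATP must be negative", call. = FALSE)
  cn <- tonoplast_constants()
  n <- coupling_ratio(pH_vac, pump)
  -dG_ATP / (n * cn$Faraday) +
    (cn$R * temperature / cn$Faraday) * log(10) * (pH_vac - pump$pH_cyt)
}

#' Di-anion fraction of vacuolar malate
#'
#' Fraction of total malate present as the transported di-anion form at the
#' medium's pH, using the apparent acidity constants:
#' K'1 K'2 / (h^2 + h K'1 + K'1 K'2), with h = 10^-pH_vac.
#'
#' @param pH_vac Vacuolar pH; vectorized.
#' @param medium A [vacuolar_medium()] (only its constants are used).
#' @return Fraction in \[0, 1\].
#' @export
dianion_fraction <- function(pH_vac, medium) {
  h <- 10^(-pH_vac)
  k12 <- medium$K1_app * medium$K2_app
  k12 / (h^2 + h * medium$K1_app + k12)
}

#' Electrochemical potential difference of di-anion malate
#'
#' dG_Mal2- = -2 F dPsi + R T ln(a_vac / a_cyt), the driving force for
#' passive di-anion transport across the tonoplast (vacuole-directed
#' transport while negative). Diagnostic: the equilibrium relations assume
#' this is zero.
#'
#' @param delta_psi Tonoplast potential psi_vac - psi_cyt, V.
#' @param mal2_vac_activity,mal2_cyt_activity Di-anion malate activities on
#'   the two sides, mol L^-1 (> 0).
#' @param temperature Temperature, K.
#' @return dG_Mal2- in J mol^-1.
#' @export
delta_g_mal <- function(delta_psi, mal2_vac_activity, mal2_cyt_activity,
                        temperature) {
  if (any(mal2_vac_activity <= 0) || any(mal2_cyt_activity <= 0))
    stop("di-anion activities must be > 0", call. = FALSE)
  cn <- tonoplast_constants()
  -2 * cn$Faraday * delta_psi +
    cn$R * temperature * log(mal2_vac_activity / mal2_cyt_activity)
}

#' Vacuolar malate at di-anion equilibrium
#'
#' Total vacuolar malate concentration implied by di-anion transport
#' equilibrium (dG_Mal2- = 0) at a given membrane potential:
#' \[Mal_vac\] = (1/a) * ((h^2 + h K'1 + K'1 K'2)/(K'1 K'2)) * (Mal2-cyt)
#'             * exp(2 F dPsi / (R T)).
#'
#' @param medium A [vacuolar_medium()].
#' @param pump A [pump_parameters()] (supplies the cytosolic di-anion
#'   activity).
#' @param delta_psi Tonoplast potential, V.
#' @param temperature Temperature, K.
#' @param exponent_guard Bound on |2 F dPsi / (R T)| beyond which the state
#'   is reported as non-physical instead of evaluated.
#' @return Total vacuolar malate, mol L^-1.
#' @examples
#' med <- vacuolar_medium(4.6, 10^-3.4, 10^-5.11, 0.3)
#' vacuolar_malate_equilibrium(med, pump_parameters(), 0.01, 291.15)
#' @export
vacuolar_malate_equilibrium <- function(medium, pump, delta_psi, temperature,
                                        exponent_guard = 50) {
  cn <- tonoplast_constants()
  expo <- 2 * cn$Faraday * delta_psi / (cn$R * temperature)
  if (any(!is.finite(expo)) || any(abs(expo) > exponent_guard))
    stop("non-physical state: |2 F dPsi / RT| exceeds the exponent guard (",
         exponent_guard, ")", call. = FALSE)
  frac <- dianion_fraction(medium$pH_vac, medium)
  (1 / medium$a_mal2) * (1 / frac) * pump$mal2_cyt * exp(expo)
}

#' Pulp malate from vacuolar malate
#'
#' Converts vacuolar malate concentration (mol per L of vacuolar water) to a
#' pulp concentration (mmol per kg fresh weight), assuming the vacuolar
#' water volume equals the water mass of the pulp:
#' \[Mal_fruit\] = \[Mal_vac\] * ((FW - DW)/FW) * 1000.
#'
#' @param mal_vac Vacuolar malate, mol L^-1; vectorized.
#' @param FW,DW Pulp fresh and dry weight, g (FW > DW > 0).
#' @return Pulp malate, mmol kg FW^-1.
#' @export
pulp_malate <- function(mal_vac, FW, DW) {
  if (any(DW <= 0) || any(DW >= FW))
    stop("weights must satisfy FW > DW > 0", call. = FALSE)
  mal_vac * ((FW - DW) / FW) * 1000
}

#' ATP-hydrolysis energy required by an observed vacuolar state
#'
#' Inverts the coupled equilibrium relations: given an observed total
#' vacuolar malate and the medium state, returns the dG_ATP under which both
#' the di-anion and the proton pump are simultaneously at thermodynamic
#' equilibrium:
#' dG_ATP = n R T ln(10) (pH_vac - pH_cyt)
#'        - (n R T / 2) ln( K'1 K'2 \[Mal_vac\] a / (D (Mal2-cyt)) ),
#' with D = h^2 + h K'1 + K'1 K'2.
#'
#' Defaults for the pump follow the convention used when diagnosing energy
#' requirements from composition data: pH_cyt = 7, (Mal2-cyt) = 0.001
#' mol L^-1, n-constants n0 = 4, alpha = 0.3, beta = -0.12 (and a = 0.3 if
#' a plain pH is supplied instead of a full medium). All are overridable.
#'
#' @param observed_mal_vac Observed total vacuolar malate, mol L^-1 (> 0).
#' @param medium A [vacuolar_medium()] describing the vacuole.
#' @param pump A [pump_parameters()] object.
#' @param temperature Temperature, K.
#' @return dG_ATP in J mol^-1.
#' @export
invert_dg_atp <- function(observed_mal_vac, medium,
                          pump = pump_parameters(), temperature) {
  if (any(!is.finite(observed_mal_vac)) || any(observed_mal_vac <= 0))
    stop("observed_mal_vac must be > 0", call. = FALSE)
  cn <- tonoplast_constants()
  n <- coupling_ratio(medium$pH_vac, pump)
  frac <- dianion_fraction(medium$pH_vac, medium)
  q <- frac * observed_mal_vac * medium$a_mal2 / pump$mal2_cyt
  n * cn$R * temperature * log(10) * (medium$pH_vac - pump$pH_cyt) -
    (n * cn$R * temperature / 2) * log(q)
}

#' Membrane potential required by an observed vacuolar malate
#'
#' Inverts the di-anion equilibrium: dPsi = (R T / 2F) ln(a_vac / a_cyt),
#' where a_vac is the vacuolar di-anion activity implied by the observed
#' total malate and the medium. Used as a validity diagnostic against the
#' potential predicted by the ATPase model.
#'
#' @inheritParams invert_dg_atp
#' @return dPsi = psi_vac - psi_cyt, in volts.
#' @export
delta_psi_from_malate <- function(observed_mal_vac, medium,
                                  pump = pump_parameters(), temperature) {
  if (any(!is.finite(observed_mal_vac)) || any(observed_mal_vac <= 0))
    stop("observed_mal_vac must be > 0", call. = FALSE)
  cn <- tonoplast_constants()
  a_vac <- medium$a_mal2 * observed_mal_vac *
    dianion_fraction(medium$pH_vac, medium)
  (cn$R * temperature / (2 * cn$Faraday)) * log(a_vac / pump$mal2_cyt)
}
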