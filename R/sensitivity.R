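#' Normalized local sensitivity coefficient
#'
#' SC = (dM/M) / (dP/|P|), estimated by perturbing the parameter by a small
#' relative step on each side of its baseline and averaging the two
#' one-sided coefficients. Normalizing the perturbation by |P| makes the
#' sign of SC the direction of the model response to an algebraic increase
#' in the parameter, including for negative parameters such as dG_ATP.
#'
#' @param model_fn Function of the scalar parameter value returning the
#'   scalar model output M.
#' @param baseline_value Baseline parameter value P (non-zero).
#' @param perturbation Relative step (fraction of |P|); default 0.001.
#' @return A list with `sc` (central average), `sc_plus`, `sc_minus`.
#' @examples
#' normalized_sc(function(p) 3 * p, baseline_value = 2)$sc   # exactly 1
#' @export
normalized_sc <- function(model_fn, baseline_value, perturbation = 0.001) {
  if (!is.finite(baseline_value) || baseline_value == 0)
    stop("baseline parameter value must be non-zero", call. = FALSE)
  M0 <- model_fn(baseline_value)
  if (any(!is.finite(M0)) || any(M0 == 0))
    stop("model output at the baseline must be finite and non-zero",
         call. = FALSE)
  step <- perturbation * abs(baseline_value)
  Mp <- model_fn(baseline_value + step)
  Mm <- model_fn(baseline_value - step)
  sc_plus <- ((Mp - M0) / M0) / perturbation
  sc_minus <- ((M0 - Mm) / M0) / perturbation
  list(sc = (sc_plus + sc_minus) / 2, sc_plus = sc_plus, sc_minus = sc_minus)
}

# pulp malate prediction with pH_vac fixed at the measured pulp pH
# (vectorized). The medium constants are computed from the composition
# including the observed malate; dG may be a per-sample vector.
predict_ph_known <- function(samples, pump, dG, cfg) {
  mal_obs <- conc_fw_to_molar(samples$observed_malate, samples$FW,
                              samples$DW)
  comp <- samples_composition(samples, malate = mal_obs)
  pH <- samples$measured_pH
  st <- spec_core(comp, pH, cfg)
  cn <- tonoplast_constants()
  dPsi <- delta_psi_atpase(pH, pump, dG, samples$temperature)
  h <- 10^(-pH)
  k12 <- st$K1_app * st$K2_app
  dfac <- (h^2 + h * st$K1_app + k12) / k12
  mal <- (1 / st$a_mal2) * dfac * pump$mal2_cyt *
    exp(2 * cn$Faraday * dPsi / (cn$R * samples$temperature))
  pulp_malate(mal, samples$FW, samples$DW)
}

perturb_pump <- function(pump, field, value) {
  pump[[field]] <- value
  do.call(pump_parameters, unclass(pump))
}

#' Sensitivity suite of the malate model
#'
#' Normalized sensitivity coefficients of predicted pulp malate, per
#' sampling date, in the two modes of the analysis protocol:
#'
#' * `"parameters_ph_known"` — vacuolar pH is fixed at the measured pulp pH
#'   and the pump/energy parameters are perturbed: `pH_cyt`, `mal2_cyt`,
#'   `n0`, `alpha`, `beta`, and the ATP energy (`dG_ATP`, perturbed as the
#'   evaluated per-date value; for a ripening polynomial the coefficients
#'   `G1`, `G2`, `G3` are additionally reported).
#' * `"total_model"` — the full coupled model (speciation + transport) is
#'   re-solved under perturbed inputs: `citrate`, `oxalate`, `K`, `Mg`,
#'   `P`, `Ca`, `Cl` and `temperature`.
#'
#' @param samples Sample data.frame; the parameters mode additionally needs
#'   `measured_pH` and `observed_malate` columns.
#' @param pump A [pump_parameters()].
#' @param energy An energy model consistent with the samples' stage.
#' @param mode `"parameters_ph_known"` or `"total_model"`.
#' @param perturbation Relative perturbation (fraction of |P|).
#' @param targets Optional character subset of the mode's targets.
#' @param settings,cfg Solver and speciation controls.
#' @return A long data.frame of class `sensitivity_report`: `time`,
#'   `target`, `sc_plus`, `sc_minus`, `sc`, plus `mode` and `perturbation`
#'   attributes. Per-target failures yield NA rows rather than an error.
#' @export
sensitivity_suite <- function(samples, pump = pump_parameters(), energy,
                              mode = c("parameters_ph_known", "total_model"),
                              perturbation = 0.001, targets = NULL,
                              settings = solve_settings(),
                              cfg = speciation_config()) {
  mode <- match.arg(mode)
  samples <- as.data.frame(samples)
  check_samples(samples)
  m <- nrow(samples)

  if (mode == "parameters_ph_known") {
    if (is.null(samples$measured_pH) || any(is.na(samples$measured_pH)))
      stop("parameters_ph_known mode needs a measured_pH column",
           call. = FALSE)
    if (is.null(samples$observed_malate) ||
        any(is.na(samples$observed_malate)))
      stop("parameters_ph_known mode needs observed_malate", call. = FALSE)
    dG0 <- dg_atp_for(energy, samples$stage, samples$time)
    all_targets <- c("mal2_cyt", "pH_cyt", "dG_ATP", "n0", "alpha", "beta")
    if (energy$mode == "ripening_polynomial")
      all_targets <- c(all_targets, "G1", "G2", "G3")
    eval_target <- function(tg) {
      # returns model output vector for perturbation factor f on the target
      function(f) {
        if (tg %in% c("pH_cyt", "mal2_cyt", "n0", "alpha", "beta")) {
          p0 <- pump[[tg]]
          predict_ph_known(samples,
                           perturb_pump(pump, tg, p0 + f * abs(p0)),
                           dG0, cfg)
        } else if (tg == "dG_ATP") {
          predict_ph_known(samples, pump, dG0 + f * abs(dG0), cfg)
        } else { # G1, G2, G3
          e <- energy
          e[[tg]] <- e[[tg]] + f * abs(e[[tg]])
          predict_ph_known(samples, pump,
                           dg_atp_for(e, samples$stage, samples$time), cfg)
        }
      }
    }
    M0 <- predict_ph_known(samples, pump, dG0, cfg)
  } else {
    all_targets <- c("citrate", "oxalate", "K", "Mg", "P", "Ca", "Cl",
                     "temperature")
    eval_target <- function(tg) {
      function(f) {
        s <- samples
        s[[tg]] <- s[[tg]] + f * abs(s[[tg]])
        solve_engine(s, pump, energy, settings, cfg)$mal_fruit
      }
    }
    M0 <- solve_engine(samples, pump, energy, settings, cfg)$mal_fruit
  }

  if (!is.null(targets)) {
    bad <- setdiff(targets, all_targets)
    if (length(bad)) stop("unknown target(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    all_targets <- targets
  }
  if (any(!is.finite(M0)) || any(M0 == 0))
    stop("baseline model output must be finite and non-zero on every sample",
         call. = FALSE)

  rows <- lapply(all_targets, function(tg) {
    out <- tryCatch({
      fn <- eval_target(tg)
      Mp <- fn(perturbation)
      Mm <- fn(-perturbation)
      sc_plus <- ((Mp - M0) / M0) / perturbation
      sc_minus <- ((M0 - Mm) / M0) / perturbation
      data.frame(time = samples$time, target = tg,
                 sc_plus = sc_plus, sc_minus = sc_minus,
                 sc = (sc_plus + sc_minus) / 2)
    }, error = function(e) {
      warning("sensitivity target '", tg, "' failed: ",
              conditionMessage(e), call. = FALSE)
      data.frame(time = samples$time, target = tg,
                 sc_plus = NA_real_, sc_minus = NA_real_, sc = NA_real_)
    })
    out
  })
  rep <- do.call(rbind, rows)
  attr(rep, "mode") <- mode
  attr(rep, "perturbation") <- perturbation
  class(rep) <- c("sensitivity_report", "data.frame")
  rep
}

#' Summarize a sensitivity report
#'
#' Unweighted mean of the central sensitivity coefficient across dates, per
#' target.
#'
#' @param report A `sensitivity_report` from [sensitivity_suite()].
#' @return A data.frame with `target` and `mean_sc`.
#' @export
sc_summary <- function(report) {
  stopifnot(inherits(report, "sensitivity_report"))
  agg <- stats::aggregate(sc ~ target, data = as.data.frame(report),
                          FUN = mean)
  names(agg)[2] <- "mean_sc"
  agg
}
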