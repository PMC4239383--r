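#' PSO settings for calibration
#'
#' @param n_particles,n_iter Swarm size and iteration count.
#' @param inertia,cognitive,social PSO coefficients.
#' @return A plain list passed to [pso_minimize()].
#' @export
pso_settings <- function(n_particles = 40L, n_iter = 200L,
                         inertia = 0.729, cognitive = 1.494,
                         social = 1.494) {
  list(n_particles = as.integer(n_particles), n_iter = as.integer(n_iter),
       inertia = inertia, cognitive = cognitive, social = social)
}

new_fit_result <- function(par, units, sse, observed, predicted, pso, seed,
                           what) {
  structure(list(par = par, units = units, sse = sse,
                 rmse = rmse(observed, predicted),
                 rrmse = rrmse(observed, predicted),
                 n = length(observed),
                 trace = pso$trace, n_eval = pso$n_eval,
                 settings = pso$settings, seed = seed, what = what),
            class = "malate_fit")
}

#' @export
print.malate_fit <- function(x, ...) {
  cat("Malate model fit:", x$what, "\n")
  for (nm in names(x$par))
    cat(sprintf("  %-8s = %.6g %s\n", nm, x$par[[nm]], x$units[[nm]]))
  cat(sprintf("  SSE = %.6g   RMSE = %.4g   RRMSE = %.4g   (n = %d)\n",
              x$sse, x$rmse, x$rrmse, x$n))
  invisible(x)
}

#' Calibrate the growth-stage ATP-hydrolysis energy
#'
#' Estimates the constant dG_ATP of the growth stage by minimizing the sum
#' of squared differences between observed and predicted pulp malate over a
#' growth dataset, using particle swarm optimization. The default swarm is
#' small (the objective is one-dimensional and smooth); bounds span the
#' physiological range of ATP-hydrolysis free energies.
#'
#' @param samples Growth-stage samples with an `observed_malate` column
#'   (mmol kg FW^-1); see [solve_state()] for the full schema.
#' @param pump A [pump_parameters()].
#' @param bounds Length-2 vector, search interval for dG_ATP (J mol^-1).
#' @param swarm A [pso_settings()] list.
#' @param seed Integer seed for the PSO (mandatory).
#' @param settings,cfg Solver and speciation controls.
#' @param max_fail Maximum tolerated fraction of non-converged sample solves
#'   per objective evaluation.
#' @return A `malate_fit` with `par$dG_ATP`.
#' @export
fit_growth_dg <- function(samples, pump = pump_parameters(),
                          bounds = c(-60e3, -20e3),
                          swarm = pso_settings(n_particles = 12L,
                                               n_iter = 40L),
                          seed,
                          settings = solve_settings(),
                          cfg = speciation_config(),
                          max_fail = 0.2) {
  samples <- as.data.frame(samples)
  check_samples(samples)
  if (!all(samples$stage == "growth"))
    stop("fit_growth_dg() expects growth-stage samples", call. = FALSE)
  obs <- samples$observed_malate
  if (is.null(obs) || any(is.na(obs)))
    stop("all samples must carry observed_malate", call. = FALSE)

  objective <- function(p) {
    out <- solve_engine(samples, pump, energy_constant(p[1]), settings, cfg)
    if (mean(!out$converged) > max_fail) return(Inf)
    sse(obs[out$converged], out$mal_fruit[out$converged])
  }
  pso <- pso_minimize(objective, bounds[1], bounds[2],
                      n_particles = swarm$n_particles, n_iter = swarm$n_iter,
                      inertia = swarm$inertia, cognitive = swarm$cognitive,
                      social = swarm$social, seed = seed)
  if (!is.finite(pso$value))
    stop("PSO found no parameter with enough converged solves", call. = FALSE)
  pred <- solve_engine(samples, pump, energy_constant(pso$par[1]),
                       settings, cfg)$mal_fruit
  new_fit_result(par = list(dG_ATP = pso$par[1]),
                 units = list(dG_ATP = "J/mol"),
                 sse = pso$value, observed = obs, predicted = pred,
                 pso = pso, seed = seed, what = "growth dG_ATP")
}

#' Per-sample ATP energies implied by a ripening dataset
#'
#' For each sample: converts the observed pulp malate to a vacuolar
#' concentration, solves the speciation of the full composition (observed
#' malate included) for the vacuolar medium, and inverts the coupled
#' equilibria ([invert_dg_atp()]) for the dG_ATP the observation requires.
#'
#' @inheritParams fit_growth_dg
#' @return A data.frame with `time` (days after ethylene), `dG_ATP`
#'   (J mol^-1) and the speciation pH.
#' @export
ripening_dg_series <- function(samples, pump = pump_parameters(),
                               cfg = speciation_config()) {
  samples <- as.data.frame(samples)
  check_samples(samples)
  obs <- samples$observed_malate
  if (is.null(obs) || any(is.na(obs)) || any(obs <= 0))
    stop("all samples must carry positive observed_malate", call. = FALSE)
  mal_vac <- conc_fw_to_molar(obs, samples$FW, samples$DW)
  sp <- speciate(samples_composition(samples, malate = mal_vac), cfg = cfg)
  cn <- tonoplast_constants()
  n <- coupling_ratio(sp$pH_vac, pump)
  h <- 10^(-sp$pH_vac)
  k12 <- sp$K1_app * sp$K2_app
  frac <- k12 / (h^2 + h * sp$K1_app + k12)
  q <- frac * mal_vac * sp$a_mal2 / pump$mal2_cyt
  dg <- n * cn$R * samples$temperature * log(10) *
    (sp$pH_vac - pump$pH_cyt) -
    (n * cn$R * samples$temperature / 2) * log(q)
  data.frame(time = samples$time, dG_ATP = dg, pH_vac = sp$pH_vac)
}

#' Calibrate the ripening energy polynomial
#'
#' Two-step estimation of (G1, G2, G3): each ripening sample's observed
#' malate is inverted into the dG_ATP it requires ([ripening_dg_series()]),
#' then the quadratic dG_ATP(DAE) = G1 DAE^2 + G2 DAE + G3 is fitted to
#' those values by particle swarm optimization (the problem is linear in the
#' coefficients, so an ordinary least-squares fit is the natural
#' cross-check).
#'
#' @inheritParams fit_growth_dg
#' @param samples Ripening-stage samples with positive `observed_malate`
#'   and `time` = days after ethylene; at least 3 distinct times.
#' @param bounds 2x3 matrix (rows lower/upper) or list of length-2 vectors
#'   for G1, G2, G3.
#' @return A `malate_fit` with `par$G1`, `par$G2`, `par$G3`; `sse`, `rmse`
#'   and `rrmse` are computed on the predicted pulp malate of the fitted
#'   model (the optimizer criterion itself is on the dG_ATP values and is
#'   stored as `dg_sse`).
#' @export
fit_ripening_G <- function(samples, pump = pump_parameters(),
                           bounds = list(G1 = c(0, 500),
                                         G2 = c(-5000, 0),
                                         G3 = c(-60e3, -30e3)),
                           swarm = pso_settings(n_particles = 40L,
                                                n_iter = 200L),
                           seed,
                           settings = solve_settings(),
                           cfg = speciation_config()) {
  samples <- as.data.frame(samples)
  if (!all(samples$stage == "ripening"))
    stop("fit_ripening_G() expects ripening-stage samples", call. = FALSE)
  if (length(unique(samples$time)) < 3L)
    stop("need at least 3 distinct days-after-ethylene values", call. = FALSE)
  dgs <- ripening_dg_series(samples, pump, cfg)
  lower <- vapply(bounds, `[`, numeric(1), 1L)
  upper <- vapply(bounds, `[`, numeric(1), 2L)
  objective <- function(p) {
    sse(dgs$dG_ATP, p[1] * dgs$time^2 + p[2] * dgs$time + p[3])
  }
  pso <- pso_minimize(objective, lower, upper,
                      n_particles = swarm$n_particles, n_iter = swarm$n_iter,
                      inertia = swarm$inertia, cognitive = swarm$cognitive,
                      social = swarm$social, seed = seed)
  energy <- energy_polynomial(pso$par[1], pso$par[2], pso$par[3],
                              dae_window = range(samples$time))
  pred <- solve_engine(samples, pump, energy, settings, cfg)$mal_fruit
  fit <- new_fit_result(
    par = list(G1 = pso$par[1], G2 = pso$par[2], G3 = pso$par[3]),
    units = list(G1 = "J/mol/day^2", G2 = "J/mol/day", G3 = "J/mol"),
    sse = sse(samples$observed_malate, pred),
    observed = samples$observed_malate, predicted = pred,
    pso = pso, seed = seed, what = "ripening G1-G3")
  fit$dg_sse <- pso$value
  fit$dg_series <- dgs
  fit
}

#' Serialize a fit result to JSON
#'
#' Writes parameters, fit metrics, PSO settings and seed (plus an input
#' digest when the data file is given) so a calibration run is fully
#' reproducible.
#'
#' @param fit A `malate_fit`.
#' @param path Output JSON path.
#' @param input_file Optional path of the input data file; its md5 digest is
#'   recorded.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path, input_file = NULL) {
  stopifnot(inherits(fit, "malate_fit"))
  x <- list(what = fit$what, par = fit$par, units = fit$units,
            sse = fit$sse, rmse = fit$rmse, rrmse = fit$rrmse, n = fit$n,
            seed = fit$seed, pso_settings = fit$settings)
  if (!is.null(input_file))
    x$input_md5 <- unname(tools::md5sum(input_file))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
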