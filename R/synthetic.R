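# smooth trajectory primitives for composition time courses
logistic_traj <- function(t, start, end, midpoint, rate) {
  start + (end - start) / (1 + exp(-(t - midpoint) / rate))
}
hump_traj <- function(t, base, amplitude, peak, width) {
  base + amplitude * exp(-((t - peak) / width)^2)
}

#' Generate synthetic cultivar profiles
#'
#' Builds reproducible cultivar-like ground truths for the synthetic study
#' design: a true constant dG_ATP for the growth stage (drawn over the
#' calibrated range of the three banana cultivars, -47.4e3 to -36.9e3
#' J mol^-1), true ripening coefficients (G1, G2, G3) near the published
#' rows, and smooth per-solute composition trajectories whose speciation pH
#' lands in the acidic band of banana pulp (about 4-5.5).
#'
#' Sampling design mirrors the field protocol: fruit sampled every 15 days
#' during growth and at days 0, 3, 6, 9 and 13 after ethylene treatment
#' during ripening; growth at the seasonal mean temperature (27 degC),
#' ripening in storage at 18 degC.
#'
#' @param n_cultivars Number of profiles (>= 1).
#' @param seed Integer seed.
#' @param noise_sd Relative measurement noise (sd of a multiplicative
#'   Gaussian) applied to every measured quantity; 0 gives noiseless data.
#' @return A list of `cultivar_profile` objects.
#' @examples
#' p <- generate_profiles(3, seed = 1)
#' p[[1]]$dG_ATP
#' @export
generate_profiles <- function(n_cultivars = 3L, seed, noise_sd = 0.05) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  stopifnot(n_cultivars >= 1L, noise_sd >= 0)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(as.integer(seed))
  lapply(seq_len(n_cultivars), function(i) {
    jit <- function(x, f = 0.15) x * stats::runif(1, 1 - f, 1 + f)
    structure(list(
      name = sprintf("SYN%02d", i),
      seed = as.integer(seed) + i,
      noise_sd = noise_sd,
      dG_ATP = stats::runif(1, -47.4e3, -36.9e3),
      G = c(G1 = stats::runif(1, 75, 95), G2 = stats::runif(1, -1600, -1350),
            G3 = stats::runif(1, -47.0e3, -45.5e3)),
      growth_days = seq(15, 90, by = 15),
      ripening_dae = c(0, 3, 6, 9, 13),
      n_rep_growth = 5L,
      n_rep_ripening = 12L,
      temperature_growth = 300.15,   # 27 degC seasonal mean
      temperature_ripening = 291.15, # 18 degC storage
      harvest_day = 70,
      traj = list(
        K       = c(start = jit(0.055), end = jit(0.072), mid = 45, rate = 15),
        Mg      = c(start = jit(0.004), end = jit(0.010), mid = 45, rate = 15),
        Ca      = c(start = jit(0.0010), end = jit(0.0025), mid = 40,
                    rate = 12),
        P       = c(start = jit(0.006), end = jit(0.009), mid = 50, rate = 15),
        Cl      = c(start = jit(0.003), end = jit(0.005), mid = 45, rate = 20),
        citrate = c(base = jit(0.008), amplitude = jit(0.018), peak = 60,
                    width = 28),
        oxalate = c(base = jit(0.003), amplitude = jit(0.007), peak = 20,
                    width = 35),
        FW      = c(start = 15, end = jit(110), mid = 50, rate = 12),
        DWfrac  = c(start = 0.15, end = jit(0.28), mid = 55, rate = 15)
      )
    ), class = "cultivar_profile")
  })
}

#' @export
print.cultivar_profile <- function(x, ...) {
  cat(sprintf("Synthetic cultivar %s: dG_ATP = %.0f J/mol, G = (%.1f, %.0f, %.0f), noise sd = %g\n",
              x$name, x$dG_ATP, x$G[1], x$G[2], x$G[3], x$noise_sd))
  invisible(x)
}

# noiseless composition/weight design for one profile at given stage
profile_design <- function(profile, stage) {
  tr <- profile$traj
  if (stage == "growth") {
    t <- rep(profile$growth_days, each = profile$n_rep_growth)
    tc <- t
    temp <- profile$temperature_growth
  } else {
    t <- rep(profile$ripening_dae, each = profile$n_rep_ripening)
    tc <- rep(profile$harvest_day, length(t)) # composition frozen at harvest
    temp <- profile$temperature_ripening
  }
  FW <- logistic_traj(tc, tr$FW["start"], tr$FW["end"], tr$FW["mid"],
                      tr$FW["rate"])
  DW <- FW * logistic_traj(tc, tr$DWfrac["start"], tr$DWfrac["end"],
                           tr$DWfrac["mid"], tr$DWfrac["rate"])
  data.frame(
    cultivar = profile$name, stage = stage, time = t, temperature = temp,
    FW = unname(FW), DW = unname(DW),
    K  = logistic_traj(tc, tr$K["start"], tr$K["end"], tr$K["mid"],
                       tr$K["rate"]),
    Mg = logistic_traj(tc, tr$Mg["start"], tr$Mg["end"], tr$Mg["mid"],
                       tr$Mg["rate"]),
    Ca = logistic_traj(tc, tr$Ca["start"], tr$Ca["end"], tr$Ca["mid"],
                       tr$Ca["rate"]),
    P  = logistic_traj(tc, tr$P["start"], tr$P["end"], tr$P["mid"],
                       tr$P["rate"]),
    Cl = logistic_traj(tc, tr$Cl["start"], tr$Cl["end"], tr$Cl["mid"],
                       tr$Cl["rate"]),
    citrate = hump_traj(tc, tr$citrate["base"], tr$citrate["amplitude"],
                        tr$citrate["peak"], tr$citrate["width"]),
    oxalate = hump_traj(tc, tr$oxalate["base"], tr$oxalate["amplitude"],
                        tr$oxalate["peak"], tr$oxalate["width"]),
    row.names = NULL
  )
}

#' Forward-simulate a synthetic dataset
#'
#' Runs the full model at the profile's true parameters over its sampling
#' design and returns samples whose `observed_malate` is the model
#' prediction times multiplicative Gaussian noise. Measured composition
#' columns carry the same kind of noise (assay error), and the prediction is
#' made at the recorded (noisy) composition, so at zero noise observation
#' equals prediction exactly and calibration round-trips. `measured_pH` is
#' set to the speciation pH of the solved state, so both sensitivity modes
#' run on generated data.
#'
#' @param profile A `cultivar_profile` from [generate_profiles()].
#' @param stage `"growth"` or `"ripening"`.
#' @param pump A [pump_parameters()].
#' @param settings,cfg Solver and speciation controls.
#' @return A samples data.frame (see [solve_state()]) with
#'   `observed_malate`, `measured_pH` and a `true_malate` column holding the
#'   noiseless prediction.
#' @export
forward_dataset <- function(profile, stage = c("growth", "ripening"),
                            pump = pump_parameters(),
                            settings = solve_settings(),
                            cfg = speciation_config()) {
  stopifnot(inherits(profile, "cultivar_profile"))
  stage <- match.arg(stage)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(profile$seed + if (stage == "growth") 0L else 1000L)

  s <- profile_design(profile, stage)
  # assay noise on the recorded composition and weights
  if (profile$noise_sd > 0) {
    for (col in c("K", "Mg", "Ca", "P", "Cl", "citrate", "oxalate",
                  "FW", "DW")) {
      s[[col]] <- s[[col]] *
        pmax(0.5, 1 + stats::rnorm(nrow(s), 0, profile$noise_sd))
    }
    s$DW <- pmin(s$DW, 0.9 * s$FW)
  }
  energy <- if (stage == "growth") {
    energy_constant(profile$dG_ATP)
  } else {
    energy_polynomial(profile$G["G1"], profile$G["G2"], profile$G["G3"],
                      dae_window = range(profile$ripening_dae))
  }
  sol <- solve_engine(s, pump, energy, settings, cfg)
  if (any(!sol$converged))
    stop("solver failed inside data generation for ",
         sum(!sol$converged), " sample(s)", call. = FALSE)
  s$true_malate <- sol$mal_fruit
  s$observed_malate <- sol$mal_fruit *
    pmax(0.1, 1 + stats::rnorm(nrow(s), 0, profile$noise_sd))
  s$measured_pH <- sol$pH_vac
  s
}
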