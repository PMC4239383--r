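# file-boundary schema: measurements as assayed (mmol per kg fresh weight,
# temperature in degC); internal schema in mol per litre of pulp water and K.
file_solute_cols <- function() {
  c(K = "K_mmol_kgFW", Mg = "Mg_mmol_kgFW", Ca = "Ca_mmol_kgFW",
    P = "P_mmol_kgFW", Cl = "Cl_mmol_kgFW", citrate = "citrate_mmol_kgFW",
    oxalate = "oxalate_mmol_kgFW")
}

#' Read a sample table
#'
#' Reads a CSV of fruit pulp samples (one row per fruit per date) and
#' converts it to the internal schema used by the solver. Required columns:
#' `cultivar`, `stage` (growth/ripening), `time` (days after bloom or days
#' after ethylene), `temperature_C`, `FW_g`, `DW_g`, and the solutes
#' `K_mmol_kgFW`, `Mg_mmol_kgFW`, `Ca_mmol_kgFW`, `P_mmol_kgFW`,
#' `Cl_mmol_kgFW`, `citrate_mmol_kgFW`, `oxalate_mmol_kgFW`. Optional:
#' `malate_mmol_kgFW` (observed malate) and `measured_pH`. Units are part of
#' the column names on purpose: a file with ambiguous units is refused
#' rather than guessed. Solutes are converted to mol per litre of pulp
#' water using FW - DW as the water mass; temperature to kelvin.
#'
#' @param path CSV file path.
#' @return A samples data.frame in the internal schema (see
#'   [solve_state()]).
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cultivar", "stage", "time", "temperature_C", "FW_g", "DW_g",
            unname(file_solute_cols()))
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("sample file is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(raw$DW_g <= 0) || any(raw$DW_g >= raw$FW_g))
    stop("weights must satisfy FW > DW > 0", call. = FALSE)
  sol <- file_solute_cols()
  conc <- lapply(names(sol), function(k) {
    x <- raw[[sol[[k]]]]
    if (any(x < 0)) stop("negative concentration in column ", sol[[k]],
                         call. = FALSE)
    conc_fw_to_molar(x, raw$FW_g, raw$DW_g) # mmol/kgFW -> mol/L pulp water
  })
  out <- data.frame(cultivar = raw$cultivar, stage = raw$stage,
                    time = raw$time, temperature = raw$temperature_C + 273.15,
                    FW = raw$FW_g, DW = raw$DW_g, stringsAsFactors = FALSE)
  for (i in seq_along(sol)) out[[names(sol)[i]]] <- conc[[i]]
  if ("malate_mmol_kgFW" %in% names(raw))
    out$observed_malate <- raw$malate_mmol_kgFW
  if ("measured_pH" %in% names(raw)) out$measured_pH <- raw$measured_pH
  check_samples(out)
  out
}

#' Write a sample table
#'
#' Inverse of [read_samples()]: converts internal samples back to the file
#' schema (mmol kg FW^-1, degC) and writes CSV.
#'
#' @param samples Samples data.frame in the internal schema.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  check_samples(samples)
  sol <- file_solute_cols()
  out <- data.frame(cultivar = if (is.null(samples$cultivar)) ""
                    else samples$cultivar,
                    stage = samples$stage, time = samples$time,
                    temperature_C = samples$temperature - 273.15,
                    FW_g = samples$FW, DW_g = samples$DW,
                    stringsAsFactors = FALSE)
  for (k in names(sol))
    out[[sol[[k]]]] <- conc_molar_to_fw(samples[[k]], samples$FW, samples$DW)
  if (!is.null(samples$observed_malate))
    out$malate_mmol_kgFW <- samples$observed_malate
  if (!is.null(samples$measured_pH)) out$measured_pH <- samples$measured_pH
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write model predictions
#'
#' Writes a [simulate_series()] result (solution fields plus residual
#' diagnostics) as CSV.
#'
#' @param predictions Data.frame from [simulate_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.csv(predictions, path, row.names = FALSE)
  invisible(path)
}

#' Goodness-of-fit report per cultivar and stage
#'
#' RMSE and RRMSE of predicted versus observed pulp malate for each
#' cultivar x stage cell of a prediction table.
#'
#' @param predictions Data.frame from [simulate_series()] carrying
#'   `observed_malate` and `mal_fruit`.
#' @return A data.frame with `cultivar`, `stage`, `n`, `rmse`
#'   (mmol kg FW^-1) and `rrmse`.
#' @export
fit_report <- function(predictions) {
  stopifnot(all(c("observed_malate", "mal_fruit", "stage")
                %in% names(predictions)))
  if (is.null(predictions$cultivar)) predictions$cultivar <- "all"
  cells <- unique(predictions[c("cultivar", "stage")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- predictions$cultivar == cells$cultivar[i] &
      predictions$stage == cells$stage[i]
    obs <- predictions$observed_malate[sel]
    prd <- predictions$mal_fruit[sel]
    data.frame(cultivar = cells$cultivar[i], stage = cells$stage[i],
               n = sum(sel), rmse = rmse(obs, prd), rrmse = rrmse(obs, prd))
  })
  do.call(rbind, rows)
}

#' Run configuration
#'
#' Bundles the tunables of a pipeline run — speciation constants, solver
#' tolerances, PSO settings and the seed — and serializes them losslessly to
#' YAML, so a run is a pure function of (input files, config, seed).
#'
#' @param seed Integer seed.
#' @param speciation A [speciation_config()].
#' @param solver A [solve_settings()].
#' @param pso A [pso_settings()] list.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, speciation = speciation_config(),
                       solver = solve_settings(), pso = pso_settings()) {
  structure(list(seed = as.integer(seed), speciation = unclass(speciation),
                 solver = unclass(solver), pso = pso),
            class = "run_config")
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path, precision = 15L)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- yaml::read_yaml(path)
  run_config(seed = x$seed,
             speciation = do.call(speciation_config, x$speciation),
             solver = do.call(solve_settings, x$solver),
             pso = do.call(pso_settings, x$pso))
}
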