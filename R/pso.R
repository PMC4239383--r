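#' Particle swarm minimization
#'
#' Global-best particle swarm optimizer with inertia weight, cognitive and
#' social acceleration, and reflective box bounds. Deterministic for a given
#' seed: two runs with the same seed produce identical traces.
#'
#' @param objective Function of a numeric parameter vector returning a
#'   scalar; non-finite values are treated as very poor fitness.
#' @param lower,upper Finite bound vectors, one entry per dimension.
#' @param n_particles Swarm size.
#' @param n_iter Number of iterations.
#' @param inertia Inertia weight.
#' @param cognitive,social Acceleration coefficients toward the personal and
#'   global best.
#' @param seed Integer seed (mandatory; calibration must be reproducible).
#' @return A list of class `pso_fit`: `par` (best position), `value` (best
#'   objective), `trace` (global-best value per iteration), `n_eval`, and
#'   the settings used.
#' @examples
#' fit <- pso_minimize(function(x) sum(x^2), c(-5, -5, -5), c(5, 5, 5),
#'                     seed = 1)
#' fit$value
#' @export
pso_minimize <- function(objective, lower, upper,
                         n_particles = 40L, n_iter = 200L,
                         inertia = 0.729, cognitive = 1.494, social = 1.494,
                         seed) {
  if (missing(seed) || !is.finite(seed))
    stop("a seed is required for reproducible calibration", call. = FALSE)
  d <- length(lower)
  stopifnot(length(upper) == d, all(is.finite(lower)), all(is.finite(upper)),
            all(upper > lower))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(as.integer(seed))

  span <- upper - lower
  pos <- matrix(stats::runif(n_particles * d), n_particles, d)
  pos <- sweep(sweep(pos, 2, span, `*`), 2, lower, `+`)
  vel <- matrix(stats::runif(n_particles * d, -1, 1), n_particles, d) *
    matrix(span, n_particles, d, byrow = TRUE) * 0.1

  eval_all <- function(p) {
    v <- apply(p, 1L, function(x) {
      f <- objective(x)
      if (is.finite(f)) f else Inf
    })
    as.numeric(v)
  }

  fit <- eval_all(pos)
  if (all(!is.finite(fit)))
    stop("objective is non-finite over the initial swarm", call. = FALSE)
  pbest <- pos
  pbest_f <- fit
  g <- which.min(fit)
  gbest <- pos[g, ]
  gbest_f <- fit[g]
  trace <- numeric(n_iter)
  n_eval <- n_particles

  for (it in seq_len(n_iter)) {
    r1 <- matrix(stats::runif(n_particles * d), n_particles, d)
    r2 <- matrix(stats::runif(n_particles * d), n_particles, d)
    gmat <- matrix(gbest, n_particles, d, byrow = TRUE)
    vel <- inertia * vel +
      cognitive * r1 * (pbest - pos) +
      social * r2 * (gmat - pos)
    pos <- pos + vel
    # reflective bounds: fold back and reverse velocity
    for (j in seq_len(d)) {
      below <- pos[, j] < lower[j]
      above <- pos[, j] > upper[j]
      pos[below, j] <- 2 * lower[j] - pos[below, j]
      pos[above, j] <- 2 * upper[j] - pos[above, j]
      vel[below | above, j] <- -vel[below | above, j]
      # clamp any residual excursion (deep overshoot)
      pos[, j] <- pmin(pmax(pos[, j], lower[j]), upper[j])
    }
    fit <- eval_all(pos)
    n_eval <- n_eval + n_particles
    better <- fit < pbest_f
    pbest[better, ] <- pos[better, , drop = FALSE]
    pbest_f[better] <- fit[better]
    g <- which.min(pbest_f)
    if (pbest_f[g] < gbest_f) {
      gbest <- pbest[g, ]
      gbest_f <- pbest_f[g]
    }
    trace[it] <- gbest_f
  }
  structure(list(par = as.numeric(gbest), value = gbest_f, trace = trace,
                 n_eval = n_eval,
                 settings = list(n_particles = n_particles, n_iter = n_iter,
                                 inertia = inertia, cognitive = cognitive,
                                 social = social, seed = seed)),
            class = "pso_fit")
}
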