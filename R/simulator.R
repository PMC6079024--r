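#' Per-step parameter noise specification
#'
#' Within-trial variability of the functional response: at every step of the
#' fixed-step numerical integration, each predator's attack rate and handling
#' time are redrawn from normal distributions centred on the true values with
#' standard deviations of 10% (attack rate) and 5% (handling time) of the
#' mean — typical parameter uncertainty in functional response experiments.
#' Draws are truncated at a small positive floor rather than resampled, which
#' preserves the draw count per step and keeps seeded runs stable.
#'
#' @param sd_frac_a fractional sd of the attack rate, default 0.10, in `[0, 1)`.
#' @param sd_frac_h fractional sd of the handling time, default 0.05, in `[0, 1)`.
#' @param redraw_dt redraw interval in days; `NULL` (default) means `t / n_steps`
#'   is chosen at simulation time and recorded in the dataset metadata.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(sd_frac_a = 0.10, sd_frac_h = 0.05, redraw_dt = NULL) {
  if (sd_frac_a < 0 || sd_frac_a >= 1 || sd_frac_h < 0 || sd_frac_h >= 1) {
    stop("noise fractions must lie in [0, 1)")
  }
  if (!is.null(redraw_dt) && redraw_dt <= 0) stop("redraw_dt must be > 0")
  structure(list(sd_frac_a = sd_frac_a, sd_frac_h = sd_frac_h,
                 redraw_dt = redraw_dt),
            class = "noise_spec")
}

#' Default prey-density grid
#'
#' 25 approximately log-spaced integer densities spanning 1 to 800
#' prey.arena^-1, covering both the rising and the asymptotic part of a
#' type-II functional response. Duplicated integers after rounding are bumped
#' to keep the grid strictly increasing.
#'
#' @param n number of densities, default 25.
#' @param lo,hi range bounds, defaults 1 and 800.
#' @return strictly increasing integer vector of length `n`.
#' @export
default_density_grid <- function(n = 25, lo = 1, hi = 800) {
  g <- round(exp(seq(log(lo), log(hi), length.out = n)))
  for (i in seq_along(g)[-1]) if (g[i] <= g[i - 1]) g[i] <- g[i - 1] + 1
  as.integer(g)
}

#' Deterministic single-predator trials
#'
#' One noiseless trial per prey density: the expected eaten number from the
#' random predator equation, rounded to the nearest integer so the dataset
#' can be fitted with a binomial likelihood.
#'
#' @param params [fr_params()] of the predator.
#' @param grid prey densities, default [default_density_grid()].
#' @param t trial duration in days.
#' @param species assemblage label written into the trial table, default "A".
#' @return object of class `sim_dataset`: list with `trials` (trial table),
#'   and `meta` (generating parameters, grid, integrator settings).
#' @export
simulate_deterministic <- function(params, grid = default_density_grid(), t,
                                   species = "A") {
  stopifnot(inherits(params, "fr_params"))
  if (any(grid < 1 | grid != round(grid))) {
    stop("density grid must contain integers >= 1")
  }
  grid <- as.integer(grid)
  ne <- if (params$response == "type2") {
    rogers_eaten(params, grid, t)
  } else {
    popdyn_predict(predator_assemblage(species, 1L, params), grid, t)
  }
  trials <- data.frame(
    assemblage_id = species,
    replicate_id = 1L,
    N0 = grid,
    Ne = pmin(round_half_up(ne), grid),
    t_days = t
  )
  structure(
    list(trials = trials,
         meta = list(kind = "deterministic", params = format(params),
                     grid = grid, t_days = t, species = species)),
    class = "sim_dataset"
  )
}

#' Stochastic multi-predator predation trials
#'
#' Simulates realistic feeding trials for a predator assemblage by integrating
#' the prey-depletion model `dN/dt = - sum_i f_i(N) P_i` with a fixed-step
#' RK4 scheme, redrawing every member's `(a, h)` from the [noise_spec()]
#' normal distributions at each step (parameters are frozen within a step;
#' each member draws independently). Each (density, replicate) trajectory uses
#' its own draw sequence; the eaten count is `round(N0 - N(t))` clipped to
#' `[0, N0]`.
#'
#' @param assemblage a [predator_assemblage()] (type-II members).
#' @param grid prey densities, default [default_density_grid()].
#' @param t trial duration in days.
#' @param noise a [noise_spec()].
#' @param n_replicates replicates per density, default 10.
#' @param seed integer seed, mandatory.
#' @param n_steps integration steps over `[0, t]` when `noise$redraw_dt` is
#'   `NULL`; default 100. Fewer than 10 steps degenerates the noise model and
#'   is an error.
#' @return object of class `sim_dataset` (see [simulate_deterministic()]);
#'   metadata records the integrator, step size and seed so any dataset is
#'   exactly regenerable.
#' @export
simulate_stochastic <- function(assemblage, grid = default_density_grid(), t,
                                noise = noise_spec(), n_replicates = 10,
                                seed, n_steps = 100L) {
  stopifnot(inherits(assemblage, "predator_assemblage"),
            inherits(noise, "noise_spec"))
  if (missing(seed) || is.null(seed)) stop("an explicit seed is mandatory")
  if (any(grid < 1 | grid != round(grid))) {
    stop("density grid must contain integers >= 1")
  }
  if (length(t) != 1L || t <= 0) stop("t must be a single value > 0")
  if (!is.null(noise$redraw_dt)) n_steps <- ceiling(t / noise$redraw_dt)
  n_steps <- as.integer(n_steps)
  if (n_steps < 10L) {
    stop("fewer than 10 integration steps over [0, t]: the per-step noise ",
         "model degenerates; decrease redraw_dt or increase n_steps")
  }
  members <- assemblage$members
  grid <- as.integer(grid)
  set.seed(as.integer(seed))

  # one state per (density, replicate); all trajectories step together,
  # each with independent per-step parameter draws
  n_traj <- length(grid) * n_replicates
  N <- rep(as.numeric(grid), each = n_replicates)
  dt <- t / n_steps
  for (s in seq_len(n_steps)) {
    as_draw <- lapply(members, function(m) {
      sd <- noise$sd_frac_a * m$params$a
      if (sd == 0) rep(m$params$a, n_traj)
      else pmax(stats::rnorm(n_traj, m$params$a, sd), 1e-6)
    })
    hs_draw <- lapply(members, function(m) {
      sd <- noise$sd_frac_h * m$params$h
      if (sd == 0) rep(m$params$h, n_traj)
      else pmax(stats::rnorm(n_traj, m$params$h, sd), 1e-6)
    })
    deriv <- function(NN) {
      tot <- 0
      for (i in seq_along(members)) {
        a <- as_draw[[i]]
        h <- hs_draw[[i]]
        tot <- tot + members[[i]]$P * a * NN / (1 + a * h * NN)
      }
      -tot
    }
    N <- rk4_step(deriv, N, dt)
  }
  N0_vec <- rep(grid, each = n_replicates)
  ne <- pmin(pmax(round_half_up(N0_vec - N), 0), N0_vec)
  trials <- data.frame(
    assemblage_id = paste(vapply(members, `[[`, "", "species"), collapse = "+"),
    replicate_id = rep(seq_len(n_replicates), times = length(grid)),
    N0 = N0_vec,
    Ne = ne,
    t_days = t
  )
  structure(
    list(trials = trials,
         meta = list(kind = "stochastic",
                     params = vapply(members, function(m) format(m$params), ""),
                     P = vapply(members, `[[`, 1L, "P"),
                     grid = grid, t_days = t,
                     noise = unclass(noise)[c("sd_frac_a", "sd_frac_h")],
                     integrator = "rk4-fixed", n_steps = n_steps,
                     redraw_dt = dt, n_replicates = n_replicates,
                     seed = as.integer(seed))),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated dataset (", x$meta$kind, "): ", nrow(x$trials), " trials over ",
      length(x$meta$grid), " densities\n", sep = "")
  invisible(x)
}
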