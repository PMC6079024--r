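# Independent oracles, deliberately sharing no code path with the package:
# the package evaluates the random predator equation via Lambert W and
# integrates depletion with adaptive Cash-Karp; these use damped fixed-point
# iteration and a brute-force fixed-step RK4 with a large step count.

# bracketed root of g(Ne) = Ne - N0 (1 - exp(-a (t - h Ne))) on [0, N0];
# g(0) < 0 and g(N0) > 0 always, so bisection-based uniroot is safe even where
# plain fixed-point iteration diverges
fixed_point_rogers <- function(a, h, N0, t) {
  g <- function(ne) ne - N0 * (1 - exp(-a * (t - h * ne)))
  stats::uniroot(g, c(0, N0), tol = 1e-12)$root
}

# brute-force integration of dN/dt = -sum_i P_i a_i N / (1 + a_i h_i N)
# members: list of list(a=, h=, P=)
brute_ode_eaten <- function(members, N0, t, nstep = 20000) {
  f <- function(N) {
    -sum(vapply(members, function(m) m$P * m$a * N / (1 + m$a * m$h * N), 0))
  }
  N <- N0
  dt <- t / nstep
  for (i in seq_len(nstep)) {
    k1 <- f(N); k2 <- f(N + dt / 2 * k1)
    k3 <- f(N + dt / 2 * k2); k4 <- f(N + dt * k3)
    N <- max(0, N + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
  }
  N0 - N
}

# quick deterministic trial table from true parameters
det_trials <- function(a, h, grid, t, species = "A") {
  simulate_deterministic(fr_params(a, h), grid, t, species = species)$trials
}

# synthetic fr_fit with prescribed estimates and CIs, for CI-propagation tests
stub_fit <- function(a, h, ci_a, ci_h) {
  structure(
    list(estimates = fr_params(a, max(h, 1e-12)), log_likelihood = NA_real_,
         ci95_a = ci_a, ci95_h = ci_h,
         vcov = diag(2), vcov_log = diag(2) * 1e-4,
         n_trials = 0L, converged = TRUE, message = "stub",
         t_days = 1),
    class = "fr_fit"
  )
}
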