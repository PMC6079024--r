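# Numerical integration of the scalar prey-depletion ODE dN/dt = deriv(N).
# Cash-Karp embedded RK4(5) with adaptive step control; the trajectory is
# monotone decreasing and bounded below by 0, enforced with a hard floor.

ck_a <- c(1 / 5, 3 / 10, 3 / 5, 1, 7 / 8)
ck_b <- list(
  c(1 / 5),
  c(3 / 40, 9 / 40),
  c(3 / 10, -9 / 10, 6 / 5),
  c(-11 / 54, 5 / 2, -70 / 27, 35 / 27),
  c(1631 / 55296, 175 / 512, 575 / 13824, 44275 / 110592, 253 / 4096)
)
ck_c5 <- c(37 / 378, 0, 250 / 621, 125 / 594, 0, 512 / 1771)
ck_c4 <- c(2825 / 27648, 0, 18575 / 48384, 13525 / 55296, 277 / 14336, 1 / 4)

#' Integrate a scalar depletion ODE
#'
#' Adaptive Cash-Karp Runge-Kutta 4(5) integration of `dN/dt = deriv(N)` from
#' `N(0) = N0` over `[0, t]`, with step-size control on the embedded error
#' estimate and a hard floor at `N = 0`.
#'
#' @param deriv function of `N` returning `dN/dt` (expected <= 0).
#' @param N0 initial state, scalar >= 0.
#' @param t integration horizon, days, scalar >= 0.
#' @param rtol,atol relative and absolute local error tolerances.
#' @param max_steps step budget; exceeding it is an error, never a clamp.
#' @return `N(t)`, scalar in `[0, N0]`.
#' @keywords internal
ode_depletion <- function(deriv, N0, t, rtol = 1e-8, atol = 1e-10,
                          max_steps = 100000L) {
  if (t < 0) stop("t must be >= 0")
  if (N0 < 0) stop("N0 must be >= 0")
  if (t == 0 || N0 == 0) return(max(N0, 0))
  N <- N0
  tt <- 0
  dt <- t / 100
  steps <- 0L
  while (tt < t) {
    steps <- steps + 1L
    if (steps > max_steps) {
      stop("ode_depletion: step budget exhausted (non-convergence)")
    }
    dt <- min(dt, t - tt)
    k <- numeric(6)
    k[1] <- deriv(N)
    for (s in 1:5) {
      Ns <- N + dt * sum(ck_b[[s]] * k[seq_len(s)])
      k[s + 1] <- deriv(max(Ns, 0))
    }
    N5 <- N + dt * sum(ck_c5 * k)
    N4 <- N + dt * sum(ck_c4 * k)
    err <- abs(N5 - N4) / (atol + rtol * max(abs(N), abs(N5)))
    if (is.finite(err) && err <= 1) {
      tt <- tt + dt
      N <- max(N5, 0)
      dt <- dt * min(5, max(0.2, 0.9 * err^(-0.2)))
      if (N == 0) break # prey exhausted; deriv(0) = 0 for all members
    } else {
      dt <- dt * max(0.1, 0.9 * if (is.finite(err)) err^(-0.25) else 0.1)
    }
  }
  min(max(N, 0), N0)
}

# One fixed-size RK4 step of dN/dt = deriv(N), vectorised over states.
# Used by the stochastic simulator, where parameters are frozen within a step.
rk4_step <- function(deriv, N, dt) {
  k1 <- deriv(N)
  k2 <- deriv(pmax(N + dt / 2 * k1, 0))
  k3 <- deriv(pmax(N + dt / 2 * k2, 0))
  k4 <- deriv(pmax(N + dt * k3, 0))
  pmax(N + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
}
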