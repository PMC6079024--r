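#' Functional response parameters
#'
#' Container for a predator's type-II functional response parameters: attack
#' rate `a` (arena.day^-1) and handling time `h` (day.prey^-1). A type-III
#' hook is provided through `attack_fn`, a caller-supplied monotone
#' non-negative function giving the attack rate as a function of prey density;
#' all estimation in this package targets the type-II form.
#'
#' @param a attack rate, arena.day^-1, must be > 0. For `response = "type3"`
#'   this is ignored in favour of `attack_fn`.
#' @param h handling time, day.prey^-1, must be >= 0.
#' @param response functional response type, `"type2"` (default) or `"type3"`.
#' @param attack_fn for `"type3"` only: function of prey density `N` returning
#'   the attack rate, vectorised, non-negative.
#' @return an object of class `fr_params`.
#' @examples
#' fr_params(a = 2, h = 0.005)
#' @export
fr_params <- function(a, h, response = c("type2", "type3"), attack_fn = NULL) {
  response <- match.arg(response)
  if (response == "type2") {
    if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0) {
      stop("attack rate 'a' must be a single finite value > 0")
    }
  } else {
    if (!is.function(attack_fn)) {
      stop("response 'type3' requires 'attack_fn', a function of prey density")
    }
    a <- NA_real_
  }
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h < 0) {
    stop("handling time 'h' must be a single finite value >= 0")
  }
  structure(
    list(a = as.numeric(a), h = as.numeric(h), response = response,
         attack_fn = attack_fn),
    class = "fr_params"
  )
}

#' @export
print.fr_params <- function(x, ...) {
  cat("Functional response (", x$response, "): a = ",
      if (x$response == "type3") "attack_fn(N)" else format(x$a),
      ", h = ", format(x$h), "\n", sep = "")
  invisible(x)
}

#' @export
format.fr_params <- function(x, ...) {
  sprintf("a=%.10g;h=%.10g;response=%s", x$a, x$h, x$response)
}

#' Instantaneous per-capita feeding rate
#'
#' Holling disc equation `f(N) = a N / (1 + a h N)` for a type-II response;
#' for the type-III hook the attack rate is evaluated as `attack_fn(N)` at
#' each density.
#'
#' @param params an [fr_params()] object.
#' @param N prey density (prey.arena^-1), numeric vector >= 0.
#' @return per-capita feeding rate (prey.day^-1), same length as `N`.
#' @examples
#' holling2_rate(fr_params(2, 0.005), N = 100)
#' @export
holling2_rate <- function(params, N) {
  stopifnot(inherits(params, "fr_params"))
  if (any(N < 0)) stop("prey density N must be >= 0")
  a <- if (params$response == "type3") params$attack_fn(N) else params$a
  if (any(a < 0)) stop("attack rate must be non-negative")
  a * N / (1 + a * params$h * N)
}

#' Expected prey eaten under the Rogers random predator equation
#'
#' The random predator equation is the exact time-integral of prey depletion
#' under a type-II functional response: the number eaten `Ne` solves
#' `Ne = N0 (1 - exp(-a (t - h Ne)))`. It is evaluated in closed form via the
#' principal branch of the Lambert W function,
#' `Ne = N0 - W(a h N0 exp(a h N0 - a t)) / (a h)`,
#' computed in log space so large arguments never overflow. The `h = 0` limit
#' uses the exponential-depletion closed form `N0 (1 - exp(-a P t))`.
#'
#' For `P` identical predators the depletion ODE `dN/dt = -P a N/(1 + a h N)`
#' is integrated exactly by the same formula with parameters `(P a, h / P)`.
#'
#' @param params an [fr_params()] object (type II; the type-III hook has no
#'   closed form and is handled by [popdyn_predict()]).
#' @param N0 initial prey count(s), numeric vector >= 1 (0 allowed, returns 0).
#' @param t trial duration in days, scalar or vector recycled against `N0`,
#'   must be > 0 (the limit `t -> 0` returns 0).
#' @param P number of identical predators, integer >= 1.
#' @return expected number of prey eaten, in `[0, N0)`, same length as
#'   `max(length(N0), length(t))`.
#' @examples
#' rogers_eaten(fr_params(2, 0.005), N0 = 100, t = 1)
#' @export
rogers_eaten <- function(params, N0, t, P = 1) {
  stopifnot(inherits(params, "fr_params"))
  if (params$response != "type2") {
    stop("rogers_eaten is defined for type-II responses; use popdyn_predict()")
  }
  if (any(N0 < 0)) stop("N0 must be >= 0")
  if (any(t < 0)) stop("t must be >= 0")
  if (length(P) != 1L || P < 1 || P != round(P)) {
    stop("P must be a single integer >= 1")
  }
  n <- max(length(N0), length(t))
  N0 <- rep_len(as.numeric(N0), n)
  t <- rep_len(as.numeric(t), n)
  a <- params$a
  h <- params$h
  if (h == 0) {
    ne <- N0 * (1 - exp(-a * P * t))
  } else {
    ne <- numeric(n)
    pos <- N0 > 0 & t > 0
    # log-space argument of W: z = log(a h N0) + a h N0 - a P t
    z <- log(a * h * N0[pos]) + a * h * N0[pos] - a * P * t[pos]
    ne[pos] <- N0[pos] - lambert_w0_exp(z) / (a * h)
  }
  # clamp sub-ulp negatives from cancellation
  pmin(pmax(ne, 0), N0)
}
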