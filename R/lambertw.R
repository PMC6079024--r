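#' Lambert W function, principal branch
#'
#' Solves \eqn{w e^w = x} for \eqn{w \ge -1}, vectorised. Used to evaluate the
#' Rogers random predator equation in closed form.
#'
#' @param x numeric vector, each element >= -1/e.
#' @return numeric vector of the same length.
#' @keywords internal
lambert_w0 <- function(x) {
  if (any(x < -exp(-1) - 1e-12)) {
    stop("lambert_w0: argument below -1/e, outside the principal branch")
  }
  x <- pmax(x, -exp(-1))
  # initial guess: branch-point expansion near -1/e, ratio for small x,
  # asymptotic log form for large x
  p <- sqrt(2 * (exp(1) * x + 1))
  w <- ifelse(x < -0.25,
    -1 + p * (1 + p * (-1 / 3 + p * 11 / 72)),
    ifelse(x < 3, x / (1 + x), log(x) - log(pmax(log(x), 1e-12)))
  )
  for (i in seq_len(100)) {
    ew <- exp(w)
    f <- w * ew - x
    # Halley step
    w1 <- w - f / (ew * (w + 1) - (w + 2) * f / (2 * w + 2))
    done <- abs(w1 - w) <= 1e-13 * (abs(w1) + 1e-300)
    w <- w1
    if (all(done)) break
  }
  w
}

#' Lambert W of an exponential, overflow-safe
#'
#' Computes \eqn{W(e^z)} without forming \eqn{e^z}. For large z solves
#' \eqn{w + \log w = z} by Newton iteration, so arguments far beyond the
#' double-precision overflow threshold are handled exactly.
#'
#' @param z numeric vector.
#' @return numeric vector, \eqn{W(e^z)}.
#' @keywords internal
lambert_w0_exp <- function(z) {
  out <- numeric(length(z))
  small <- z < 500
  if (any(small)) out[small] <- lambert_w0(exp(z[small]))
  if (any(!small)) {
    zz <- z[!small]
    w <- zz - log(zz)
    for (i in seq_len(50)) {
      w1 <- w - (w + log(w) - zz) / (1 + 1 / w)
      if (all(abs(w1 - w) <= 1e-13 * abs(w1))) {
        w <- w1
        break
      }
      w <- w1
    }
    out[!small] <- w
  }
  out
}
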