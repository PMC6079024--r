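#' Fit the Rogers random predator equation by maximum likelihood
#'
#' Estimates attack rate `a` and handling time `h` from single-predator (or
#' aggregated multi-predator) feeding trials by maximising the binomial
#' log-likelihood of the numbers eaten,
#' `sum log Binom(Ne | N0, p)` with `p = rogers_eaten(a, h, N0, t) / N0`
#' clipped to `[1e-9, 1 - 1e-9]`. The expected proportion uses the
#' depletion-corrected random predator equation, not a constant-risk
#' approximation. Optimisation is over `(log a, log h)` so positivity is
#' structural; box bounds keep degenerate data (e.g. all `Ne = 0`) on a finite
#' edge instead of crashing.
#'
#' @param trials data frame of feeding trials with columns `N0`, `Ne`,
#'   `t_days` (see [read_trials()] for the full schema). `Ne` must be integer:
#'   expected values produced by the multiplicative risk model must be rounded
#'   to the nearest integer first (see [pair_replicates()]).
#' @param start optional [fr_params()] giving starting values; a moment-based
#'   heuristic is used otherwise.
#' @return an object of class `fr_fit`: list with `estimates` ([fr_params()]),
#'   `log_likelihood`, `ci95_a`, `ci95_h` (Wald intervals on the log scale,
#'   back-transformed), `vcov` (2x2, natural scale; `NA` when the observed
#'   information is singular), `vcov_log`, `n_trials`, `converged`, `message`,
#'   `t_days` (the trial durations seen).
#' @examples
#' d <- simulate_deterministic(fr_params(2, 0.005), grid = c(5, 50, 200, 800), t = 1)
#' fit_rogers(d$trials)
#' @export
fit_rogers <- function(trials, start = NULL) {
  trials <- validate_trials(trials)
  if (any(trials$Ne != round(trials$Ne))) {
    stop("Ne must be integer counts; round multiplicative-risk expectations ",
         "to the nearest integer before fitting (see pair_replicates())")
  }
  if (length(unique(trials$N0)) < 2L) {
    stop("fit_rogers needs trials at >= 2 distinct prey densities")
  }

  N0 <- trials$N0
  Ne <- trials$Ne
  tt <- trials$t_days

  if (is.null(start)) {
    p_bar <- Ne / N0
    low <- N0 <= stats::quantile(N0, 0.35)
    a0 <- stats::median(-log(1 - pmin(p_bar[low], 0.95)) / tt[low])
    if (!is.finite(a0) || a0 <= 0) a0 <- 1e-3
    h0 <- stats::median(tt) / max(max(Ne), 1)
    start <- fr_params(min(max(a0, 1e-6), 1e3), min(max(h0, 1e-8), 1))
  }
  stopifnot(inherits(start, "fr_params"))

  nll <- function(par) {
    prm <- fr_params(exp(par[1]), exp(par[2]))
    p <- rogers_eaten(prm, N0, tt) / N0
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    -sum(stats::dbinom(Ne, N0, p, log = TRUE))
  }

  par0 <- c(log(start$a), log(max(start$h, 1e-8)))
  lower <- c(log(1e-8), log(1e-9))
  upper <- c(log(1e4), log(10))
  opt <- tryCatch(
    stats::optim(par0, nll, method = "L-BFGS-B", lower = lower, upper = upper,
                 hessian = TRUE, control = list(maxit = 500)),
    error = function(e) e
  )

  if (inherits(opt, "error") || !is.finite(opt$value)) {
    msg <- if (inherits(opt, "error")) conditionMessage(opt) else "non-finite objective"
    return(structure(
      list(estimates = start, log_likelihood = NA_real_,
           ci95_a = c(NA_real_, NA_real_), ci95_h = c(NA_real_, NA_real_),
           vcov = matrix(NA_real_, 2, 2), vcov_log = matrix(NA_real_, 2, 2),
           n_trials = nrow(trials), converged = FALSE, message = msg,
           t_days = sort(unique(tt))),
      class = "fr_fit"
    ))
  }

  est <- fr_params(exp(opt$par[1]), exp(opt$par[2]))
  vcov_log <- tryCatch({
    v <- solve(opt$hessian)
    if (any(!is.finite(v)) || any(diag(v) < 0)) stop("bad information")
    v
  }, error = function(e) matrix(NA_real_, 2, 2))
  se_log <- sqrt(diag(vcov_log))
  ci_a <- exp(opt$par[1] + c(-1, 1) * 1.96 * se_log[1])
  ci_h <- exp(opt$par[2] + c(-1, 1) * 1.96 * se_log[2])
  D <- diag(c(est$a, est$h))
  vcov_nat <- D %*% vcov_log %*% D
  dimnames(vcov_nat) <- dimnames(vcov_log) <- list(c("a", "h"), c("a", "h"))

  structure(
    list(estimates = est, log_likelihood = -opt$value,
         ci95_a = ci_a, ci95_h = ci_h,
         vcov = vcov_nat, vcov_log = vcov_log,
         n_trials = nrow(trials),
         converged = opt$convergence == 0,
         message = if (opt$convergence == 0) "converged" else opt$message,
         t_days = sort(unique(tt))),
    class = "fr_fit"
  )
}

#' @export
print.fr_fit <- function(x, ...) {
  cat("Rogers random predator fit (binomial ML,", x$n_trials, "trials)\n")
  cat(sprintf("  a = %.5g  [%.5g, %.5g]\n", x$estimates$a, x$ci95_a[1], x$ci95_a[2]))
  cat(sprintf("  h = %.5g  [%.5g, %.5g]\n", x$estimates$h, x$ci95_h[1], x$ci95_h[2]))
  cat(sprintf("  logLik = %.4f  converged = %s\n", x$log_likelihood, x$converged))
  invisible(x)
}

#' Predicted feeding curve from a fit
#'
#' @param object an `fr_fit`.
#' @param N0 prey densities at which to predict.
#' @param t trial duration in days; defaults to the (single) duration seen by
#'   the fit.
#' @param ... unused.
#' @return data frame with columns `N0`, `expected`.
#' @export
predict.fr_fit <- function(object, N0, t = NULL, ...) {
  if (is.null(t)) {
    if (length(object$t_days) != 1L) {
      stop("fit saw multiple durations; supply t explicitly")
    }
    t <- object$t_days
  }
  data.frame(N0 = N0, expected = rogers_eaten(object$estimates, N0, t))
}

#' Non-parametric bootstrap confidence band for a functional response curve
#'
#' Resamples trials with replacement `n_boot` times, refits the random
#' predator equation to each resample using the original estimates as starting
#' values, and returns pointwise 2.5%/97.5% quantiles of the predicted
#' expected-eaten curves over a prey-density grid. Replicates that fail to
#' converge (or collapse to a single density) are dropped and counted; more
#' than 20% dropped is an error.
#'
#' @param trials the trial table the fit was computed from.
#' @param fit a converged `fr_fit`.
#' @param n_boot number of bootstrap resamples, default 2000.
#' @param seed integer seed; required for reproducibility.
#' @param grid prey-density grid for the band; defaults to the distinct `N0`
#'   in `trials`.
#' @return object of class `fr_band`: list with `grid`, `lower95`, `upper95`,
#'   `point` (the fit's own curve), `n_boot`, `n_dropped`, `boot_params`
#'   (matrix of resample estimates, for covariance fall-backs), `seed`.
#' @export
bootstrap_band <- function(trials, fit, n_boot = 2000, seed, grid = NULL) {
  stopifnot(inherits(fit, "fr_fit"))
  if (!fit$converged) stop("bootstrap_band requires a converged fit")
  trials <- validate_trials(trials)
  if (length(unique(trials$N0)) < 2L) {
    stop("bootstrap_band needs trials at >= 2 distinct prey densities")
  }
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  if (length(unique(trials$t_days)) != 1L) {
    stop("bootstrap_band expects a single trial duration")
  }
  t <- trials$t_days[1]
  if (is.null(grid)) grid <- sort(unique(trials$N0))

  set.seed(as.integer(seed))
  n <- nrow(trials)
  curves <- matrix(NA_real_, nrow = n_boot, ncol = length(grid))
  pars <- matrix(NA_real_, nrow = n_boot, ncol = 2,
                 dimnames = list(NULL, c("a", "h")))
  dropped <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    res <- trials[idx, , drop = FALSE]
    if (length(unique(res$N0)) < 2L) {
      dropped <- dropped + 1L
      next
    }
    fb <- tryCatch(suppressWarnings(fit_rogers(res, start = fit$estimates)),
                   error = function(e) NULL)
    if (is.null(fb) || !fb$converged) {
      dropped <- dropped + 1L
      next
    }
    curves[b, ] <- rogers_eaten(fb$estimates, grid, t)
    pars[b, ] <- c(fb$estimates$a, fb$estimates$h)
  }
  if (dropped > 0.2 * n_boot) {
    stop(sprintf("bootstrap_band: %d of %d resamples failed to converge (> 20%%)",
                 dropped, n_boot))
  }
  ok <- stats::complete.cases(curves)
  structure(
    list(grid = grid,
         lower95 = apply(curves[ok, , drop = FALSE], 2, stats::quantile, 0.025),
         upper95 = apply(curves[ok, , drop = FALSE], 2, stats::quantile, 0.975),
         point = rogers_eaten(fit$estimates, grid, t),
         t_days = t, n_boot = n_boot, n_dropped = dropped,
         boot_params = pars[ok, , drop = FALSE], seed = as.integer(seed)),
    class = "fr_band"
  )
}

#' @export
print.fr_band <- function(x, ...) {
  cat("Bootstrap 95% band over", length(x$grid), "densities;",
      x$n_boot, "resamples,", x$n_dropped, "dropped\n")
  invisible(x)
}

#' Confidence-band overlap test between two functional response curves
#'
#' Implements the visual-comparison rule used with bootstrapped functional
#' response bands: two curves are classified as significantly different
#' wherever their 95% bands do not intersect.
#'
#' @param bandA,bandB `fr_band` objects on identical density grids.
#' @return list with `grid`, `overlap` (logical per density), `significant`
#'   (TRUE when any contiguous non-overlap region exists) and `regions`
#'   (data frame of density bounds of non-overlap runs).
#' @export
ci_overlap <- function(bandA, bandB) {
  stopifnot(inherits(bandA, "fr_band"), inherits(bandB, "fr_band"))
  if (length(bandA$grid) != length(bandB$grid) ||
      any(bandA$grid != bandB$grid)) {
    stop("ci_overlap: density grids differ")
  }
  overlap <- bandA$lower95 <= bandB$upper95 & bandB$lower95 <= bandA$upper95
  runs <- rle(!overlap)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  regions <- data.frame(
    from_N0 = bandA$grid[starts[keep]],
    to_N0 = bandA$grid[ends[keep]]
  )
  list(grid = bandA$grid, overlap = overlap,
       significant = any(!overlap), regions = regions)
}
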