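#' Predator assemblage
#'
#' One or more predator species foraging together in an arena, each with a
#' population density (predators.arena^-1, positive integer) and functional
#' response parameters.
#'
#' @param species character vector of species labels, one per member.
#' @param density integer vector of predator densities, one per member.
#' @param params list of [fr_params()], one per member.
#' @return object of class `predator_assemblage` with a derived `conspecific`
#'   flag (all species labels equal).
#' @examples
#' predator_assemblage(c("A", "A"), c(1, 1),
#'                     list(fr_params(2, 0.005), fr_params(2, 0.005)))
#' @export
predator_assemblage <- function(species, density, params) {
  if (inherits(params, "fr_params")) params <- list(params)
  n <- length(species)
  if (n < 1L) stop("an assemblage needs >= 1 member")
  if (length(density) != n || length(params) != n) {
    stop("species, density and params must have the same length")
  }
  if (any(density < 1 | density != round(density))) {
    stop("densities must be positive integers")
  }
  if (!all(vapply(params, inherits, TRUE, "fr_params"))) {
    stop("params must be a list of fr_params objects")
  }
  members <- lapply(seq_len(n), function(i) {
    list(species = as.character(species[i]), P = as.integer(density[i]),
         params = params[[i]])
  })
  structure(
    list(members = members,
         conspecific = length(unique(as.character(species))) == 1L),
    class = "predator_assemblage"
  )
}

#' @export
print.predator_assemblage <- function(x, ...) {
  cat("Predator assemblage (",
      if (x$conspecific) "conspecific" else "heterospecific", "):\n", sep = "")
  for (m in x$members) {
    cat(sprintf("  %s  P = %d  a = %s  h = %g\n", m$species, m$P,
                if (m$params$response == "type3") "fn(N)" else format(m$params$a),
                m$params$h))
  }
  invisible(x)
}

#' Multiplicative risk model
#'
#' Independence null model for two predators: with per-prey probabilities of
#' being eaten `pA` and `pB` measured in single-predator trials at the same
#' prey density, the expected number eaten by both together is
#' `N_AB = N0 (pA + pB - pA pB)`.
#'
#' @param N0 initial prey count(s).
#' @param pA,pB probabilities of being eaten by each predator over the trial,
#'   in `[0, 1]`; vectors are recycled against `N0`.
#' @return expected number of prey eaten, `<= N0`.
#' @examples
#' multiplicative_risk(100, 0.5, 0.5) # 75
#' @export
multiplicative_risk <- function(N0, pA, pB) {
  if (any(pA < 0 | pA > 1) || any(pB < 0 | pB > 1)) {
    stop("eaten probabilities must lie in [0, 1]")
  }
  if (any(N0 < 0)) stop("N0 must be >= 0")
  N0 * (pA + pB - pA * pB)
}

#' Pair single-predator replicates into expected two-predator trials
#'
#' Step 1 of the direct functional-response protocol: replicate numbers are
#' randomly re-assigned within each prey density, replicate r of predator A is
#' matched with replicate r of predator B at the same density, and the
#' expected two-predator catch is computed with the multiplicative risk model
#' from the per-replicate eaten proportions, then rounded to the nearest
#' integer (half away from zero) so the result can be fitted with a binomial
#' likelihood. For conspecific pairs (`trialsB = NULL`) the same replicate is
#' used twice, which is pseudoreplication; a warning is emitted and the output
#' carries `attr(, "pseudoreplication") = TRUE`.
#'
#' @param trialsA,trialsB trial tables covering the same `N0` grid with equal
#'   replicate counts per density; `trialsB = NULL` means a conspecific pair.
#' @param seed integer seed for the random replicate assignment.
#' @return trial table of expected two-predator trials (schema as
#'   [read_trials()]), with columns `pA`, `pB` retained for inspection.
#' @export
pair_replicates <- function(trialsA, trialsB = NULL, seed = NULL) {
  trialsA <- validate_trials(trialsA)
  conspecific <- is.null(trialsB)
  if (!conspecific) trialsB <- validate_trials(trialsB)
  if (!is.null(seed)) set.seed(as.integer(seed))

  gridA <- sort(unique(trialsA$N0))
  if (!conspecific) {
    gridB <- sort(unique(trialsB$N0))
    if (length(gridA) != length(gridB) || any(gridA != gridB)) {
      stop("pair_replicates: the two trial sets cover different N0 grids")
    }
  }
  if (conspecific) {
    warning("conspecific pairing reuses each replicate twice (pseudoreplication)")
  }

  out <- do.call(rbind, lapply(gridA, function(n0) {
    A <- trialsA[trialsA$N0 == n0, , drop = FALSE]
    A <- A[sample.int(nrow(A)), , drop = FALSE]
    if (conspecific) {
      B <- A
    } else {
      B <- trialsB[trialsB$N0 == n0, , drop = FALSE]
      if (nrow(B) != nrow(A)) {
        stop("pair_replicates: unequal replicate counts at N0 = ", n0)
      }
      B <- B[sample.int(nrow(B)), , drop = FALSE]
    }
    if (length(unique(c(A$t_days, B$t_days))) != 1L) {
      stop("pair_replicates: trial durations differ at N0 = ", n0)
    }
    pA <- A$Ne / n0
    pB <- B$Ne / n0
    data.frame(
      assemblage_id = paste0(A$assemblage_id, "+", B$assemblage_id),
      replicate_id = seq_len(nrow(A)),
      N0 = n0,
      Ne = round_half_up(multiplicative_risk(n0, pA, pB)),
      t_days = A$t_days,
      pA = pA, pB = pB
    )
  }))
  rownames(out) <- NULL
  attr(out, "pseudoreplication") <- conspecific
  out
}

#' Direct functional-response null model
#'
#' Steps 1-3 of the direct FR protocol: pair single-predator replicates into
#' expected two-predator trials with the multiplicative risk model
#' ([pair_replicates()]), fit the random predator equation to the rounded
#' expectations ([fit_rogers()]), and bootstrap a 95% band around the fitted
#' curve ([bootstrap_band()]). The same machinery applied to observed
#' two-predator trials gives the empirical curve an MPE test compares against
#' (see [mpe_test()]).
#'
#' @inheritParams pair_replicates
#' @param n_boot bootstrap resamples for the band, default 2000.
#' @param grid density grid for the curve and band; defaults to the distinct
#'   `N0` in the paired data.
#' @return list of class `direct_fr` with `model = "direct_fr"`, `paired`
#'   (the expected trials), `fit`, `curve` (data frame `N0`, `expected`) and
#'   `band` (an `fr_band`).
#' @export
direct_fr_predict <- function(trialsA, trialsB = NULL, seed, n_boot = 2000,
                              grid = NULL) {
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  seed <- as.integer(seed)
  paired <- pair_replicates(trialsA, trialsB, seed = seed)
  fit <- fit_rogers(paired)
  if (!fit$converged) stop("direct FR fit did not converge: ", fit$message)
  if (is.null(grid)) grid <- sort(unique(paired$N0))
  band <- bootstrap_band(paired, fit, n_boot = n_boot, seed = seed + 1L,
                         grid = grid)
  structure(
    list(model = "direct_fr", paired = paired, fit = fit,
         curve = predict(fit, grid), band = band),
    class = "direct_fr"
  )
}

#' Population-dynamic null model prediction
#'
#' Integrates the prey-depletion model
#' `dN/dt = - sum_i f_i(N) P_i`
#' from `N(0) = N0` over the trial duration, where `f_i` is member i's
#' functional response (any shape, including the type-III hook), and returns
#' the expected number eaten `N0 - N(t)`. For a single type-II predator this
#' equals [rogers_eaten()] exactly; two identical conspecifics reduce to
#' `rogers_eaten` with parameters `(2a, h/2)`.
#'
#' @param assemblage a [predator_assemblage()].
#' @param N0 initial prey count(s), vectorised.
#' @param t trial duration in days.
#' @param rtol,atol integrator tolerances (see [ode_depletion()]).
#' @return expected number of prey eaten, in `[0, N0]`.
#' @examples
#' asm <- predator_assemblage("A", 1, fr_params(2, 0.005))
#' popdyn_predict(asm, N0 = 100, t = 1)
#' @export
popdyn_predict <- function(assemblage, N0, t, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(assemblage, "predator_assemblage"))
  if (any(N0 < 1)) stop("N0 must be >= 1")
  if (length(t) != 1L || t <= 0) stop("t must be a single value > 0")
  members <- assemblage$members
  deriv <- function(N) {
    -sum(vapply(members, function(m) m$P * holling2_rate(m$params, N), 0))
  }
  vapply(N0, function(n0) n0 - ode_depletion(deriv, n0, t, rtol, atol), 0)
}

#' Latin-hypercube confidence interval for the population-dynamic prediction
#'
#' Propagates functional-response parameter uncertainty into the prediction:
#' parameter sets are drawn by Latin hypercube sampling across the 95% CIs of
#' each member's fitted `(a, h)` (uniform within the interval, independent
#' across parameters — covariance is taken as zero when unknown, the default;
#' `method = "normal"` instead uses Gaussian marginals correlated through each
#' fit's log-scale variance-covariance matrix). The depletion model is
#' integrated for every draw and the 2.5% and 97.5% quantiles of the resulting
#' eaten values are returned.
#'
#' @param fits list of `fr_fit`, one per assemblage member.
#' @param P integer vector of member densities (default all 1).
#' @param N0 initial prey count (scalar).
#' @param t trial duration, days.
#' @param n_lhs number of Latin hypercube draws, default 1000.
#' @param seed integer seed, required.
#' @param method `"uniform"` (default) or `"normal"` (see Details).
#' @param inflate multiplier applied to all CI half-widths (diagnostic use).
#' @return list with `lower`, `upper`, `point`, `n_truncated` (draws clipped
#'   at the positivity floor), `n_lhs`, `seed`.
#' @export
popdyn_ci <- function(fits, P = rep(1L, length(fits)), N0, t, n_lhs = 1000,
                      seed, method = c("uniform", "normal"), inflate = 1) {
  method <- match.arg(method)
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  stopifnot(all(vapply(fits, inherits, TRUE, "fr_fit")), length(P) == length(fits))
  if (length(N0) != 1L) stop("popdyn_ci takes a single N0")
  for (f in fits) {
    if (anyNA(f$ci95_a) || anyNA(f$ci95_h)) {
      stop("each fit must carry finite 95% CIs (refit or use bootstrap covariance)")
    }
  }
  set.seed(as.integer(seed))
  m <- length(fits)
  U <- latin_hypercube(n_lhs, 2L * m)
  draws <- matrix(NA_real_, n_lhs, 2L * m)
  for (i in seq_len(m)) {
    f <- fits[[i]]
    mid_a <- f$estimates$a
    mid_h <- f$estimates$h
    half_a <- inflate * (f$ci95_a[2] - f$ci95_a[1]) / 2
    half_h <- inflate * (f$ci95_h[2] - f$ci95_h[1]) / 2
    cols <- c(2L * i - 1L, 2L * i)
    if (method == "uniform") {
      ctr_a <- mean(f$ci95_a)
      ctr_h <- mean(f$ci95_h)
      draws[, cols[1]] <- ctr_a - half_a + 2 * half_a * U[, cols[1]]
      draws[, cols[2]] <- ctr_h - half_h + 2 * half_h * U[, cols[2]]
    } else {
      z <- stats::qnorm(U[, cols, drop = FALSE])
      vl <- f$vcov_log
      if (anyNA(vl)) stop("method = 'normal' needs a finite vcov_log")
      L <- chol(vl * inflate^2)
      lg <- sweep(z %*% L, 2, log(c(mid_a, max(mid_h, 1e-12))), "+")
      draws[, cols[1]] <- exp(lg[, 1])
      draws[, cols[2]] <- exp(lg[, 2])
    }
  }
  # positivity: a > 0 strictly, h >= 0
  n_trunc <- sum(draws[, seq(1, 2 * m, by = 2)] < 1e-6) +
    sum(draws[, seq(2, 2 * m, by = 2)] < 0)
  draws[, seq(1, 2 * m, by = 2)] <- pmax(draws[, seq(1, 2 * m, by = 2)], 1e-6)
  draws[, seq(2, 2 * m, by = 2)] <- pmax(draws[, seq(2, 2 * m, by = 2)], 0)

  eaten <- apply(draws, 1, function(d) {
    asm <- predator_assemblage(
      species = paste0("m", seq_len(m)),
      density = P,
      params = lapply(seq_len(m), function(i) fr_params(d[2 * i - 1], d[2 * i]))
    )
    popdyn_predict(asm, N0, t, rtol = 1e-6, atol = 1e-8)
  })
  asm0 <- predator_assemblage(
    species = paste0("m", seq_len(m)), density = P,
    params = lapply(fits, function(f) f$estimates)
  )
  point <- popdyn_predict(asm0, N0, t)
  list(lower = unname(stats::quantile(eaten, 0.025)),
       upper = unname(stats::quantile(eaten, 0.975)),
       point = point, n_truncated = n_trunc,
       n_lhs = n_lhs, seed = as.integer(seed))
}
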