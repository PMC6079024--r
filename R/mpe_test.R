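#' Test for emergent multiple predator effects
#'
#' Compares observed multi-predator feeding trials with the predictions of a
#' null model built from single-predator trials. Under the population-dynamic
#' route, each species' functional response is fitted to its single-predator
#' trials, the depletion model is integrated for the declared assemblage, and
#' a Latin-hypercube 95% interval is computed per density. The observed side
#' gets its own 95% interval (t-based CI of the replicate mean, expanded by
#' the 0.5-prey resolution of integer eaten counts), and the verdict per
#' density follows the CI-overlap rule: overlapping intervals are
#' `independent`; an observed interval entirely below the prediction is
#' `risk_reduction` (fewer prey are killed than predicted), entirely above is
#' `risk_enhancement`. Under the direct-FR route, the null curve is
#' the [direct_fr_predict()] band from paired single-predator replicates, the
#' observed curve is a [fit_rogers()] + [bootstrap_band()] fit of the
#' multi-predator trials, and the verdict per density follows the CI-overlap
#' rule of [ci_overlap()].
#'
#' @param single_trials trial table of single-predator trials;
#'   `assemblage_id` identifies the species (1 or 2 distinct values).
#' @param multi_trials trial table of observed multi-predator trials
#'   (non-empty).
#' @param model `"pop_dyn"` (default) or `"direct_fr"`.
#' @param P named integer vector of predator densities per species; defaults
#'   to 1 for every species present in `single_trials`.
#' @param seed integer seed, required.
#' @param n_lhs Latin hypercube draws for the population-dynamic interval.
#' @param n_boot bootstrap resamples for the direct-FR bands.
#' @return data frame with one row per multi-trial density: `N0`, `model`,
#'   `predicted`, `lower`, `upper`, `observed`, `verdict`; fits attached as
#'   attributes `"fits"`.
#' @export
mpe_test <- function(single_trials, multi_trials,
                     model = c("pop_dyn", "direct_fr"),
                     P = NULL, seed, n_lhs = 1000, n_boot = 2000) {
  model <- match.arg(model)
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  seed <- as.integer(seed)
  single_trials <- validate_trials(single_trials)
  multi_trials <- validate_trials(multi_trials)
  if (!nrow(multi_trials)) stop("observed multi-predator table is empty")
  species <- sort(unique(single_trials$assemblage_id))
  if (!length(species) %in% 1:2) {
    stop("single-predator table must contain 1 or 2 species")
  }
  if (is.null(P)) P <- stats::setNames(rep(1L, length(species)), species)
  if (length(species) == 1L && length(P) == 1L && is.null(names(P))) {
    names(P) <- species
  }
  if (!all(species %in% names(P))) stop("P must name every species")
  t_multi <- unique(multi_trials$t_days)
  if (length(t_multi) != 1L) stop("multi-predator trials must share one duration")
  dens <- sort(unique(multi_trials$N0))
  by_dens <- split(multi_trials$Ne, factor(multi_trials$N0, levels = dens))
  obs <- vapply(by_dens, mean, 0)
  # 95% CI of the observed mean, widened by the half-prey resolution of
  # integer eaten counts (degenerate replicate sets get the resolution only)
  obs_ci <- t(vapply(by_dens, function(x) {
    half <- if (length(x) >= 2 && stats::sd(x) > 0) {
      stats::qt(0.975, length(x) - 1) * stats::sd(x) / sqrt(length(x))
    } else 0
    mean(x) + c(-1, 1) * (half + 0.5)
  }, numeric(2)))

  if (model == "pop_dyn") {
    fits <- lapply(species, function(sp) {
      fit_rogers(single_trials[single_trials$assemblage_id == sp, , drop = FALSE])
    })
    names(fits) <- species
    for (sp in species) {
      if (!fits[[sp]]$converged) stop("single-predator fit failed for ", sp)
    }
    # a conspecific pair declared via P = 2 on one species, or one fit per member
    use_fits <- fits
    use_P <- as.integer(P[species])
    rows <- lapply(seq_along(dens), function(i) {
      ci <- popdyn_ci(use_fits, P = use_P, N0 = dens[i], t = t_multi,
                      n_lhs = n_lhs, seed = derive_seed(seed, i))
      verdict <- if (obs_ci[i, 2] < ci$lower) "risk_reduction"
      else if (obs_ci[i, 1] > ci$upper) "risk_enhancement"
      else "independent"
      data.frame(N0 = dens[i], model = model, predicted = ci$point,
                 lower = ci$lower, upper = ci$upper,
                 observed = unname(obs[i]), verdict = verdict)
    })
    out <- do.call(rbind, rows)
    attr(out, "fits") <- fits
    return(out)
  }

  # direct FR route
  if (length(species) == 2L) {
    null_pred <- direct_fr_predict(
      single_trials[single_trials$assemblage_id == species[1], , drop = FALSE],
      single_trials[single_trials$assemblage_id == species[2], , drop = FALSE],
      seed = seed, n_boot = n_boot, grid = dens
    )
  } else {
    null_pred <- suppressWarnings(direct_fr_predict(
      single_trials, seed = seed, n_boot = n_boot, grid = dens
    ))
  }
  obs_fit <- fit_rogers(multi_trials)
  if (!obs_fit$converged) stop("observed multi-predator fit failed")
  obs_band <- bootstrap_band(multi_trials, obs_fit, n_boot = n_boot,
                             seed = seed + 2L, grid = dens)
  ov <- ci_overlap(null_pred$band, obs_band)
  verdict <- ifelse(ov$overlap, "independent",
                    ifelse(obs_band$point < null_pred$band$point,
                           "risk_reduction", "risk_enhancement"))
  out <- data.frame(N0 = dens, model = model,
                    predicted = null_pred$band$point,
                    lower = null_pred$band$lower95,
                    upper = null_pred$band$upper95,
                    observed = obs_band$point,
                    verdict = verdict)
  attr(out, "fits") <- list(null = null_pred$fit, observed = obs_fit)
  out
}
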