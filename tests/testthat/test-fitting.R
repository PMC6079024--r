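test_that("fit_rogers recovers generating parameters from noiseless data", {
  trials <- det_trials(2, 0.005, 1:800, t = 1)
  fit <- fit_rogers(trials)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates$a - 2) / 2, 0.05)
  expect_lt(abs(fit$estimates$h - 0.005) / 0.005, 0.05)
  # CIs bracket the estimates; vcov is PSD
  expect_true(fit$ci95_a[1] <= fit$estimates$a && fit$estimates$a <= fit$ci95_a[2])
  expect_true(fit$ci95_h[1] <= fit$estimates$h && fit$estimates$h <= fit$ci95_h[2])
  expect_true(all(eigen(fit$vcov, only.values = TRUE)$values > -1e-12))
})

test_that("fit_rogers recovers a linear (h = 0) functional response", {
  trials <- det_trials(2, 0, seq(1, 800, by = 10), t = 0.25)
  fit <- fit_rogers(trials)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates$a - 2) / 2, 0.05)
  expect_lt(fit$estimates$h, 1e-4) # h-hat pinned near zero
})

test_that("fit_rogers handles degenerate no-predation data without crashing", {
  trials <- data.frame(assemblage_id = "A", replicate_id = 1,
                       N0 = rep(c(10, 50, 100), each = 3), Ne = 0, t_days = 1)
  fit <- fit_rogers(trials)
  expect_true(fit$converged)
  expect_lt(fit$estimates$a, 0.01) # attack rate driven to the lower edge
})

test_that("fit_rogers enforces its preconditions", {
  trials <- det_trials(2, 0.005, c(50, 100, 200), t = 1)
  trials$Ne[1] <- trials$Ne[1] + 0.4
  expect_error(fit_rogers(trials), "round")
  one_dens <- data.frame(assemblage_id = "A", replicate_id = 1:5,
                         N0 = 100, Ne = 40, t_days = 1)
  expect_error(fit_rogers(one_dens), "distinct")
})

test_that("log-likelihood at the truth never beats the ML optimum", {
  set.seed(31)
  asm <- predator_assemblage("A", 1, fr_params(2, 0.005))
  for (i in 1:5) {
    s <- simulate_stochastic(asm, grid = default_density_grid(12), t = 1,
                             seed = 400 + i)
    fit <- fit_rogers(s$trials)
    p_true <- rogers_eaten(fr_params(2, 0.005), s$trials$N0, 1) / s$trials$N0
    p_true <- pmin(pmax(p_true, 1e-9), 1 - 1e-9)
    ll_true <- sum(dbinom(s$trials$Ne, s$trials$N0, p_true, log = TRUE))
    expect_lte(ll_true, fit$log_likelihood + 1e-8)
  }
})

test_that("parameter recovery under the stochastic noise model stays under 10%", {
  asm <- predator_assemblage("A", 1, fr_params(2, 0.005))
  errs <- vapply(1:6, function(i) {
    s <- simulate_stochastic(asm, t = 1, seed = 500 + i)
    fit <- fit_rogers(s$trials)
    c(abs(fit$estimates$a - 2) / 2, abs(fit$estimates$h - 0.005) / 0.005)
  }, numeric(2))
  expect_lt(median(errs[1, ]), 0.10)
  expect_lt(median(errs[2, ]), 0.10)
})

test_that("bootstrap_band is reproducible, brackets the point curve, and widens with noise", {
  asm <- predator_assemblage("A", 1, fr_params(2, 0.005))
  grid <- default_density_grid(10)
  s <- simulate_stochastic(asm, grid, t = 1, seed = 61)
  fit <- fit_rogers(s$trials)
  b1 <- bootstrap_band(s$trials, fit, n_boot = 40, seed = 9)
  b2 <- bootstrap_band(s$trials, fit, n_boot = 40, seed = 9)
  expect_identical(b1$lower95, b2$lower95)
  expect_identical(b1$upper95, b2$upper95)
  expect_true(all(b1$lower95 <= b1$upper95))
  expect_true(all(b1$lower95 >= 0 & b1$upper95 <= grid))
  # point-estimate curve inside the band at >= 95% of grid points
  inside <- b1$lower95 - 1e-9 <= b1$point & b1$point <= b1$upper95 + 1e-9
  expect_gte(mean(inside), 0.95)

  widths <- vapply(c(0, 0.05, 0.10), function(s_a) {
    d <- simulate_stochastic(asm, grid, t = 1, seed = 62,
                             noise = noise_spec(s_a, s_a / 2))
    f <- fit_rogers(d$trials)
    b <- bootstrap_band(d$trials, f, n_boot = 120, seed = 10)
    mean(b$upper95 - b$lower95)
  }, 0)
  expect_true(widths[1] < widths[2] && widths[2] < widths[3])
})

test_that("bootstrap_band rejects ill-posed inputs", {
  trials <- det_trials(2, 0.005, c(50, 100, 200), t = 1)
  fit <- fit_rogers(trials)
  one_dens <- data.frame(assemblage_id = "A", replicate_id = 1:6,
                         N0 = 100, Ne = 40, t_days = 1)
  expect_error(bootstrap_band(one_dens, fit, n_boot = 10, seed = 1), "distinct")
  expect_error(bootstrap_band(trials, fit, n_boot = 10), "seed")
})

test_that("ci_overlap classifies identity, disjoint bands and grid mismatch", {
  mk <- function(grid, lo, hi) {
    structure(list(grid = grid, lower95 = lo, upper95 = hi, point = (lo + hi) / 2),
              class = "fr_band")
  }
  g <- c(10, 50, 100)
  a <- mk(g, c(0, 1, 2), c(1, 2, 3))
  ident <- ci_overlap(a, a)
  expect_true(all(ident$overlap))
  expect_false(ident$significant)
  expect_equal(nrow(ident$regions), 0)
  b <- mk(g, c(2.5, 3.5, 4.5), c(3, 4, 5))
  dis <- ci_overlap(a, b)
  expect_true(all(!dis$overlap))
  expect_true(dis$significant)
  expect_equal(dis$regions, data.frame(from_N0 = 10, to_N0 = 100))
  expect_error(ci_overlap(a, mk(c(10, 50), c(0, 0), c(1, 1))), "grid")
})
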