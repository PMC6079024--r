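test_that("multiplicative_risk implements N0 (pA + pB - pA pB)", {
  expect_identical(multiplicative_risk(100, 0, 0), 0)
  expect_identical(multiplicative_risk(100, 1, 0.3), 100)
  expect_identical(multiplicative_risk(100, 0.5, 0.5), 75)
  expect_identical(multiplicative_risk(100, 0.2, 0.7),
                   multiplicative_risk(100, 0.7, 0.2))
  expect_true(all(multiplicative_risk(50, seq(0, 1, 0.1), 0.9) <= 50))
  expect_error(multiplicative_risk(100, -0.1, 0.5), "\\[0, 1\\]")
  expect_error(multiplicative_risk(100, 0.5, 1.2), "\\[0, 1\\]")
})

test_that("predator_assemblage derives the conspecific flag and validates", {
  p <- fr_params(2, 0.005)
  asm <- predator_assemblage(c("A", "A"), c(1, 1), list(p, p))
  expect_true(asm$conspecific)
  het <- predator_assemblage(c("A", "B"), c(1, 1), list(p, fr_params(3, 0.01)))
  expect_false(het$conspecific)
  expect_error(predator_assemblage("A", 0, p), "positive integers")
  expect_error(predator_assemblage(character(), integer(), list()), ">= 1")
})

test_that("pair_replicates applies the risk formula and rounding rule", {
  mk <- function(id, ne_by_rep, n0, t = 1) {
    data.frame(assemblage_id = id, replicate_id = seq_along(ne_by_rep),
               N0 = n0, Ne = ne_by_rep, t_days = t)
  }
  # one replicate each: pairing is forced, pA = 0.2, pB = 0.3 at N0 = 10 -> 4
  out <- pair_replicates(mk("A", 2, 10), mk("B", 3, 10), seed = 1)
  expect_equal(out$Ne, 4)
  # conspecific: p = 0.4 at N0 = 50 -> round(50 * 0.64) = 32, with warning
  expect_warning(outc <- pair_replicates(mk("A", 20, 50)), "pseudoreplication")
  expect_equal(outc$Ne, 32)
  expect_true(attr(outc, "pseudoreplication"))
  expect_error(pair_replicates(mk("A", 2, 10), mk("B", 3, 20)), "grids")
})

test_that("pair_replicates reshuffles pairings but preserves per-density marginals", {
  mk <- function(id, ne) data.frame(assemblage_id = id, replicate_id = 1:3,
                                    N0 = 20, Ne = ne, t_days = 1)
  A <- mk("A", c(2, 8, 14))
  B <- mk("B", c(1, 5, 19))
  o1 <- pair_replicates(A, B, seed = 1)
  o2 <- pair_replicates(A[3:1, ], B, seed = 2)
  expect_setequal(o1$pA, o2$pA)
  expect_setequal(o1$pB, o2$pB)
  expect_false(isTRUE(all.equal(o1$Ne, o2$Ne))) # pairings differ
  expect_identical(pair_replicates(A, B, seed = 5)$Ne,
                   pair_replicates(A, B, seed = 5)$Ne)
})

test_that("direct FR equals multiplicative risk when depletion is negligible", {
  # h = 0 and small a t: the paired expectations follow Rogers(2a, 0) exactly
  grid <- default_density_grid(15)
  A <- det_trials(0.1, 0, grid, t = 1, species = "A")
  B <- det_trials(0.1, 0, grid, t = 1, species = "B")
  pred <- direct_fr_predict(A, B, seed = 3, n_boot = 60)
  pA <- rogers_eaten(fr_params(0.1, 0), grid, 1) / grid
  mult <- multiplicative_risk(grid, pA, pA)
  expect_true(all(abs(pred$curve$expected - mult) <= pmax(0.01 * mult, 0.5)))
  # seed-fixed rerun is identical
  pred2 <- direct_fr_predict(A, B, seed = 3, n_boot = 60)
  expect_identical(pred$curve, pred2$curve)
  expect_identical(pred$band$lower95, pred2$band$lower95)
})

test_that("popdyn_predict matches the random predator closed form", {
  p <- fr_params(2, 0.005)
  asm1 <- predator_assemblage("A", 1, p)
  for (N0 in c(10, 100, 800)) {
    expect_equal(popdyn_predict(asm1, N0, 1), rogers_eaten(p, N0, 1),
                 tolerance = 1e-6)
  }
  # two identical conspecifics reduce to (2a, h/2)
  asm2 <- predator_assemblage(c("A", "A"), c(1, 1), list(p, p))
  expect_equal(popdyn_predict(asm2, 800, 1),
               rogers_eaten(fr_params(4, 0.0025), 800, 1), tolerance = 1e-6)
  # member of density 2 == two members of density 1
  asmP2 <- predator_assemblage("A", 2, p)
  expect_equal(popdyn_predict(asmP2, 300, 0.5), popdyn_predict(asm2, 300, 0.5),
               tolerance = 1e-9)
  # total depletion for long trials
  expect_gt(popdyn_predict(asm1, 50, 100), 50 - 1e-3)
})

test_that("popdyn_predict accommodates mixed response shapes", {
  p2 <- fr_params(2, 0.005)
  p3 <- fr_params(h = 0.005, response = "type3",
                  attack_fn = function(N) 2 * N / (N + 100))
  mixed <- predator_assemblage(c("A", "B"), c(1, 1), list(p2, p3))
  got <- popdyn_predict(mixed, 400, 1)
  expect_true(got > popdyn_predict(predator_assemblage("A", 1, p2), 400, 1))
  expect_lte(got, 400)
  # oracle: brute RK4 with the same mixed right-hand side
  f3 <- function(N) 2 * N / (N + 100) * N / (1 + 2 * N / (N + 100) * 0.005 * N)
  brute <- {
    N <- 400; dt <- 1 / 20000
    for (i in 1:20000) {
      f <- function(N) -(2 * N / (1 + 0.01 * N)) - f3(N)
      k1 <- f(N); k2 <- f(N + dt / 2 * k1); k3 <- f(N + dt / 2 * k2); k4 <- f(N + dt * k3)
      N <- max(0, N + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
    }
    400 - N
  }
  expect_equal(got, brute, tolerance = 1e-5)
})

test_that("popdyn_ci propagates CI width monotonically and degenerates cleanly", {
  fitA <- stub_fit(2, 0.005, ci_a = c(1.8, 2.2), ci_h = c(0.004, 0.006))
  # zero-width CIs -> interval collapses onto the point prediction
  fit0 <- stub_fit(2, 0.005, ci_a = c(2, 2), ci_h = c(0.005, 0.005))
  ci0 <- popdyn_ci(list(fit0, fit0), N0 = 400, t = 1, n_lhs = 50, seed = 1)
  # draws collapse onto the estimates; only integrator tolerance remains
  expect_equal(ci0$lower, ci0$point, tolerance = 1e-5)
  expect_equal(ci0$upper, ci0$point, tolerance = 1e-5)
  # seed-fixed determinism
  c1 <- popdyn_ci(list(fitA, fitA), N0 = 400, t = 1, n_lhs = 100, seed = 4)
  c2 <- popdyn_ci(list(fitA, fitA), N0 = 400, t = 1, n_lhs = 100, seed = 4)
  expect_identical(c(c1$lower, c1$upper), c(c2$lower, c2$upper))
  expect_true(c1$lower <= c1$point && c1$point <= c1$upper)
  # width grows monotonically as the CIs are inflated x{1, 2, 4}
  w <- vapply(c(1, 2, 4), function(k) {
    ci <- popdyn_ci(list(fitA, fitA), N0 = 400, t = 1, n_lhs = 100, seed = 4,
                    inflate = k)
    ci$upper - ci$lower
  }, 0)
  expect_true(w[1] < w[2] && w[2] < w[3])
})

test_that("all three null models agree when depletion is negligible", {
  p <- fr_params(2, 0.005)
  grid <- c(20, 100, 200)
  t <- 1e-3 # depletion << 1% of N0
  pA <- rogers_eaten(p, grid, t) / grid
  mult <- multiplicative_risk(grid, pA, pA)
  popdyn <- popdyn_predict(predator_assemblage(c("A", "A"), c(1, 1), list(p, p)),
                           grid, t)
  A <- det_trials(2, 0.005, grid, t)
  dfr <- suppressWarnings(direct_fr_predict(A, seed = 8, n_boot = 60))
  expect_true(all(abs(mult - popdyn) <= 1))
  expect_true(all(abs(dfr$curve$expected - popdyn) <= 1))
})
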