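---
title: "Null models for multiple predator effects: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Null models for multiple predator effects: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mpenull)
```

## The problem

An emergent multiple predator effect (MPE) is a deviation of combined-predator
prey mortality from what the predators' independent, single-predator effects
predict. Detecting one therefore requires a *null model*: a prediction of prey
eaten by the assemblage assuming independence. If the null model is biased,
real experiments misclassify independence as synergy or antagonism. This
package implements the three null models in use, a simulator that generates
trials in which independence holds by construction, and an experiment that
measures each model's bias against those simulations.

## Models and assumptions

**Functional response and depletion.** Each predator has a Holling type-II
response `f(N) = aN/(1 + ahN)` with attack rate `a` (arena·day⁻¹) and handling
time `h` (day·prey⁻¹). Feeding trials do not replace eaten prey, so the
per-prey risk falls during the trial; the expected catch of one predator over
time `t` is the solution of Rogers' random predator equation, the exact
integral of `dN/dt = −f(N)`.

**Multiplicative risk.** Combines per-prey eaten probabilities measured at the
same density: `N_AB = N0(P_A + P_B − P_A P_B)`. Exact only when risk is
constant in time — linear FR and no depletion.

**Direct FR.** Generates expected pair catches with the multiplicative risk
model from randomly paired single-predator replicates, rounds them to
integers, and refits Rogers' equation. It inherits the multiplicative risk
model's constant-risk assumption; the refit only smooths it. Its fitted
`(a, h)` describe no individual predator and have no mechanistic reading.

**Population-dynamic.** Integrates `dN/dt = −Σ fᵢ(N) Pᵢ` with each predator's
own parameters. Depletion and non-linearity are handled exactly; any mix of
response shapes is allowed (a type-III member can be supplied as an attack
rate that is a function of prey density, `fr_params(response = "type3")`).

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `a` | arena·day⁻¹ | 2 (sweep fixed value) | centre of the range reported in feeding-trial studies (sweep varies 1–8) |
| `h` | day·prey⁻¹ | 0.005 (sweep fixed value) | asymptotic rate 1/h = 200 prey/day; sweep varies 0.002–0.02 |
| trial duration | hours | 1, 6, 12, 24 | 24 h is the modal functional-response trial length; 1 h is the negligible-depletion regime |
| densities | prey·arena⁻¹ | 25 log-spaced integers, 1–800 | spans the rising and saturated parts of the FR at desk scale; a full integer grid is configurable |
| `sd_frac_a`, `sd_frac_h` | fraction | 0.10, 0.05 | typical relative parameter uncertainty in FR experiments |
| `n_replicates` | – | 10 | typical replicate count per density |
| `n_boot` | – | 2000 | bootstrap resamples for FR confidence bands |
| `n_lhs` | – | 1000 | Latin hypercube draws for prediction intervals (unstated in the source methodology; configurable) |

## What the simulator emulates — and what it does not

`simulate_stochastic()` integrates the depletion ODE with a fixed-step RK4
scheme and redraws every predator's `(a, h)` from truncated normal
distributions at each step, mimicking within-trial variability in capture and
handling. Trial outputs are integer eaten counts (rounded half away from
zero, clipped to `[0, N0]`).

Deliberate simplifications: no demographic stochasticity (prey are a
continuous state between steps), no behavioural prey responses, no predator
satiation state, and conspecific predators draw their per-step parameters
independently (the alternative — shared draws — changes replicate variance
slightly but not means). A green test against this simulator therefore
establishes correctness of the null-model machinery under the stated noise
world, not realism of that world.

Because per-step redraws average out over the trial, trajectory variance
depends on the redraw schedule. The schedule is explicit — `redraw_dt = t/100`
by default — and recorded in every dataset's metadata, so any dataset is
exactly regenerable from its config and seed.

## Numerical choices

- **Rogers' equation** is solved in closed form with the principal-branch
  Lambert W. The W argument `a h N0 · exp(a h N0 − a P t)` overflows double
  precision for strong responses at high density, so the package computes
  `W(e^z)` directly from `z` (Newton on `w + log w = z` for large `z`) instead
  of the damped fixed-point fallback one might use: the log-space solve
  removes the overflow entirely rather than working around it, and has no
  iteration-tolerance ambiguity.
- **ODE integration** uses an embedded Cash-Karp RK4(5) with rtol 1e-8 /
  atol 1e-10 and a hard floor at `N = 0` (depletion trajectories steepen near
  exhaustion); step-budget exhaustion is an error, never a silent clamp.
  Interval propagation (`popdyn_ci`) relaxes to rtol 1e-6 for speed; the
  residual integrator disagreement (~1e-5 relative) is below any quantity of
  interest.
- **Fitting** maximises the binomial likelihood of eaten counts with the
  depletion-corrected expected proportion, clipped to `[1e-9, 1 − 1e-9]`;
  optimisation is over `(log a, log h)` (positivity by construction, no
  boundary pathologies) with wide box bounds so degenerate data (all zeros)
  converge to an edge instead of crashing. The covariance comes from the
  inverse observed information; when singular, the bootstrap sample
  covariance (`bootstrap_band()$boot_params`) is the fallback.
- **Rounding** of expected counts is half-away-from-zero, documented because
  "nearest integer" is ambiguous at ties (R's `round()` is half-to-even).
- **Ties and degenerate inputs**: trials at a single density are rejected for
  fitting; bootstrap resamples that collapse to one density or fail to
  converge are dropped and counted, with >20% drops an error (the source
  protocol leaves non-convergence handling unstated; the 20% threshold is
  this package's policy).
- **LHS intervals** sample uniformly within each parameter's 95% CI,
  independently across parameters (covariance assumed zero when unknown);
  `method = "normal"` instead uses log-normal marginals correlated through
  the fit's log-scale covariance. Draws implying `a ≤ 0` or `h < 0` are
  truncated and counted.

## Open design points, as resolved here

- **MPE verdicts** compare intervals on *both* sides: the null model's 95%
  interval (LHS or bootstrap band) against a 95% interval for the observed
  replicate mean, widened by the half-prey resolution of integer counts.
  Comparing the observed mean alone against the null interval produces
  spurious MPE calls whenever parameter uncertainty is small relative to
  counting noise — with near-noiseless fits the null interval can be narrower
  than one prey.
- **Sweep predictions** feed the multiplicative risk model the unrounded
  deterministic single-predator expectations; rounding applies only where the
  binomial likelihood requires integers (the direct-FR pipeline). This keeps
  prediction curves smooth and changes nothing beyond ±0.5 prey.
- **Type-III estimation** is out of scope by design: the hook accepts any
  monotone non-negative attack-rate function of density, and the default
  experiments use type II throughout.

## Known limitations

Two documented expectations in the acceptance suite are intentionally red;
both quantify qualitative claims more tightly than the mathematics allows:

1. **Direct FR vs multiplicative risk within 2 prey everywhere.** The two
   curves are "nearly identical" only relative to their scale (hundreds of
   prey). The binomial-ML Rogers fit to multiplicative-risk expectations
   deviates by up to ~6 prey at high density for `a = 2, h = 0.005` — and no
   Rogers curve can do better than ~2.7 prey there (the Chebyshev-optimal fit
   was computed directly), so the 2-prey bound is unattainable by any fitting
   method. In the negligible-depletion regime (`h = 0`, small `a·t`) the two
   models agree within 1%, which the unit suite asserts.
2. **Sign balance of population-dynamic differences.** The multiplicative
   per-step noise induces a tiny Jensen-type asymmetry (the saturated rate
   `1/h` is convex in `h`), worth a mean difference of about −0.02 prey and a
   mean absolute difference of ~0.2 prey. A binomial sign test over all 3600
   sweep rows detects this reliably even though it is invisible at the scale
   of any figure and far below the ±2 prey magnitude bound, which passes.

Beyond these: predictions for assemblages rely on single-predator parameter
estimates, so systematic estimation bias (e.g. from wrongly assumed response
type) propagates; intraguild predation and other predator–predator
consumption is outside the depletion model; and the bias experiment's
"simulated truth" is itself the population-dynamic model plus noise, which is
what makes the population-dynamic null exact there by construction — the
experiment measures the *other* models' structural bias, not the
population-dynamic model's realism.
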