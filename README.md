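# mpenull

Null models for detecting **emergent multiple predator effects (MPEs)** in
feeding-trial experiments.

When two predators share a prey population, ecologists ask whether they act
independently or interact — interference or facilitation among predators makes
combined prey mortality lower (*risk reduction*) or higher (*risk
enhancement*) than expected. The test is always the same: predict prey eaten
by the pair from single-predator trials under an independence assumption, and
compare the prediction with observed multi-predator trials. `mpenull`
implements the three null models used for that prediction, a stochastic
predation-trial simulator, and a bias-quantification experiment that compares
the models against simulated trials where independence is true by
construction. It is aimed at experimentalists running functional-response and
multiple-predator feeding trials, and at methodologists studying the biases
of MPE null models.

## The models

A type-II functional response gives the per-capita feeding rate at prey
density *N*:

    f(N) = a N / (1 + a h N)

with attack rate *a* (arena·day⁻¹) and handling time *h* (day·prey⁻¹). Over a
trial of duration *t* without prey replacement, depletion makes the eaten
number *Nₑ* the solution of **Rogers' random predator equation**

    Nₑ = N₀ (1 − exp(−a (t − h Nₑ)))

which `mpenull` evaluates exactly via the Lambert W function (`rogers_eaten()`)
and fits to trial data by binomial maximum likelihood (`fit_rogers()`).

The three independence null models for a predator pair:

1. **Multiplicative risk** (`multiplicative_risk()`): with per-prey eaten
   probabilities *P_A*, *P_B* from single-predator trials,
   `N_AB = N₀ (P_A + P_B − P_A P_B)`.
2. **Direct FR** (`direct_fr_predict()`): pair single-predator replicates,
   generate expected pair catches with the multiplicative risk model, round to
   integers, refit Rogers' equation, and bootstrap a 95% band around the
   fitted curve.
3. **Population-dynamic** (`popdyn_predict()`, `popdyn_ci()`): integrate prey
   depletion `dN/dt = −Σᵢ fᵢ(N) Pᵢ` using each predator's own fitted
   parameters; 95% intervals by Latin hypercube sampling over the parameter
   CIs. This is the only model that accounts for depletion and non-linear
   feeding exactly, and the one this package's bias experiment (and the
   literature it follows) recommends.

`mpe_test()` runs the full workflow on real or simulated trial tables and
returns a per-density verdict: `independent`, `risk_reduction` or
`risk_enhancement`.

## Worked example

Two conspecific predators (a = 2, h = 0.005) over a 24-hour trial:

```r
library(mpenull)
p   <- fr_params(a = 2, h = 0.005)
asm <- predator_assemblage(c("A", "A"), c(1, 1), list(p, p))

# single-predator expectation at N0 = 800 over one day
rogers_eaten(p, N0 = 800, t = 1)
#> [1] 175.2707

# what the pair eats if truly independent (population-dynamic model)
popdyn_predict(asm, N0 = 800, t = 1)
#> [1] 343.8262

# multiplicative risk prediction from the same single-predator expectation
pr <- rogers_eaten(p, 800, 1) / 800
multiplicative_risk(800, pr, pr)
#> [1] 312.1416
```

The pair truly eats 343.8 prey, but the multiplicative risk model predicts
312.1 — an underestimate of ~32 prey, because each predator's measured
per-prey risk already includes the depletion it caused alone, and combining
risks multiplicatively cannot account for how two predators deplete prey
together. The sweep quantifies this bias across the whole parameter space:

```r
tab <- run_sweep(sweep_config(modes = "conspecific_h", durations_h = 24,
                              seed = 101))
summarize_extremes(tab, "mult_risk", duration_h = 24, N0 = 800)
#>        min        max
#> -70.597301  -3.055801
```

i.e. across handling times 0.002–0.02 the multiplicative risk model
under-predicts the simulated independent pair catch by 3 to 70 prey at the
highest density — so applied to real data it mistakes independence for
synergy. The population-dynamic model's differences on the same slice stay
within ±1.5 prey.

## Command line

```sh
inst/cli/mpe simulate --a 2 --h-time 0.005 --duration-hours 24 --seed 7 --out trials.csv
inst/cli/mpe fit --in trials.csv --out fit.csv
inst/cli/mpe mpe-test --single single.csv --multi pair.csv --P 2 --seed 1 --out verdicts.csv
inst/cli/mpe sweep --seed 1 --out bias_table.csv
```

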