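---
title: "Clutch size as multitasking: the season model and its closed forms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clutch size as multitasking: the season model and its closed forms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clutchsim)
set.seed(1)
```

## The model

A breeder lives through one season of `T` discrete time steps and does one
of two things per step: forage, gaining `f_f` energy units, or breed. A
clutch of `c` offspring costs `c * x` per step for `t_r` consecutive steps,
so breeding only starts once the reserve covers the whole attempt:
`E >= E_i + c*x*t_r` (ties breed). The step on which the threshold check
passes is already the first breeding step — a separate "decision step"
would shift every possible start time by one and break the renewal lattice
used by the closed forms below.

While breeding, the individual retains reduced foraging ability,
`f_b = f_f * (1 - c/c_max)`: a maximal clutch leaves no time to forage at
all. Each breeding step the nest faces a fresh environmental hazard `h`
drawn from `Beta(alpha, beta)` with `alpha = h_m/h_v`,
`beta = (1 - h_m)/h_v`; the nest is destroyed with probability exactly
`h`. Only convex, positively skewed shapes (`1 < alpha < beta`,
`h_m < 0.5`) are admitted — per-step failure is rare, but it compounds:
with `h = 0.10` and `t_r = 25`, only `(1 - 0.10)^25 ~ 7.2%` of attempts
fledge. An attempt that survives all `t_r` tests yields `c` fledglings; on
failure (or at step `T`, which truncates any open attempt) the individual
returns to the forage/breed decision. Season fitness is the summed
fledgling count.

Small clutches are therefore a *multitasking* strategy — frequent
switching between short breeding bouts and short recovery bouts — while
large clutches concentrate on fewer, longer, energetically deeper
attempts.

### Within-step order

Each breeding step proceeds: pay the care cost `c * x`; test the hazard;
if the nest survives, collect the breeding-time foraging income `f_b`.
Two consequences are deliberate:

* **The failing step's cost is sunk.** The closed-form start-time lattice
  (below) spaces restarts by `1 + c*x/f_f` per breeding step *including*
  the failing one, so the simulator must charge it too.
* **A destroyed nest yields no foraging income for that step.** This is
  the one point where the model is genuinely underdetermined by its verbal
  description, and the choice matters. If `f_b` accrued on the failing
  step as well, the long-season fledgling rate `c*q / E[cycle]` would be
  *exactly* flat in `c` at the default parameterization (the per-attempt
  cycle length collapses to `(1 + 1/c_max) * c * k` steps, cancelling `c`
  throughout), leaving the end-of-season waste as the only
  clutch-size-dependent term — large clutches could then never overtake
  small ones, however long the season. Denying the destroyed nest its last
  income breaks that degeneracy and produces the model's signature
  crossover: small clutches win short seasons, large clutches win long
  ones, by a margin of a few percent in rate.

### Parameters

| symbol | meaning | default | units |
|---|---|---|---|
| `T` | season length | 500 | steps |
| `E_i` | basic (and initial) reserve | 250 | energy |
| `c`, `c_max` | clutch size and its cap | 1, 10 | offspring |
| `f_f` | foraging efficiency | 1 | energy/step |
| `x` | care cost per offspring | 1 | energy/step |
| `t_r` | successful attempt duration | 24 | steps |
| `h_m`, `h_v` | hazard mean and inverse scale | 0.03, 0.01 | — |
| `n` | replicate seasons | 10,000 | — |

Defaults are the standard design used by every experiment; sweeps override
only the axes they vary. Two experiment settings are not fixed by the
standard designs and are package assumptions, recorded in preset metadata:
the alternative hazard-variance level (`h_v = 0.001`, a low-variance
contrast to the 0.01 default) and the "high predation" mean
(`h_m = 0.10`).

Clutch-size-dependent predation has no canonical functional form; the
package inflates each sampled hazard by `1 + gamma*(c - 1)/(c_max - 1)`
(clamped at 1). The form is monotone in `c`, has a single interpretable
knob, and nests the independent model exactly at `gamma = 0`, so the
null comparison never changes the sampling path.

## The excessive reserve

The time and energy at the end of the season that cannot contribute to
any completed attempt is the *excessive reserve*: the central cost of
large clutches in short seasons.

* **time** — `T` minus the end step of the last attempt that ran to
  completion (success *or* failure); steps of a final truncated attempt
  are pure waste; all of `T` if nothing completed. This is the quantity
  the closed forms below describe: their derivation weights the late
  start times by their completion probabilities, so a completed failure
  resets the clock just as a success does. A stricter variant measuring
  from the last *success* (every post-success failure also counts as
  waste) is available as
  `measure_excessive_reserve(trace, from = "last_success")`; it runs
  roughly `1/q` higher and is not what the closed forms approximate.
* **energy** — the terminal reserve above basic, `E_T - E_i`.

```{r}
p <- clutch_params(c = 10, n = 1)
r <- run_season(p, constant_hazard(0), keep_trace = TRUE)
r
measure_excessive_reserve(r$trace, p)
```

With the hazard switched off the season is a fixed schedule: forage 240
steps, breed steps 241–264, and waste the remaining 236 steps — too few to
stock another 10-offspring clutch.

## Closed forms

With `f_b` set aside, a failure after `k` breeding steps costs `k*c*x`
energy and `k*c*x/f_f` recovery steps, so attempts can only start on the
lattice `t_n = c*x*t_r/f_f + n*(1 + c*x/f_f)`. Three indices structure the
season's end: `n1`, the last possible start; `n2`, the last start that can
complete; `n3`, the last start that can fail and still restart by `n2`.
Up to floor rounding, `n2 - n3 = t_r` exactly and
`(n2 - n3)/(n1 - n2) = 1 + c*x/f_f`.

At the zeroth order the last completed start is uniform over a window of
width `t_r*(1 + c*x/f_f)`, giving

* mean waste `(t_r/2)(1 + c*x/f_f)` — linear in `c`,
* SD `(t_r/sqrt(12))(1 + c*x/f_f)`,
* a fitness-loss fraction `rho_max * t_r/(2T) * (1 + c*x/f_f)`, where
  `rho_max` (the maximum breeding success) has no canonical value and
  defaults to 1 so the loss reads as a fraction of the maximum.

Both moments are independent of `h`. The weighted refinement mixes the
never-completing late starts (waste `t_r/2` on average) with the
last-success window, with weight `w = 1/(1 + (1 + c*x/f_f) q)`,
`q = (1 - h)^t_r`; as `h -> 1` the mean drops to `t_r/2`.

```{r}
analytic_waste(clutch_params(c = 10, T = 10000,
                             forage_while_breeding = FALSE))
```

Two further refinements:

* **Stochastic hazard.** Under `h ~ Beta(alpha, beta)` the per-attempt
  success expectation is `E[(1 - h)^t_r]`, computed by the exact product
  `prod_j (beta + j)/(alpha + beta + j)` — above the plug-in
  `(1 - h_m)^t_r` by Jensen's inequality. A truncated-series diagnostic
  (`expected_survival_series()`) that treats `h_v` as a standard
  deviation (`<h^2> = h_m^2 + h_v^2`) is exposed for comparison, but that
  reading of `h_v` is inconsistent with the beta parameterization
  `alpha = h_m/h_v` (under which the variance is
  `h_m(1 - h_m) h_v/(1 + h_v)`), so the product form is canonical.
  Whether `h_v` "means" the scale or the SD is left as the two explicit
  functions rather than resolved by fiat. Note also that the expectation
  treats `h` as fixed within an attempt while the simulator redraws it
  every step (per-step expectation `(1 - h_m)^t_r`); the two bracket the
  simulated value and differ by under 8% at the defaults.
* **Foraging while breeding.** `apply_fb_substitution()` folds `f_b` back
  in as a net-flow correction: the per-offspring cost is rescaled so that
  `c*x'` equals the simulator's actual per-step outflow `c*x - f_b`.
  This matches recovery times by construction; a literal per-offspring
  rewrite `x - f_f(1 - c/c_max)` would overcount the income `c`-fold for
  `c > 1`. The substitution changes the lattice spacing but not the
  `t_r/T` scaling of the loss.

## Simulation versus closed form

```{r, eval = FALSE}
sp <- sweep_spec(clutch_params(T = 10000, forage_while_breeding = FALSE),
                 axes = list(c = 1:10), n = 1000, seed = 303)
compare_sim_analytic(sp)
```

At `T = 10,000` the simulated mean waste sits inside the zeroth-order
mean ± SD band for every clutch size and within a few steps of the
weighted/beta means; both series grow linearly in `c`.

## Randomness and reproducibility

A master seed spawns one L'Ecuyer-CMRG stream per replicate index
(`parallel::nextRNGStream`), so replicate `r` is reproducible in
isolation and summaries are independent of evaluation order; the caller's
RNG state is saved and restored around every replicate run. Sweep cells
derive their seeds from a deterministic hash of the cell's own parameter
values folded into the master seed, so reordering axis declarations (or
parallelizing cells) cannot change any number. Identical seeds produce
byte-identical CSVs.

## Scale choices

The full experiment designs use `n = 10,000` replicates per cell. The
test suite and the acceptance script run the same machinery at reduced
scale — `n = 2,000` for the fitness-reversal and variance-insensitivity
checks, `n = 1,000` per clutch size for the waste comparison — chosen so
that each assertion's Monte-Carlo error is at least threefold smaller
than the effect it tests. The distribution-level oracle check runs at
`T = 60`, `t_r = 5`, where the success-count distribution can be
enumerated exactly.

## What the simulator does and does not emulate

The model is deliberately minimal: fixed clutch size per individual (no
within-season adjustment), no mortality, aging, carryover between
seasons, upper bound on reserves, temporal autocorrelation or seasonal
trend in the hazard, and no predator dynamics — hazard draws are i.i.d.
across steps. Fitness comparisons are mean fecundity of fixed strategies;
there is no mutation/selection dynamics. Passing tests therefore
establish the internal logic of the energy-budget/renewal argument, not
its adequacy for any particular bird population: a step is a relative
unit, not a day, and mapping to field data requires rescaling `f_f`,
`t_r`, `T` and the hazard to the organism.
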