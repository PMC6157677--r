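# clutchsim

Why do birds lay fewer eggs where breeding seasons are long, and more
where they are short — and sometimes the reverse? `clutchsim` implements
a discrete-time, energy-budget, individual-based model of repeated
breeding attempts within a finite season, built for theoreticians and
quantitative ecologists studying clutch-size evolution under
environmental stochasticity.

A breeder alternates between foraging (gain `f_f` per step) and breeding
(pay `c·x` per step for `t_r` steps, foraging only at the reduced rate
`f_b = f_f(1 − c/c_max)`), and may start a clutch only once its reserve
covers the whole attempt: `E ≥ E_i + c·x·t_r`. Each breeding step the
nest survives an environmental hazard `h ~ Beta(h_m/h_v, (1 − h_m)/h_v)`;
surviving all `t_r` steps fledges `c` offspring. Laying small clutches is
a *multitasking* strategy — frequent switching between breeding and
recovery — whose payoff is wasting less time at the end of a short
season. That terminal waste (the **excessive reserve**) has a closed
form on the lattice of possible attempt start times
`t_n = c·x·t_r/f_f + n(1 + c·x/f_f)`:

- zeroth order: mean `(t_r/2)(1 + c·x/f_f)`, SD
  `(t_r/√12)(1 + c·x/f_f)` — linear in clutch size, independent of `h`;
- weighted: a mixture with weight `w = 1/(1 + (1 + c·x/f_f)(1 − h)^{t_r})`
  between `t_r/2` and the zeroth-order mean;
- beta-hazard correction via the exact product
  `E[(1 − h)^{t_r}] = Π_j (β + j)/(α + β + j)`;

with implied fitness loss `ρ_max · t_r/(2T) · (1 + c·x/f_f)`. The package
provides the simulator (compiled inner loop), these closed forms, a
replicate/sweep engine with season-length-standardized summaries, presets
for the standard experiment designs, and a simulation-versus-analytic
comparison harness.

## Worked example

```r
library(clutchsim)

# one hazard-free season of the large-clutch strategy
p <- clutch_params(c = 10, n = 1)
run_season(p, constant_hazard(0))
#> Season: 10 fledglings (1/1 attempts successful), wasted 236 steps
#> and 236.0 energy at season end
```

Foraging to the 490-unit threshold takes 240 steps, the single successful
attempt runs steps 241–264, and the remaining 236 steps cannot stock
another ten-offspring clutch — they are pure waste, almost half the
season.

```r
# short versus long seasons, small versus large clutches
sp  <- sweep_spec(clutch_params(),
                  axes = list(c = c(2, 10), T = c(500, 10000)),
                  n = 2000, seed = 101)
tab <- run_sweep(sp)
subset(tab, statistic == "fledglings")[, c("c", "T", "std_mean")]
#>     c     T  std_mean
#> 1   2   500 0.0225400
#> 8  10   500 0.0156100
#> 15  2 10000 0.0249167
#> 22 10 10000 0.0248570
```

Standardized fitness (fledglings per step): at `T = 500` the small clutch
out-produces the large one by ~44%, because the large-clutch strategy
wastes a 132-step-scale excessive reserve out of only 500 steps; at
`T = 10,000` that waste is unchanged but trivial relative to the season,
and the large clutch pulls even (within sampling error here; its
underlying rate advantage is a few tenths of a percent).

```r
# closed forms for the waste behind that reversal
analytic_waste(clutch_params(c = 10, T = 10000,
                             forage_while_breeding = FALSE))
#> Analytic end-of-season waste (c = 10, T = 10000, h = 0.03)
#>   start lattice: origin 240, spacing 11; n1/n2/n3 = 887/885/861
#>   zeroth order: 132 +/- 76.21 steps (loss fraction 0.0132)
#>   weighted (q = 0.4814): 112.9 +/- 64.1;  beta hazard: 114.1 +/- 64.84
```

`compare_sim_analytic()` runs both routes over a clutch-size grid: at
`T = 10,000` the simulated mean waste (e.g. 110.8 steps at `c = 10`,
18.6 at `c = 1`) lies inside the zeroth-order mean ± SD band for every
clutch size and tracks the beta-corrected mean within a few steps.

A thin CLI over the same functions lives at `inst/cli/clutchsim.R`
(subcommands `simulate`, `sweep`, `preset`, `analytic`, `compare`; every
CSV gets a JSON metadata sidecar).

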