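# openscr

Open-population spatial capture–recapture (SCR) models for multi-year
trap-array surveys of individually identifiable animals: a simulator, a
compiled Bayesian sampler, and a factorial simulation-study driver for
probing how the state-space definition and the between-year movement model
affect estimates of survival and density.

## The problem

Camera-trap and similar surveys detect marked individuals at known
locations over several years. Closed SCR models estimate density within one
season; open SCR models add the demographic dynamics between seasons —
survival, recruitment, and movement of home ranges. Survival estimated from
such data is *apparent* survival: an animal that shifts its activity center
off the trapping grid looks just like a dead one. How severely the two are
confounded depends on two analysis choices that are rarely examined:

* the **state space** `S` — how far beyond the traps activity centers are
  allowed to live (a buffered rectangle around the array), and
* the **movement model** — how activity centers change between primary
  periods: held constant, redrawn independently each year, or following a
  Gaussian random walk (Markovian) truncated to `S`.

`openscr` implements the full model stack for all three movement models so
that these sensitivities can be quantified by simulation, and real datasets
(trap deployment and detection-count tables) can be fitted with any
combination of buffer and movement specification.

## The model

For individual `i`, trap `j` with effort `K_jt` trap-days, primary period
`t`:

```
y_ijt | z_it ~ Binomial(K_jt, p(d_ijt) * z_it)      detection
p(d) = 1 - exp(-lambda0 * exp(-d^2 / (2 sigma_p^2)))
z_it ~ Bernoulli(phi^dt * z_i,t-1 + gamma_t * alpha_it)   survival/entrance
s_it ~ {constant | Uniform(S) | Normal(s_i,t-1, sigma_s^2 I) truncated to S}
```

Abundance is recovered by data augmentation (`M` potential individuals;
`N_t = sum_i z_it`; density `D_t = N_t / area(S)`). Fitting is by
Metropolis-within-Gibbs in compiled C++, with an exact joint update of each
individual's life history (all entry/death period pairs enumerated), exact
truncated-normal constants for the Markovian walk, conjugate Beta draws for
survival and entrance probabilities, and adaptive MH for the scale
parameters. A conditional-on-first-capture (Cormack–Jolly–Seber) variant
estimates survival without recruitment or augmentation. See the methods
vignette (`vignettes/open-scr-models.Rmd`) for the full account.

## A worked example

Simulate five years of data under the reference design (7 × 7 trap grid,
10 × 10 state space, 40 animals, survival 0.75) and refit it:

```r
library(openscr)

d <- simulate_scenario(sim_config(movement = "constant"), seed = 1)
d
#> <scr_dataset> 5 periods, 49 traps, 47 observed individuals (movement: constant, seed 1)

cfg <- fit_config("constant", S = d$S_gen, M = 150, n_periods = 5,
                  n_chains = 1, n_iter = 2000, n_burnin = 500, seed = 1)
fit <- fit_open_scr(d$detections, d$traps, cfg)
dplyr::filter(tidy(fit), parameter %in% c("phi", "lambda0", "sigma_p", "N_1", "D_1"))
#> # A tibble: 5 × 6
#>   parameter   mean     sd median conf.low conf.high
#>   <chr>      <dbl>  <dbl>  <dbl>    <dbl>     <dbl>
#> 1 phi        0.741 0.0466  0.743    0.642     0.829
#> 2 lambda0    0.423 0.0343  0.425    0.350     0.488
#> 3 sigma_p    0.534 0.0158  0.532    0.509     0.571
#> 4 N_1       41.4   5.34   41       32        52
#> 5 D_1        0.414 0.0534  0.41     0.32      0.52
```

The posterior means sit close to the generating values (`phi` 0.75,
`lambda0` 0.5, `sigma_p` 0.5, `N_1` 40, `D_1` 0.4): annual survival around
0.74, first-year abundance around 41 animals on the 100-unit² state space.
`tidy()`, `glance()` and `autoplot()` follow the usual broom/ggplot2
conventions; `gelman_rubin()` reports the potential scale reduction factor
for multi-chain runs.

The buffer-sensitivity experiment itself is one call:

```r
study <- run_factorial(sim_config(), n_reps = 20, seed = 42)
make_table(study)   # movement × buffer table of mean and rRMSE of phi
```

Under constant or Markovian activity centers, survival estimates barely
move as the analysis buffer changes; under independent activity centers
they slide from roughly 0.67 at a 3σ buffer to roughly 0.79 at 5σ, because
nothing constrains between-year movement and the model trades mortality
against emigration as `S` grows. `run_misspecification()` crosses a
generating movement model (including a jump-mixture walk) with a different
fitting model, and `fit_cjs()` gives the survival-only comparison.

A thin command-line wrapper (`inst/cli/openscr.R`) exposes `simulate`,
`fit`, `study` and `summarize` subcommands over the same functions, writing
CSV/JSON outputs plus a reproducibility manifest.

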