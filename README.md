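# nestcrw

Nested switching correlated random walk models for satellite telemetry and
transmitted dive summaries.

Satellite tags on marine predators produce two data streams at very
different rates: sparse, noisy Argos location fixes (a handful per day, with
kilometre-scale class-dependent error) and frequent on-board-summarized dive
records (depth, duration, shape). `nestcrw` is for movement ecologists who
want to infer *behavior* from both streams jointly without down-sampling
either: a top-layer hidden Markov chain switches horizontal movement between
**traveling** and **area-restricted search (ARS)** on a regular six-hour
grid, and a nested dive-level chain splits ARS into **foraging** and
**resting** from the dive-depth mixture.

## The model

Locations follow a switching correlated random walk on grid nodes
$Y_t \in \mathbb{R}^2$ (km):

$$Y_{t+1} \sim \mathcal N_2\!\big(Y_t + \gamma_{S'_t} R(\theta_{S'_t})
(Y_t - Y_{t-1}),\ \operatorname{diag}(\sigma_x^2, \sigma_y^2)\big),$$

with state-dependent step autocorrelation $\gamma$ and mean turning angle
$\theta$ ($R$ a rotation matrix), and
$\operatorname{logit} P(S'_t = \text{travel} \mid S'_{t-1}) =
\alpha'_{S'_{t-1}}$. An Argos fix at fraction $j$ of interval $t$ observes
$(1-j)Y_t + jY_{t+1}$ plus normal error with a fixed per-class standard
deviation. Dive depths are emitted from normal components truncated below
at the 10 m dive-definition depth: a single traveling component, or — inside
ARS — a foraging/resting mixture selected by a dive-level chain with
$\operatorname{logit} P(S''_u = \text{forage} \mid S'_t, S''_{u-1}) =
\alpha''_{S'_t, S''_{u-1}}$. Inference is Bayesian: forward
filtering–backward sampling for both discrete layers, adaptive Metropolis
for the latent locations, Metropolis-within-Gibbs (with a partially
collapsed update for $\alpha''$) for the parameters, and Gelman-Rubin
diagnostics across chains. See the methods vignette
(`vignettes/nested-movement-model.Rmd`) for priors, identifiability and
numerical choices.

The package also ships the standard Argos/dive preprocessing chain
(duplicate and speed filtering, track segmentation, the strict
10 m / 20 s dive definition, six-hour regularization with interval
fractions) and a generative simulator for both data streams, so the whole
pipeline is testable end to end without tag data.

## Worked example

Simulate a small two-animal deployment, push it through the text-file and
filtering pipeline, fit the model with two chains, and summarize behavior:

```r
library(nestcrw)

sim <- simulation_config(n_animals = 2, steps_per_animal = 60,
                         dives_per_interval_rate = 4, seed = 42)
write_dataset(simulate_dataset(sim), "data")

prep <- preprocess(read_fixes("data/fixes.csv"), read_dives("data/dives.csv"))
draws <- run_mcmc(prep$tracks,
                  mcmc_config(n_chains = 2, n_iter = 4000, n_burnin = 3000,
                              thin = 2, seed = 42))
max(rhat_table(draws)$rhat)
#> [1] 1.025054
```

Both chains agree (every Gelman-Rubin statistic is below the 1.1
convergence threshold). Decoding and summaries:

```r
dec <- decode(draws)
state_time_proportions(dec)$summary[, c("behavior", "mean_pct", "sd_pct")]
#>    behavior mean_pct   sd_pct
#> 1 traveling 48.57127 49.06708
#> 2  foraging 39.18870 34.57422
#> 3   resting 12.24004 14.49287
```

Per individual, 49% of dive observations fall in traveling, 39% in foraging
and 12% in resting (the large standard deviations reflect only two animals
with very different behavioral mixes).

```r
depth_distribution_summary(dec, draws)[, c("behavior", "mu_mean", "mu_lower",
                                           "mu_upper", "q25", "q75", "n_dives")]
#>    behavior   mu_mean   mu_lower  mu_upper       q25       q75 n_dives
#> 1 traveling   7.91170   2.567755  11.66134  11.98383  17.04066     238
#> 2  foraging 192.77861 182.959912 202.28764 149.50432 229.33043     170
#> 3   resting  20.47518   5.233473  25.86871  19.92946  30.31667      52
```

The foraging depth parameter is estimated at 192.8 m (95% CI 183.0–202.3);
the quartile columns are the empirical quartiles of the dives decoded into
each behavior. Note the location parameter of a truncated component is
smaller than the mean depth it implies (traveling: $\mu \approx 7.9$ m, but
dives concentrate at 12–17 m above the 10 m truncation).

```r
deep_dive_count(dec, 300)
#> $total
#> [1] 9
#> $by_behavior
#> traveling  foraging   resting
#>         0         9         0
```

All nine dives deeper than 300 m are decoded as foraging.

A YAML-driven pipeline (`cmd_simulate()`, `cmd_fit()`, `cmd_report()`, thin
CLI wrapper in `inst/cli/nestcrw`) orchestrates the same steps with
structured logging; the shipped profile `wap2016` carries the reference
settings (20 km/h speed filter, 12 h gap, 24 h minimum span, 10 m / 20 s
dive definition, 6 h interval, 2 × 30,000-iteration chains with 28,000
burn-in thinned by 4).

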