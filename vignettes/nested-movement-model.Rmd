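---
title: "A nested switching correlated random walk for telemetry and dive data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A nested switching correlated random walk for telemetry and dive data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestcrw)
```

## The model

`nestcrw` fits a two-layer hidden-state movement model to two data streams a
satellite tag produces at very different rates: sparse, noisy Argos location
fixes and frequent on-board-summarized dive records. The model's premise is
that a marine predator alternates between *traveling* and *area-restricted
search* (ARS) at the scale of hours-to-days, and that within ARS the animal
further alternates, dive by dive, between *foraging* and *resting*.

**Movement layer.** Time is discretized into six-hour intervals indexed
$t$; the latent planar location at grid node $t$ is $Y_t$ (km). Movement is
a switching correlated random walk:

$$Y_{t+1} \sim \mathcal N_2(d_t, \operatorname{diag}(\sigma_x^2,
\sigma_y^2)), \qquad
d_t = Y_t + \gamma_{S'_t}\, R(\theta_{S'_t})\,(Y_t - Y_{t-1}),$$

where $R(\theta)$ is the rotation matrix, $\gamma_s \in [0,1]$ the step
autocorrelation and $\theta_s$ the mean turning angle of the active state
$S'_t \in \{\text{travel}, \text{ARS}\}$. Traveling is persistent and
directed (large $\gamma$, $\theta \approx 0$); ARS is diffuse with large
turning angles. The state follows a first-order chain,
$\operatorname{logit} P(S'_t = \text{travel} \mid S'_{t-1}) =
\alpha'_{S'_{t-1}}$; the first interval's state is uniform. The process
standard deviation is shared across states (one $\sigma$ per planar
coordinate), following the single-$\sigma$ structure of the movement layer.

**Observation layer.** An Argos fix inside interval $t$, at fraction $j \in
[0,1]$ of the interval, observes the straight-line interpolation
$(1-j)Y_t + jY_{t+1}$ plus isotropic normal error whose standard deviation
is fixed per Argos quality class (3, 2, 1, 0, A, B). The shipped class table
follows the magnitudes reported in the Argos calibration literature (Jonsen
et al. 2005) and is configuration, not code.

**Dive layer.** Each transmitted dive record carries a maximum depth. Inside
ARS intervals, dives are emitted from a two-component truncated-normal
mixture selected by a dive-level chain $S''_u \in \{\text{forage},
\text{rest}\}$ with $\operatorname{logit} P(S''_u = \text{forage} \mid
S''_{u-1}) = \alpha''_{S'_t, S''_{u-1}}$ — the transition row is indexed by
the *current top state*, so the sub-chain keeps evolving through traveling
intervals (using the traveling row) even though traveling dives are emitted
from their own single component, ignoring $S''$. The first dive of a track
draws its sub-state uniformly. All depth emissions are normal distributions
truncated below at the 10 m dive-definition depth and renormalized: a
transmitted record only exists for submergence past that threshold, so
untruncated emissions would put mass on impossible depths. An untruncated
mode (`truncated = FALSE` in `dive_loglik()`) exists for sensitivity
checks.

For a two-state Bernoulli transition law there is exactly one free logit per
conditioning state, so $\alpha'$ is stored as a length-2 vector (indexed by
the previous state) and $\alpha''$ as a 2×2 matrix (current top state ×
previous sub-state).

## Priors and identifiability

Mean-depth priors are uniform on bounded supports: traveling and resting on
$[0, 30]$ m, foraging on $[50, 250]$ m (bounds inclusive). Depth and process
standard deviations get weakly-informative half-normal priors (scales 100 m
and 10 km); transition logits get $\mathcal N(0, 2)$; turning angles are
uniform on the circle; $(\gamma_\text{travel}, \gamma_\text{ARS})$ are
uniform on $[0,1]^2$ restricted to the ordering $\gamma_\text{travel} >
\gamma_\text{ARS}$.

Two devices pin the state labels: the depth bounds separate foraging from
the two shallow behaviors, and the $\gamma$ ordering makes "traveling" the
more persistent movement state. They do not, and cannot, separate traveling
from resting *by depth alone*: both are shallow. That separation must come
from movement. A consequence we verified empirically on synthetic data: if
the traveling and resting depth components are made nearly identical while
location noise dominates the movement signal, the posterior's dominant mode
merges both top states into a single ARS state whose internal forage/rest
mixture explains every dive — the top layer is then simply not identified,
and no sampler can recover a truth the data do not carry. This is a known
boundary of the model class, inherited by any analysis of real tracks whose
movement signal is weak relative to Argos error.

## The synthetic-data generator

`simulate_dataset()` draws from exactly the generative model above, then
degrades it the way a deployment would: Poisson numbers of fixes and dives
per interval, uniform within-interval timing, class-specific location noise
with a realistic class mix dominated by the poor classes (A, B), and whole
intervals silenced with probability 0.1. Defaults emulate a multi-animal
austral-season deployment: 11 animals, 107 six-hour intervals (~27 days)
each, about 8 fixes and 22 dives per interval before filtering.

The default generative truth is a *well-separated* regime chosen once, with
the separation argued biologically: traveling at $\gamma = 0.9$,
$\theta = 0$ versus ARS at $\gamma = 0.25$, $\theta = 2.5$ rad; a 5 km
process scale, so traveling covers 20–30 km per interval (a 3–5 km/h
transit, the right magnitude for a migrating rorqual) while ARS mills at
roughly a third of that; shallow, tight transit dives (12 ± 5 m — traveling
animals avoid deep excursions), resting dives at 25.1 ± 10 m and foraging
dives at 194.3 ± 60 m, the scales reported for humpback foraging off the
West Antarctic Peninsula. Dive durations and shape codes are lognormal and
uniform stubs so files are schema-complete; the model ignores both.

What the generator does *not* emulate: t-distributed Argos outliers, tag
duty-cycling, on-board 1-Hz pressure traces (summaries are generated
directly), land, and behavior-dependent fix/dive rates. Passing tests on
synthetic data therefore demonstrate correctness of the machinery under the
model's own assumptions, not robustness to every field pathology.

## Preprocessing

The filtering chain reproduces the standard conservative track hygiene, in
this order: drop records without coordinates, unparseable rows and
duplicate timestamps (first kept); optional user-supplied exclusion windows
(e.g. manually identified northward-migration episodes — identification is
deliberately *not* automated, since any detector would silently change
results); a 20 km/h speed filter that drops the later member of each
violating pair and re-checks (a deterministic forward pass); segmentation at
gaps over 12 h with segments spanning under 24 h discarded; and the dive
definition, strictly deeper than 10 m *and* strictly longer than 20 s.
Geographic input is projected once to planar km by an azimuthal equidistant
projection centered on the data centroid; synthetic data are already planar.

Regularization anchors a grid of exact six-hour intervals at each track's
first fix. Intervals are half-open $[\text{start}, \text{start} + 6\,h)$,
except that a fix at the final grid endpoint closes the last interval with
$j = 1$, so every instant maps to exactly one interval. Because the grid is
anchored at the first fix, a fitted grid is generally offset from the
generator's grid; dives near interval boundaries can then be judged under
the neighboring interval's state. At the scales used here this contributes
a small downward bias to the resting depth location (a few meters at most)
that the credible intervals absorb.

## Posterior computation

The sampler is Metropolis-within-Gibbs with three blocks per iteration.

1. **Discrete states by FFBS.** The top-layer path of each track and the
   sub-state path over each track's full dive sequence are drawn from their
   exact full conditionals by forward filtering–backward sampling. The
   forward recursions run in compiled code; correctness is pinned by an
   exact-enumeration oracle (all $2^T \times 2^D$ paths on toy problems).
2. **Locations by per-node Metropolis.** Each grid node's full conditional
   involves only terms within two nodes, so nodes are updated in three
   interleaved batches (every third node) with exact, independent
   accept/reject decisions. Per-node proposal scales adapt toward 20–50%
   acceptance during burn-in only; the retained chain is Markovian.
3. **Parameters.** Random-walk Metropolis for $\gamma$ (respecting the
   ordering), $\theta$ (wrapped onto the circle), and log-scale walks with
   Jacobians for all standard deviations; the top-layer logits use the
   chains' sufficient transition counts. The sub-chain logits $\alpha''$ are
   updated against the *marginal* likelihood with the dive sub-states
   integrated out by the forward algorithm (a partially collapsed update,
   run last in the block so FFBS redraws the sub-states before anything
   conditions on them again), using a mixture of an adapted random walk and
   prior-independence proposals. The collapsed update matters: conditioned
   on sub-state draws, the traveling row of $\alpha''$ — whose chain has no
   emissions of its own — mixes extremely slowly, while marginally its
   posterior is close to the prior and mixes in a few steps.

Initialization is deterministic: locations at time-interpolated fixes; top
states set to ARS wherever an interval holds a ≥ 100 m dive (an unambiguous
foraging signature) and by a step-length threshold elsewhere; sub-states by
a 50 m split; parameters at fixed in-support values with the two shallow
depth components started apart (traveling 10 m, resting 25 m). The
asymmetric start matters: from a symmetric start the first sweeps can attach
both shallow components to the same depth cluster and lock a relabeled
mode.

Chain protocol defaults mirror the reference analysis: 2 chains × 30,000
iterations, 28,000 burn-in, thinning by 4 (500 retained draws per chain).
Per-chain seeds derive from the master seed as $\text{seed} + 10007(c-1)$,
so adding chains never reshuffles earlier ones. Convergence is judged by
the classic Gelman-Rubin potential scale reduction factor with the 1.1
threshold; constant chains are flagged degenerate rather than returned as
NaN.

## Decoding and summaries

`decode()` pools retained draws: an interval is labeled traveling only when
its posterior traveling probability strictly exceeds 0.5 (a tie goes to
ARS); each dive's three-way behavior is the plurality label across draws,
ties broken in the fixed order traveling, foraging, resting. "Percent time
per behavior" is computed over dive observations — the only layer where all
three behaviors exist — per individual, then averaged across individuals
with a sample standard deviation reported on both the percent and the
proportion scale. Depth summaries report the posterior mean and 95%
credible interval of each component's location parameter together with
type-7 empirical quartiles and the maximum of the decoded dives — note the
printed "mean depth" of a truncated component is larger than its location
parameter, a distinction that matters when comparing to published tables.
Seasonal and diel profiles bin dives by UTC calendar month or UTC hour (no
local-time conversion is attempted) with uncertainty bands spanning the
per-draw frequencies of 50 evenly spaced posterior draws of the labels.

## Numerical choices and problem sizes

All filters run in log space; two-state log-sum-exp uses the stable
`max + log1p(exp(-|diff|))` form; truncated-normal sampling uses the
inverse CDF. The exactness tolerances are 1e-10 (relative) against
enumeration oracles and three Monte-Carlo standard errors for sampling
checks. The packaged experiments are sized for a desk machine: the
convergence and decoding study uses 2 animals × 100 intervals (~800 dives)
with 2 × 10,000 iterations; parameter recovery uses five seeded replicates
of the same data scale with single 4,000-iteration chains, pooling coverage
over replicates × parameters; the enumeration oracles use $T \le 6$
intervals. These sizes are the package's own scaled defaults for its test
suite; the full protocol (30,000 iterations, 20 replicates) is available by
changing the configuration.

## Known limitations

* The top layer is identified by movement contrast; datasets whose location
  noise swamps the movement signal collapse traveling into ARS (see
  *Priors and identifiability*). Real deployments with mostly class-B fixes
  and slow animals sit near this boundary.
* Argos errors are normal, not heavy-tailed; the speed filter is the only
  outlier defense.
* Transition probabilities carry no covariates, and the model has exactly
  2 + 2 states.
* The regularization grid is anchored per track, so model intervals are not
  aligned across animals; monthly/hourly summaries operate on dive
  timestamps and are unaffected.
* Dive duration and shape are transmitted but deliberately unused, matching
  the depth-only emission model.
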