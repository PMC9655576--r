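---
title: "Modelling trophallactic food-exchange networks in ant colonies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling trophallactic food-exchange networks in ant colonies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trophsim)
```

## The model

`trophsim` simulates how food collected by a few foragers spreads through
an ant colony by mouth-to-mouth (trophallactic) exchange. The colony is a
set of agents, each carrying a crop load $Q_i \ge 0$ (food units). Every
agent starts in the nest as a non-forager (NF) with an empty crop; the
food source outside the nest is unlimited. Time advances in one-second
steps over one hour (3600 steps) for a colony of 53 workers by default.

Three per-second probabilities are modulated by the current crop load
through Hill functions with half-saturation $k$ (food units) and
steepness $n$:

* giving: $\theta_i(Q) = \theta_i(0)\, Q^n/(k^n + Q^n)$ — an ant gives
  only when it carries food;
* receiving: $\gamma_i(Q) = \gamma_i(0)\, k^n/(k^n + Q^n)$ — a loaded
  crop suppresses further intake;
* leaving the nest: $\alpha_i(Q) = \alpha_i(0)\, k^n/(k^n + Q^n)$ —
  hungry ants are the ones that forage.

We keep the canonical values $n = 2$ and $k = 120$ food units; $k$ is on
the order of the mean amount exchanged in a single observed trophallactic
event. Both remain configurable, and $k$ is global (a single threshold
for the whole colony).

Within one timestep the colony is updated in four phases: (1) ongoing
exchange pairs either separate (probability $\Phi$ per second, so event
durations are geometric with mean $1/\Phi$) or transfer another
`transfer_rate` units from donor to receiver — a pair also stops
immediately when the donor empties; (2) every unpaired nest ant, visited
in fresh random order, may leave for the source with probability
$\alpha_i(Q_i)$; (3) ants at the source ingest `intake_rate` units per
second and start back with probability $\beta$; (4) every unpaired nest
ant, again in random order, encounters one uniformly random unpaired
nestmate, and a donor–receiver pair forms with probability
$\theta_i(Q_i)\,\gamma_j(Q_j)$. The first transfer happens at formation,
so an event lasting $m$ seconds moves $m \cdot$ `transfer_rate` units
unless the donor runs dry. Food is conserved exactly: at every step the
summed crop contents equal the total withdrawn from the source, which the
test suite asserts step by step.

Encounters are initiated in both roles: each ant first tries to act as a
donor towards its drawn partner and, if that fails, as a receiver from an
independently drawn partner (`dual_initiation = TRUE`). This follows the
model description in which every individual in the nest can engage in an
exchange either as a donor (probability $\theta_i$) or as a receiver
(probability $\gamma_i$). The single-attempt variant remains available
(`dual_initiation = FALSE`); under it the encounter rate is roughly
halved and the reference event counts are unreachable with the reference
giving/receiving means.

An ant's first visit to the source permanently promotes it to forager
(F). Under the one-caste regime (OC) promotion changes nothing but the
nest-leaving maximum ($\alpha'_i(0) > \alpha_i(0)$, here a configurable
multiplier, default 1.5). Under the two-emergent-caste regime (TEC) the
giving and receiving maxima are additionally redrawn from the forager
distributions, independent of the ant's non-forager values — the test
suite checks that pre- and post-promotion values are uncorrelated. Note
that the reference calibration puts the forager receiving mean well above
the non-forager one; only the giving means are required to satisfy
$\bar\theta_F > \bar\theta_{NF}$.

## Interindividual variability

Giving and receiving maxima are drawn once per ant from one of three
distributions sharing a population mean $\varepsilon$: a point mass
(delta), $U(0, 2\varepsilon)$ (uniform), or an exponential law with mean
$\varepsilon$ (the right-skewed case). Draws above 1 are redrawn rather
than clipped, so no probability mass accumulates at 1. Two readings of
the printed distributions deserve a note. First, the exponential density
is parameterised by its mean (pdf $\varepsilon^{-1} e^{-x/\varepsilon}$):
the per-caste reference values (e.g. $1/9$) are then population means on
the probability scale, commensurate with the delta case. Second, a
nonnegative uniform cannot have a standard deviation equal to its mean
(the maximum is $\varepsilon/\sqrt 3$ on $[0, 2\varepsilon]$); we use the
maximal-spread nonnegative uniform with the correct mean.

The nest-leaving maxima $\alpha_i(0)$ follow a bounded power law
(Pareto) — a few ants leave readily, most almost never — sampled by
inverse transform on $[\alpha_{\min}, \alpha_{\max}]$. The survival curve
of first arrivals at the source in the reference experiments is well
described by such a law; its exponent and bounds are not printed, so they
are calibration targets here (below).

## Calibration

The rate parameters that a reader cannot take from the reference tables
($\beta$, $\Phi$, the intake and transfer rates, and the
$\alpha$-distribution parameters) were fitted once, by grid refinement,
so that the two-emergent-caste exponential model with the reference
giving/receiving means reproduces the reference foraging statistics of a
53-worker, one-hour colony: about 99 trophallactic events, about 12.5
foragers, and roughly 40% of the donated food volume given by
non-foragers. The fitted defaults are

| parameter | value | meaning |
|---|---|---|
| exponent | 1.8 | power-law tail of $\alpha_i(0)$ |
| bounds | $[2\times10^{-5}, 0.3]$ | support of $\alpha_i(0)$, per second |
| forager multiplier | 1.5 | $\alpha'_i(0)/\alpha_i(0)$ after first visit |
| $\beta$ | 1/15 | leave the source; mean feeding bout 15 s |
| $\Phi$ | 0.06 | pair separation; mean event duration about 17 s |
| intake rate | 25 units/s | feeding at the source |
| transfer rate | 27 units/s | flow within an exchange |

Two calibration findings are worth recording as design choices. The mean
amount moved per event implied by these defaults
(`transfer_rate / phi` $\approx 450$ units when the donor does not run
dry) is several times $k$: holding the per-event amount at $k = 120$
makes it impossible to reach the observed non-forager donation share,
because non-foragers then never accumulate enough crop to become donors
themselves. And the heavier-than-expected tail (exponent 1.8 rather than
2) concentrates enough first departures early in the hour for the event
count to ramp up as observed.

With one shared rate set across all six model variants (OC/TEC × three
distributions), the reference per-variant giving/receiving means
reproduce the TEC-exponential reference statistics to within about 1%,
while the delta variants land about 10% low (OC) and 10% high (TEC) on
the event count. Trait heterogeneity is self-limiting in these dynamics
(strong givers drain their own crops; strong receivers saturate), and
that penalty evidently differs from the implementation the reference
means were fitted to. We report the delta-variant misfit rather than
tuning per-variant rates, which would amount to refitting the reference
means.

`calibrate()` exposes the same machinery for the giving/receiving means
themselves: a coordinate grid search over per-caste means, scoring each
candidate with a fixed-seed replicate ensemble against target event,
forager and pair-type counts (weighted L1; the pair-type part is the
discrepancy $D$, the summed absolute difference over the four
donor–receiver caste combinations). Reusing the same seeds across
candidates makes the loss surface smooth; the parameter-recovery test
regenerates targets from known means, displaces the start by +40%, and
requires recovery of the giving means within 25%.

## Observation model and synthetic experiments

Real colonies are observed by scan sampling: once per minute every
ongoing mandible-to-mandible contact longer than 5 s is noted with donor
and receiver identity, and the same ordered pair seen on consecutive
scans is merged into one observed event whose duration is the number of
scans. `scan_sample()` applies exactly this protocol to simulated logs
("longer than 5 s" read strictly; scans at $t = 60, 120, \dots$, never at
$t = 0$; reversed roles never merge, since flow cannot reverse within an
event). `generate_synthetic_experiment()` packages several simulated
colonies through this observation model into the two CSV tables a field
study would produce (per-minute event records and a worker table whose
forager flag uses the five-consecutive-seconds-feeding rule). These
fixtures emulate the *format* and the headline statistics of real
recordings; they do not reproduce any particular empirical dataset, and
passing the pipeline on them shows the machinery is sound, not that the
model fits real ants.

Raw and observed counts live on different scales: a simulated hour
yields about 99 raw events, of which scan sampling sees only the
fraction straddling a minute boundary (roughly a quarter at the default
event duration). Reference event counts are treated as raw simulated
counts throughout — the convention under which the reference ensemble
means are reproduced — while both pathways remain available, and the
command-line `compare` subcommand scan-samples the simulated replicates
so that ensembles and experiment-format tables meet on the observation
scale.

## Network and inequality metrics

The event log defines a weighted directed network (edge weight = number
of events donor→receiver; inactive ants remain as isolates). Distances
are unweighted hop counts. Global efficiency — the mean inverse
shortest-path distance over ordered pairs, with disconnected pairs
contributing zero — and local clustering are computed on the undirected
projection; betweenness uses directed paths; closeness uses the
component-normalised form ($r/(n-1) \cdot r/\sum d$ over the $r$
reachable nodes), zero for isolates. Each choice is switchable by flag,
since the reference analysis does not state directedness per metric.
All shortest-path metrics are verified in the tests against brute-force
Floyd–Warshall and exhaustive path-enumeration oracles on every random
graph up to seven nodes.

Inequality of participation is summarised by the Lorenz curve of per-ant
event counts (ascending cumulative shares) and its Gini coefficient via
the trapezoid rule, without small-sample correction: 0 for perfect
equality, $1 - 1/N$ when a single ant does everything. `t50()` reports
the earliest time by which half of all events have started — the
food-flow half-time.

Ensembles are compared with (synthetic) experimental colonies using a
two-sample Kolmogorov–Smirnov test on activity distributions, pairwise
Mann–Whitney tests on pair-type counts, and a resampling Z-test that
mirrors the small-n experimental design: 200 groups of 5 distinct
replicates are drawn from the ensemble, and the experimental mean is
referred to the spread of the 200 group means. Significance is reported
at 0.05 and never gates any pipeline step. On matched synthetic null
ensembles $|Z| < 2$ in about 95% of seeds, which the acceptance tests
check by Monte Carlo.

## Numerical and degenerate-input choices

Randomness flows through R's generator only (including inside the
compiled stepping core), so a `(config, seed)` pair replays
bit-identically; ensemble replicate $i$ uses `base_seed + i`. With
integer-valued intake and transfer rates all crop arithmetic is exact in
double precision, and the per-step conservation check in the core keeps
the maximum deviation, which tests require to be numerically zero. An
all-zero activity vector has no Lorenz curve (error), an empty event log
has no T50 (error), efficiency needs at least two nodes (error), and a
degenerate ensemble (zero spread of resampled means) makes the Z-test
refuse rather than divide by zero. Ties in the Mann–Whitney test fall
back to the normal approximation; two identical constant samples report
$p = 1$.

## Problem sizes

The packaged tests exercise full-size colonies (53 ants, 3600 steps) in
ensembles of 200 replicates — enough for a standard error of about two
events on the mean count — and the acceptance script uses the same
ensemble size; the reference protocol's 1000 replicates change the means
by less than their standard errors. Unit and property tests run on
colonies of 12–30 ants and logs of a few hundred steps.

## Known limitations

No space: the nest is a single well-mixed compartment, so spatial
heterogeneity of encounters, queen/brood demand, and food consumption are
all absent. Exchange within an event is strictly one-directional.
Delta-variant event counts carry the ~10% structural misfit discussed
under calibration. The synthetic experiment generator
shares the simulator's assumptions, so model-vs-fixture comparisons
cannot detect model misspecification — they validate plumbing and
statistics, not biology.
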