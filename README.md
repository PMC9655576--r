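# trophsim

Agent-based simulation of trophallactic food-exchange networks in ant
colonies, with the full analysis stack used to confront such models with
scan-sampled behavioural observations.

## The problem

In many ant species only a small set of workers (the *foragers*) ever
visits a food source; everyone else depends on mouth-to-mouth food
transfer (*trophallaxis*) inside the nest. The resulting exchanges form
a weighted directed network whose structure controls how fast food
percolates through the colony. `trophsim` implements a parsimonious
individual-based model of this process for *Lasius niger*-like
colonies and asks which ingredients — a behavioural caste switch after
the first source visit, and right-skewed interindividual variability in
the propensity to give and receive — are needed to reproduce observed
colony-level statistics.

Each ant carries a crop load $Q$ and acts with crop-dependent
per-second probabilities (Hill functions with threshold $k = 120$ food
units and steepness $n = 2$):

$$\theta(Q) = \theta(0)\frac{Q^n}{k^n+Q^n},\qquad
  \gamma(Q) = \gamma(0)\frac{k^n}{k^n+Q^n},\qquad
  \alpha(Q) = \alpha(0)\frac{k^n}{k^n+Q^n}$$

for giving, receiving, and leaving the nest. A donor–receiver pair
forms between randomly encountering nest ants with probability
$\theta_i(Q_i)\,\gamma_j(Q_j)$, transfers food at a constant rate and
separates with probability $\Phi$ per second (or when the donor
empties). Two caste regimes (one-caste OC vs two-emergent-caste TEC,
where traits are redrawn on the first source visit) and three trait
distributions (delta, uniform, exponential) span six model variants.
Nest-leaving maxima follow a bounded power law — a few eager foragers,
many homebodies.

The package also provides:

* an observation model (`scan_sample()`): minute-resolution scan
  sampling with a strict 5-second threshold and merging of
  consecutive-scan observations, plus a generator of synthetic
  experiment tables in the field format (`generate_synthetic_experiment()`);
* network metrics on the event log (`global_efficiency()`,
  `node_centralities()`), inequality of participation (`lorenz_gini()`),
  food-flow dynamics (`t50()`, `activity_distributions()`);
* ensemble summaries, grid-search calibration of giving/receiving means
  (`calibrate()`), and the comparison protocols (`ks_compare()`,
  `mw_compare()`, resampling `z_compare()`).

## A worked example

```r
library(trophsim)

cfg <- preset_config("TEC", "exponential")   # 53 ants, 3600 s, reference means
res <- run_simulation(cfg, seed = 1)
res
#> <troph_sim> TEC colony of 53 ants, 3600 timesteps (seed 1)
#>   118 trophallactic events, 18 foragers, 13575 food units withdrawn

glance(res)[, c("n_events", "n_foragers", "nf_donation_share", "gini", "t50", "efficiency")]
#> # A tibble: 1 × 6
#>   n_events n_foragers nf_donation_share  gini   t50 efficiency
#>      <int>      <int>             <dbl> <dbl> <int>      <dbl>
#> 1      118         18             0.400 0.487  2523      0.358
```

One hour of colony life produced 118 exchange events; 18 of the 53
workers became foragers; non-foragers donated 40% of the transferred
volume in this particular run; activity was strongly unequal
(Gini 0.49); half of all events had started by t = 2523 s; and the
exchange network reaches a global efficiency of 0.36.

Ensembles average away single-run noise:

```r
ens <- run_ensemble(cfg, n_reps = 200, base_seed = 0)
glance(ens)[, c("mean_events", "mean_foragers", "mean_nf_donation_share")]
#> # A tibble: 1 × 3
#>   mean_events mean_foragers mean_nf_donation_share
#>         <dbl>         <dbl>                  <dbl>
#> 1        99.8          12.4                  0.423
```

— about 99 events and 12½ foragers per simulated hour, with roughly 40%
of the donated volume given by non-foragers, matching the reference
statistics the rate defaults were calibrated to (see the vignette).
`plot_lorenz()`, `plot_cumulative_events()`,
`plot_activity_distributions()` and `autoplot()` visualise the results;
`exec/trophsim` wraps the same functions as a command-line tool
(`trophsim ensemble --reps 200 --seed 0 --out-dir runs/`).

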