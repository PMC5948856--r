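# pestgrid

An agent-based simulator of pest infestation and sensor-coordinated pesticide
control on a lattice crop field, with a pluggable communication-strategy
framework and a replicate-experiment harness for comparing strategies
statistically.

## The problem

Precision-agriculture fields are monitored by a wireless sensor network
(WSN): one station per zone, each able to detect alive bugs in its zone and
to trigger fumigation there. Stations coordinate by exchanging warning
messages, and every message costs electric power — a scarce resource for
battery-driven stations. The engineering question is how much communication
is actually needed to keep the crop healthy: a protocol that warns everyone
on every detection defends the crop but wastes power and pesticide, while a
protocol that warns selectively may do just as well for a fraction of the
cost. `pestgrid` lets protocol designers quantify that trade-off in
simulation before deploying anything.

## The model

Time advances in hours over an `M × N` grid of zones (defaults `10 × 16`,
48 h). Each hour:

- With probability `p_a` (default 0.10/h), `r_b ~ U{0, …, M_b}` new bugs
  appear at uniformly random zones (`M_b = 3`); the run starts with 2
  infested zones.
- Each alive bug takes a clamped random-walk step: both coordinates shift
  independently by `U{−1, 0, 1}` and are clamped to the grid, so bugs move at
  most one zone per hour (Chebyshev distance ≤ 1).
- Every sensor runs its strategy's periodic hook; received warnings trigger
  the reactive hook synchronously in the same hour.
- A bug in a zone fumigated this hour accrues one exposure-hour and dies
  after 3 cumulative exposure-hours.
- A surviving bug eats 2 percentage points of its zone's crop health per hour
  unless the zone was fumigated in the *previous* hour; every zone regrows
  0.1 %/h, capped at 100 %.

Three built-in strategies:

| strategy | on detection | on warning |
|---|---|---|
| `broadcast` | fumigate; warn all `M·N − 1` other sensors | fumigate |
| `neighbor` | fumigate; warn the clipped 8-neighborhood | fumigate |
| `lowcost_neighbor` | warn only neighbors whose last warning is older than `d` hours; keep fumigating for `d` hours after a detection | fumigate; record the warning time in a 3 × 3 last-warnings matrix `W` |

Four metrics are tracked hourly: average electric power per active station
(a station is active in an hour if it sent a message or fumigated;
instantaneous power is `messages × E_msg / active stations`, reported as the
running mean over hours with activity), mean crop health (%), percentage of
alive bugs among all bugs ever (100 % before any bug exists), and cumulative
pesticide per station.

## Worked example

```r
library(pestgrid)

sim <- run_simulation(sim_config(strategy = "lowcost_neighbor", seed = 7))
sim
#> <pest_sim> strategy 'lowcost_neighbor', 10 x 16 grid, 48 h, seed 7
#>   final: power/active station 0.3865, crop health 99.99%, alive bugs 0.00%,
#>   pesticide/station 1.137 mL
```

The final record says: over this 48-h run the low-cost protocol needed on
average 0.39 energy units per active station-hour, the crop ended essentially
unharmed (99.99 %), every bug that ever entered the field was exterminated
(0 % alive), and 1.14 mL of pesticide per station were dispensed in total.

Replicate batches and the statistical comparison (here 20 replicates per
strategy; the full study design uses 100):

```r
b_n  <- run_batch(sim_config(), strategy = "neighbor",
                  n_reps = 20, base_seed = 1)
b_lc <- run_batch(sim_config(), strategy = "lowcost_neighbor",
                  n_reps = 20, base_seed = 100001)
compare_strategies(list(neighbor = b_n, lowcost_neighbor = b_lc))
#> Per-strategy final metrics (mean, SD):
#>          strategy      metric    mean      sd
#>          neighbor       power  0.8985 0.04863
#>  ...
#>  lowcost_neighbor       power  0.3861 0.03920
#>  ...
#> Pairwise robust tests:
#>  lowcost_neighbor vs neighbor  power  welch  1.346e+03  1  36.36  2.510e-30 **
#>  ...
#> Effect sizes (mean difference, Cohen's d):
#>  lowcost_neighbor - neighbor  power  -0.5124  -11.60
```

The low-cost neighbor protocol cuts power per active station by more than
half relative to the plain neighbor protocol (Welch p ≈ 10⁻³⁰, a very large
effect by any conventional reading of Cohen's d), while crop health and
extermination are statistically indistinguishable.

A command-line front end wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "pestgrid.R", package = "pestgrid"))')
Rscript $CLI simulate --strategy lowcost_neighbor --seed 1 \
        --out-csv evolution.csv --out-json summary.json
Rscript $CLI batch --reps 100 --strategies all --base-seed 42 --out-dir batch_out
```

## Documentation

The methods vignette (`vignettes/pest-control-simulation.Rmd`) describes the
model, the strategy semantics, the numerical and design choices, and the
limits of what the simulated conditions can show about real fields.
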