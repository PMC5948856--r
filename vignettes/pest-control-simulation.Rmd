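---
title: "Simulating sensor-coordinated pest control: model, strategies and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating sensor-coordinated pest control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pestgrid)
```

## The system being modelled

A crop field is divided into an `M × N` lattice of zones, each monitored by
one wireless sensor station that can (a) detect alive bugs in its own zone,
(b) fumigate its zone, and (c) exchange warning messages with other
stations. Bugs enter the field stochastically, walk between adjacent zones,
eat the crop, and die after sufficient pesticide exposure. The scientific
object of study is the *communication strategy*: the rule deciding when a
station fumigates and whom it warns, evaluated on four axes — electric power
per active station, crop health, extermination of bugs, and pesticide
consumption.

## Environment dynamics

Each simulated hour consists of eight phases in a fixed order (appearance →
movement → sensing/communication → exposure → eating → growth → metrics,
with a ledger-reset phase first). The order is not a neutral choice — it
affects traces — so it is fixed and documented here; equal seeds give
bitwise-identical runs.

**Appearance.** With probability `p_appear` per hour an appearance event
occurs and `U{0, …, max_new_bugs}` bugs materialise at uniformly random
zones. The two-stage draw means the expected influx is
`p_appear · max_new_bugs / 2` bugs per hour (0.15/h at the defaults).

**Movement.** Each alive bug shifts both coordinates independently by an
integer uniform on `{−1, 0, 1}`, each coordinate clamped to its own
dimension's index range `[0, dim − 1]` — on non-square grids it matters that
the column index is clamped with the column count and the row index with the
row count. The result is a Chebyshev-distance-≤1 step that never leaves the
grid. Movement draws
are vectorised per hour — all column offsets for alive bugs in creation
order, then all row offsets — a deterministic draw ordering under the seed.

**Exposure and death.** A bug standing in a zone fumigated *this* hour
accrues one exposure-hour. Exposure is cumulative, not necessarily
consecutive, and the bug dies when it reaches `exposure_hours_to_die`
(default 3). A gradually decreasing health indicator and a discrete exposure
counter are equivalent framings; the counter is the simpler mechanism and is
what the package implements.

**Eating and regrowth.** A surviving bug eats `eat_rate` (default 2)
percentage points of its zone's health per hour *unless the zone was
fumigated in the previous hour*; fumigation in the current hour does not
block eating (it drives exposure instead). This follows the stricter literal
reading of the protection rule; the alternative (same-hour fumigation also
blocks eating) would slightly improve crop health for all strategies alike
and would not change any comparative conclusion. Every zone regrows
`grow_rate` (default 0.1) points per hour, capped at 100. The absolute
values of the two rates are calibration constants; only their ordering
(`grow_rate < eat_rate`, enforced as a configuration invariant) is
structural: bugs eat much faster than the crop recovers.

## The strategy framework

A strategy is a pair of hooks over a fixed six-operation capability set
(`sense_bugs`, `fumigate`, `send_message`, `broadcast_message`,
`send_neighbors`, plus the current iteration):

- the **periodic hook** runs once per sensor per hour, in row-major raster
  order;
- the **reactive hook** runs on message delivery, synchronously within the
  sender's turn, so a warning sent at hour `t` causes fumigation at hour
  `t`. Reactive hooks never send messages, so there are no cascades and the
  per-hour message count is bounded by
  `(detecting sensors) × (M·N − 1)`.

Fumigation is idempotent within the hour: one dose of
`pesticide_per_fumigation` millilitres no matter how many calls. Every sent
message costs `energy_per_message`. Detection is perfect (no error rate).

Raster-order iteration matters for the low-cost strategy: a sensor warned
earlier in the same hour will suppress its own outgoing warning to the
warner (the last-warnings entry already holds `t`), which is exactly the
redundancy-avoidance the protocol is designed around.

**Broadcast.** On detection: fumigate and warn all `M·N − 1` other sensors.
A warned sensor fumigates unconditionally. In both the broadcast and
neighborhood target sets, only the sender itself is excluded — a
formalisation that excludes every sensor sharing the sender's row *or*
column (`i ≠ x ∧ j ≠ y`) is a tempting but wrong way to write "everyone but
me", and the package deliberately does not do that.

**Neighbor.** On detection: fumigate and warn the boundary-clipped
8-neighborhood (8 sends interior, 5 on edges, 3 in corners). Warning
handling is identical to broadcast.

**Low-cost neighbor.** Each sensor keeps two pieces of state: `b`, the hour
of its last own detection, and `W`, a 3 × 3 matrix of the last hour each
neighbor warned it (both initialised to the sentinel "never" = −∞ so a first
event is never suppressed). The periodic hook fumigates whenever
`t − b ≤ d` (the *fumigation window*, a strategy parameter; the default of
3 h matches the exposure time a bug needs to die), and on a fresh detection
(`sense` and `t − b > d`) warns only the neighbors whose `W` entry satisfies
`t − W > d`, then sets `b := t` — so a detecting sensor fumigates from the
detection hour onward, not from `t + 1`. The reactive hook fumigates for the
current hour only and files the warning time under the sender's local
position (`global_to_local`, the target minus reference offset shifted to
the matrix centre). Whether a *warned* low-cost sensor should also fumigate
for a window was genuinely open; the one-hour reading was chosen because it
is the literal reactive rule, and the window semantics remain attached to
detection where the learning argument needs them.

## Metrics

A station is *active* in an hour if it sent at least one message or
fumigated. Instantaneous power of an hour with activity is
`messages × energy_per_message / active stations`; the reported average
power is the running mean of instantaneous power over hours with at least
one active station (hours with none are excluded rather than counted as
zero, avoiding division by zero and matching the smooth converging power
evolutions the metric is meant to show). Only communication contributes to
the numerator; fumigating stations enter the denominator. Crop health is the
mean zone health; the alive-bug percentage is `100 · alive / total ever`
(reported as 100 before any bug exists, so an untouched field reads as
"nothing wrong"); pesticide per station is the cumulative dispensed volume
over `M·N`. Cumulative pesticide and energy are non-decreasing by
construction.

## The stochastic scenario and what it does (not) show

The default configuration — `10 × 16` grid, 2 initial affected zones,
`p_appear = 0.10`/h, 48 h, 100 replicates per strategy with seeds
`base_seed + i` and widely separated per-strategy seed blocks — is the
reference study design, and the replicate harness
(`run_batch`, `compare_strategies`) reproduces its analysis: per-metric
means and SDs, Levene's test (centre = mean, configurable to median) as the
homogeneity check, Welch and Brown–Forsythe robust tests (the classical
one-way ANOVA being inappropriate under the strong heteroscedasticity the
power metric shows), and pooled-SD Cohen's d with the (low-cost − neighbor)
sign convention.

Energy and pesticide are reported in calibration units (`energy_per_message`
and `pesticide_per_fumigation` default to 1), so absolute magnitudes in
kW or mL are not comparable to any particular hardware; ratios, orderings,
p-values and standardized effect sizes are the meaningful outputs. The
generator also idealises reality in ways the simulated experiments cannot
probe: detection is perfect, bugs walk independently (no flocking, no
attraction to healthy crop), appearance is weather-independent, message
delivery is lossless and free of propagation effects, and energy cost is
distance-independent. Conclusions transfer to real WSNs only to the extent
those idealisations are harmless.

## Numerical and testing choices

Scripted scenarios (`scenario_script`) inject bugs at prescribed hours and
zones and can disable movement and random appearance; they exist to make the
protocol semantics unit-testable against hand-worked traces and an
independent brute-force reference implementation (kept in the test suite,
written with explicit nested loops over 2-D matrices). Oracle-equality tests
run on 2×2 and 3×3 grids over 10–12 hours for all three strategies.
Stochastic frequency checks (appearance rate, uniform placement, uniform
9-outcome movement) use 10⁴–10⁵ draws with 3-standard-error bands; the
statistics are validated against independently coded textbook formulas, the
algebraic identity of Welch's F with the squared Welch t at k = 2, the exact
coincidence of the Brown–Forsythe statistic with the classical F for
balanced designs, and a 1000-resample type-I-error calibration at n = 30.
End-to-end checks use the full reference design (100 replicates per
strategy, about 20 s in total); these sizes are the package's own choice of
desk-scale study. Degenerate inputs fail loudly: zero within-group variance
for the robust tests, zero pooled SD for Cohen's d, all-equal data for
Levene's test, fewer than two replicates for an SD.

## Known limitations

Bugs live at zone granularity (no sub-zone position — all dynamics and
metrics operate on zones); there is a single bug species and a single crop;
strategy state is unbounded in principle but the built-ins use O(1) memory
per sensor. The power metric counts communication energy only; if fumigation
itself drew metered power, the broadcast strategy's power disadvantage would
only widen.
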