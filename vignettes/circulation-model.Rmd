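---
title: "An agent-based model of blockchain adoption in agricultural product circulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of blockchain adoption in agricultural product circulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agrichain)
```

## The system being modeled

Agricultural product safety is a credence attribute: only the producer knows
whether a lot meets residue standards, and downstream buyers cannot verify
it. The simulator models a production base of `n` homogeneous farmers, each
producing `s` units per period, whose lots flow to consumers through one of
two coexisting channels:

* **traditional chain** — farmer → wholesaler → retailer → consumer, at
  prices `P1` (farmgate), `P3` (wholesale) and `P5` (retail);
* **blockchain chain** — farmer → retailer directly, at the traceable
  farmgate price `P2` and retail price `P4`, with blockchain wholesalers
  reduced to fee-for-service logistics at `theta` per unit.

A regulator samples each role with per-role probabilities `a1`, `a2`, `a3`
and fines unsafe lots `B1`–`B3` per unit. The decisive structural
difference between the chains is *traceability*: an unsafe blockchain lot
detected at any node is traced back to the producing farmer, who pays `B1`
per unit, whereas in the traditional chain the fine falls on whichever node
happens to be holding the lot.

Consumers are passive absorbing demand: every unit sells, and consumer
preference for verified safety enters only through the price premia on `P2`
and `P4`.

## Agent state and dynamics

**Honesty.** Each farmer carries an honesty state `h` in `[0, 1]`. When the
farmer's chain is untouched by the regulator in a period, honesty decays by
the affine map `h' = (1 - f_plus) h + minimal_honesty`, whose fixed point
`minimal_honesty / f_plus` (0.1 at the defaults) is the behavioral floor.
When the farmer is sampled — or, for blockchain farmers, when *any* node
handling their lot is sampled, since traceability makes inspection salient
to the producer — honesty rises by `h' = (1 - f_minus) h + f_minus`, a
contraction toward 1. `f_minus > f_plus`: being inspected moves behavior
more than another quiet period does. Because blockchain lots face
inspection at three nodes, blockchain farmers experience boost probability
`1 - (1-a1)(1-a2)(1-a3)` per period against `a1` for traditional ones; the
two modes therefore settle at different honesty levels, which is the
mechanical source of the qualification-rate gap between chains.

**Production decisions.** Each period the farmer weighs the standardized
benefit gap of unsafe production `k = plogis(Delta / ki_scale)`, where
`Delta` is the expected profit of an unsafe lot (including the expected
traceback or spot-check fine) minus that of a safe lot, against honesty and
a uniform shock: the lot is safe iff `alpha * k + (1 - alpha) * rho <= h`.
This orientation makes a fully honest farmer always produce safely and a
fully dishonest one never, and gives the exact closed form
`P(safe) = clamp((h - alpha k) / (1 - alpha))` used by the test suite. The
configuration flag `decision_direction = "literal"` runs the reversed
inequality for comparison. The logistic standardization was chosen over
population min–max because the population is homogeneous in expectation,
which makes min–max degenerate; `ki_scale` (default 30, the currency scale
of one lot's cost difference) sets how sharply the gap saturates.

**Profits.** Per lot of `s` units: traditional farmers earn
`s (P1 - Cu)`, `s (P1 - Cu - B1)` or `s (P1 - Cs)` for unsafe-undetected,
unsafe-detected and safe lots; blockchain farmers the same with `P2` and
the per-unit technology cost `Ct` subtracted. Traditional wholesalers earn
the margin `P3 - P1` (less `B2` if caught holding an unsafe lot);
blockchain wholesalers earn the fixed logistics fee. Traditional retailers
earn `P5 - P3` (less `B3` if caught); blockchain retailers earn
`P4 - P2 - theta - Ct`. Safe lots are never fined, and a lot is fined at
most once per period (the earliest node in chain order pays).

**Chain switching.** After profits are realized, each agent compares its
period result with the mean result of the other mode of its role and
converts when `alpha * (peer - own)/peer + (1 - alpha) p > G`, with the
relative gain capped at 1 and set to 0 when the reference mean is
non-positive. Farmer thresholds `G` respond to the four income/fine
combinations (marked rise when income is high without a fine, slight fall
when low, slight rise when high with a fine, marked fall when low with a
fine, with rates ordered `v2_minus > v1_minus > v1_plus > v2_plus`);
wholesaler and retailer thresholds `G1`, `G2` are constant, since no update
law is defined for them. Conversions are applied simultaneously at the end
of the period from a consistent profit snapshot, and require the other
mode to be populated — a single-mode state is absorbing.

## Price formation

`P1 = alpha Cu + (1-alpha) Cs + eps1 + e1` anchors the farmgate price
between the two unit production costs; `P2` adds a traceability premium on
top of the same anchor. Downstream prices are proportional markups:
`P3 = (1+eta) P1 + e3`, `P4 = (1+beta) P2 + e4`, `P5 = (1+delta) P3 + e5`.
Each `eps` is an independent `N(mu, sigma^2)` draw per price per period;
realized prices are floored at zero. The market effects `e1..e5` are
constants (simplest faithful reading of "the effect of market conditions").

## Event order within a period

(1) realize prices → (2) production decisions → (3) route lots (uniform
random same-mode trader assignment) → (4) regulator samples, detects,
fines → (5) profits accrue → (6) honesty updates → (7) threshold updates,
then simultaneous conversions → (8) metrics. Honesty must follow
regulation because the two honesty maps condition on being sampled this
period; conversion must follow profits because it compares this period's
incomes.

## Outcome metrics

Per chain and period: the **qualification rate** (safe units / total
units); the **input–output ratio** (consumer expenditure over resource
cost: production + technology + logistics; fines are transfers to the
regulator, not resources, and are excluded by default, with a flag to
include them); and **circulation efficiency**
`CE = w q + (1 - w) io/(1 + io)`. The `io/(1+io)` normalization is
monotone, bounded and run-independent, so periods remain comparable across
scenarios; a run-level min–max alternative is available behind the
`io_normalization` flag but makes scenarios incommensurable. "Stabilized"
values are trailing-window means (default 30 periods) — stabilization is
read off the flat late part of a trajectory, not detected by a convergence
test.

The sweep experiment sets all three sampling probabilities to a common
value and runs paired replications on common random numbers: replication
`j` uses the same master seed at every probability, and each subsystem
(prices, decisions, sampling, routing, conversion, initialization) draws
from its own named stream derived from that seed. Contrasts between
probabilities are therefore within-seed, and changing regulatory intensity
provably leaves the realized price series untouched.

## Calibration

No part of the parameterization is an empirical estimate; the defaults are
a reference calibration built in three steps.

*Structural constants.* 100 farmers (10 units each), 20 wholesalers, 30
retailers, 120 periods, 30% initial blockchain adoption in every role,
initial honesty uniform on `[0.4, 0.6]`, `Cs = 8`, `Cu = 5`, fines
`B1 = B2 = B3 = 6` per unit, sampling `a1 = a2 = a3 = 0.2`,
`f_plus = 0.05`, `f_minus = 0.2`, `minimal_honesty = 0.005` (honesty floor
0.1), all mixing weights `alpha = 0.5`, efficiency weight `w = 0.5`.

*Margin parity.* For two chains to coexist for a whole run, no role may
find one mode strictly dominant in expectation, otherwise conversion
drains that mode. With `e1 = 2` the expected farmgate price is
`P1 = 8.5`; the blockchain premium of 3.5 puts `P2 = 10`. Setting
`eta = 0.2` gives traditional wholesalers an expected net margin of
`0.2 * 8.5 - a2 (1-a1)(1-q) B2 ≈ 1.2` per unit at a mid-range
qualification rate `q`, matched by the logistics fee `theta = 1.2`.
Setting `beta = 0.3` and `Ct = 0.5` gives blockchain retailers
`0.3 * 10 - 1.2 - 0.5 = 1.3`, matched by traditional retailers'
`delta * 1.2 * 8.5 - a3 (1-a1)(1-a2)(1-q) B3 ≈ 1.3` at `delta = 0.16`.
Farmers land near parity automatically (`≈ 13` vs `≈ 15` per period at the
default intensity). Price noise `sigma = 1` keeps period profits
overlapping across modes.

*Switching resistance.* Fines are levied on whole lots, so a fined agent's
relative shortfall saturates the capped gain term; at low conversion
thresholds this "fined agents defect" pump absorbs one mode within a few
dozen periods (which mode dies depends on the threshold level, and
single-mode states are absorbing). The defaults therefore encode high,
durable resistance to switching: initial thresholds
`G0 = G1_0 = G2_0 = 0.99` and per-mille adjustment rates
(`v1_plus = 2e-4`, `v1_minus = 3e-4`, `v2_plus = 1e-4`,
`v2_minus = 6e-4`, preserving the required ordering), so thresholds move
on the timescale of the whole run rather than collapsing within a dozen
periods. Conversion then proceeds at a few tenths of a percent of the
population per period, led by fined agents — visible adoption drift
without extinction. Raising the `v` rates produces faster and eventually
absorbing adoption dynamics; the package supports studying that regime,
but does not default to it.

## What a default run shows

```{r, eval = FALSE}
cfg <- default_config()
sim <- run_simulation(cfg)
stabilized_summary(sim$metrics, cfg$efficiency$stabilization_window)
sw <- regulatory_sweep(cfg, probs = c(0.1, 0.2, 0.3), reps = 30)
sw$summary
```

Under the default calibration the blockchain chain's qualification rate
climbs from its initial level as honesty converges upward and stabilizes
well above the traditional chain's; circulation efficiency does the same.
Across the sampling-probability sweep, the traditional chain's stabilized
qualification rate rises steeply with regulatory intensity while the
blockchain chain's metrics stay high and move comparatively little — its
traceability acts as internal regulation. These are the directional
patterns the test suite asserts (paired sign tests over 30 common-random-
number replications); the exact levels are properties of this calibration,
not estimates of any real system.

## Numerical choices and degenerate inputs

* Same seed ⇒ byte-identical output files; runs never perturb the caller's
  RNG state (generator state is swapped in and out around every draw).
* Prices are floored at zero; honesty and thresholds are clipped to
  `[0, 1]` after every update.
* A mode with farmers but no same-mode wholesaler or retailer produces no
  lots that period (one warning per run); a chain with no lots in a period
  simply has no metrics row, and empty chains never produce `NaN` metrics.
* Traders that handled no lots in a period have no margin signal and do
  not convert; agents with no other-mode peers cannot convert at all.
* Zero sampling yields no fines and population-wide honesty decay toward
  the floor — the qualification rate collapses accordingly.

## Problem sizes used by the test suite

Unit tests run reduced populations (40 farmers, 10 wholesalers, 12
retailers, 8–40 periods), chosen so the full suite completes in a few
minutes. The end-to-end checks run the full default calibration: one
120-period run for ledger reconciliation, 30 replications for the trend
checks, and 90 paired runs (3 probabilities × 30 replications) for the
sweep. Monte-Carlo checks of the decision rule use 100,000 draws per grid
point against the closed form.

## Limitations

* Prices are exogenous: no supply–demand feedback, inventories or
  multi-period contracts, so the input–output ratio is driven by
  calibration constants plus the safe/unsafe cost mix.
* Consumers have no decision model; safety preference lives entirely in
  the price premia.
* Mode populations are conserved; entry and exit are out of scope.
* The long-run limit of the conversion dynamics is single-mode absorption;
  the default calibration postpones it far beyond the default horizon
  rather than removing it.
* Homogeneous farmers and global peer comparison by default. A square
  lattice neighborhood (`neighborhood_mode = "grid_radius"`) restricts a
  farmer's comparison to other-mode farmers within a Chebyshev radius, but
  the reference analyses all use global comparison.
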