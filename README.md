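# agrichain

An agent-based simulator of an agricultural product circulation system in
which a **traditional chain** (farmer → wholesaler → retailer → consumer)
coexists with a **blockchain-traceable chain** (farmer → retailer, with
wholesalers reduced to fee-for-service logistics). It is aimed at
food-safety and supply-chain researchers who want a reproducible testbed
for how traceability and regulatory sampling intensity shape the **product
qualification rate** (the fraction of circulated units meeting safety
standards) and **circulation efficiency**.

## The model in brief

Each of `n` farmers carries an honesty state `h ∈ [0,1]` that decays by
`h' = (1 − f⁺)h + minimal_honesty` in uninspected periods and rises by
`h' = (1 − f⁻)h + f⁻` when the regulator touches the farmer's chain. A lot
of `s` units is produced safely iff

    α·k + (1 − α)·ρ ≤ h,      k = logistic(Δ / scale),

where `Δ` is the expected-profit advantage of unsafe production net of
expected fines, and `ρ` is a uniform shock. Prices are cost-anchored with
markups (`P1, P2` farmgate; `P3` wholesale; `P4, P5` retail); the
blockchain farmgate price `P2` carries a traceability premium. The
regulator samples farmers, wholesalers and retailers with probabilities
`a1, a2, a3` and fines unsafe lots `B1–B3` per unit — with the key
structural difference that an unsafe *blockchain* lot detected at any node
is traced back to the producing farmer. Agents switch chains when the
relative profit gap of the other mode beats a resistance threshold,
`α(π′ − π)/π′ + (1 − α)p > G`. Per chain and period the simulator records
the qualification rate `q`, the input–output ratio `io` (consumer
expenditure over resource cost) and circulation efficiency
`CE = w·q + (1 − w)·io/(1 + io)`.

See `vignettes/circulation-model.Rmd` for the full model, the calibration
rationale and the design decisions.

## Worked example

```r
library(agrichain)

cfg <- default_config()       # 100 farmers, 20 wholesalers, 30 retailers,
                              # 120 periods, sampling 0.2, seed 42
sim <- run_simulation(cfg)
print(sim)
#> <agrichain_sim>
#>   periods: 120   lots: 12000
#>   traditional  stabilized qualification 0.473, efficiency 0.556
#>   blockchain   stabilized qualification 0.957, efficiency 0.760

stabilized_summary(sim$metrics, 30)
#>        chain qualification_rate io_ratio io_normalized circulation_efficiency total_fines n_periods
#>  traditional             0.4732     1.79        0.6391                 0.5561         534        30
#>   blockchain             0.9572     1.29        0.5618                 0.7595          68        30
```

Over the last 30 of 120 periods, 47% of units in the traditional chain met
the safety standard against 96% in the blockchain chain: three-node
traceback exposes blockchain farmers to inspection almost every period, so
their honesty — and with it the safe-production probability — converges
far higher. The blockchain chain also pays an order of magnitude less in
fines. Its input–output ratio is lower (the premium product carries
technology and logistics costs), but the efficiency blend still favors it,
0.76 against 0.56.

The regulatory sweep runs paired replications (common random numbers)
across sampling probabilities:

```r
sw <- regulatory_sweep(cfg, probs = c(0.1, 0.2, 0.3), reps = 30)
sw$summary
```

Raising sampling intensity from 0.1 to 0.3 roughly quintuples the
traditional chain's stabilized qualification rate, while the blockchain
chain's metrics stay high and move comparatively little — traceability
acts as built-in regulation.

A thin CLI wraps the same functions:

```sh
Rscript inst/scripts/agrichain run --seed 7 --out out/ --ledger
Rscript inst/scripts/agrichain sweep --probs 0.1,0.2,0.3 --reps 30 --out out/
```

Configurations are YAML files mirroring `default_config()`; unknown keys
are rejected. Runs are fully deterministic per seed, with independent
per-subsystem random streams.

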