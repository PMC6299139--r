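# tiledisp

Kinetic modeling, simulation and fitting for **DNA origami tile
displacement** — reactions in which an invader tile binds a multi-tile
complex through a *toehold* of edge staples, branch-migrates along tile
edges (and across tile corners), and releases a previously bound tile.
Tile displacement brings the two workhorse properties of strand
displacement circuits — kinetics tunable through toehold strength, and
cascading through toehold sequestering — to interacting 100-nm origami
structures, enabling competitive, sequential and cooperative
reconfiguration of tile arrays.

The package is for people who design or analyze such systems: it turns a
declarative description of tiles, toeholds and branch-migration domains
into a mass-action reaction network, simulates it deterministically and
stochastically, normalizes and fits fluorescence plate-reader data, and
quantifies AFM count-based yields.

## The model

Each displacement pathway is a three-step scheme

```
Inv + CT:BT  <-->  Inv~CT:BT  -->  Inv:BT + CT
        k_bind / k_diss     k_disp,path
```

with

* `k_bind(sticky_nt)` — bimolecular toehold binding, a lookup by sticky-end
  length (tile binding is 10–100x slower than strand-displacement
  hybridization, depending on that length);
* `k_diss(n) = k_diss0 · b^-n` — toehold dissociation, exponential in the
  *total* toehold nucleotides `n = staples × sticky_nt`;
* `k_disp,path` — the mean-first-passage rate `1/Σ(1/r_i)` of the branch
  migration chain, one coarse step per edge segment and per corner
  crossing, corners ~100x slower and coded (staple-subset) domains ~25x
  slower.

The effective bimolecular rate is `k_eff = k_bind·k_disp,path /
(k_diss + k_disp,path)`; with the calibrated defaults it peaks at
4.5×10⁵ M⁻¹s⁻¹ (2-nt 4-staple toehold) and spans more than five orders of
magnitude across nonzero toeholds, with the binding/displacement regime
crossover near 50 nM.

## Worked example

```r
library(tiledisp)
p <- default_rate_params()   # the calibrated "fig1e" set

# 2-nt 4-staple toehold displacement: 2 nM complex + 4 nM invader
cc <- simulate_system(make_basic_displacement(4, 2), p, hours = 24)
cc$completion[cc$time_s == 3600]
#> [1] 0.9792648      # 98% of cover tiles released after 1 h

# the fast competitive pathway is 18x the slow one
effective_rate_ratio(p, toehold_spec(4, 2), toehold_spec(4, 1))
#> [1] 17.99996

# competitive reconfiguration thresholds at the fast complex concentration
completion_curve(p, c(0.6, 1.0, 1.4, 2.0, 3.0), horizon_h = 24)
#>   multiple  fast  slow
#> 1      0.6 0.556 0.044
#> 2      1.0 0.886 0.114
#> 3      1.4 1.000 0.385
#> 4      2.0 1.000 0.813
#> 5      3.0 1.000 0.993

# AFM count-based yield with the Bernoulli standard error convention
yield_estimate(1, 12)
#> yield: 8.3 +/- 2.3 % (n = 12)
```

Below 1× invader the fast pathway consumes the shared invader pool and the
slow product stays dark; past 1× the fast complexes saturate and the slow
product rises sigmoidally — the fast reaction acts as a concentration
threshold.

A command-line interface wraps the same functions
(`inst/cli/tiledisp simulate --system basic:y4x2 --time 24h --out traj.tsv`;
subcommands `enumerate`, `simulate`, `fit`, `synth`, `yield`, `curve`).

The methods vignette (`vignettes/tile-displacement-kinetics.Rmd`) documents
the model assumptions, the derivation of the default parameter set, preset
geometry choices, numerical tolerances, and what the synthetic-data
generator does and does not emulate.

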