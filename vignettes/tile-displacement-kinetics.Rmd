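---
title: "Modeling DNA tile displacement kinetics with tiledisp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling DNA tile displacement kinetics with tiledisp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiledisp)
```

## The reaction being modeled

A DNA origami tile displacement reaction is the origami-scale analogue of
toehold-mediated strand displacement. An invader tile carries a *toehold*: a
small set of edge staples (up to 4) whose short sticky ends (1--5 nt) can
hybridize to matching truncated staples on a tile bound inside a complex.
After toehold binding, the invader competes with the incumbent *cover* tile
staple-by-staple through a *branch migration domain* along the shared edge,
possibly continuing across 90-degree tile corners into adjacent edges, until
the cover tile's last bond is displaced and it diffuses away. Because a
released tile retains no toehold, release is irreversible; everything before
it is reversible.

`tiledisp` models this with a three-step scheme per displacement pathway:

1. **Toehold binding** — bimolecular, rate `k_bind(sticky_nt)` in
   M^-1 s^-1. Binding is mediated by the sticky ends, so the rate is a
   lookup by sticky-end length (1, 2 or 5 nt), not a formula.
2. **Toehold dissociation** — unimolecular from the pre-migration state,
   `k_diss(n) = k_diss0 * b^-n`, where `n` is the *total* toehold
   nucleotides (staple count x sticky-end length). The exponential form
   mirrors strand displacement; stacking-bond contributions are absorbed
   into `k_diss0` and `b` rather than modeled separately.
3. **Branch migration** — a chain of coarse-grained steps, one per edge
   segment and one per corner crossing, each at `k_disp` divided by
   `corner_factor` (100) for corners and `code_factor` (25) for coded
   domains, with both factors multiplying when both apply (the simplest
   composition consistent with independent mechanisms). Internal steps are
   an unbiased reversible walk (forward rate = backward rate); the final
   release step is irreversible.

The low-concentration reduction of this scheme is the effective bimolecular
constant

$$k_\mathrm{eff} = \frac{k_\mathrm{bind}\,k_\mathrm{disp,path}}
 {k_\mathrm{diss} + k_\mathrm{disp,path}},$$

where `k_disp_path` is the inverse mean first-passage time of the migration
chain, `1 / sum(1 / r_i)` (`path_rate()`). The crossover concentration
`k_disp_path / k_bind` separates the binding-limited regime (rate grows
with invader concentration) from the displacement-limited regime (added
invader saturates); with the default parameters it sits at 56 nM, far above
the 2--8 nM working range, so most systems here are binding-limited.

### Migration granularity

One state per edge segment and per corner crossing — not per staple — is a
deliberate coarse-graining. Per-staple states would multiply the state space
by seven while introducing no new observable structure: fluorescence only
reports release. Corner crossings are two orders of magnitude slower than
within-edge migration, so they dominate first-passage times and must be
explicit states; sub-edge positions need not be.

## The default parameter set and its calibration

The shipped `"fig1e"` set was fixed, once, from the measured behaviors the
model is known to reproduce, before any test in this package was written:

| parameter | default | units | anchored by |
|---|---|---|---|
| `k_bind` (1 nt) | 4.5e4 | /M/s | binding ~100x slower than strand-displacement hybridization (~4.5e6 /M/s) |
| `k_bind` (2 nt) | 4.5e5 | /M/s | ~10x slower than hybridization; equals the measured maximum k_eff |
| `k_bind` (5 nt) | 4.5e5 | /M/s | 5-nt 2-staple toeholds behave like 2-nt 4-staple ones |
| `k_disp` | 0.025 | /s | displacement ~40x slower than strand displacement (~1 /s); crossover near 50 nM |
| `b_per_nt` | 24 | — | ~1.9 kcal/mol of pairing free energy per nucleotide at 25 C |
| `k_diss0` | 0.02 x 24^4 ≈ 6636 | /s | fixes the 18x fast/slow contrast (below) |
| `corner_factor` | 100 | — | corner migration ~100x slower than within-edge |
| `code_factor` | 25 | — | coded domains ~25x slower than continuous ones |
| `k_leak` | 55 | /M/s | zero-toehold invasion reaching ~3.8% completion at 48 h (2 nM complex, 4 nM invader) |
| `k_dimer` | 1e6 | /M/s | invader dimerization deep enough to visibly depress cooperative completion |

Three constraints pin the dissociation law jointly. Writing `m = k_disp`
and `d_n = k_diss0 b^{-n}`: the strongest toehold (8 nt) must be
binding-limited with `k_eff = 4.5e5 = k_bind(2) * m / (d_8 + m)`, which
forces `d_8 << m`; the 2-nt 4-staple over 1-nt 4-staple contrast must be
18, and since the binding lookup contributes a factor 10, the dissociation
term must contribute 1.8, i.e. `d_4 = 0.8 m = 0.02`; and the weakest
nonzero toehold (1 nt) must sit five decades below the strongest, i.e.
`d_1 >~ 1e4 m`, which requires `b >= 24`. `b = 24` corresponds to about
1.9 kcal/mol per nucleotide at 25 C — an entirely ordinary pairing energy —
and makes all three constraints consistent:

```{r}
p <- default_rate_params()
toehold_k_eff(p, toehold_spec(4, 2))                          # ~4.5e5 /M/s
effective_rate_ratio(p, toehold_spec(4, 2), toehold_spec(4, 1))  # 18
log10(toehold_k_eff(p, toehold_spec(4, 2)) /
      toehold_k_eff(p, toehold_spec(1, 1)))                   # > 5
```

`k_dimer` deserves a note: spurious invader--invader dimerization is an
effective channel for aggregate formation seen by AFM, with no independently
measured rate. Because the invaders are supplied at 2x, a dimerization flux
merely comparable to productive binding only consumes the excess; for the
channel to depress completion at all — which is its entire modeling purpose —
it must outpace binding, hence 1e6 /M/s (comparable to edge binding itself).
No quantitative claim is calibrated against it.

## System presets and their geometry choices

Each preset encodes one demonstrated reconfiguration system as a
`system_spec`: species (with tile compositions and, where sequestering
matters, explicit grid complexes), displacement pathways (toehold + ordered
segment list + products), leak channels and observables. Where the source
geometry is genuinely ambiguous the choice is exposed as an argument:

* **Basic** (`make_basic_displacement(y, x)`): one cover:base complex at
  1x = 2 nM, invader at 2x; a single-edge-segment pathway. `y = 0` builds a
  leak-only system.
* **Competitive** (`make_competitive()`): one invader pool shared by a
  2-nt (fast) and a 1-nt (slow) receiving complex, distinct fluorophores.
  The invader's dangling extra nucleotide on the slow pathway is treated as
  kinetically inert.
* **Sequential** (`make_sequential()`): a 2x2 array in which the step-2
  toehold staples on one tile are hybridized by its neighbor until the
  first invader replaces that neighbor — the replacement lacks the
  protecting staples, so displacement *reveals* the toehold. This is
  represented structurally: bonds record which domain labels they engage,
  and `toehold_accessible()` is checked by the enumerator against the
  grids. Which corner tile the first invader replaces is not derivable
  from the kinetics, so it is an argument (`first_replaces`), with the two
  options symmetric in a 2x2. Both displacement paths are
  edge--corner--edge: a displaced tile in a 2x2 has two bound edges joined
  by one corner. The second invader can attack the unreacted array only
  through the zero-toehold leak channel, which bounds the spurious signal
  at a few percent per 48 h.
* **Cooperative** (`make_cooperative()`): two invaders with 2-nt 3-staple
  toeholds (6 nt: fast-binding yet dissociable) each reversibly
  half-migrate; a joint irreversible release fires only from the doubly
  half-migrated state, making release structurally impossible with one
  invader. Dimerization is an optional dead-end channel.
* **3x3** (`make_3x3(reaction)`): 4 nM array, 8 nM invader, 5-nt 2-staple
  toeholds, coded branch domains. Paths: corner = edge + corner (2
  segments); edge = 3 edges + 2 corners (5 segments); center = four
  independent edge disconnections. The center tile's four disconnections
  are order-free states `d = 0..4` with forward multiplicity `4 - d` and
  backward `d + 1` (each connected edge can disconnect, each disconnected
  edge can reconnect), and release only from `d = 4`. Because corners are
  the slowest steps, center (no corners) is fastest and edge (two corners)
  slowest.
* **Self-assembly** (`make_2x2_selfassembly(allow_displacement)`): coarse
  species-level bookkeeping M, D, Tr, Q of one tile type in four rotations.
  Binding multiplicities (2, 2, 1, 1 for M+M, M+D, M+Tr, D+D; 2 for each
  displacement) count distinct assembly routes at the species level; they
  scale rates by small integers and none of the qualitative conclusions
  (trimer trap without displacement, complete assembly with it) depends on
  them. The displacement reactions use an effective 1e3 /M/s — slow
  relative to binding, as expected for a toehold-less frayed-edge exchange —
  so trap resolution is the long-time behavior, not a fast channel.

The enumerator is a rule expander over these declared pathways (binding,
dissociation, reversible migration, release, leak, dimerization), not a
geometric compiler: it generates the intermediate state space mechanically
and verifies declared toeholds against the structural grids where they
exist. That matches the scale of the systems actually built — the largest
network here has a few dozen species — while keeping every generated
reaction auditable (each carries its generating rule). A configurable
species cap (default 10,000) guards against accidental state-space
explosion in hand-built systems.

## Numerics

* **ODE**: `deSolve::lsoda`, rtol 1e-8, atol 1e-12 nM — the rate constants
  span more than five decades, so a stiff-capable integrator is required.
  Concentrations are nM internally; bimolecular constants convert from
  M^-1 s^-1 at the network boundary. Tile-type conservation is checked
  structurally at enumeration and numerically on every trajectory
  (`conservation_drift()`, typically ~1e-15).
* **Dosing** is an exact state reset: integration restarts at each dose
  time with the dosed species incremented, matching discrete pipetted
  additions.
* **SSA**: Gillespie direct method with propensities `k n1 n2 / Omega`
  (distinct) and `k n (n-1) / Omega` (identical pairs), which reproduces
  the deterministic flux in the large-copy limit. Seeded runs are exactly
  reproducible and leave the caller's RNG state untouched.
* **Fitting**: Levenberg--Marquardt (`minpack.lm::nls.lm`) on log10
  parameters, residuals pooled across all conditions (a global fit — one
  parameter set must explain every toehold variant simultaneously).
  Uniform time weighting: plate noise is approximately homoscedastic after
  normalization. Networks are enumerated once per condition and re-rated
  per iteration, so fits are deterministic.
* **Normalization** follows the control convention exactly: 0% from the
  first 5 negative-control points, 100% from the last 5 positive-control
  points, with a sample's own first/last-5 mean substituted when it falls
  outside the control levels. The map is invariant under common positive
  affine transforms of the raw data.
* **Yield SE** is implemented exactly in the printed convention
  `p sqrt(1-p) / sqrt(n)` — reproducing published values such as
  8.3 +/- 2.3% at (1, 12) — with the textbook `sqrt(p(1-p)/n)` available
  separately as `yield_se_binomial()` to avoid silent convention mixups.
* **Competitive threshold**: `competitive_threshold()` reports the
  interpolated invader multiple at half-maximal slow-product completion
  minus the slow pathway's own stoichiometric half-capacity; the midpoint
  of a capacity-limited titration sits half a capacity above its onset, so
  this estimator returns the thresholding capacity itself (the fast
  complex concentration) and doubles when that concentration doubles.

## What the synthetic generator does and does not emulate

`generate_plate()` reproduces the *statistical structure* of the
plate-reader experiments: 3-min sampling over 48 h, 1x = 2 nM (4 nM for
3x3 systems), invaders at 2x, per-well baseline and scale, optional linear
drift, additive Gaussian noise (fluorescence at fixed gain; shot noise is
not modeled), and the negative/positive control wells the normalization
needs. It does not emulate evaporation, well-position effects, pipetting
stoichiometry errors, partially reactive structures (missing staples or
synthesis errors), or spurious stacking aggregates beyond the explicit
dimerization channel. Consequently, passing recovery tests demonstrate
that the inference machinery is unbiased on data generated by the model
itself — they do not certify fits to real plates, where partial
reactivity depresses plateaus (an optional max-completion scale parameter
is the usual remedy and deliberately left out of the default model).

## Problem sizes used by the test suite

The suite runs entirely on synthetic data at sizes chosen for a laptop:
SSA/ODE agreement uses 200 seeded runs at 1e4 copies; parameter recovery
uses 10 seeds x 5 toehold conditions at 1% noise with 5-min sampling;
trajectory tests use 3--30-min grids over 24--48 h (300 h for the slow 3x3
edge reaction, and a multi-year horizon for the asymptotic self-assembly
yield, where integration cost is negligible). These sizes are statements
about what suffices to exercise the model, not about the method's limits.

## Known limitations

* Complementarity is by label; no sequence content, so sequence-dependent
  spurious interactions (stacking-bond artifacts, sticky-end similarity)
  are representable only as explicit leak/dimerization channels.
* No geometric mechanics: tile bending, seam flexibility and mica-surface
  effects are outside the model; the corner and code factors are effective
  constants, not derived quantities.
* The full 9-move tic-tac-toe cascade is expressible (dosing schedules and
  coded domains are supported) but no preset enumerates its complete
  combinatorial state space; the three elementary 3x3 reactions are the
  supported units.
* Temperature is a fixed 25 C context; no thermodynamic rate derivation.
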