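---
title: "Modeling bivalent chromatin domain dynamics on a nucleosome lattice"
author: "bivalentSim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling bivalent chromatin domain dynamics on a nucleosome lattice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bivalentSim)
```

## The model

Bivalent chromatin domains are regions — prominent at lineage-control genes
in embryonic stem cells — whose nucleosomes simultaneously carry the
activating H3K4me3 and the repressive H3K27me3 mark. `bivalentSim`
simulates how such combinatorial mark patterns form, spread, localize and
decay on a one-dimensional lattice of `N` nucleosomes.

Each nucleosome is represented by its two H3 copies. An H3 has two
modification slots, one that may carry an active mark (`a`) and one that
may carry a repressive mark (`r`); this gives $2^4 = 16$ ordered
configurations per nucleosome. Two constraints reduce them to the working
state space:

* a single H3 does not carry an active and a repressive mark at the same
  time (an experimentally motivated exclusion), and
* the two H3 copies within a nucleosome are physically interchangeable, so
  states are unordered pairs.

Filtering and deduplicating the raw enumeration (the package computes this,
it does not hard-code it) leaves six distinct states: `UU`, `AU`, `UR`,
`AR`, `AA`, `RR`. The reduced model used for all simulations additionally
treats the doubly-active `AA` and doubly-repressive `RR` states as
negligible, leaving four states in which `AR` — one active H3 and one
repressive H3 — is the *bivalent* nucleosome:

```{r}
enumerateStates("four_state")$label
nrow(enumerateTransitions(enumerateStates("six_state")))   # 12
nrow(enumerateTransitions(enumerateStates("four_state")))  # 8
```

Because the time step is short, at most one of the four modification slots
may change per step; transitions that would change two slots at once
(`UU`↔`AR`, `AU`↔`UR`) are forbidden.

## Dynamics

Time advances in discrete steps of `dtMinutes` (default 2 minutes). Per
step, a site's one-step distribution over the four states is assembled from
two kinds of conversion:

* **Recruitment** — enzyme recruitment by existing marks. The local mark
  density $\theta_m(i)$ is the fraction of nucleosomes in the window
  $[i-r,\, i+r]$ (default $r = 2$, a window of five nucleosomes) whose
  state carries mark $m \in \{A, R\}$; positions beyond the lattice ends
  count as unmodified "phantom" sites, and `AR` counts toward both marks.
  Mark *addition* scales with the density of the same mark
  ($k^{me}_m \theta_m$); mark *removal* is catalyzed by demethylases
  recruited by the *opposite* mark ($k^{dm}_m \theta_{\bar m}$), which is
  the crosstalk between the two mark systems.
* **Exchange** — neighbour-independent conversion: spontaneous placement
  $k^{ex+}_m(i)$ (nucleation; may be elevated at designated sites to model
  sequence-specific enzyme docking such as CpG islands) and spontaneous
  loss $k^{ex-}_m$ (histone turnover).

Out of the fully unmodified `UU` state both H3 copies are eligible to
receive the first mark, so addition channels out of `UU` carry a
multiplicity factor $m = 2$ (configurable to 1; whether the factor also
applies to the nucleation channel is a flag, on by default). The
self-transition takes the remaining probability; any parameterization whose
exit mass exceeds 1 violates the small-step assumption and is rejected with
the offending site named.

All sites are updated *synchronously*: every per-site distribution is
computed from the time-$t$ lattice, then each site is sampled independently
with a single uniform draw, inverse-CDF over the fixed state order
`AU, UR, AR, UU`. This fixed order, together with per-run seeds derived
deterministically from the base seed, makes trajectories bit-reproducible;
the compiled engine and the reference R engine consume the RNG stream
identically and are tested to produce identical trajectories.

At the end of every cell cycle (`stepsPerCycle`, default 360 steps = 12 h)
**replication dilution** replaces each nucleosome independently with `UU`
with probability 1/2 — the model follows one daughter strand, to which each
parental nucleosome is assigned with even odds. The snapshot recorded at a
cycle boundary is the post-replication lattice; $t = 0$ is not a
replication event.

### Parameter defaults and provenance

| parameter | default | meaning |
|---|---|---|
| `kMeA` | 0.046 | active-mark spreading per step (≈30 min timescale) |
| `kMeR` | 0.023 | repressive-mark spreading |
| `kDmA`, `kDmR` | 0 | crosstalk demethylation (decay scenarios: 0.008–0.034) |
| `kExMinusA`, `kExMinusR` | 0.003, 0.0015 | histone turnover |
| `kExPlusA`, `kExPlusR` | 0 | nucleation (0.01 / 0.005 at nucleation sites) |
| `r` | 2 | recruitment half-range (window 2r+1 = 5) |
| `dtMinutes` | 2 | minutes per step |
| `stepsPerCycle` | 360 | 12-hour embryonic-stem-cell cycle |

Active-mark rates default to twice their repressive counterparts
throughout, reflecting the faster turnover and catalysis of active marks;
the turnover pairs (0.003, 0.0015) and (0.005, 0.0025) bracket the regime
in which formation succeeds. Several knobs — `r`, the exact `kMeR`, the
`kDmA:kDmR` ratio, and the nucleation magnitude — are not pinned by
published measurements; they are explicit configuration keys with the 2:1
ratio convention, chosen once and never silently embedded in an analysis.
`dtMinutes = 2` follows from the 12-hour cycle being resolved into 360
steps. The recruitment window includes the focal site itself (an
`includeSelf` flag offers the alternative).

## Scenarios

`scenarioConfig()` bundles four canonical experiments, which also serve as
the test fixtures — every initial lattice is generated programmatically:

* **formation_localized / formation_delocalized** — 5 bivalent seeds on an
  80-site `UU` lattice, either a contiguous central block (sites 38–42) or
  equally spaced across the lattice (sites 1, 20, 40, 60, 80); crosstalk
  demethylation and nucleation off.
* **decay** — all-`AR` initial lattice with crosstalk demethylation
  switched on; swept over `kDmA`.
* **nucleation** — elevated spontaneous placement at the central site only,
  mild demethylation; run for 5 cycles and read out at step 1800.
* **cellcycle_sweep** — an established all-`AR` domain, cycle length swept
  from 6 h to 24 h.

```{r}
cfg <- scenarioConfig("formation_localized", nRuns = 50, nCycles = 1,
                      seed = 7)
res <- runScenario(cfg)
res$summary
```

Sweeps reuse the same per-run seeds at every sweep point, so comparisons
along the axis are paired.

## Ensemble observables

The level of a state at (site, time) is the fraction of runs in that state
(`EnsembleOccupancy`, accumulated incrementally so memory stays bounded).
On top of it the package computes:

* `frontTrack()` — edges of the connected occupancy block (threshold 0.5,
  the midpoint of the color transition in ensemble space-time plots)
  containing the seed, and the expansion *speed*: the least-squares growth
  rate of the domain width converted to nucleosomes per cell cycle. In the
  default localized formation the bivalent domain expands at roughly 10
  nucleosomes per cycle during the first two cycles.
* `mergeTime()` — first step at which every site between the outermost
  seeds carries a mark (non-`UU` occupancy ≥ threshold): the fronts from
  delocalized seeds have fused into one block. The fast-spreading active
  mark drives this detector, so it fires earlier than the visually apparent
  fusion of the bivalent pattern itself.
* `equilibrationTime()` — replication imprints a sawtooth of period one
  cycle on every occupancy curve, so convergence is judged at matching
  cycle phases: each time is compared with the last recorded time of the
  same phase, and equilibration is the first step from which this
  deviation, maximised over sites and states, stays below `tol` (default
  0.05) for a full window (default one cycle).
* `fractionRunsWithState()` — persistence: the fraction of runs that still
  contain at least one bivalent nucleosome, which decays more slowly than
  the mean bivalent level because a single surviving `AR` keeps a run
  "alive".
* `domainProfileStats()` — amplitude, FWHM width in sites, and
  occupancy-weighted center of a final profile.

### Numerical and detector conventions

Choices the published description leaves open, fixed here once:

* Front/connectivity threshold 0.5 (exposed as an argument).
* Detectors operate on ensemble averages; single runs are too noisy to
  define fronts sharply (single-run variants can be built from stored
  trajectories).
* The equilibration detector is a *maximum* statistic: its Monte-Carlo
  bias is strictly positive, of order $3\sqrt{0.5/n_{\text{runs}}}$ at the
  worst occupancy variance. With the 0.05 tolerance this demands ensembles
  of several thousand runs — the packaged analyses use 10 000 runs for the
  equilibration readout (noise floor ≈ 0.02) and 200-run ensembles for the
  more robust front-speed and merge readouts. Published ensemble sizes
  (1000–2000 runs) sit between these.
* The localization scenario is run for five 360-step cycles so its final
  read-out falls at step 1800.
* Ties and degenerate inputs: an all-zero profile has width 0 and an
  undefined center; a front that never reaches threshold yields an empty
  (all-`NA`) track rather than an error; a merge or equilibration that
  never happens returns `NA` as a sentinel.

## Exact oracle

For lattices of up to 4 sites the full Markov chain over $4^N$
configurations is built explicitly (`buildTransitionMatrix()`, exact
replication operator included) and transient distributions are propagated
exactly. This is the package's independent correctness standard: the
Monte-Carlo engine is required to match it within per-configuration
3-sigma binomial bands (`oracleCheck()`), and structural properties —
Chapman–Kolmogorov consistency, absorption of the all-`UU` configuration
when nucleation is off, exact mirror symmetry under exchanging the two mark
identities — are asserted on the matrices themselves.

```{r}
chk <- oracleCheck(lattice(c("AR", "UU")), rateParams(), tSteps = 20,
                   nRuns = 3000, seed = 1)
chk$maxAbsDeviation
chk$nViolations
```

## What the simulations do and do not show

The generator emulates the *model's* study conditions: uniform rates (or a
single designated nucleation site), a clean 80-site lattice, strict
periodicity of replication, and mark-count-independent kinetics. Real
chromatin has sequence-dependent nucleosome spacing and occupancy,
nucleosome sliding and eviction, graded methylation valences (me1/me2/me3),
both daughter strands after replication, and coupling to transcription —
none of which are modeled. Passing tests therefore validate the
implementation of this idealized dynamics and its published behavioral
anchors (front propagation near 10 nucleosomes per cycle, front merging
within the first cycle, slow equilibration over several cycles, the decay
and cell-cycle trends), not quantitative predictions for any genomic locus.

Known limitations: absolute occupancies depend on reconstructed rate ratios
that published work does not fully pin down; the merge detector reads the
fast active-mark front rather than the slower bivalent front; and the exact
oracle is limited to 4 sites by design — correctness, not scale, is its
job.

## Session info

```{r}
sessionInfo()
```
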