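---
title: "A hippocampal change-manager circuit: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hippocampal change-manager circuit: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcmsim)
```

## The model

`hcmsim` simulates, in discrete time, a circuit-level account of the
hippocampal system as the *change manager* of the cortex: cortical
pyramidal neurons define receptive fields heuristically, and the
hippocampal system decides **when** receptive fields may expand (when
current input is novel enough that existing fields under-detect) and
**where** (in columns that are close to detecting their fields and have
expanded together with currently active columns in the past). The same
interface circuitry that gates expansion also records which deep cortical
neurons were active during each expansion episode, which is what later
supports episodic pattern completion and sequential recall from a partial
cue.

The model is built from four nested pieces.

**Units.** A pyramidal unit is two thresholded dendritic trees. A
*terminal branch* holds a set of weighted synapses and detects its
*condition* at a step when the summed weight of its active synapses
reaches the branch threshold (the boundary uses `>=`). A tree detects its
*receptive field* when enough branches detect conditions. The basal tree
carries the direct (sensory-driven) field; the apical tree carries the
indirect field that fires the unit on the basis of past temporally
correlated activity. Interneuron gating is modelled as a boolean
computed from its stated driver population, not as explicit units: while
a column has sensory-driven II/III activity, the apical contribution to
firing is blocked, so at most one compartment ever contributes to firing
at a step. Gated trees still record branch condition detections — the
gate blocks the firing contribution, not the dendritic bookkeeping (and
gated-but-detected apical branches remain eligible for the
backpropagation rule below). Activity is binary per step; there are no
membrane dynamics, because every mechanism the model needs is stated in
detection/threshold terms.

**Columns.** A cortical column is three feedforward layers (the usual
five are simplified to three): external features drive layer IV, layer IV
drives the II/III units (the column's *internal activity*), and II/III
drives the deep V/VI units, whose firing is the column's output.
Receptive fields grow more specific along the chain, so deep fields are
detected least often. A column with internal activity at or above the
candidacy floor (default 0.5) and no output is an *expansion candidate*:
it is close to detecting its field, so a small expansion is low-risk.

**The perirhinal interface.** Perirhinal columns cover the cortical
columns (default: three independent random partitions into groups of
about three members, so each column belongs to three perirhinal
columns). Intermediate units relay member II/III activity; per-area
detection rates are summarized to the entorhinal input. Three deep
populations divide the interface's work:

* **P1** (regular-spiking) detects the perirhinal column's own trained
  field — in the default wiring it comes to fire exactly when all member
  columns produce output — and inhibits P2 through interneurons: a group
  that is already fully detecting needs no expansion.
* **P2** (burst-spiking) fires when hippocampally decoded drive arrives
  and the P1 gate is open. Its output is the *manager synapse* present on
  deep basal, deep apical, P1 and P3 branches: a strong input that can
  push an otherwise sub-threshold branch over its detection threshold.
* **P3** (late-spiking) records episodes. During P2 activity a P3 unit
  whose basal branch detects (manager plus a modest group of active
  member deep units) can be recruited; recruitment is k-winners-take-all
  per step with a refractory period, so distinct P3 units are allocated
  to distinct event moments. A recruited P3 unit strengthens basal
  synapses from the deep units active at its recruitment step, and emits
  its output with a per-unit delay; deep units firing when that delayed
  output arrives strengthen the corresponding apical synapses. Output
  delays are heterogeneous (default: half the population at 1 step, half
  at 2, against a 2-step moment dwell): short-delay units land within
  the moment and carry completion links, long-delay units land in the
  next moment and carry the sequence links by which recall of one moment
  drives recall of the next.

**The dentate/CA3 competition.** Granule cells relay entorhinal input to
CA3 through an excitatory path and an interneuron-mediated inhibitory
path that switches on above a granule-activity crossover; CA3 excites
itself recurrently and feeds back onto the granule population through
mossy cells. With high detection rates everywhere (familiar input) the
inhibitory path dominates and CA3 activity is exactly zero; depressed
rates release CA3 activity, which grows until its own mossy feedback
recruits enough inhibition — a self-limiting rise whose equilibrium is,
over the operating range, a linearly decreasing function of the
entorhinal input and hence proportional to novelty. Only a converged
competition is released (the abstraction of the septal theta-band
release) and decoded into P2 drive over the column groups represented by
the active CA3 units.

## One presentation

The evaluation order is fixed and single-threaded: deliver pending
delayed P3 output → step every cortical column (IV, II/III, deep) →
summarize per-area detection rates → run the competition → release and
decode into per-perirhinal-column drive → step perirhinal columns
(intermediate, P1, gate, P2, P3) → in plastic modes, apply expansion
drive and episodic recording, then the slow change constraints
(overdetection threshold raising; elimination of synapses that never
contribute to detections, with a one-window grace period for new
synapses, applied prune-first). Identical configuration and seed give
identical logs.

Retrieval is a separate regime: plasticity frozen (any expansion call
raises a `plasticity frozen` condition), no competition run (release
withheld), cue deep units clamped for a couple of steps, and activity
circulating around the deep → P3-basal → delayed P3 output → deep-apical
loop. With no sensory input the apical gates are open, which is the only
reason indirect activation can drive deep units at all.

## Parameters and why

All synaptic weights are exact binary fractions so that threshold
boundaries are exact in floating point. The load-bearing choices:

* `manager_weight = 0.5` with `branch_threshold = 1`: hippocampal drive
  alone cannot trigger a branch; it needs co-active regular synapses.
  With untrained deep basal weights of 1/16 over the 8 II/III inputs, a
  fresh branch needs full internal activity plus the manager (0.5 + 0.5
  = 1.0 exactly); after one expansion event (increment 1/16, ceiling
  1/8) the branch sums to 1.0 on its own, and the manager tips it over
  threshold exactly when 4–7 of 8 II/III units fire — the same window as
  the candidacy definition, which is what makes expansion drive land on
  candidates.
* Per-pathway weight ceilings (`deep_w_max = 0.125`, etc.) implement the
  minimal-change constraint: expansion raises a weight only to the level
  at which the trained pattern detects, never beyond, so detection and
  candidacy windows do not drift however often a column is driven.
* Layer IV tuning widths cycle over five classes (a branch fires on 3–7
  of its 8 sampled support features), so per-area detection rates
  degrade gradually over the whole novelty range instead of collapsing —
  this is what gives the competition a graded input.
* Competition gains (`w_gc_exc = 1`, `w_gc_inh = 4`, crossover 0.55,
  `w_rec = 0.5`, `w_mossy = 1`, baseline 0.2, cap 1): chosen so that (i)
  the dominance requirement holds (saturated granule input suppresses
  CA3 outright), (ii) the equilibrium is interior and linear in the
  entorhinal input over the active range, and (iii) CA3 activity can
  seed from the tonic baseline under complete novelty. The construction
  refuses gain sets that violate (i).
* P3 geometry: 18 units per perirhinal column, recruitment cap 3 per
  step, refractory 6 steps — the pool rations exactly over a 3-moment
  event at 2 steps dwell. At retrieval, recruitment ranks candidates by
  the *matched fraction* of the trained basal field (active trained
  weight normalized by total trained weight, a synaptic-scaling
  normalization), which keeps recall moving through the episode in
  order instead of igniting all recorded moments at once; an optional
  activity-scaled recruitment floor (`retrieval_match_slope`, default
  off) additionally models feedback inhibition growing with global
  activity. Deep apical branches sample 6 of the 18 P3 units per
  containing perirhinal column, so a single stray P3 emission
  reactivates only a few units while a legitimate multi-unit emission
  wave reactivates a moment.

## The synthetic world

Stimuli are sets of abstract feature identifiers (no modality
structure; the mechanisms are modality-agnostic). A context is a fixed
random pattern over a designated pool; 35% of the feature space is a
reservoir never used by any context, so replacing a fraction of a
context's features with reservoir features guarantees genuine novelty
with an exact label. Events are sequences of moments with constant
composition: a context part (a fraction carried from the previous
moment, the rest refreshed preferentially from features absent in
recent moments, so feature overlap decays with temporal distance) plus
fresh reservoir features. The default event novelty (0.5) and
consecutive-moment overlap (0.5) are chosen so that the three moments'
context parts tile the context pattern exactly, with overlap decaying
over temporal distance — events are distinct, temporally ordered scenes
of a familiar environment, not three copies of it. Familiarization is repeated zero-novelty
presentation with plasticity on; the initial, entirely novel exposure
drives one round of expansions, after which detection saturates, CA3
drops to exactly zero, P1 gates close, and the state is stable.

What the generator does *not* emulate: graded feature intensities,
correlated feature noise, occlusion, multiple simultaneous contexts, or
continuous time. Passing tests therefore show that the circuit logic
produces the claimed activity signatures under clean combinatorial
input, not that it would do so under natural sensory statistics.

## Measurement conventions

* *Receiving above-threshold expansion drive* is measured at the
  dendrite: a column counts as driven when an active manager synapse
  takes an otherwise sub-threshold deep basal branch over its detection
  threshold. A branch already over threshold gains nothing from the
  manager input, so an already-detecting column is not "driven" by it.
* *Recall latency* of a moment is the mean first-reactivation step of
  its deep units, weighted down for units shared between moments (a
  unit in several moments says little about which moment returned);
  recall order is the Spearman correlation of these latencies with the
  encoded order. The recall fraction is unweighted.
* The episode trace (which deep units fired during each encoding
  moment) is a ground-truth log used only by the metrics; the retrieval
  circuitry never reads it.

## Numerical choices

Clipped-linear transfer everywhere in the competition; synchronous
relaxation update (factor 0.4), tolerance `1e-6`, iteration cap 500,
with the fixed point written back exactly on convergence and a warning
(never an error) on non-convergence, which also withholds release.
Detection ties (sum equal to threshold) detect. K-winner ties break by
unit index. Experiment problem sizes (4 areas x 16 columns, 63
perirhinal columns, 10 seeds per experiment, 50-presentation null
blocks, 1000-case oracle and boundedness sweeps) are chosen so every
desk experiment is quick on a laptop while leaving the statistics
stable.

## Known limitations

* The complexity-gradient ordering of detection frequencies (layer IV
  above II/III above deep) holds under strong degradation; deep fields
  are rarer than II/III fields at any novelty. Under mild degradation,
  population redundancy among II/III units (several units sampling the
  same small layer IV pool) can locally push the II/III rate to or
  slightly above the layer IV rate; wirings that remove the redundancy
  restore the strict ordering everywhere but starve the episodic
  machinery of graded internal activity.

* Activity is binary and synchronous; rate and phase phenomena (theta,
  gamma) appear only as the converged-release gate.
* The basal-ganglia side of the architecture, subcortical biasing of
  the competition, semantic consolidation, and working-memory/priming
  correlations are out of scope.
* CA3 column-group fields use a random initial cover updated by
  co-expansion (set-union with decay); with a single training context
  the groups stay coarse, and uniform granule fan-in makes CA3 units
  redundant — selection specificity in this regime comes from the P1
  gate and the dendritic tipping condition, not from group identity.
* P3 allocation uses explicit k-winners-take-all with refractoriness as
  the stand-in for lateral inhibition among late-spiking neurons; the
  moment-resolution of episodic recall depends on that sparseness and
  on the heterogeneity of P3 output delays.
* With weight ceilings at the trained level, a fully familiarized
  column's basal field no longer changes; continued novelty is absorbed
  by the episodic (P3/apical) pathway rather than by unbounded growth
  of the direct field. Structural synaptogenesis is not modelled, only
  recruitment of pre-placed weak synapses.
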