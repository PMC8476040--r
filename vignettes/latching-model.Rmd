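---
title: "A Potts attractor network as a model of short-term recall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Potts attractor network as a model of short-term recall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pottslatch)
```

## The model

A Potts network abstracts the cortex as `N` interacting patches. Each patch
is a single Potts unit with `S` active states — the local attractors the
patch can fall into — plus one background state. A memory is a distributed
assignment `xi` of one state per unit, with each unit active with probability
`a` (the sparsity) and, when active, uniform over the `S` states. Long-range
couplings between units are set once by a Hebbian covariance rule on a dilute
random graph in which every unit receives input from `c_m` others: the
coupling between state `k` of unit `i` and state `l` of unit `j` sums, over
the `p` stored patterns, the product of deviations of the state indicators
from their mean `a/S`, normalized by `c_m a (1 - a/S)`.

The dynamics are continuous-time firing-rate equations. Each unit carries a
potential `r_ik` per active state, integrating the synaptic field with time
constant `tau1`; an adaptive threshold `theta_ik` per state, tracking the
state's own activation with the slower constant `tau2` (neural fatigue
confined to the active local attractor, not the patch as a whole); and two
inhibitory thresholds shared across states — fast (`tauA`, weight `gammaA`)
and slow (`tauB`, weight `1 - gammaA`) — tracking the unit's total activity.
Activations follow a softmax over `beta * r` with the background state
competing at `beta * (U + thetaA + thetaB)`. The *overlap* `m_mu` of the
network state with each stored pattern, normalized to 1 at perfect retrieval,
is the order parameter everything else is computed from.

Adaptation makes retrieval self-limiting: the retrieved pattern fatigues, and
the network hops — *latches* — to a correlated pattern, producing a
quasi-random walk over the stored memories. Depending on the local feedback
`w` and inhibition balance `gammaA` the network shows four regimes — no
latching, finite latching, infinite latching, stable attractor — which
`classify_phase()` labels from the digitized event count and the termination
reason.

Short-term memory is modelled as a transient *boost* of one pre-existing
parameter, restricted to the elements used by a list of `L` items: stronger
local feedback on the units of the listed patterns (Model 1, `delta_w`), a
reduction `delta_theta` of the adaptive threshold on the listed (unit, state)
pairs (Model 2), or a coupling increment `delta_J` on the listed couplings,
within items (Model 3a) or across all pairs of listed items (Model 3b). The
membership indicator is a Heaviside of a count, taken as 0 at 0: no
membership, no boost. The coarser the boosted elements, the sooner the boost
saturates the network: the fraction of elements claimed by `L` random
patterns (`boosted_fraction()`) reaches the discrimination limit `1 - 1/e`
at the critical length `critical_length()`, giving capacities of about 3.5,
27.5, 783.5 and 43.5 items for Models 1, 2, 3a and 3b at `a = 0.25`,
`S = 7`.

Serial recall adds heteroassociative couplings of strength `lambda` from
each instructed item to its successor, driven by the *adaptive thresholds*
rather than the activations: an item biases the walk toward its successor
only once it begins to fatigue. Instructions avoid `AA` and `ABA`
subsequences, which adaptation prevents the network from expressing.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `tau1` | 0.01 | s | potential integration |
| `tau2` | 0.2  | s | adaptive threshold (fatigue) |
| `tauA` | 0.005 | s | fast (GABA-A-like) inhibition |
| `tauB` | 100 | s | slow (GABA-B-like) inhibition |
| `gammaA` | 0.5 | – | share of fast inhibition |
| `beta` | 11 | – | softmax inverse temperature |
| `U` | 0.1 | – | background threshold |
| `w` | 1.1 | – | local feedback (attractor depth) |
| `N`, `c_m` | 600, 90 | – | units, in-degree |
| `p`, `S`, `a` | 200, 7, 0.25 | – | patterns, states, sparsity |

`tau1`, `tau2`, `tauB` (the caption's slow constant), `p`, `S`, `a`,
`gammaA`, `w` are the printed values of the reference simulations. The
remaining engine constants (`N`, `c_m`, `beta`, `U`) are not printed in the
available text; they are taken from the prior Potts-latching literature that
the model builds on, and exposed in `sim_config()` / the presets so any
alternative can be supplied. `tauA = 0.005` s respects the required ordering
`tauA < tau1 << tau2 << tauB`. The cue is an additive field aligned with the
cued pattern, strength 1.0 for `10 * tau1`; an additive transient (rather
than clamping) keeps the state equations unchanged and makes "removing the
cue" literal.

## What the generator emulates — and what it does not

`generate_patterns()` draws one categorical sample per (unit, pattern) cell:
patterns are *randomly correlated*, sharing states at chance level `a/S`.
The number of active units per pattern is binomial around `N a`, not fixed,
and the pair statistics are normalized by `N a` rather than the realized
count, so self-similarity fluctuates slightly around 1. Real semantic
memories are *hierarchically* correlated; none of the structured-correlation
phenomenology is represented here, so passing tests say nothing about
recall of semantically clustered material. Human data enter only through the
scoring conventions (the `m_*` metrics and the `2L - h` click budget), never
as fitted curves.

## Numerical choices

* **Integration** is synchronous explicit Euler over all units with
  `dt = tauA / 4`; one "update" is one full-network step, capped at `1e5`
  updates. The equations are a stiff-ish relaxation cascade, and halving
  `dt` changes trajectories at first order (asserted in the tests); the
  digitized event strings are insensitive to refinement over the horizon the
  metrics use.
* **Softmax** is computed with max-subtraction, so normalization is exact at
  any `beta` and overflow cannot occur.
* **Null-attractor detection**: the run ends when every overlap stays below
  `m_null = 0.1` *and* mean activity stays below a threshold for a full
  `tau2` window. Because the softmax background never absorbs all mass, the
  quiescent state retains activity around 0.19 (`quiescent_activity()`
  solves the fixed point); the default threshold is 1.5 times that value,
  which separates quiescence (~0.2) from retrieval episodes (>= 0.26 in the
  reference regime) by a comfortable margin on both sides. An absolute
  near-zero cutoff would never fire.
* **Digitization**: an item is recalled when its overlap is the maximum over
  patterns and above `m_star = 0.5` for at least `min_dwell = tau2 / 4`;
  consecutive same-pattern events merge. Both thresholds are config-exposed;
  in the reference regime intrusion events peak at overlaps 0.6-0.9, so the
  digitized strings are robust to `m_star` in 0.4-0.6.
* **The `2L - h` budget** is a single automaton consuming events while fewer
  than `2L - h` have been consumed (`h` = distinct correct recalls so far,
  i.e. each novel recall grants one event back), optionally stopping at the
  first repeat-or-intrusion. It is the single source of truth for both
  `m_r_budgeted()` and `m_corr_budgeted()`. Note that with the
  stop-at-violation rule every consumed event is a novel correct recall, so
  the budget only binds once all `L` items are recalled: the budgeted
  error-limited count coincides with `m_corr()` on any sequence that ends in
  a violation.
* **Mutual information** is the plug-in estimator in bits with `0 log 0 = 0`
  and no bias correction; pairs never straddle sequence boundaries; the
  normalizing entropy uses the pooled item distribution. Plug-in bias makes
  `I(z)/H` positive even for independent draws, at order
  `(K-1)^2 / (2 n ln 2)`.
* **Ties** in the digitizer's argmax resolve to the lowest pattern index;
  off-diagonal ties in greedy-similarity matrices are broken by a
  deterministic jitter of 1e-12.
* **Seeding**: one root seed spawns separate sub-seeds for patterns,
  connectivity and item selection, so each component is independently
  reproducible; the dynamics themselves are deterministic — the apparent
  stochasticity of latching comes entirely from the quenched randomness of
  patterns and graph.

## Design decisions on open points

* "Number of updates" is read as full-network updates (one Euler step).
* The initial state sets `r = theta = thetaA = thetaB = 0` with activations
  at their softmax equilibrium — a background-biased rest state.
* The deterministic greedy-similarity baseline moves to the most similar
  item *excluding the immediately preceding one* (waived at `L = 2`). A pure
  argmax over the others locks into a two-cycle between mutually most
  similar items within a couple of steps and cannot produce the observed
  square-root growth of loop sizes; the one-step exclusion is what the
  deterministic-recall models this baseline emulates actually use.
* Serial recall is scored by exact ordered prefix match
  (`serial_score()`); the softer per-transition reading is available as
  `serial_transition_accuracy()`. The capacity is the area under the
  proportion-correct curve with lengths 1 and 2 credited as perfect.
* "Repeated twice" in `m_i()` means an item's third occurrence; all metric
  counts exclude the event that triggers the stop.
* Instruction sampling grows sequences one item at a time uniformly over the
  admissible continuations (a constant number at each position, so the
  sequence distribution is uniform over the admissible set), rejecting
  duplicates, with a hard cap of 1e6 draws.

## Problem sizes used by the shipped experiments

The multi-seed sweeps (`recall_gain_curve()`) run the full reference network
(`N = 600`, `p = 200`) at 20 seeds per list length over
`L = 2, 4, ..., 128`, stopping each run at the first repeat-or-intrusion,
which decides the error-limited metrics; budget- and repetition-tolerant
metrics use longer runs (`mode = "full"`). Null-model and pattern-statistics
checks use 1e4 Monte-Carlo samples. The oracle tests run tiny networks
(`N <= 12`) against pure-R reference loops and quadruple-loop weight
enumerations.

## Known limitations

* The engine parameters not printed in the available text (`N`, `c_m`,
  `beta`, `U`, `tauA`, cue shape) are educated defaults from the prior
  literature. The qualitative recall structure is robust — the boost-induced
  gain `Delta M_corr` rises, peaks in the interior of the list-length scan
  and collapses under long-term-memory interference, and the error-limited
  capacity saturates at a few items — but the precise peak location and
  saturation level shift with these parameters: with the shipped defaults
  the peak sits one octave below, and the saturation level at roughly half,
  the reference simulations' values.
* Hierarchically correlated pattern ensembles, mean-field analyses of the
  phase boundaries, and spiking-level implementations are out of scope.
* The serial-recall experiment at full scale (80 instructions per length,
  lengths 3-10) is expensive; the shipped defaults run reduced instruction
  sets, and `serial_experiment()` exposes the full protocol.
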