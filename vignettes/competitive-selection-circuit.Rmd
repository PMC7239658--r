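---
title: "A canonical winner-take-all circuit for competitive selection: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A canonical winner-take-all circuit for competitive selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wtacircuit)
```

## The problem and the model

Competitive selection is the transformation of several simultaneously
represented options into a single choice. Its idealized description is the
winner-take-all (WTA) operation: given per-option "norms" `x_i` (the worth
of each option on a common scale — stimulus priority, subjective value,
degree of category membership), the option with the largest norm drives the
output and all others are set to zero. `ideal_wta()` implements that
operation exactly and serves as the ground-truth oracle throughout the
package.

The package's main object is a firing-rate circuit that *approximates* the
WTA operation with biologically meaningful parts. Each option owns a
channel of four units:

* an **input** unit — a linear relay that encodes the option's norm in the
  common currency of firing rate (clipped to `[0, r_max]`);
* an **inhibitory** unit (or, under a combinatorial code, a share of a
  smaller pool of multilobe inhibitory units);
* an optional **amplifier** unit, recurrently and strictly point-to-point
  coupled to the channel's output unit;
* an **output** unit, whose rate is the channel's vote.

Four motifs are independently toggleable in `network_config()`:

1. **Global feedforward inhibition** (`feedforward_inhibition`): each
   option's input drives inhibition onto the other options, implementing
   the `>` comparison. Each inhibitory unit's drive grows with its
   channel's norm, so representations come to reflect *relative* norms.
2. **Donut-like inhibition** (`donut`): the inhibitory drive of channel
   *i* projects to every channel *except i* (an exactly zero
   self-inhibition diagonal). This is what makes the selection boundary
   categorical: responses on the two sides of the boundary are driven
   apart rather than uniformly scaled, which is the only way to improve
   discriminability `d' = |Δmean| / sqrt(mean variance)` — uniform gain
   cancels out of d'.
3. **Feedback inhibition among options** (`feedback_inhibition`),
   implemented as direct reciprocal inhibition between inhibitory units of
   distinct channels. This makes the boundary *flexible*: the
   inhibitory layer runs its own WTA, so whichever option is currently
   strongest silences the inhibition directed at itself, and the
   transition point of a competitor-strength response profile tracks the
   preferred option's norm instead of sitting at a hardwired value.
4. **Recurrent amplification** (`amplifiers`) plus the
   `inhibition_gain_multiplier` knob: high-gain inhibition drives losing
   options far below the functional output threshold, and the
   winner-selective recurrent loop lifts the winner far above it, yielding
   a unitary, first-to-threshold choice (`first_threshold_crossing()`).

The indirect feedback variants (feedback routed through intermediate
excitatory units) are not implemented; the direct reciprocal form is the
most efficient implementation and is the one documented in the avian
midbrain. Amplifier units do **not** project to the inhibitory layer (the
anatomical evidence is ambiguous on this edge; we default to "no" — see
*Known limitations* for a measurable consequence of this choice).

## Dynamics and numerical choices

All non-input units obey the leaky rate equation
`tau * dr/dt = -r + f(total input)` with `tau = 10` ms, integrated by
explicit Euler at `dt = 0.1` ms (halving `dt` moves steady states by far
less than 1%, which the test suite checks). The nonlinearity is a logistic
sigmoid with `threshold = 15`, `slope = 3`, `r_max = 100` spikes/s,
shifted and rescaled so that `f(0) = 0` exactly and `f(u) = 0` for
`u <= 0`; rates therefore live in `[0, r_max]` at every step and the
all-zero state is the exact fixed point of an unstimulated network.

Noise is an independent Gaussian perturbation of every unit's input at
every step. `sigma0` (default 0.5 a.u.) is expressed at 1 ms resolution;
per-step draws are scaled by `1/sqrt(dt)` so the effective noise level does
not depend on the integration step. The `sqrt-mean` option scales the sd
with the square root of the momentary drive (rate-scaled variability).

When several inhibitory units converge on one target, their contributions
`s_k = w_k r_k` are combined by `combination_rule` before entering the
target's input: `linear` (sum), `max`, or the default `softmax-weighted`
average `sum_k s_k exp(beta s_k) / sum_j exp(beta s_j)` — a smooth,
max-dominated combination (the combination of inhibition from multiple
options is believed to be nonlinear). Only units that actually project to
the target enter the weights; `combination_beta` (default 0.5) sets the
sharpness and is exposed in the configuration because the rule's name alone
does not fix it.

### Default gains

Defaults were calibrated once, before the test suite was frozen, so that
competitive inhibition is comparable in magnitude to stimulus drive over
the working norm range (~0–20 a.u.) — the regime in which the motif-level
arguments apply — and were not revisited afterwards:

| parameter | value | role |
|---|---|---|
| `w_in` | 1 | input → output drive (norms map 1:1 onto drive) |
| `w_ei` | 3 | input → inhibitory drive (inhibitory units saturate above the working range, making the feedforward-only boundary inflexible) |
| `w_ie` | 0.2 | inhibitory → output (max inhibition ≈ 20, comparable to drive) |
| `w_ii` | 0.5 | reciprocal inhibition of inhibition (strong enough that the symmetric inhibitory state is unstable: a winner emerges) |
| `w_amp` | 0.4 | output ↔ amplifier loop |
| `w_ia` | 0.45 | inhibitory → amplifier (losers' amplifiers are shut down) |
| `sigma0` | 0.5 | trial-to-trial variability of window-averaged rates ≈ 0.3–0.5 spikes/s |

With these values the recurrent amplifier loop has an ignition boundary
near a norm of ~8.7: below it responses are graded in the norm, above it
the winner's loop ignites and saturates. The assays are placed
deliberately with respect to this boundary: response-profile and
flexibility assays run below it (graded regime), the unitary-choice assay
at norm 10 rides the ignition, which is precisely the amplifier's job —
without amplifiers the winner of a (10, 2) competition plateaus near 15
spikes/s and never reaches a 50 spikes/s functional threshold.

## The assays

`measure_crp()` presents a preferred option A at a fixed norm together
with a competitor B swept from below to above A's norm and summarizes the
probed channel's output in the final 50 ms of the stimulus epoch (a
steady-state proxy). All assays derive per-condition RNG streams from one
master seed (`spawn_seeds()`), so interleaved conditions are matched
trial-for-trial.

**Categorization index.** The source framework names the index but defers
its formula, asking only that it account for response variability. We
define it over *adjacent* competitor-norm pairs: with d' computed for each
adjacent pair, `CatI = (mean d' of pairs straddling the boundary − mean d'
of within-side pairs) / (sum of the two)`, boundary at competitor norm =
`norm_A`. The adjacent-pair form is forced by the two calibration cases we
require: a perfect step with equal variances gives exactly 1, and a linear
profile with equal spacing and variances gives exactly 0 (an all-pairs
variant violates the second case, because between-group separations are
systematically larger even for a linear profile). Two numerical guards
apply, both documented here because they affect degenerate profiles only:
window means below 0.01 spikes/s are treated as silence (a fully
suppressed channel's window mean is a decaying numerical residue whose
mean/sd ratio is meaningless), and a zero-variance pair is d' = 0 if its
means coincide, +Inf otherwise. A fully silent CRP therefore scores 0 —
"not distinguishable from zero categoricality", which is the expected
outcome for the donut-filled ablation.

**Transition norm.** The competitor norm at which the mean response
crosses the midpoint between its upper and lower plateaus, located by
linear interpolation between bracketing samples. The estimator is
assumption-light and exact on synthetic steps; on a finite competitor grid
its resolution is about one sample spacing, which is why the continuity
test allows a one-spacing tolerance for an infinitesimal change of
`norm_A`. A flat or out-of-range profile raises a classed error
(`wta_no_transition`) rather than returning a number.

**Flexibility assay.** Two CRPs at `norm_A` low/high under one seed
schedule; `shift_ratio = Δtransition / Δnorm_A`. With feedback the
inhibitory-layer WTA flips exactly where the competitor overtakes the
preferred option, so the ratio is ≈ 1. With feedback silenced the
transition is anchored by the inhibitory units' own saturating transfer
function — and, in the sub-ignition regime, by the exponential tail of the
output sigmoid, for which halving the response corresponds to a fixed
input decrement regardless of `norm_A` — so the ratio is ≈ 0 while the
response *reduction* in each curve survives, separating the two
predictions cleanly.

**Multi-option and unitary-choice assays.** `multi_option_assay()` scores
per-trial winners against the oracle and reports the winner's output as
distracters are added. In the full circuit the winner's output is *flat*
in the number of distracters: feedback inhibition silences the losing
options' inhibitory drives, which is exactly how the circuit avoids floor
effects (the winner is not washed out by inhibition from an increasing
number of options). The acceptance check of non-increase is run
noise-free, where that statement is deterministic.
`unitary_choice_assay()` runs noisy trials through the first-to-threshold
readout and reports `p_unitary` (exactly one channel ever crosses),
accuracy against the oracle, and reaction-time statistics; ties at a
crossing step are broken by rate then by lowest index, and the tie-break
used is recorded in the event.

## Combinatorial inhibitory codes

With one inhibitory unit per channel ("copy-and-paste") the circuit grows
linearly in units and quadratically in pairwise wiring. `cosmi_code()`
describes the alternative: few inhibitory units with multilobe receptive
fields, each projecting (donut-wise) to the complement of its RF. A code
is usable iff for every ordered pair (i, j) some unit is driven by i and
projects to j; `coverage_ok()` checks this and `build_network()` refuses
non-covering codes with a diagnostic naming an uncovered pair.

Costs follow the stated model: metabolic = total RF membership count
(single-stimulus activity model), wiring = one input edge per lobe plus
one projection edge per inhibited channel (so each unit contributes
exactly `L` edges); `total = alpha * metabolic + beta * wiring` with
`alpha = beta = 1` by default (no weights are prescribed by the source
framework). Inhibitory–inhibitory feedback wiring is *not* costed; costing
it would only further favour small codes.

`search_min_cost_code()`'s exhaustive mode is exact. It rests on a
reformulation proved in the test suite by brute force: coverage holds iff
the channels' *incidence vectors* (which units each channel drives) form
an antichain of distinct non-empty subsets of the unit set, and the cost
decomposes as `alpha * (total incidence weight) + beta * L * n_units`.
Minimum-weight antichains are found by branch-and-bound. Two consequences
are worth noting. First, by Sperner's theorem no covered code for 4
channels exists with only 3 units — the search reports explicit
infeasibility, as does the literal enumeration oracle. Second, for 6
channels the optimum is the classic 4-unit arrangement with 3-lobe
receptive fields (cost 36 vs. 42 for copy-and-paste): sparse multilobe
inhibitory units are cheaper than one unit per channel once `L` exceeds 4.

## What the synthetic world does and does not establish

All inputs are synthetic: `make_norm_protocol()` generates the norm
vectors (CRP grids, multi-option sets with controlled top-two gaps,
single-option sweeps), and the network is the model itself — there is no
external data. A green test therefore establishes that the *circuit
mechanisms* produce the predicted behavioural signatures under the stated
dynamics, noise model and calibrated gains; it says nothing about whether
a particular brain area implements them, and it does not emulate
unmodelled features of real recordings (rate adaptation, correlated noise
across units, spiking discreteness, multi-area routing).

## Known limitations

* **Amplifier perturbation of the weaker option.** Because amplifiers do
  not feed the inhibitory layer, the identity of the winner is decided in
  the inhibitory WTA, which amplifier gain cannot influence; and a fully
  suppressed loser sits at exactly zero rate, so its (donut-inhibited)
  recurrent loop cannot bootstrap. Boosting the weaker option's amplifier
  with `set_amplifier_gain()` therefore leaves selection unchanged up to
  roughly 6× and then flips it abruptly by noise-driven self-ignition of
  the boosted loop, with *shorter* — not longer — reaction times. The
  prediction that such a boost raises the weaker option's selection
  probability holds in this regime; the predicted reaction-time slowing
  does not, and we report that divergence rather than tune it away. A
  variant in which amplifiers drive the inhibitory units would likely
  restore it and is a natural extension.
* **Hard winner-take-all at default gains.** Losing options are driven to
  (numerically) zero rather than to a graded sub-threshold level; the
  "soft WTA" regime can be reached by lowering `w_ie`/`w_ii` but is not
  the calibrated default.
* **Degenerate ablations.** Filling the donut completely
  (`add_self_inhibition(net, 1)`) silences the probed channel across the
  whole sweep at default gains — an extreme but valid reading of "far less
  categorical" (CatI = 0). Partial fractions (0.3–0.5) give graded,
  non-silent ablations.
* The functional output threshold is a fixed assay parameter, not a
  dynamic quantity; urgency signals, learned/plastic weights, spiking
  neurons, circular feature spaces and multi-area implementations are out
  of scope.

## A worked example

```{r example, eval = FALSE}
net <- build_network(network_config(n_channels = 2))

steady_state(net, c(10, 2))$output   # winner saturates, loser silenced
#> [1] 99.99669  0.00000

crp <- measure_crp(net, norm_A = 7, competitor_norms = 2:12,
                   n_trials = 50, seed = 1)
categorization_index(crp)            # ~0.88: step-like boundary
transition_norm(crp)                 # ~7: boundary sits at the winner's norm

fx <- flexibility_assay(net, 5, 7, competitor_norms = 1:12,
                        n_trials = 20, seed = 1)
fx$shift_ratio                       # ~1 with feedback on
flexibility_assay(silence_feedback(net), 5, 7, 1:12, 20, 1)$shift_ratio
                                     # ~0 with feedback silenced

unitary_choice_assay(net, c(10, 2), threshold = 50, n_trials = 200,
                     seed = 1)       # p_unitary = 1, accuracy = 1
```

The numbers these calls print are the ones the acceptance suite
(`tests/testthat/test-acceptance.R`) recomputes and checks.
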