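---
title: "Symbolic neural dynamics and the sense-react machine: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symbolic neural dynamics and the sense-react machine: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virtcog)
```

## The model

`virtcog` simulates cognition on a virtual neurological substrate rather
than on a numerical neural network. The basic unit is a **thread**, an
abstraction of a neuron or a cluster of neurons, declared with a symbolic
pattern such as `see(obj(Q,X+1))`. Threads are grouped into disjoint
**streams** (neural assemblies); integer **weights** attach to pairs of
threads that communicate within a stream, and a signal passes from a sender
to a receiver only while the weight meets a threshold (default
$\theta = 1$) and the pathway is not `BLOCKED`. Communication is
asynchronous and message-based: incoming signals are processed
individually, never summed into a membrane potential, which is a deliberate
departure from integrate-and-fire models. There are no continuous dynamics,
no spike waveforms, and no stochastic synapses anywhere in the machine.

Circuits written in a small line-oriented language (`.vcir`; see
`parse_circuit()`) are **compiled** into ordered *virtual-code
implications*: guard patterns over the currently active thread instances
paired with one or more virtual-machine instructions (fire, send, adjust a
weight, store or retrieve a trace, push or pop a FIFO memory, emit an
effector action). The interpreter repeats a **sense-react** cycle: `sense`
fires every sensor whose pattern unifies with an arriving stimulus; `react`
performs *contextual deduction* — the `ist` ("is true") predicate matches
freshened guards against the current instances — and applies the deduced
instructions, repeating deduce-apply-deliver passes within the cycle until
a fixpoint. Whatever state the machine is in at any time is acceptable;
there is no designated final state.

Terms are first order: atoms, integers on a one-dimensional spatial axis,
named variables (`X`), anonymous variables (`_`, pairwise distinct),
compounds, and the single arithmetic form `X+k` which is evaluated eagerly
(and solved backwards when matched against an integer). The applied
notation `P(X)` for "image P at position X" is represented as the compound
`obj(P, X)`, and a box `F` containing `I` at `X` as `box(F, I, X)`; this
keeps unification standard and decidable. There is no occurs-check —
circuit guards are shallow and the circuit language cannot build cyclic
terms — but term resolution guards against reference cycles so that even
adversarial programmatic input cannot crash it.

## Plasticity

Synaptic change is abstracted into protocol threads operating on the weight
table:

* **STP** (short-term potentiation) raises a pathway to the threshold for a
  fixed number of cycles (default 1), then restores it.
* **LTP** is a coincidence detector: the potentiated sender posts a *merge*
  when it fires, the modulating trigger spawns a *join*, and when the two
  lie within the **coincidence window** the weight of the sender-receiver
  edge is incremented by 1. **Weak** plasticity freezes the pathway to the
  ground instance of its first potentiation — later activations replay that
  instance and rebinding attempts are refused — while **strong** plasticity
  rebinds on every activation. The distinction mirrors anonymous versus
  named logical variables: a weakly potentiated pathway behaves like a rule
  whose variables were consumed by their first binding. The mode is a run
  configuration, not a circuit property, so one circuit can be run at two
  maturation levels.
* **LTD** decrements a weight (floor 0); **LTB** blocks an edge permanently
  (`BLOCKED` is absorbing: no potentiation, depression or STP restores it).
* **LTS/LTR** implement the associative memory: `lts` appends a ground
  trace `{P}` to a store that never decays; `ltr(P,Q,R)`, fired by a cue
  thread `Q`, scans the store newest-first for a trace unifying with `P`,
  increments the `Q`-to-`R` weight and fires `R` with the retrieval
  bindings. Retrieval is non-destructive, allowing repeated image-driven
  searches, and is the only mechanism relating threads of *different*
  streams — which is what distinguishes a remembered relation from a wired
  reflex.
* **Short-term memories** `<t>` are per-tag FIFO queues of ground terms;
  entries persist until consumed and popping an empty queue is an empty
  marker, not an error.

## Tunable parameters

| parameter | unit | default | role |
|---|---|---|---|
| `threshold` | weight units | 1 | minimum weight for delivery; "open at start" edges initialize at 1, "closed" at 0 |
| `signal_ttl` | cycles | 1 | undelivered signals expire after this many extra cycles |
| `coincidence_window` | cycles | 1 | tolerance \|t~join~ − t~merge~\| for LTP |
| `stp_duration` | cycles | 1 | default STP opening |
| `pass_limit` | react passes | 8 | guard against pathological circuits; exceeding it flags truncation, never throws |
| `mode` | — | `strong` | weak/strong LTP semantics |

LTP/LTD deltas are fixed at ±1: the substrate is deliberately the smallest
integer system realizing "open" versus "closed" pathways. The conditioning
and tracking experiments run at the default window of 1 cycle (the paired
stimuli are adjacent). The two box experiments run at a window of 8 cycles
because their reinforcement is trial-level: the `excite` signal following a
successful grasp arrives several cycles after the `watch` thread fired, and
the eligibility of that association spans the trial. Node activations carry
a `ttl` (default 1 cycle); sustained-attention nodes — the tracking
expectation (2 cycles) and the trial-long `watch` (8 cycles) — stay active
longer so that same-cycle conjunction semantics still realize the
coincidences the behavior requires. These values were fixed when the
circuits were designed and are part of the model, not fitting knobs.

## Semantics decisions

Several points the informal protocol descriptions leave open were resolved
as follows (they are visible in traces, so they are documented here):

* **Fixpoint react with snapshotting.** Each react pass computes `ist` over
  the pre-pass snapshot, applies the deduced instructions in rule order,
  then drains weight-gated deliveries; passes repeat until nothing new
  happens. A (implication, guard-facts, binding) triple applies at most
  once per run, so an instance that stays active several cycles does not
  re-fire the same rule, while one fact may feed any number of *different*
  implications (divergence).
* **Choice order.** Converging `+` alternatives resolve deterministically
  by declaration order; the first alternative whose gate passes (weight,
  blockedness, retrieval success) consumes the choice for the cycle. This
  is what lets the covered-box circuit fall back from "open the box"
  (blocked after the empty opening) to "search the remembered screen"
  without any stochastic arbitration.
* **Conjunction** requires all in-signals within the same cycle, with
  positions linked by shared variables; each in-edge is separately
  weight-gated, so a single conjunction can mix learned and innate inputs
  (the practical-learning gate of the box experiments is exactly an LTP'd
  in-edge of a conjunction).
* **Firing is idempotent** per (template, instance, cycle), and sensors
  fire for every matching stimulus; unknown stimuli are dropped and logged.
* **Variable scoping.** Guards within one implication share variables;
  distinct implications never do (each deduction starts from an empty
  substitution over ground facts, which is equivalent to freshening each
  rule instance).
* **Traces are canonical**: generated fresh names are renamed `v1, v2, ...`
  in first-appearance order, so independently produced traces compare
  byte-for-byte. The machine contains no randomness, and the determinism of
  every bundled experiment is asserted in the test suite.

## The synthetic world

The `world` module is the data generator: a one-dimensional axis with
movable objects, occluding screens and coverable boxes. Scenario scripts
are timed stimulus schedules (`move`, `see`, `halt`, `stop`, `view`,
`open`, `close`, `spot`, `cs`/`us`, `excite`/`inhibit`) plus world
mutations; the experimenter's covert manipulations (emptying a box under a
screen) are mutations *without* stimuli — that is precisely what makes a
displacement invisible to the simulated subject. Effector actions feed back
as stimuli with a latency of exactly one cycle: a search at a hiding screen
uncovers the object (`view`), a search at an empty place reports
`spot(...empty...)`, opening a box reports its content, and a successful
grasp can emit an `excite` reinforcement. Motion advances one position per
scripted step (`X+1`), matching the saccade convention of the tracking
circuit; the exact inter-event spacing of the scripts is a modeling choice
(1 cycle) and is fixed in `make_scenario()`.

What the generator does *not* emulate is worth stating: no perceptual
noise, no 2-D or 3-D space, no physics, no timing jitter, no competing
objects, and reinforcement is a single deterministic `excite`/`inhibit`
token. Passing experiments therefore show that the circuits realize the
*qualitative* behavioral signatures (which search happens, where, in what
order) under clean inputs — not that the mechanism is robust to noisy
perception or that it fits infant reaction-time or error-rate data.

## The simulated experiments

Seven bundled experiments exercise the framework end to end
(`list_experiments()`):

1. **aplysia** — classical conditioning: 2 paired `cs`-`us` presentations
   within the window potentiate the `cs` pathway; a lone `cs` then drives
   `motor(cs)`; unpaired schedules never potentiate.
2. **operant** — disinhibition learning: after one `excite` reinforcement
   the repeat presentation deterministically yields `accept(I)` and the
   watch-to-spot path is LTD-closed (after `inhibit`, `reject(I)`).
3. **grasp** (substages 1–2) — object and hand in the same visual field,
   same cycle, drive `grasp(obj(P,X))`; a position or cycle mismatch drives
   nothing.
4. **track** (substage 3) — a visible halt while tracking drives a grasp at
   the anticipated position `X+1`; an occlusion drives a look at the
   occluder.
5. **anotb** (substage 4) — hiding at one screen and then another: the weak
   run searches the first screen again (the A-not-B error), the strong run
   follows the displacement; the two traces are identical up to the refused
   rebinding.
6. **obs55** (substage 5) — the box-under-screen apprenticeship: box-only
   search in phase I (twice, the default repetition count for "after a few
   repetitions"), immediate screen search and grasp in phase II whose
   success reinforces the watch-gated recall, and in phase III box search,
   failure, then the corrected screen search. A naive model run on the
   phase-III protocol alone never searches the screen
   (`params = list(phase3_only = TRUE)`).
7. **obs64** (substage 6) — the covered box: watching the object boxed and
   covered stores `{image(box(F,I,X))}`; at the stop a retrieval drives the
   box opening; the empty opening triggers an LTB that blocks all later
   openings; retrievals then drive searches from the FIFO memory of passed
   screens, in passing order, across phases Ia/Ib/II.

The sensory-motor circuits form a strict extension chain (each later
circuit contains the previous one's nodes and edges), mirroring the idea
that each substage differentiates the previous schema rather than replacing
it. Two simplifications are inherited from the observation protocols
themselves: the box-opening details of observation 55 are ignored (the box
there is open), and a box search that finds content reports the uncovered
object directly as a `view` stimulus rather than a separate spotting step.
In observation 64 the operant sub-circuit inherited from observation 55 is
present but quiescent (its reinforcement rule is not part of the obs64
feedback set): the substage-6 subject's box behavior is representation-
driven, not apprenticeship-driven.

## Numerical and degenerate-input behavior

Everything is integer and symbolic; there are no tolerances. Unification
failure is a value, not an exception, including arity mismatches. Degenerate
inputs are handled without raising: sub-threshold signals stay queued until
they expire; sends from dormant threads, adjustments of blocked edges,
non-ground storage attempts from compiled rules, and pops of empty memories
are logged no-ops; the react pass limit and the cycle bound flag truncation
in the trace. Hard errors are reserved for malformed programs: unknown
templates, invalid circuits (undeclared endpoints, cross-stream edges,
modulation of a non-synapse, range-restriction violations), and unparseable
terms, all reported with line numbers at parse/validation time.

## Problem sizes

The bundled experiments run in well under a second each (tens of cycles,
at most ~40 implications). The property suites use 250 random term pairs
for the unification oracle, 1000 random rule-base/fact-set cases for the
deduction oracle, and 20–30 randomized operation sequences of length 30–40
for the substrate invariants; these sizes give full coverage of the small
combinatorial space while keeping the whole test suite under half a minute.

## Known limitations

* Weak-mode potentiation requires a ground first instance; a weak
  potentiation whose payload still contains variables is refused and
  logged (the bundled circuits never produce one).
* The deduction engine is forward-chaining only: no backtracking over rule
  bodies and no negation-as-failure beyond guard non-match. Behavioral
  alternatives must be expressed with choice groups, as the tracking
  discrimination does.
* The world is single-subject and single-experimenter; there is no model of
  the experimenter's intentions, only their scripted manipulations.
* Golden traces are self-generated regression anchors, not external ground
  truth; the behavioral assertions quoted from the observation protocols
  are the real acceptance surface.
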