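# virtcog

Symbolic neural dynamics and a deterministic sense–react virtual machine
for simulating early sensory-motor cognitive development.

`virtcog` is for computational cognitive scientists who want to ground
developmental phenomena — reflexes, conditioning, object tracking, the
A-not-B search error, object permanence — in explicit, inspectable neural
mechanism without committing to numerical network dynamics. The substrate
is symbolic: **threads** (neurons or neuron clusters, declared as
first-order term patterns) grouped into disjoint **streams**, with integer
weights on communicating pairs. A signal from thread *P* to thread *Q* is
delivered only while *weight(P→Q) ≥ θ* and the pathway is not `BLOCKED`.
Plasticity is protocol-based:

* **STP** — transient opening of a pathway for a fixed number of cycles;
* **LTP** — coincidence detection by a join/merge synchronization,
  incrementing *weight(Q→R)* by 1; in **weak** mode the pathway binds to
  the ground instance of its first potentiation (anonymous-variable
  semantics — the mechanism behind the A-not-B error), in **strong** mode
  it rebinds on each activation;
* **LTD** / **LTB** — decrement (floor 0) / permanent absorbing block;
* **LTS/LTR** — an associative memory: ground traces `{P}` are stored and
  later retrieved by unification to relate a cue thread to a recall thread
  across streams;
* FIFO short-term memories `<t>` for remembering sequences of
  displacements in order.

Circuits written in a small text DSL (`.vcir`) are compiled into ordered
*virtual-code implications* (guard patterns ⇒ machine instruction); the
virtual machine realizes `run : I × L → L × O`, repeating a sense–react
cycle in which the `ist` predicate performs contextual deduction over the
currently active instances. A synthetic one-dimensional world (objects,
occluding screens, coverable boxes) closes the perception–action loop.
Everything is deterministic: identical runs produce byte-identical traces.

## Worked example: the A-not-B error and its correction

The substage-4 circuit tracks a toy, and when it disappears behind a
screen, a search pathway is potentiated by an LTP whose trigger is the
diversion of attention. The scenario hides the toy under screen `s1`
(position 3), lets the subject retrieve it, then hides it under `s2`
(position 5). Run at the two plasticity maturation levels:

```r
library(virtcog)

weak <- run_experiment("anotb", config = list(mode = "weak"))
weak$actions
#>   cycle            action
#> 1     3   look(obj(s1,3))
#> 2     4 search(obj(s1,3))
#> 3     5 grasp(obj(toy,3))
#> 4     7   look(obj(s2,5))
#> 5     8 search(obj(s1,3))

strong <- run_experiment("anotb", config = list(mode = "strong"))
strong$actions
#>   cycle            action
#> 1     3   look(obj(s1,3))
#> 2     4 search(obj(s1,3))
#> 3     5 grasp(obj(toy,3))
#> 4     7   look(obj(s2,5))
#> 5     8 search(obj(s2,5))
#> 6     9 grasp(obj(toy,5))
```

Both subjects look at the occluder and find the toy at `s1`. After the
visible displacement to `s2`, the weak subject searches position 3 again —
the A-not-B error: its search pathway replays the frozen first instance
`search(obj(s1,3))` and refuses to rebind — while the strong subject
rebinds and searches position 5, where it grasps the toy. The two traces
are identical up to the refused rebinding (`compare_traces(weak$model,
strong$model)` reports the divergence point).

The other bundled experiments (`list_experiments()`) cover classical
conditioning, operant disinhibition learning, the grasping reflex, visual
tracking, and the two box-and-screen observation protocols of substages 5
and 6 (practical apprenticeship; image storage, blocked box reopening, and
FIFO-ordered two-screen search). A thin CLI wraps the same functions:

```sh
Rscript scripts/virtcog.R run-experiment anotb --plasticity strong
Rscript scripts/virtcog.R gen-scenario anotb --out anotb.yaml
Rscript scripts/virtcog.R run --circuit inst/extdata/circuits/searching.vcir \
        --script anotb.yaml --plasticity weak
```

## Package layout

* `R/terms.R` — first-order term algebra: parsing, printing, unification
  with named/anonymous variables and `X+k` position arithmetic.
* `R/model.R` — the substrate: templates, instances, weight table,
  signal queue, join/merge coincidence, plasticity protocols, stores.
* `R/compiler.R` — the `.vcir` DSL, validation, compilation to
  implications.
* `R/vm.R` — `ist`, the sense–react loop, traces and trace comparison.
* `R/world.R` — the synthetic 1-D world, mutations, feedback rules,
  scenario scripts (YAML round-trip).
* `R/experiments.R` — the bundled experiments, behavioral assertions,
  golden-trace regression.
* `inst/extdata/circuits/*.vcir` — the seven circuit sources.
* `vignettes/virtcog-methods.Rmd` — the model, its parameters and the
  design decisions, in detail.
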