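---
title: "The segmented attractor network: model, behaviors, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The segmented attractor network: model, behaviors, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sanet)
```

## The model

A segmented attractor network (SAN) stores high-level categorical
memories. Information is partitioned into $n$ *sets* (categories such as
"first name" or "state"); each set $i$ holds $M_i$ distinct *features*,
and each feature is one neuron, giving $N = \sum_i M_i$ neurons in a
single recurrently connected layer. A *memory* is one feature per set.
Neurons within a set are never connected — the weight grid has empty
diagonal blocks — so associations always relate information *across*
categories.

At any analysis step, each neuron's output is

$$ f = E + W^\top f^{*}, $$

where $E$ is the external input vector (entries $0$ or $|E| = 1$), $W$ is
the $N \times N$ weight grid indexed (pre-synaptic, post-synaptic), and
$f^{*}$ is the previous output state, initialized to $E$. Storing a
memory is binary Hebbian programming: every ordered cross-set pair of the
memory's features has its weight set to $v_{ON}$ (default $0.001$).
Because $v_{ON} \ll |E| / N$, recurrent feedback can never reach the
magnitude of external input, so clamped input is always trusted as
correct.

Recall is pattern completion: external input is applied to the memory's
features in only $k$ of the $n$ sets (default $k = n/2$), outputs are
computed, and each set's winner is the feature with the strictly
positive, unique maximum output. A set whose outputs are all zero yields
a "none" sentinel and is ignored. If a set's maximum is tied, one tied
feature is chosen uniformly at random, clamped with external input, and
the network is re-analyzed; clamps persist for the rest of the trial. A
trial is a *hit* only when all $n$ winners reproduce the queried memory
exactly.

### Settling semantics

The output equation is recurrent, but the recall procedure it belongs to
is an analyze → clamp → re-analyze loop. We therefore define the output
of one analysis as a *single* synchronous pass $f = E + W^\top E$,
recomputed from scratch after every tie-breaking clamp. This matches the
described procedure, keeps feedback bounded, and makes the
neuron-by-neuron reference implementation (used in the oracle tests)
well-defined. Whether the original implementation iterates the equation
to a fixed point is not documented; multi-pass settling is exposed as the
`passes` argument of `compute_outputs()` (default 1) rather than guessed.

### Tie handling details

Sets are examined in schema order and only the *first* tied set is
resolved per iteration, after which outputs are recomputed; fixed order
makes runs reproducible given the tie-breaking seed. Ties among
zero-output features never attract a clamp (an all-zero set is ignored).
Each iteration clamps a previously unclamped neuron, so a trial
terminates after at most $N$ iterations. Two outputs count as tied when
they agree to within $10^{-12}$ relative tolerance: weights are common
multiples of $v_{ON}$ (possibly decayed by identical factors), so true
ties are bit-equal in practice and the tolerance only guards accumulated
floating error; genuinely distinct feedback levels differ by at least one
unit of $v_{ON}$, many orders of magnitude above it.

## Learning behaviors

Three cognitively inspired rules extend the baseline, applied each time
step in the order: **forgetting → associate → predictive → erase**. The
behaviors live inside the association phase of the simulation loop;
decaying *before* associating guarantees the step's own memory is stored
at full strength during that step's evaluation, and the predictive sweep
uses feedback produced by prior memories (association only touches
weights among the clamped features, so the order of the middle two steps
cannot change the predictive trigger computation).

* **Predictive** (`p_th_von`, default 6): during an association, any
  neuron *not* receiving external input whose output (equal to its
  feedback) reaches $P_{th}$ associates itself, both directions at
  $v_{ON}$, with every clamped cross-set feature. With threshold
  $6\,v_{ON}$ this fires when six or more of the stored memory's features
  already connect to the bystander. The sweep is single and
  non-cascading — freshly created weights cannot trigger further neurons
  within the same association — because cascade semantics are not
  documented for the original model; the choice is logged here and the
  per-step prediction count is recorded.
* **Erase / consolidation** (`r_th_von`, default 400): a neuron whose
  incoming weight sum reaches $R_{th}$ is a "commonly recurring feature"
  and has all its pre- and post-synaptic weights reset to zero (not
  pruned — they can be re-programmed). All neurons are judged against a
  snapshot of the sums taken before any zeroing, so simultaneous
  over-threshold neurons are all erased. If a feature's similarity
  frequency $f_{sim}$ (fraction of memories carrying it) is known,
  `erase_threshold_from_similarity()` sizes the threshold as
  $R_{th} = I_{tot} \cdot f_{sim} \cdot v_{ON}$, erasing the feature
  exactly when all of its occurrences have been stored. The erase check
  runs once per time step, after the association (the alternative — after
  every weight write — is not documented for the original model).
* **Forgetting** (`d_rate`, default 0.015): every weight decays by
  $w \leftarrow w(1 - D_{rate})$ once per step, so an untouched weight
  follows $v_{ON}(1 - D_{rate})^t$ exactly. Re-association restores a
  decayed weight to full $v_{ON}$, which is what lets weakened memories
  re-emerge when similar newer memories arrive (ecphory). The degenerate
  value $D_{rate} = 1$ is accepted for diagnostic runs even though the
  configured range is nominally $[0, 1)$: it isolates the newest memory
  each step and produces the diagonal-only occurrence matrix used as an
  exact regression target.

Thresholds are configured in multiples of $v_{ON}$ (the field's idiom,
"$6\,v_{ON}$", "$400\,v_{ON}$") and converted internally.

## The simulation loop

`run_simulation()` implements the five-phase lifelong-learning protocol:
one-time setup (network initialization, a seeded random permutation of
all $I_{tot}$ memories), then per step $t$: behaviors + association of
the $t$-th memory, followed by a full evaluation — every memory shown so
far is recalled under every one of the $\binom{n}{k}$ input-set
combinations — and metric logging. Evaluation is strictly read-only:
recall clamps live on a scratch input vector, never on the weights.

Three metrics are logged:

* **Hit-rate surface** over (step, combination), with combinations
  ordered by $U_{avg}$, the mean *U-factor* $U_i = M_i / I_{tot}$ of the
  input sets. Combinations sharing the same $U_{avg}$ are kept as
  distinct rows (lossless; ties broken lexicographically).
* **Unique memory ratio (UMR)**: the number of distinct dataset memories
  recalled at least once during the step's evaluation — whether or not
  they were the queried memory, and whether or not they have been shown
  yet — divided by the number shown so far. Computed per step from
  scratch, not cumulatively; it can exceed 1 when unshown memories are
  recalled by chance.
* **Occurrence matrix**: per-memory, per-step recall counts, indexed by
  presentation order so introductions form the matrix diagonal.

A full-size run is $\binom{8}{4} \cdot I_{tot}(I_{tot}+1)/2 \approx
17.2$M recall trials for 700 memories, which motivates two engineering
escape hatches: `eval_every` (evaluate every $j$-th step; default 1, the
protocol's cadence) and a batched evaluation engine. The batched engine
computes all of one memory's combinations from a pre-multiplied slice of
the weight grid and falls back to the scalar tie-resolution procedure
only for trials with first-pass ties, in trial order, so its results —
including the random tie draws — are *bit-identical* to the
trial-by-trial reference; the test suite asserts this identity on
randomized small instances rather than trusting it.

Two independent seeds control a run: `seed_sequence` fixes the memory
presentation order and `seed_ties` the tie-break draws, so enabling a
behavior never perturbs which memories arrive when.

## The synthetic generator

The deposited 700-leader dataset this model was studied on cannot be
bundled here, so `generate_synthetic()` creates datasets with the
statistical structure the experiments depend on: per set, the realized
distinct-feature count equals `target_m[i]` *exactly* (each target
feature appears at least once, remaining rows drawn uniformly), and each
planted common feature occurs in exactly `round(f_sim * i_tot)` memories.
`ehos_like_spec()` reproduces the reference uniqueness profile
(per-set counts 328, 190, 29, 22, 24, 117, 9, 59 over 700 memories, 778
neurons); for scaled-down runs the counts are scaled proportionally with
a floor of one feature, because the full-size counts exceed small
$I_{tot}$ — this preserves the U-factor profile, which is the quantity
the hit-rate analysis is stratified by.

Two deliberate deviations from the simplest construction are worth
recording. First, each set's column is shuffled *independently*; a single
joint row shuffle would leave strong cross-set correlations from the
deterministic assignment prefix. The generator therefore treats sets as
independent — real data has cross-set dependencies (rulers' states and
dynasties co-vary) that it does not emulate, and nothing here
characterizes them. Second, planted features are built into the column
construction rather than overwriting sampled values afterwards, because
overwriting could silently delete some other feature's last occurrence
and break the exact-uniqueness invariant.

What a green synthetic test establishes, then, is that the machinery is
correct on data with the right *uniqueness profile* and a high mean
pairwise Hamming distance (the generated full-size profile gives ~7.7 of
8; the real dataset's printed value is 7.19 — real label distributions
are more skewed than the near-uniform sampling here). It does not
establish the deposited dataset's exact end-of-run numbers, which also
depend on its label frequencies and cross-set structure;
`scripts/reproduce_ehos.R` runs that reproduction when the CSV is
supplied.

## Numerical and design choices

* All output computations funnel through one accumulation routine
  (active pre-synaptic rows summed in ascending neuron order), so scalar
  recall, batched evaluation and the exported `compute_outputs()` agree
  bit for bit.
* Feature indices are assigned by first appearance in file order, cell
  values are whitespace-trimmed and compared case-sensitively, and every
  constructed dataset is canonicalized to that indexing, making CSV
  round-trips exact. Numeric-looking columns (reign years, centuries)
  stay categorical labels.
* `d_rate = 1` and `eval_every > 1` are documented deviations from the
  nominal protocol, available for diagnostics and desk-scale work.
* Memory lookup during evaluation matches full feature vectors only;
  readouts containing a sentinel never match any memory. If a dataset
  contains duplicated memories, occurrences are attributed to the first
  matching row.

## Limitations

* The original study's fixed random presentation sequence is not
  published, so its exact trajectories (e.g. a specific prediction count)
  cannot be replayed; all reproductions are statistical across seeds.
* No continuous-attractor dynamics, graded Hebbian increments, weight
  values outside $\{0, \dots, v_{ON}\}$ (decayed), memristive hardware
  modelling, or cross-benchmark comparison metrics.
* The per-step evaluation cost grows linearly in $t$, so full-protocol
  runs are quadratic in dataset size; beyond ~$10^3$ memories use
  `eval_every` or expect long runtimes.
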