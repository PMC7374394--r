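---
title: "Harmony Search hyperparameter optimization for 1D CNN respiration pattern recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmony Search hyperparameter optimization for 1D CNN respiration pattern recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Non-contact respiration monitoring (for example with an ultra-wideband
impulse radar pointed at a sleeping person's chest) produces a 1-D
displacement signal whose shape distinguishes clinically meaningful
breathing patterns: **eupnea** (normal breathing, 15–20 breaths/min),
**bradypnea** (slow and shallow, ≤ 12 breaths/min), **tachypnea** (rapid and
shallow, ≥ 20 breaths/min), **apnea** (airflow reduced by more than 90% of
the person's normal depth) and **movement** (body motion overwhelming the
respiratory oscillation). A small 1-D convolutional neural network
classifies fixed-length signal *pieces* (10 s segments) into these five
classes.

The recognition rate of such a network depends strongly on a handful of
discrete architecture hyperparameters: the kernel size `ks^d` and kernel
count `kc^d` of each of the `cld` convolutional layers, and the widths
`dlnc^1, dlnc^2` of the two dense layers (the dense part is always two
layers, whatever the convolution depth). Over realistic ranges — odd kernel
sizes 3–81, kernel counts 16–1024, dense widths 256–4096, three conv layers
— the space holds

$$ 40^3 \times 1009^3 \times 3841^2 \;=\; 969{,}933{,}784{,}923{,}190{,}336{,}000 \;\approx\; 9.69934\times10^{20} $$

architectures, far beyond any grid. Conventional grid tuning predetermines
a few values per axis and still needs millions of trainings; this package
instead searches the space with the **Harmony Search (HS)** metaheuristic,
treating the validation recognition rate $R$ (percent correct) as the
objective to maximize.

## The optimizer

HS maintains a **harmony memory** (HM): the `hms` best architectures found
so far, each paired with its recognition rate and kept sorted by rate
descending. Each iteration proposes one new architecture:

* with probability **HMCR** (harmony memory considering ratio) a stored
  architecture is recalled uniformly from HM;
  * with probability **PAR** (pitch adjusting ratio) *every* coordinate of
    the recalled vector is then perturbed by a step drawn uniformly from the
    signed steps of magnitude at most **MPAP** (maximum pitch adjustment
    proportion), otherwise the recall is proposed unchanged;
* with probability 1 − HMCR a uniformly random architecture is drawn.

The proposal is trained and scored; if its rate strictly exceeds the worst
stored rate, it replaces the worst entry and HM is re-sorted. A run stops at
the iteration budget, or early once the best entry has not improved for `k`
consecutive iterations (the stagnation counter ΔI is the number of
iterations since the last best-update, with the interval origin at
iteration 0).

Defaults follow the full-scale study protocol: `hms = 1000`, HMCR sampled
from {0.50, 0.55, 0.60, 0.65, 0.70}, PAR from {0.60, …, 0.80}, MPAP from
10–18, budget 10,000 iterations, `k = 200`. The HMCR/PAR/MPAP draw happens
once per run, before the loop. Mid-range HMCR keeps memory recall frequent
without the two failure modes of the extremes: high HMCR with small MPAP
stalls in local maxima, while low HMCR (or very large MPAP) degrades into
plain random search.

### Design choices in the engine

* **Signed pitch steps.** A literal reading of the update rule adds `+MPAP`
  to every coordinate, which would drift all coordinates monotonically to
  their upper bounds instead of searching *around* stored solutions. The
  engine therefore draws the step uniformly from the signed nonzero steps in
  `[-mpap, +mpap]` — even steps only on the odd-kernel axis so parity is
  preserved — and clips out-of-range results to the nearest admissible
  value, restoring parity toward the interior. `pitch_adjust(mode =
  "literal")` keeps the verbatim add-only rule available for fidelity
  experiments.
* **Strict replacement.** A candidate tying the worst stored rate does not
  replace it; sort ties break by insertion recency (newer first) so runs are
  deterministic. Duplicate architectures in HM are permitted (tiny spaces
  force them by pigeonhole).
* **Stagnation bookkeeping.** "Improvement" means a strict increase of the
  *best* entry's rate; an HM update that only improves the tail still
  increments ΔI. With the interval origin at iteration 0, ΔI first reaches
  `k` at iteration index `k` when nothing ever improves, i.e. after `k + 1`
  executed iterations; after a best-update at iteration `j*`, the run stops
  at `j* + k`.
* **Objective caching.** Proposals are cached by hyperparameter tuple, so
  recalling an already-scored architecture does not retrain it. When
  comparing optimizers under a *training* budget, `run_hs(max_evaluations =
  n)` counts distinct trainings (including the `hms` initialization
  trainings) instead of iterations, which keeps the comparison to an
  `n`-draw random search fair.
* **Exact cardinality.** The space size exceeds 64-bit integer range, so
  `space_cardinality()` multiplies in a small base-10⁴ big-integer
  representation and returns every decimal digit exactly.

## The CNN objective

`build_model()` assembles, per hyperparameter vector: `cld` valid (no
padding, stride 1) 1 × `ks` convolutions with `kc` kernels and ReLU, each
followed by non-overlapping max-pooling of width 2 (skipped automatically
for a block whose feature map would collapse below one sample), a flatten,
two ReLU dense layers of widths `dlnc^1`, `dlnc^2`, and a 5-unit softmax
output. Training is mini-batch stochastic gradient descent on the
cross-entropy loss with classical momentum (0.9), a global gradient-norm
clip (default 5, guarding the occasional exploding step at small batch
sizes), and He-normal initialization; it stops at the epoch budget or once
the mean epoch loss falls below a threshold. The forward/backward passes
are implemented as im2col matrix products and are verified in the test
suite against central finite differences.

`make_objective()` wraps build → train → validate into the `hp → R`
function the optimizer consumes. Per-architecture training seeds derive
deterministically from a base seed and the tuple, so re-evaluating an
architecture reproduces its score; architectures that cannot be built (a
kernel wider than its feature map) or whose training diverges score 0 with
a warning, keeping the objective total over the space. Pieces are
z-normalized per piece by default, since the sensor's amplitude units are
arbitrary.

Pooling presence and size, epochs, learning rate, batch size and input
length are not dictated by the recognition task itself; the values above
are this package's own defaults, all configurable through
`training_config()`.

## The synthetic data

The original multi-subject radar recordings are not publicly deposited, so
`generate_dataset()` emulates the acquisition protocol: each subject gets a
profile (baseline amplitude ~ U(0.8, 1.2), rate offset ~ U(−1.5, +1.5)
breaths/min, noise level), and contributes equal numbers of pieces per
class. Pieces are asymmetric raised sinusoids (inspiration rises faster
than expiration decays, via a phase-modulation skew that leaves the
fundamental frequency untouched) at 20 Hz for 10 s — 200 samples, chosen so
the respiration band (≤ 1 Hz) is well above Nyquist and the largest kernel
(81) still fits the piece. Class semantics: eupnea 15–20 breaths/min at
full amplitude; bradypnea 8–12 breaths/min at 0.6× depth (the longer cycle
follows from the rate); tachypnea 22–30 breaths/min at 0.35× depth; apnea
at 0.04× depth (under the 10% threshold by construction); movement adds a
smoothed random-walk drift of 3.5× the respiratory amplitude. The default
protocol is 10 subjects × 5 classes × 50 pieces = 2500 pieces, a
1500-piece learning pool split 8:2 into 1200 training and 300 validation
pieces, and a 1000-piece held-out test set.

What the simulator does **not** model: radar physics (clutter, ranging,
distance-dependent SNR), within-piece pattern transitions, measurement
artifacts other than additive Gaussian noise, and the idiosyncrasies of
real chest-motion waveforms. Passing tests on synthetic data therefore
demonstrate that the optimizer and training machinery work and that the
search improves architectures on a learnable 1-D classification task — not
that any particular recognition rate transfers to real recordings. A
two-feature sanity classifier (dominant spectral frequency plus
peak-to-peak amplitude) separates the four breathing classes at > 90%
accuracy at low noise, establishing that the synthetic task is learnable
before any CNN enters the picture.

## Scaled-down study sizes

The test suite and the acceptance script run everything at desk scale on a
single CPU; the sizes are the package's declared experimental conditions:

* **Exact protocol checks** use the full 2500-piece dataset (generation is
  cheap; only training is expensive).
* **Optimizer verification** replaces the CNN with a deterministic
  surrogate, `100·exp(−Σ((x−target)/scale)²)`, whose unique maximum is a
  planted target; recovery is checked against exhaustive enumeration on
  64–256-tuple spaces under the full 10,000-iteration budget. Because the
  pitch step is never zero, an interior coordinate that is already optimal
  cannot survive a pitch, so exact recovery flows through memory seeding
  and the random branch — the expected number of random target draws under
  the default budget makes 5/5-seed recovery essentially certain at these
  space sizes.
* **End-to-end comparison**: 4 subjects × 15 pieces/class (300 pieces,
  noise 0.05), pool 240 split 180/60, test 60; desk space `cld = 2`, odd
  kernels 3–31, kernel counts 2–16, dense widths 8–128 (wide enough that
  weak architectures exist and the objective has real structure); training
  8 epochs, batch 30, learning rate 0.05. Harmony Search with a 30-training
  budget (`hms = 10`, HMCR 0.6, PAR 0.7, MPAP 4) is paired against a
  30-draw random search over 5 seeds; the median HS best validation rate
  must match or beat the median random-search best, and every best-so-far
  curve must be non-decreasing.

## Known limitations

* Full-scale runs (thousands of trainings of networks with up to 4096-wide
  dense layers) are out of reach of the pure-R trainer; the package scales
  the protocol down rather than approximating the algorithm.
* The recognition rates reported on synthetic data say nothing quantitative
  about real radar recordings (see above).
* The HS engine treats all axes as discrete; continuous hyperparameters
  (learning rate, etc.) and per-variable pitch-adjustment schedules are out
  of scope.
* Reproducibility is exact for a fixed seed on a given BLAS; training
  trajectories may differ in the last bits across numerically different
  BLAS builds.
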