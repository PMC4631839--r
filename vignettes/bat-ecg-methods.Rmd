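---
title: "Bat-algorithm feature selection for ECG beats: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bat-algorithm feature selection for ECG beats: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the optimizer
model and its quirks, the beat-processing pipeline, the synthetic data
world and exactly what a green test does and does not establish, the
numerical choices, and the design decisions that were genuinely open.

## 1. The optimizers

### Standard bat algorithm (BA)

A population of `N` candidate solutions ("bats") minimizes an objective
over a bounded box. Each bat `i` holds a position `x_i`, a velocity `v_i`,
a loudness `A_i > 0` and a pulse emission rate `r_i ∈ [0, r0]`. One
generation, in the order the engine draws random numbers (frequencies,
local-search gates, perturbations, acceptance draws — fixed so a seed
reproduces a run bit-for-bit):

1. **Frequency move.** `f_i = fmin + (fmax − fmin)·u_i`;
   `v_i ← v_i + (x_i − x*)·f_i`; candidate `c_i = clamp(x_i + v_i)`.
   The `(x_i − x*)` sign is kept exactly as published even though the
   textbook form uses `(x* − x_i)`; it makes the move *repulsive* around
   the global best `x*`, so sustained progress comes almost entirely from
   the local-search branch. `classic_velocity = TRUE` restores the
   textbook sign for comparison.
2. **Local search.** With probability `r_i` the candidate is replaced by
   `x* + ε·Ā`, with `ε ~ U(−1, 1)` per dimension and `Ā` the population
   mean loudness. `Ā` starts around 2 (loudness is initialized uniform in
   `[1, 3]`) and decays as bats accept improvements, so the search ball
   tightens as the swarm succeeds — an annealing schedule driven by
   acceptance, not by iteration count.
3. **Greedy acceptance.** The candidate replaces the bat's state iff an
   acceptance draw falls below `A_i` *and* the candidate strictly improves
   that bat's own fitness; ties are rejected. On acceptance
   `A_i ← α·A_i` and `r_i ← r0·(1 − e^{−γ·t_i})`, where `t_i` counts that
   bat's accepted updates. The global best is updated from accepted
   solutions, so the best-so-far fitness is non-increasing by
   construction.

### Improved variant (IBA)

The improvement assigns loudness and pulse rate *per dimension*:
`A_ij`, `r_ij`. After the frequency move, every dimension `j` of every bat
is gated independently: when `rand_j > r_ij`, dimension `j` is redrawn as
`α·x*_j + ε_j·Ā_j` (`Ā_j` the population mean loudness of that dimension);
otherwise the moved value is kept. Acceptance is unchanged (the bat's mean
loudness gates it), and only the *gated* dimensions of an accepted bat
decay their loudness and grow their pulse rate. Early on (`r` small) almost
every dimension is redrawn with a large `Ā_j` — strong exploration; as
gated dimensions accumulate accepted updates, their `Ā_j` shrinks and the
redraws become fine exploitation around the best solution. That
per-coordinate schedule is the entire substance of the variant, and it is
visible on the bench: on the 2-D Rosenbrock valley (25 bats, 1000
generations, 20 seeds) the improved variant's median best fitness is about
an order of magnitude below the standard one's.

### Published-description conflicts, resolved here

* **Pulse-rate growth sign.** The per-dimension growth rule is printed
  with a positive exponent, which diverges; we use the saturating negative
  exponent, consistent with the scalar rule and with the published
  saturation plots.
* **Local-search base.** The per-dimension rule is printed around the
  bat's own position while the accompanying text says the search happens
  around the best solution. We follow the text (`local_base = "best"`),
  with `local_base = "self"` available.
* **Parameter table vs text.** The published parameter table prints
  several values (negative generation count, negative loudness, `fmax` of
  1, pulse rate 0.85) that contradict the running text; all defaults here
  follow the text: 30 generations, `fmax = 2`, `α = γ = 0.95`, `r0 = 0.2`,
  loudness initialized in `[1, 3]`.
* **Initial pulse rate.** The source states the pulse rate starts at 0.2,
  yet its growth law evaluates to 0 at an accepted-update count of zero.
  We initialize `r_i = r0 = 0.2`. This matters: with `r(0) = 0` a bat
  never local-searches until it first accepts, but (because of the
  repulsive velocity sign) its moves essentially never improve once
  clamped at the bounds — so most of the swarm deadlocks, the mean
  loudness never decays, and the standard variant stalls an order of
  magnitude short of its stated benchmark convergence. With `r(0) = r0`
  every bat participates from the start. The one wrinkle is that a bat's
  first accepted update *dips* its pulse rate from 0.2 to
  `r0(1 − e^{−γ})` ≈ 0.123 before the curve saturates back; tests assert
  conformance to the curve rather than global monotonicity for that
  reason.
* **Dimension collapse.** At `D = 1` the per-dimension machinery reduces
  to one scalar gate, but it is *not* the scalar rule: the gates point in
  opposite directions (`rand > r` fires ~80% of the time at `r0 = 0.2`,
  `rand < r` ~20%) and the improved rule shrinks its base by `α`. The two
  variants therefore do not produce statistically indistinguishable
  results in 1-D (the improved one is measurably better, rank-sum
  p ≈ 5e-7 over 50 seeds); the tests assert that both converge rather
  than that they coincide.

## 2. Feature selection

Bat positions live in `[-1, 1]^D`; a position maps to the mask of its `k`
largest-magnitude coordinates (ties toward the lower index). This keeps
the continuous move equations meaningful as printed; binary-bat encodings
would have required redefining them.

Two fitness modes:

* **`wrapper` (default).** Stratified 5-fold cross-validated 1-NN
  misclassification rate on the masked columns. The fold assignment is
  fixed (seeded) *before* optimization, so fitness is a pure function of
  the mask, repeated evaluations are cached, and runs are reproducible.
  Pass the same `fold_seed` to `select_features()` and
  `exhaustive_best_subset()` to make their fitness values comparable —
  the enumeration oracle is a lower bound the swarm can at best attain.
* **`rosenbrock`.** The benchmark function evaluated on the raw position,
  as in the source formulation. It is label-blind by construction —
  permuting the class labels cannot change the selected mask — which the
  test suite asserts, making the source's fitness ambiguity explicit
  rather than papering over it.

The sizes `k = 20` of `D = 200` are the protocol defaults.

## 3. The beat pipeline

* **Smoothing.** Savitzky–Golay (moving least-squares polynomial) with
  degree 3 and a window of ~25 ms of samples (nearest odd count). Edge
  windows use the off-center projection rows — the same contract as the
  common reference implementations — so polynomials of degree ≤ 3 pass
  through bit-exactly, which is also how the filter is tested (plus a
  frozen reference output computed independently).
* **R-peak detection.** The source names no method, so we use the field's
  default recipe: squared first difference, 150 ms moving-average
  integration, threshold at 25% of the peak energy, refinement to the
  largest absolute (median-centered) amplitude within ±50 ms, and a
  0.2 s refractory period. Squaring makes detection polarity-blind; an
  inverted lead yields identical peaks.
* **Segmentation.** Each beat spans `[R − round(RR/3), R + round(2·RR/3))`
  where RR is the *preceding* R-R interval (the first peak borrows the
  following one — the only length scale available there). Rounding is
  half-up so windows are bit-reproducible; windows crossing the record
  boundary are dropped, so a 10-beat record typically yields 8–10 beats.
* **Resampling.** Linear interpolation onto 200 equally spaced points;
  endpoints are exact. Because the R peak sits 1/3 into its window, it
  lands at resampled index `round(200/3) = 67 ± 2` — an invariant the
  acceptance suite checks end-to-end.

The pipeline contains no randomness: identical input gives an identical
beat matrix.

## 4. The synthetic world

`synth_dataset()` draws beats directly at the resampled 200-sample grid
from a five-Gaussian PQRST template (R centered at 1/3 of the beat, as the
segmentation produces). The type-1 infarct preset elevates the ST plateau
(fraction 0.60–0.80 of the beat, columns 121–160, +0.2 mV at full
separation, joined to baseline by half-cosine ramps) and attenuates the R
wave (×0.6); `separation` scales both deltas to zero. A type-2 preset
(deep Q, inverted T) exists but is not the default.

Within-class variability models what survives preprocessing of real,
pooled, multi-subject beats:

| knob | default | what it emulates |
|---|---|---|
| `amp_jitter` | 0.15 | per-beat, per-wave gain variation |
| `st_sd` | 0.07 mV | beat-to-beat ST-level drift, both classes |
| `shift_max` | 2 samples | residual R-alignment / RR-warp error |
| `noise_sd` | 0.05 mV | measurement noise after smoothing |

These were fixed once, on realism grounds: a first, naive world (white
noise only) produced *exactly zero* cross-validated error for almost any
mask touching a handful of informative columns — nothing like real pooled
beats, on which the same classifier family reaches 53–65%. The final world
yields ~96% full-mask accuracy (clean enough for the end-to-end criteria)
with no single perfect column. A candidate world with an additional smooth
morphology field was evaluated and rejected because it dragged full-mask
accuracy to ~85%.

What a green test establishes: the pipeline recovers R peaks within
±10 ms at 20 dB SNR, beats are 200 wide with the R at 1/3, class means
differ only on the stated columns, selection is deterministic and beats
chance, the end-to-end accuracy behaves as stated at separations 1 and 0.
What it does not establish: anything about real electrode artifacts,
baseline wander, arrhythmic beats, inter-patient morphology, or
generalization to clinical data — the generator is a controlled stand-in,
not a physiological simulator.

## 5. A known-red criterion, analyzed

One acceptance criterion asks that the 20-feature mask selected on default
synthetic data contain at least 10 of the 40 ST-window columns (chance
expectation 4). This is left red, deliberately, and the threshold was not
touched. The cause is structural, not a defect of the optimizer: with 400
beats, the 5-fold 1-NN error saturates once ~5 informative columns are in
the mask; the marginal value of a 10th window column is far below the CV
resolution (1/400), and harmless near-zero-variance columns are not
penalized. Even greedy forward selection — a direct, much stronger
optimizer of the identical criterion — plateaus at 3–7 window columns.
Measured bat-selected overlaps in the frozen acceptance configuration are
3–8 across seeds. A wrapper criterion that rewards *window concentration*
would need either vastly more beats (to resolve per-column marginal
value) or a fitness with an explicit redundancy/relevance term, both of
which would change the stated method.

## 6. Evaluation conventions

The *normal* class is the positive one — the source's convention, opposite
to clinical practice — so "sensitivity" here is the normal-recall. The
mapping is configurable (`positive =`). Counts use the standard confusion
layout (FP = predicted positive, truly negative); the source's prose swaps
the FP/FN wordings, which we treat as a typographical slip since its own
TP/TN wordings and worked numbers follow the standard layout. Metrics are
percentages; `accuracy·n/100 = TP + TN` holds as an integer identity, and
every report's metrics are recomputable from its stored counts. A zero
denominator yields `NA` with a warning, not an error.

The published evaluation protocol's train/test sizes (1800/1006 of 2806
beats, i.e. ~64% training) fix the default `train_frac = 0.64`; membership
is a seeded stratified draw since the source does not specify it. External
classifier comparators (SVM and the two neural-network trainers named in
the source) are interface-reserved ids; their backing packages are not
available in this build, so only the built-in 1-NN executes, and the ids
fail with an explanatory error rather than a silent substitution.

## 7. Other limitations

* The repulsive velocity sign makes the standard variant's frequency move
  almost purely decorative under clamping; we keep it because it is what
  is printed, and expose the classic sign as an option.
* WFDB records are not readable in this environment; raw signals enter as
  CSV.
* The 2086-bat, 30-generation replication-scale configuration is
  supported (`pop_size = 2086`) but tests run at bench scale (pop 20–25),
  which is where all stated convergence figures were measured.
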