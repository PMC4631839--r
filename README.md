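# batecg

Swarm-optimized feature selection for single-lead ECG beat classification,
built around the bat algorithm and its per-dimension "improved" variant.

## The problem

Myocardial infarction (MI) leaves morphological fingerprints on the ECG —
for the non-Q ("type 1") form, an elevated ST segment and an attenuated QRS
complex. A classifier working directly on resampled beats sees 200 samples
per beat, most of them irrelevant; selecting a small, discriminative subset
improves both speed and accuracy. `batecg` provides the whole chain for
studying that idea with full ground-truth control:

1. **Preprocessing** — Savitzky–Golay smoothing, R-peak detection
   (derivative–square–integrate with adaptive threshold), beat segmentation
   at 1/3 RR left / 2/3 RR right of each R peak, linear resampling to 200
   samples per beat.
2. **Optimizers** — the standard bat algorithm (BA) and an improved variant
   (IBA) in which loudness and pulse rate are assigned per *dimension*, so
   exploration and exploitation run simultaneously across coordinates.
3. **Feature selection** — bat positions in `[-1, 1]^200` decoded as
   top-`k`-magnitude masks (default k = 20), scored by cross-validated
   1-NN error (wrapper mode) or by the label-blind Rosenbrock benchmark.
4. **Evaluation** — 1-NN classification with sensitivity, specificity and
   accuracy (note: the *normal* class is the positive one, following the
   source protocol).
5. **Synthetic ECG** — Gaussian-sum PQRST beats, normal and type-1-MI
   presets, with known R positions and a known 40-sample discriminative ST
   window, so every stage is testable without downloads.

## The algorithm

Each of `N` bats carries a position `x_i`, velocity `v_i`, loudness `A_i`
and pulse emission rate `r_i`. Per generation:

- frequency `f = fmin + (fmax − fmin)·u`, `u ~ U(0,1)`;
- move: `v_i ← v_i + (x_i − x*)·f`, `x_i ← clamp(x_i + v_i)` (`x*` the
  global best; the published sign convention is kept, a `classic_velocity`
  switch restores the textbook one);
- with probability `r_i`, replace the candidate by a local solution
  `x* + ε·Ā`, `ε ~ U(−1,1)` per dimension, `Ā` the mean loudness;
- accept iff `rand < A_i` **and** the candidate strictly improves the bat's
  own fitness; on acceptance `A_i ← α·A_i` and
  `r_i ← r0·(1 − e^{−γ t_i})` with `t_i` the bat's accepted-update count.

IBA replaces the scalar local search by a per-dimension rule: dimension `j`
of bat `i` is redrawn as `α·x*_j + ε_j·Ā_j` whenever `rand_j > r_ij`, and
only the gated dimensions decay `A_ij` / grow `r_ij` on acceptance.

Defaults follow the source text: `α = γ = 0.95`, `r0 = 0.2`,
`f ∈ [0, 2]`, initial loudness uniform in `[1, 3]`, 30 generations.

## Worked example

```r
library(batecg)

ds  <- synth_dataset(n_normal = 200, n_mi = 200, separation = 1, seed = 42)
sel <- select_features(ds$beats, ds$labels, k = 20, seed = 42)
rep <- evaluate_pipeline(ds$beats, ds$labels, mask = sel$mask,
                         train_frac = 0.64, seed = 42)
print(rep)
#> Classification report (knn, 256 train / 144 test, seed 42)
#> Confusion counts (positive = normal): TP=70 TN=68 FP=4 FN=2
#>   sensitivity 97.22%  specificity 94.44%  accuracy 95.83%
```

The selection ran the improved bat algorithm over 200-dimensional
positions (25 bats, 30 generations) against the 5-fold 1-NN error; the
best mask's cross-validated error was 0.0325, and on a held-out stratified
36% split the masked 1-NN classifier reaches 95.8% accuracy. With
`separation = 0` the two classes are identically distributed and the same
pipeline lands at chance (~50%).

On the optimizer benchmark (2-D Rosenbrock, 25 bats, 1000 generations,
seed 1) the standard variant reaches a best fitness of `1.1e-2` and the
improved variant `1.1e-4` — the per-dimension gating explores more
effectively, which is the variant's entire point.

## Command line

```sh
BATECG=$(Rscript -e 'cat(system.file("cli/batecg", package = "batecg"))')
Rscript $BATECG simulate-dataset --normal 200 --mi 200 --seed 7 --out beats.csv
Rscript $BATECG select   --beats beats.csv --k 20 --mode iba --seed 7 --out mask.json
Rscript $BATECG classify --beats beats.csv --mask mask.json --seed 7 --out report.json
```

Every artifact embeds the configuration and seed that produced it; file
writes are atomic. `preprocess` turns a raw ECG CSV (single amplitude
column + `--fs`, or `t,amplitude`) into a beat matrix;
`optimize-benchmark` runs either optimizer on the Rosenbrock bench and
writes the convergence trace.

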