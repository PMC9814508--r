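# cardiomel

Three-class heart-sound (phonocardiogram) classification in R: **normal**,
**abnormal** (murmur / valve pathology) and **noise** (artifact), over fixed
2-second units sampled at 2000 Hz.

The package is for researchers and engineers who want a complete, verifiable
PCG classification pipeline without a deep-learning framework dependency:

* **Preprocessing** — zero-phase 5th-order Butterworth low-pass at 400 Hz
  (effective magnitude `|H(f)|² = 1/(1+(f/f_c)^{2n})`), Fourier down-sampling
  to 2000 Hz, cutting into non-overlapping 2-s segments, and unification of
  corpus-specific labels (PhysioNet/CinC 2016, Pascal/Kaggle, Yaseen) into
  the three-class scheme via an overridable label map.
* **Improved-MFCC features** — per segment, 13 static mel-frequency cepstral
  coefficients over 199 frames (20 ms frames, 10 ms hop, Hamming window with
  α = 0.46, 256-point FFT, 13 unit-peak triangular mel filters on
  `mel(f) = 2595·log₁₀(1 + f/700)`, natural-log band energies, DCT without
  the 0th coefficient), stacked with first- and second-order difference
  coefficients `D(t) = Σᵢ i·C(t+i) / Σᵢ i²` (k = 2) into a **199 × 39**
  input matrix.
* **Models** — declarative builders for a residual network with
  depthwise-separable convolutions, LSTM and GRU baselines and a plain CNN,
  with exact parameter counting (LSTM 30,979; GRU 24,515 under the dual-bias
  gate convention; CNN 97,539). The network engine (conv/BN/pool/dropout/
  dense/LSTM/GRU, backprop, Adam) is part of the package, with C++ kernels
  and finite-difference-verified gradients.
* **Evaluation** — a fixed 20% test pool and five rotating validation folds,
  always split by parent recording (no segment leakage), minority-class
  oversampling with label-preserving augmentation, and one-vs-rest
  sensitivity/specificity/precision with macro averaging.
* **Synthetic phonocardiograms** — a seeded generator of S1/S2 cycles,
  systolic murmurs and artifacts, so every stage above is testable
  end-to-end with no data download.

## Worked example

```r
library(cardiomel)

# 40 synthetic recordings per class, cleaned and cut into 2-s segments
segments <- make_segment_table(40, cfg = synth_config(seed = 42)) |>
  extract_features()
improved_mfcc(segments$samples[[1]])
#> <feature_matrix> 199 frames x 39 coefficients (static|d|d2)

# hold out 20% of recordings, train the residual network on the rest
plan <- make_splits(segments, seed = 42)
role <- plan$role[match(segments$parent_id, plan$id)]
fit <- build_model("resnet", seed = 42) |>
  train_model(segments$features[role == "pool"],
              segments$label[role == "pool"],
              epochs = 15, seed = 42)
glance(fit)
#> # A tibble: 1 × 5
#>   model  parameters epochs    loss accuracy
#>   <chr>       <int>  <int>   <dbl>    <dbl>
#> 1 resnet      36075     15 0.00556        1

pred <- predict(fit, segments$features[role == "test"], type = "class")
evaluate_metrics(confusion_matrix(segments$label[role == "test"], pred))
#> <metrics_report> accuracy 0.9583
#> # A tibble: 3 × 4
#>   class    sensitivity specificity precision
#>   <chr>          <dbl>       <dbl>     <dbl>
#> 1 normal         1           0.938     0.889
#> 2 abnormal       0.875       1         1
#> 3 noise          1           1         1
```

The fitted model reaches 95.8% accuracy on the held-out synthetic test pool:
one abnormal segment (a quiet murmur) is mistaken for normal, everything
else is correct. `cross_validate(segments, "resnet", seed = 42)` runs the
full five-fold protocol and reports the mean test accuracy over the five
fold models. Real corpora enter through `read_manifest()` +
`preprocess_manifest()` using the same functions.

A command-line interface wrapping the same functions ships at
`inst/cli/cardiomel.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","cardiomel.R",package="cardiomel"))')" \
    synth --n 100 --seed 7 --out runs/data
# then: preprocess, features, train, evaluate, crossval, summary
```

## Scope

The synthetic classes are deliberately separable at default settings: they
verify the pipeline, not clinical performance. Published accuracies on the
fused real corpora are only attainable with those corpora supplied through
the manifest interface. See the methods vignette
(`vignettes/cardiomel-methods.Rmd`) for the model conventions, parameter
defaults and design rationale.
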