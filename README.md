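# gbseg

Gallbladder segmentation on abdominal CT slices with multi-scale channel
attention U-Nets — built, trained and evaluated entirely in R.

The gallbladder is a small hypodense organ next to the liver; on a typical
axial CT slice it covers about **0.55% of the pixels**, and neighbouring
structures can look almost identical. `gbseg` implements a family of
encoder–decoder networks for this task:

* **U-Net** — the pinned baseline (1 input channel, stages 16/32/64/128/256,
  biased 3×3 convolutions, transposed-convolution upsampling, no
  normalization; exactly **1,940,817** parameters);
* **SEU-Net** — U-Net with squeeze-and-excitation (cSE) channel attention
  after every encoder stage;
* **MCAU-Net** — the main model: the shallow encoder stages are replaced by
  *multi-scale channel attention (MCA) blocks* (parallel 3/5/7 — or 5/7/9 —
  convolutions fused by a 1×1 convolution, gated by a cSE excitation
  computed from global descriptors of the feature map and its 2×- and
  4×-average-pooled versions), and the decoder uses batch-normalized
  residual stages.

Training minimises the soft Dice loss

    L = 1 − (2 Σ pᵢgᵢ + ε) / (Σ pᵢ + Σ gᵢ + ε),

the natural objective under extreme class imbalance (binary cross-entropy is
included as the comparator), with Adam and a continuous exponential
learning-rate decay `lr0 · rate^(step/steps)`. Evaluation reports the seven
standard segmentation metrics per case — DSC, JSC, PPV, SE, Hausdorff
distance (pixels), RVD, VOE — plus cohort aggregation (mean ± SD, median,
quartiles, 1.5 IQR whiskers).

Because clinical gallbladder CT is not publicly shareable, the package ships
a seeded **synthetic phantom generator**: a textured liver-like region, one
hypodense gallbladder ellipse whose area targets the 0.55% imbalance,
intensity-matched distractor structures, and Gaussian noise. The whole
pipeline — preprocessing (Hounsfield conversion, window/level, CLAHE,
normalization), patient-grouped 54/6/40 splitting, paired geometric
augmentation, training, evaluation — runs end to end on phantoms with no
patient data. The CNN engine itself (trainable convolutions,
reverse-mode differentiation, Adam) is implemented in the package on
Rcpp/RcppArmadillo; there is no external deep-learning dependency.

## Worked example

Train MCAU-Net-2 at desk scale (64×64 phantoms, base width 8, 10 epochs,
batch 4, Dice loss) and evaluate on held-out phantoms:

```r
library(gbseg)

spec  <- phantom_spec(size = c(64, 64), seed = 42)   # fg target 0.55%
train <- phantom_dataset(200, spec)
val   <- phantom_dataset(40, spec, indices = 201:240)
test  <- phantom_dataset(40, spec, indices = 241:280)

cfg <- smoke_config("mcau", n_mca_blocks = 2, epochs = 10, seed = 42)
run <- train_model(cfg, train, val)
run
#> <gb_run mcau2: 10 epochs, best val DSC 0.9159 (epoch 9)>

ev <- evaluate_model(run$model, test)
ev
#> <gb_eval: 40 cases (0 excluded)>
#> # A tibble: 7 × 4
#>   metric  mean     sd median
#>   <chr>  <dbl>  <dbl>  <dbl>
#> 1 dsc    0.920 0.0566  0.927
#> 2 jsc    0.856 0.0919  0.864
#> 3 ppv    0.959 0.0601  1
#> 4 se     0.893 0.0977  0.911
#> 5 hd     2.19  4.01    1
#> 6 rvd    0.117 0.0920  0.110
#> 7 voe    0.144 0.0919  0.136
```

The mean test DSC of 0.92 is comfortably above the 0.70 bar usually cited
as acceptable for organ segmentation; PPV near 0.96 says false positives
are rare (the intensity-matched distractor is mostly rejected), and the
mean Hausdorff distance of ~2.2 px reflects tight boundaries on the ~22-px
phantom gallbladders. `tidy(run)` returns the per-epoch history,
`glance(run)`/`glance(ev)` one-row summaries, and `autoplot(run)` /
`autoplot(ev)` the training curves and metric box plots.

Other entry points:

```r
count_parameters(build_unet())       # 1,940,817 — the pinned baseline count
training_preset("mcau2")             # published full-scale hyperparameters
run_phantom_benchmark(c("unet", "mcau2"), seeds = 1:3)  # model comparison
preprocess_slice(pixels, slope = 1, intercept = -1024)  # CT preparation chain
```

A thin command-line front end over the same functions lives at
`inst/cli/gbseg.R` (subcommands `preprocess`, `phantoms`, `split`, `train`,
`evaluate`, `compare`, `params`).

## Package layout

* `R/preprocess.R` — CT slice preparation chain + PNG/NIfTI I/O
* `R/phantom.R`, `R/data.R` — phantom generator, patient-grouped splits,
  paired augmentation
* `R/objectives.R` — Dice and BCE losses (with gradients)
* `R/metrics.R` — the seven-metric suite and cohort aggregation
* `R/nn-tape.R`, `src/ops.cpp` — the reverse-mode network engine
* `R/models.R` — architecture specs, cSE/MCA blocks, the three model
  builders, parameter counting
* `R/workflow.R` — training loop, presets, evaluation harness, benchmark
* `vignettes/gbseg-methods.Rmd` — the full methods description and the
  reasoning behind every default
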