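# leafcnn

Lightweight channel-attention convolutional networks for plant leaf disease
image classification — a complete, self-contained R toolkit for researchers
who need a small, deployable classifier for fine-grained lesion recognition
on cluttered field backgrounds, and a fully testable harness around it.

The core architecture is a ShuffleNetV2-family backbone (channel split,
grouped transform branch, channel shuffle; one downsampling unit plus a run
of basic units per stage) extended with:

* **dual-pool channel attention** — per-channel weights
  `ω = σ(C1D_K(y₁) + C1D_K(y₂))`, where `y₁` and `y₂` are the spatial mean
  `A_c = (1/HW) Σ X_c(h,w)` and population standard deviation
  `S_c = √((1/HW) Σ (X_c − A_c)²)` of each channel, each convolved along the
  channel axis by its own bias-free 1-D kernel of adaptive odd size
  `K = |log₂(C)/γ + b/γ|_odd` (γ = 2, b = 1). SE / ECA / SRM comparators are
  included behind the same interface;
* **residual shortcuts** in both unit types (max-pool, average-pool or
  strided-convolution projections in downsampling units);
* **multi-scale shallow and deep blocks** (a pooled + stacked-convolution
  stem, and parallel 3×3/5×5 branches after the last stage);
* the full **training recipe** (SGD, momentum 0.9, weight decay 5e-4, batch
  32, cosine-annealed learning rate 0.01 → 1e-9), the **8:2 floor-rule
  stratified split**, per-class **augmentation expansion**, **robustness
  perturbations** (Gaussian noise, rotation, brightness), and a macro
  precision/recall/F1 **evaluation suite** with per-crop aggregation.

There is no external deep-learning dependency: the convolution, batch-norm,
pooling and backpropagation engine is implemented in the package (Rcpp
kernels + BLAS), and every backward pass is verified against finite
differences in the test suite. A deterministic synthetic leaf-image
generator makes the entire pipeline runnable at desk scale with no data
download.

## Worked example

Generate the default 4-class synthetic dataset (healthy + three lesion
types; 100 train / 25 test per class at 64 px), train the reduced preset
for 10 epochs, and evaluate:

```r
library(leafcnn)

spec  <- synth_spec(seed = 0)                     # 4 classes, 64 px
ds    <- generate_dataset(spec)
cfg   <- tiny_leafnet_config(num_classes = 4, input_size = 64)
model <- build_model(cfg, seed = 0)

count_parameters(model)$total_params
#> [1] 224200

tc <- train_config(epochs = 10L, seed = 0L)       # recipe defaults otherwise
h  <- train(model, ds$train, ds$test, tc, verbose = TRUE)
#> epoch  0  lr 0.010000  loss 1.1413  acc 0.6000
#> epoch  1  lr 0.009755  loss 0.5535  acc 0.8600
#> epoch  2  lr 0.009045  loss 0.2163  acc 0.9200
#> ...
#> epoch  9  lr 0.000245  loss 0.0187  acc 0.9700
print(h)
#> trained 10 epochs; best test accuracy 0.9700 at epoch 5

ev <- evaluate(h$best_model, ds$test, tc)
print(ev$report)
#> accuracy 0.9700 | macro P 0.9712 R 0.9700 F1 0.9699 (4 classes, n = 100)
```

The loss falls from chance (`log 4 ≈ 1.39`) within the first epoch and the
balanced test set is classified at 97% after ten epochs; an untrained model
scores 0.25 (chance). The per-epoch learning rates follow the cosine
schedule exactly (`cosine_lr(t, 10)`).

Architecture exploration uses the same configuration objects:

```r
count_parameters(build_model(leafnet_config(), seed = 1))$total_params    # flagship
#> [1] 3550870
count_parameters(build_model(shufflenet_config(), seed = 1))$total_params # ShuffleNetV2-1.0 grid row 0
#> [1] 1276154
```

A thin command-line wrapper (`inst/cli/leafcnn.R`) exposes `synth`, `split`,
`train`, `eval`, `build-info` and `perturb` subcommands over the same
functions.

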