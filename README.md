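# protofuse

Few-shot image classification with multi-layer feature fusion and
relative-entropy prototypes, in R.

## The problem

Field applications such as crop-insect monitoring need image classifiers
that recognize a visual category from a handful of labeled examples — often
15 or fewer images per species — where conventional deep models cannot be
trained. Metric-based few-shot learning handles this by meta-training over
*episodes*: N-way, K-shot classification tasks in which a model must label
`Q = N*q` query images given only `S = N*K` labeled support images, with the
test-time categories (the *target* classes) completely disjoint from the
training (*source*) classes.

## The model

`protofuse` implements a prototypical-network classifier with two additions:
a multi-layer fused embedding and a relative-entropy similarity.

**Backbone.** A shallow trunk of four convolutional blocks, each
`64 @ 3x3 conv -> batch norm -> ReLU -> 3x3/3 max pool`, applied to
`96 x 96 x 3` inputs (trunk map sizes 96 → 32 → 10 → 3 → 1). After every
block the output map is tapped with a *global* max pool, giving four
64-dimensional feature vectors `f1 … f4` that span low-level to global
structure. The embedding of image `x` is the componentwise mean over a
configurable fusion subset `F ⊆ {1,2,3,4}`:

```
FFO(x) = (1/|F|) * Σ_{i in F} f_i(x)
```

`F = {4}` is the classical global-feature ("Conv-4"-style) baseline. The
trunk has 113,088 learnable parameters; cumulative per-branch counts are
1.92K / 38.98K / 76.03K / 113.09K (see `count_parameters()`).

**Classifier.** Class prototypes are support centroids,
`c_n = (1/K_n) Σ_i FFO(x_i)`, and query posteriors are a softmax over
negated divergences:

```
p(y = n | x) = exp(-d(FFO(x), c_n)) / Σ_n' exp(-d(FFO(x), c_n'))
```

where `d` is either the squared Euclidean distance or the Kullback–Leibler
divergence `KL(x‖y) = Σ_j x_j log(x_j / y_j)` between ε-smoothed,
sum-normalized probability vectors derived from the embeddings
(`divergence_config()` selects kind, ε, log base and direction). Training
minimizes the mean negative log-probability of the true class with Adam
(lr `1e-3`, halved every 20 epochs), 100 epochs × 150 episodes at full
budget; every 90° image rotation is treated as a new class, quadrupling the
class inventory.

## Worked example

```r
library(protofuse)

spec <- fixture_spec(n_classes = 10, n_per_class = 10, class_separation = 1, seed = 5)
source_coll <- generate_collection(spec, "source")
target_coll <- generate_collection(spec, "target")

model <- mlf_model(extractor_config(), seed = 1)
model
#> <mlf_model> 4 blocks x 64 filters, input 96x96x3, mode=train
#>   fusion subset: {1,2,3,4}; learnable parameters: 113088

cfg <- train_config(epochs = 2, episodes_per_epoch = 20,
                    episode = episode_config(n_way = 5, k_shot = 5, n_query = 5),
                    metric = divergence_config("relative_entropy"),
                    seed = 2, verbose = TRUE)
fit <- train(model, source_coll, cfg)
#> epoch=0 lr=1.00e-03 loss=1.4827 acc=0.9800
#> epoch=1 lr=1.00e-03 loss=1.3095 acc=0.9560

evaluate(fit$model, target_coll, n_episodes = 500,
         episode = episode_config(5, 5, 5),
         metric = divergence_config("relative_entropy"), seed = 3)
#> <eval_report> 5-way 5-shot, 500 episodes: accuracy 0.9876 +/- 0.0033 (95% CI)
```

The evaluation report is the mean fraction of correctly labeled query
images over 500 frozen-model test episodes on classes never seen in
training, with a 95% confidence half-width from the per-episode spread.
On these highly separable synthetic motifs the task is intentionally easy;
real image collections are far harder (see the methods vignette).

A command-line interface wraps the same functions
(`make-fixtures | train | eval | ablate | params` — see
`system.file("cli", "protofuse.R", package = "protofuse")`), and
`ablation_sweep()` reproduces the fusion-subset × divergence × K-shot grid.

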