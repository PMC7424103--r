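# v2texture

Tools for asking where texture sensitivity emerges in a convolutional
feature hierarchy, and how closely a population of model neurons can match
texture responses recorded in early visual cortex.

## The scientific problem

Neurons in the secondary visual area (V2) of primates — but not in primary
visual cortex (V1) — respond more strongly to naturalistic textures than to
*spectrally matched noise*: images with the identical Fourier amplitude
spectrum but randomized phases, which destroys all higher-order structure.
The standard measure is the **modulation index** of a neuron's mean
responses to the two stimulus classes,

    M = (r_na − r_no) / (r_na + r_no),

positive when the neuron is sensitive to the "naturalness" that phase
randomization removes. Layered convolutional models built from the same
computations long used in visual neuroscience (filtering, rectification,
max pooling, divisive/local response normalization) develop the same
dissociation: first-stage units behave like V1 (M ≈ 0), second-stage units
like V2 (M > 0).

`v2texture` implements the full analysis pipeline around that question:

* **Stimulus preparation** — phase randomization with exact amplitude-spectrum
  conservation, block-average downsampling, and affine contrast
  normalization to a target mean β = 0.5 and contrast α = 0.22.
* **A configurable feature model** — convolution / ReLU / max pooling /
  local response normalization `b_i = a_i / (k + α Σ_j a_j²)^β`
  (defaults k = 2, m = 5, α = 1e-4, β = 0.75), with receptive-field
  arithmetic, trained/random/shuffled weight modes, and extraction of
  center-neighborhood populations.
* **Texture-sensitivity statistics** — per-neuron per-family modulation
  matrices, validity screening, random-population sampling, permutation
  null bands.
* **Three population-fitting procedures** that select or weight `n` model
  neurons to match a target modulation vector `t` (one value per family):
  greedy forward subset selection of `k` equally weighted neurons;
  the optimal weighted average `min ‖Mw − t‖²` over the simplex
  `{w ≥ 0, Σw = 1}`; and a ridge-regularized variant
  `min ‖Mw − t‖² + λ‖w‖²` (default λ = 0.8) followed by top-`k`
  thresholding. Fits are scored by Euclidean error, Spearman rank
  correlation and explained variance.
* **Cross-validation** — leave-one-group-out over stimulus groups
  (the 15-families × 15-groups-of-15 → 225-fold design) and
  leave-family-out generalization.
* **A synthetic-data module** — texture families with planted, band-limited
  higher-order structure and response tensors with planted modulation, so
  every stage is testable without external stimulus sets or pretrained
  weights.

## Worked example

```r
library(v2texture)

## receptive-field arithmetic for the stride-2 AlexNet-style front end
spec <- alexnet_spec(conv1_stride = 2)
receptive_field_size(spec, "pool1")$rf_side   # 15
receptive_field_size(spec, "pool2")$rf_side   # 39

## synthetic texture families and their spectrally matched noise partners
params <- synthetic_texture_params(n_families = 5, n_samples = 8,
                                   image_side = 64, seed = 1)
ens <- build_ensemble(generate_texture_set(params), factor = 1, seed = 2)
ens
#> texture_ensemble: 5 families x 8 samples (80 images, 64x64 px)
#>   preprocessing: downsample factor 1, contrast 0.22, mean 0.5

## two-stage feature model with structure-sensitive weights
two_stage <- synthetic_texture_spec()
w <- structured_weights(two_stage, seed = 1)
sel <- population_selector(spatial_neighborhood = 2, tap_point = "norm2")
tens <- compute_response_tensor(ens, two_stage, w, sel)
tens
#> response_tensor: 64 neurons x 5 families x 8 samples x 2 types

prof <- modulation_matrix(tens)
keep <- intersect(filter_valid_neurons(prof), filter_responsive_neurons(tens))
round(population_mean_modulation(prof, keep), 3)
#> [1] 0.271 0.153 0.288 0.167 0.236

## fit the population to a target modulation vector
target <- generate_planted_target(prof, sample(keep, 20))
greedy_subset(prof, target, k = 10)
#> texture_fit [greedy]: train error 0.01034, spearman 1.000, R^2 0.996
#>   10 selected neurons
full_population_weights(prof, target)
#> texture_fit [full_population]: train error 4.493e-16, spearman 1.000, R^2 1.000
```

Positive mean modulation across families says the second-stage population
responds more to the textures than to their phase-randomized partners —
the V2-like signature. The greedy subset of 10 equally weighted neurons
approaches the planted target closely, and the optimal simplex-weighted
average recovers it to numerical precision, as it must for a target lying
inside the population's convex hull.

`run_pipeline(pipeline_config(...))` chains all stages (stimuli → features
→ modulation → fits → cross-validation) and writes CSV tables, a JSON
summary and optional figures; `compare_structured_random()` runs the
trained-versus-random second-stage control on synthetic textures.

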