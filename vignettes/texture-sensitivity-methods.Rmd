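---
title: "Measuring texture sensitivity in convolutional feature hierarchies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring texture sensitivity in convolutional feature hierarchies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(v2texture)
```

## The model and its assumptions

Neurons in secondary visual cortex respond more strongly to naturalistic
textures than to *spectrally matched noise* — images sharing the texture's
Fourier amplitude spectrum but with randomized phases. Because first- and
second-order statistics are identical within a stimulus pair, a
differential response can only reflect sensitivity to higher-order
statistical structure. The package quantifies this with the modulation
index

$$M = \frac{r_{na} - r_{no}}{r_{na} + r_{no}} \in [-1, 1],$$

where $r_{na}$ and $r_{no}$ are a unit's mean responses to the
naturalistic and noise members of a stimulus family. The feature models
under study are stacks of the four computations standard in both
convolutional networks and visual neuroscience: linear filtering
(cross-correlation with zero padding), half-wave rectification, max
pooling, and local response normalization across channels,

$$b^i_{x,y} = \frac{a^i_{x,y}}
 {\left(k + \alpha \sum_{j=\max(0,\,i-m/2)}^{\min(N-1,\,i+m/2)}
 (a^j_{x,y})^2\right)^{\beta}},$$

with defaults $k = 2$, $m = 5$, $\alpha = 10^{-4}$, $\beta = 0.75$, the
sum clamped at the channel edges. Normalization is placed after pooling,
following the CaffeNet ordering of the reference architecture. The
`alexnet_spec()` geometry reproduces the printed receptive-field sides:
15 px at the first pooling output and 39 px at the second when the first
convolution strides by 2 (67 px with the standard stride of 4); the
`vgg_spec()` geometry gives 16 px at its second and 44 px at its third
pooling output.

Three assumptions are worth making explicit. Responses entering the
modulation index are taken at post-rectification tap points, so they are
nonnegative and the index is well defined whenever a unit responds at all
to a family. Grayscale stimuli fed to a spec declaring three input
channels are replicated across channels, the conventional treatment for a
color-trained front end. And model "neurons" are (filter, position) pairs
from a small centered spatial neighborhood — 2×2 by default — so that
their receptive fields cover the stimulus center with slight jitter.

## Stimulus preparation

`phase_randomize()` replaces all non-self-conjugate Fourier phases with
i.i.d. uniform draws while enforcing Hermitian symmetry; the DC and
Nyquist bins keep their original real values, which preserves the image
mean exactly and guarantees a real-valued output. Amplitude conservation
is exact up to floating point (the test suite requires 1e-8 relative
agreement bin by bin).

`downsample()` uses repeated 2×2 block averaging. The operation is
mean-preserving and anti-aliasing; strided subsampling is available behind
a flag for comparison. `contrast_normalize()` applies the affine map
$I_n = \alpha (I - l)/c + \beta$ with the *population* (divide-by-N)
standard deviation as $c$, making the output contrast exactly $\alpha$
for any image size; defaults are $\alpha = 0.22$, $\beta = 0.5$. Values
are not clipped: the map is affine by definition, and the feature model
accepts real-valued input. Noise partners are generated at the native
resolution, then both members of a pair are downsampled and normalized —
randomizing before downsampling keeps the pair's spectra matched at the
resolution where the noise is defined.

## The synthetic texture generator

The Portilla–Simoncelli machinery used to synthesize experimental texture
stimuli is out of scope; instead, `generate_texture_family()` plants
higher-order structure whose presence and location are known by
construction. Each family owns a reference amplitude spectrum: an
isotropic $1/f$ bed plus one or two oriented band-pass Gaussian bumps at
family-specific angles. A sample is built by (1) shaping white noise to
the oriented band and soft-thresholding it at two band standard
deviations — a pointwise nonlinearity that keeps roughly 5% of band
pixels as sparse, elongated, phase-aligned events; (2) adding an
independent Gaussian bed; (3) re-imposing the full family spectrum on the
composite. Texture/noise pairs therefore differ *only* in phase
structure, and that structure is confined to the family's orientation
band. `structure_strength` interpolates between pure spectrum-matched
Gaussian noise (0) and fully thresholded structure (1, the default).

Confining structure to a band, rather than thresholding the full-band
composite, is what gives "structure sensitivity" a meaningful definition
at the second stage: with broadband point events, any dense random readout
of rectified first-stage channels detects the events about as well as a
matched one, and the trained-versus-random contrast the package must
exhibit collapses. Band-limited events are visible to orientation-matched
filters and diluted in unselective mixtures — the frequency-localization
argument for why learned weights outperform random ones.

The generator consumes one named seed substream per (family, sample), so
enlarging an ensemble never changes existing images. Defaults (15
families × 15 samples, 320×320 px) mirror the experimental ensembles;
tests and examples use smaller ensembles (typically 5 families × 8
samples at 64×64) chosen to exercise the same code paths at interactive
problem sizes.

What the generator does *not* emulate: multi-scale correlation structure,
cross-orientation co-occurrence statistics, and the marginal-statistic
matching of real synthesized textures. Passing tests therefore show the
pipeline's operations are correct and that the qualitative
structured-versus-random ordering has a mechanism; they do not certify
quantitative agreement with cortical data, which would require the
original stimuli and recorded responses.

`generate_response_tensor()` bypasses images entirely: family-mean
responses are $s(1+m)$ and $s(1-m)$ for planted modulation $m$, so the
computed index recovers $m$ exactly at zero jitter; per-sample jitter is
Gaussian truncated at zero (responses are post-rectification, hence
nonnegative — truncation rather than resampling keeps the draw cheap and
deterministic).

## Modulation statistics

`modulation_matrix()` averages responses over a family's samples *before*
forming the ratio (the default); averaging per-sample indices first is
available behind the `order` flag. Both readings are consistent with how
such data are described; mean-first stabilizes the ratio when single-trial
responses are small. A unit whose summed family-mean response is zero for
some family has an undefined index there and is flagged invalid —
`filter_valid_neurons()` implements exactly this criterion.
`filter_responsive_neurons()` additionally screens units whose summed
response falls below a floor (default 25% of the median): near-silent
units carry indices with vanishing denominators whose values are noise,
and population analyses of recorded neurons routinely exclude
unresponsive cells. The screen matters mostly for random-weight controls,
which produce many near-silent units.

The permutation null (`null_modulation_distribution()`) shuffles
texture/noise labels within each (neuron, family) cell and reports the
2.5th/97.5th percentile band of the population mean modulation. The
experimental literature does not pin down its chance band's construction;
label permutation is the natural exchangeability null here.

## Population fitting

Let $M$ be the (neurons × families) modulation matrix and $t$ a target
vector, one mean modulation per family. Three procedures are provided.

**Greedy forward selection** grows a subset one neuron at a time, each
step minimizing the squared Euclidean distance between $t$ and the
equally weighted mean of the selected rows, stopping at $k$ (default 103,
the size of the recorded V2 population; 102 is conventional for V1-sized
populations). Ties break toward the lowest index for determinism. Greedy
error need not be monotone in $k$; what is guaranteed, and tested, is
that step 1 attains the minimum single-row distance and that greedy never
beats exhaustive search.

**Full-population weighting** solves
$\min_w \|M^\top w - t\|^2$ subject to $w \ge 0, \sum w = 1$. The
implementation is a primal active-set method on the bound constraints:
each subproblem is an equality-constrained quadratic solved from its KKT
system, with the pseudoinverse handling the rank-deficient
$\lambda = 0$ case (the objective is constant along null directions, so
any KKT solution is a subproblem minimizer). For $\lambda = 0$ the
iteration starts from the closest single row — by Carathéodory the
solution support is at most the number of families plus one, so the
active set stays small; for $\lambda > 0$ it starts from uniform weights.
Termination is by a 1e-9 KKT tolerance; finite termination makes the
solver exact to conditioning, which the planted-recovery test exercises
at 1e-8 on 500-neuron problems. The solver is cross-checked in the test
suite against enumeration on a refined simplex grid and against an
independent constrained least-squares implementation.

**Regularized selection** solves the same problem with a ridge term
$\lambda \|w\|^2$ (default $\lambda = 0.8$), which pushes weight toward
the center of the simplex and spreads mass over more units; the fraction
of weights at or above 2e-3 is reported. The final subset is the $k$
largest-weight neurons (ties toward the lowest index), *re-scored as an
equally weighted average* — matching how the recorded data's modulation
index is computed — so the reported train error refers to the
equal-weight subset, not the solver weights. When more than $k$ units
clear the threshold, top-$k$ by weight is the deterministic resolution.

Fits are scored by Euclidean error (directly related to root-mean-squared
error and sensitive to absolute values, appropriate for index data),
Spearman rank correlation, and explained variance $1 - SSE/SST$.

## Cross-validation

`make_cv_plan()` randomly partitions each family's samples into groups of
`group_size` (default 15); each group is one data point, held out in
exactly one fold. Fifteen families with 225 samples each yield the
225-point, 225-fold leave-one-out design. Per fold, the profile is
recomputed from training samples only, the population refit, and the
fitted population's mean modulation on the held-out samples compared with
the target entry for that family. Folds with undefined indices are
skipped, logged and counted rather than imputed — transparent, and rare
outside adversarial inputs. `leave_family_out()` instead fits on the
remaining families' columns and predicts the held-out family from the
selected population's profile entry for it, the natural predictor given
that selection is over neurons, not families.

## The structured-versus-random control

`compare_structured_random()` packages the qualitative control analysis:
two models share an oriented Gabor first stage; one uses
`structured_weights()` for the second stage, the other uniform
$[-1, 1]$ draws. The structured second stage is a zero-baseline collinear
coincidence detector — on each input channel, an elongated positive ridge
along the response ridge of that channel's preferred wave packet, minus
an isotropic local average. Zero net weight per channel slice makes the
unit event-driven rather than mean-driven; aligned integration responds
coherently to the elongated planted events while spatially scattered
activation cancels. Two comparisons are reported per replicate: the mean
modulation over responsive units, and the greedy fit error against a
target planted as the mean of a random 30% subset of the structured
profile on the same ensemble (the stand-in for a recorded target; the
representational claim does not require cross-validation — a population
whose profile cannot express the target fails on the training side
already). Replicates use 5 families × 8 samples at 64×64 px; at these
sizes one replicate runs in under a second and the ordering holds in
well over 95% of seeds.

## Numerical choices and degenerate inputs

Tie-breaks are everywhere by lowest neuron index. All randomness flows
through named substreams of a single integer seed, and every generator is
a pure function of its parameters and seed; callers' RNG state is saved
and restored. Degenerate inputs fail loudly: constant images cannot be
contrast-normalized; a map that shrinks below 1×1 names the offending
layer; an empty valid population raises an insufficient-population error
rather than returning an empty fit. PNG export quantizes to 8 bits
(≈2e-3), which is why ensembles are regenerated from seeds rather than
shipped as files.

## Known limitations

The feature extractor is plain R (BLAS-backed patch matrices); it is
sized for the synthetic ensembles and desk-scale experiments, not for
ImageNet-scale inputs. Real pretrained weights can be supplied through
`init_weights(mode = "provided")` together with `load_weight_set()`, but
no download or conversion path is included. Training, fully connected
layers and color processing are out of scope, as is reproducing the
numeric fit errors reported for recorded V2 data, which would require the
original stimulus set, pretrained weights and the recorded target vector.
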