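---
title: "Methods: nutrient-deficiency classification with Gabor features, a hybrid CNN-LSTM and ring-toss hyperparameter tuning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NutriVision)
```

## The problem and the pipeline

Nutrient deficiencies in crop leaves express as visually distinctive
symptoms: nitrogen starvation yellows the whole blade, phosphorus deficiency
produces dark purplish patches, potassium scorches the leaf margin, calcium
deficiency causes necrotic spotting near the apex, and iron deficiency shows
as interveinal chlorosis with the veins staying green. NutriVision classifies
an RGB leaf image into one of these five deficiency classes or a healthy
class, through five explicit stages: Gabor texture pre-processing, K-means
region-of-interest (ROI) segmentation, convolutional feature extraction,
hybrid CNN-LSTM classification with coarse and fine label heads, and
population-metaheuristic hyperparameter tuning. Everything — including the
convolution, LSTM, Adam optimizer and the metaheuristic — is implemented in
the package itself so each numerical claim can be tested against an
independent oracle.

## Synthetic data: what it emulates and what it does not

Field imagery of deficiency phenotypes is rarely redistributable, so the
package generates its own. Each image is an elliptical "leaf" on a dark
background (the background gives segmentation a genuine foreground task),
with a deterministic base pattern per class — stylized versions of the
symptoms above, chosen for visual separability — plus i.i.d. Gaussian pixel
noise (`noise_sigma`, intensity units on the [0,1] scale, default 0.02 in
pipeline recipes) clipped back to [0,1]. The generator is a pure function of
its specification: identical class counts, image size, noise level and seed
give byte-identical images and manifests. Stratified splitting uses per-class
half-up rounding of `trainFraction * n_c`, with any global remainder
corrected on the largest class so totals are deterministic; the conventional
protocols are 80:20 and 70:30.

What passing tests on this generator demonstrate is that the *pipeline
machinery* works: segmentation recovers a known foreground, features carry
class information, the classifier and its optimizer can fit and generalize
within the synthetic family, and every stage is reproducible. They do not
demonstrate field performance: real leaves vary in pose, illumination,
occlusion and symptom severity, and real phenotype boundaries are far less
separable than the stylized encodings here.

## Gabor pre-processing

The kernel is the product of an isotropic Gaussian envelope (space constant
`omega`, in pixels, identical along both axes) and a complex plane wave with
spatial frequencies `u` (horizontal) and `v` (vertical), in cycles per pixel,
evaluated at integer offsets within `[-halfSize, halfSize]`. The printed
form of the plane-wave phase in the source literature is ambiguous
("u_x + v_y"); the package reads it as the products `u·x + v·y`, the only
dimensionally sensible interpretation of a Gabor grating. Filtering is true
spatial convolution (kernel rotated 180°, zero padding, same-size output);
the real pre-processed image is the pointwise modulus of the complex
response, rescaled by its maximum — standard Gabor-energy practice, since no
reduction from the complex response is prescribed by the method description;
`real` and `imag` responses are available behind the `response` argument.
Defaults `omega = 2`, `u = 0.125`, `v = 0`, `halfSize = 12` were chosen once
as a mid-band horizontal-texture filter at the 64×64 working resolution and
are exposed in the configuration. RGB images are first reduced to Rec. 601
luminance. An optional plain histogram equalization (CDF remap over 256
bins) can sharpen contrast before filtering; it stands in for the
"dynamic fuzzy" equalization sometimes named in this context but never
specified by a formula.

## Segmentation and ROI selection

Per-pixel features are the colour channels (or luminance), optionally
augmented with a 3×3 local-mean channel that encourages spatially coherent
clusters. Lloyd's algorithm minimizes within-cluster squared Euclidean
distance with: seeded initialization by uniform choice of `k` distinct
points, empty clusters re-seeded at the point farthest from its centroid,
and termination when the inertia improvement falls below `tol` or `maxIter`
is reached. `k = 3` by default (healthy tissue / symptomatic tissue /
background). Since no ROI-selection rule follows from K-means itself, the
package declares one: the cluster owning the highest fraction of
image-border pixels is background (ties broken by lower mean luminance), and
the ROI is the union of all other clusters. The ROI mask zeroes background
pixels of both the Gabor image (classifier-trunk input) and the RGB image
(feature-extractor input). A constant image has no distinct points to
cluster and raises a "degenerate clustering" error rather than fabricating
a partition.

## Feature extractor and the 39/42 counting convention

The extractor is a compact SqueezeNet-style network: a 3×3 stem convolution,
four fire modules (squeeze 1×1 convolution feeding parallel expand 1×1 and
3×3 convolutions whose outputs concatenate), three 2×2 average-pooling
stages, one deep convolution with an enlarged 5×5 filter (the smallest
strictly larger odd size than the 3×3 used elsewhere), dropout, global
average pooling and a linear feature head. Every convolution keeps stride 1
— downsampling happens only in pooling — which postpones resolution loss and
keeps activation maps large. Counting every graph node as a layer (input,
convolutions, ReLUs, pools, concatenations, dropout, global pool, linear
head) and every directed edge as a connection (concatenations have two
incoming edges), the default build has 39 layers and 42 connections; the
convention is documented beside the builder because the counts are
meaningless without it. Dropout sits before global pooling — placed there,
once, as the last spatial tensor is the natural place to regularize; either
placement is defensible. When feature training is requested, a temporary
six-way softmax head is attached, the whole network is trained with the
package's Adam optimizer under cross-entropy, and the head is dropped; no
pretrained weights are involved (none exist for this compact variant), and
by default the pipeline uses the seeded random-initialized network as a
fixed feature projection, which is sufficient on the synthetic family
because class identity is linearly recoverable from projected colour
statistics.

## The hybrid classifier

The trunk follows `IMAGE → [(CONV→RELU)*N_CR → POOL]*N_CRP → FC` with
`N_CR ≤ 5` (default 1) and `N_CRP` defaulting to 3 at the 64×64 working
size. The rows of the final feature map are consumed as a sequence by an
LSTM — a declared construction, since no specific image-to-sequence mapping
is standard. The printed LSTM equation set this design descends from labels
its fourth gate with the cell-state symbol and never states the cell
accumulation; the package implements the standard, internally consistent
form: input gate `i`, biasless candidate `g = tanh(·)` (the printed
candidate carries no bias, and that is preserved), forget gate `f`, output
gate `o`, `c_t = f⊙c_{t-1} + i⊙g`, `h_t = o⊙tanh(c_t)` — the only reading
under which `h_t = o·tanh(c_t)` is well defined. The final hidden state,
concatenated with the extracted feature vector, feeds two softmax heads:
coarse (deficient vs healthy — the only binary grouping the six-class
taxonomy implies) and fine (six classes), arranged in parallel by default; a
sequential arrangement, where the fine head additionally reads the coarse
probabilities, is available. The loss is
`CE(fine) + λ·CE(coarse)` with `λ = 0.5`, minimized by the package's Adam.

## Adam

The optimizer follows the bias-corrected two-moment scheme exactly, with
defaults `α = 0.001`, `β₁ = 0.9`, `β₂ = 0.999`, `η = 1e-8`, and the
denominator offset added *after* the square root (`√v̂ + η`) — the pseudocode
it implements is followed literally even though the inside-the-root variant
also circulates. It operates on a flat parameter vector with a
path/shape registry, so the identical tested code serves the feature
extractor (nested layer lists) and the classifier. "Until converged" is
realized as a fixed step budget with an optional gradient-norm tolerance.
Training is full-precision deterministic given a seed; single-step behaviour
is pinned to a hand trace at 1e-12 in the tests.

## Ring Toss Game Optimization

RTGO minimizes a bounded objective with a population of `N` candidate
positions. Each iteration, the best `max(1, round(0.10·N))` members become
score bars (the elite); every member is assigned one uniformly at random and
throws: per dimension, `r ~ U[0,1]`, `F = round-half-up(1 + r) ∈ {1, 2}`
(drawn from the *same* `r`, a literal reading of the shared symbol), and
`dx_d = r(sb_d − F·x_d)` if the bar beats the member, else
`dx_d = r(x_d − F·sb_d)`. Candidates are clipped to the bounds (integral
dimensions rounded half-up) and accepted only on strict improvement, so the
best-so-far trace is non-increasing by construction. Design points decided
here: one `r` per dimension (vector throw) for search diversity; elites
re-selected every iteration; uniform member-to-bar assignment (direct
pairing is impossible with fewer bars than members); half-up tie rule at
`r = 0.5` (a measure-zero event either way). For hyperparameter tuning the
objective is the validation error rate (percent) of a reduced-budget
classifier training run over a 4-dimensional space — learning rate
`[1e-4, 1e-2]`, dropout `[0, 0.5]`, LSTM width `{8..40}`, batch size
`{8..32}` — a declared choice of the four knobs that most affect this
model family.

## Metrics

Each class is scored one-vs-rest: accuracy `(TP+TN)/total` (the only
definition under which six per-class accuracies can differ), precision,
recall, specificity, F-score `2PR/(P+R)`, and MCC — all on the percent scale
with MCC ×100 to match conventional tabulations. Macro averages are
unweighted means across the six classes; reports expose macro recall also
under its common alias *sensitivity*. Zero denominators (a class never
predicted, say) yield 0 with a warning rather than NaN. Formatted output
rounds half-up to two decimals; full precision is kept internally.

## Numerical choices and degenerate inputs

* Convolutions use im2col gather plus BLAS matrix products; backward passes
  are hand-derived and verified against central finite differences at 1e-6.
* K-means stops on inertia improvement `< 1e-8` by default; restarts
  (`nstart`) take the lowest-inertia solution.
* Softmax subtracts the row maximum before exponentiation; cross-entropy
  clamps probabilities at 1e-12.
* Gabor responses with an all-zero maximum stay all-zero rather than
  dividing by zero.
* All randomness descends from one root seed through a documented per-stage
  derivation, so every artifact (manifest, masks, features CSV, metrics
  JSON) is bit-reproducible from `(config, seed)`.

## Problem sizes used by the test-suite and acceptance script

Chosen as desk-scale workloads that still exercise every stage: the pinned
end-to-end experiment uses 300 images (50 per class) at 64×64 with noise
0.02, an 80:20 stratified split and 30 training epochs (the protocol cap),
repeated over three seeds; tuning evaluations train on 96-image subsets for 4 epochs with a
population of 5 over 3 iterations; the sphere benchmark runs 30 members for
200 iterations over 20 seeds. The oracle-equivalence suites use 50 random
small instances per numeric kernel.

## Known limitations

* The synthetic phenotypes are stylized; accuracy there is an upper bound,
  not an estimate, of field performance.
* Adam's per-epoch loss trajectory oscillates on small full-batch problems;
  convergence claims are therefore about the trend and endpoint, not
  per-epoch monotonicity.
* The layer/connection counts of the feature extractor are meaningful only
  under the documented counting convention.
* RTGO as specified contracts toward the origin on symmetric objectives
  (the `F·x` term); its benchmark dominance over random search is
  demonstrated on the sphere family, not claimed universally.
* No data augmentation beyond additive noise; no GPU path — the
  implementation favours inspectability over throughput.
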