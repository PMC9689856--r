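---
title: "wcepipe: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{wcepipe: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which
parameters matter, and where the design was genuinely open. The companion
README shows a worked run; nothing stated here goes beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## The pipeline at a glance

`run_pipeline()` chains five stages, each usable on its own:

1. `enhance()` — hybrid contrast enhancement;
2. `train_saliency_cnn()` + `segment_frame()` — saliency-guided lesion
   segmentation and localization;
3. `build_backbone()` / `finetune()` / `extract_features()` — embedding
   extraction, with `tune_hyperparams()` choosing the fine-tuning
   hyperparameters by Bayesian optimization;
4. `hybrid_select()` — whale / Harris-Hawks wrapper feature selection;
5. `elm_train()` / `elm_predict()` / `evaluate_predictions()` —
   classification and metrics.

Images are plain `H x W x 3` arrays of doubles in `[0, 1]` throughout;
8-bit files are rescaled on read and write. Every stochastic stage draws
its seed deterministically from the pipeline's global seed, so a config
plus a seed fully determines a run, including bit-identical reruns.

## Contrast enhancement

The chain is: channel split → per-channel denoise → white top-hat and
black bottom-hat (disk structuring element) → hat fusion → dark-channel
dehazing of the fused image → multiplicative final fusion
`clamp(hz * (fused * top) + hz)`.

Parameters, defaults, and reasons:

* **Structuring-element radius** (`selem_radius`, pixels, default 5 at
  256×256): the scale separating "detail" (vessels, bubbles, lesion
  margins) from "background". Structures wider than the disk are removed
  by the opening/closing and therefore do not appear in the hats.
* **Denoiser** (`denoiser`, default `"median"`): an exact 3×3 median
  (computed with a 19-operation min/max selection network, so it agrees
  with a brute-force oracle to machine precision). `"nlm"` is a patch-based
  non-local means (3×3 patches, 5×5 search window, bandwidth `h`);
  `"identity"` disables denoising. The median suppresses exactly the
  salt-type specular highlights the synthetic bubbles emulate.
* **Dehazer** (`dehaze_patch` 15 px, `dehaze_omega` 0.95, `dehaze_t0`
  0.1): the canonical single-image dark-channel prior. The atmospheric
  light is the per-channel mean over the brightest 0.1% of dark-channel
  pixels; the transmission floor `t0` keeps the recovery bounded on
  degenerate inputs (an all-white frame passes through untouched). The
  prior assumes haze-free patches have a near-zero minimum channel — true
  for colorful, vignetted endoscopic scenes, not for flat gray ones.

**The hat-fusion mode is the one place this package knowingly departs from
the formula it set out to implement.** The "replace" fusion
`clamp(top + bot − image)` is identically zero wherever the hat responses
do not exceed the pixel intensity — which is everywhere, for any normally
lit frame — and a zero fused image blanks every later stage (the dehazer
and the final fusion are both multiplicative in it). We verified this
degeneracy directly: on synthetic frames the "replace" chain returns
essentially black images for typical bright scenes. The default is
therefore the classic morphological contrast enhancement
`clamp(image + top − bot)` (`hat_mode = "additive"`), which uses the same
three terms, amplifies bright fine structure, suppresses dark fine
structure, and never annihilates the scene. The literal formula remains
available as `fuse_hat(mode = "replace")` and
`enhancement_config(hat_mode = "replace")` for comparison.

## Saliency segmentation

The 14-layer CNN (3 convolutions 3×3 stride 2, each with batch-norm and
ReLU; 2×2 stride-2 max-pools after the first two blocks; global average
pool; fully connected; softmax) is trained on *enhanced* frames with SGD.
Defaults follow the stated training recipe — learning rate 0.05, momentum
0.6, mini-batch 32, dropout 0.5 before the FC layer, 100 epochs — with the
epoch count reduced to 8 at fixture scale (the loss plateau on 30-frame
fixtures is reached far earlier; the setting is exposed in
`saliency_train_config()`). Training uses a global gradient-norm clip of 5
so the high default learning rate cannot produce non-finite losses, and
batch-norm statistics are recalibrated with one full eval pass after
training.

The saliency map reads the **second convolution block's response maps** on
the enhanced frame. Three choices here were open and are worth recording:

* *Activations, not kernel weights.* 3×3 kernel weights cannot form an
  image-sized, image-specific map; the standard deep-saliency reading uses
  the layer's response to the input. A literal weights mosaic is kept
  behind `source = "weights"` for inspection.
* *Polarity invariance.* A lesion can be a bright blob in one filter's
  response and a low-activation hole in another's; both are equally
  informative. Each map therefore enters as the absolute deviation from
  its own spatial mean before min-max normalization. Without this, the
  merged map's polarity depends on the random initialization.
* *Border trim.* The outermost ring of second-conv activations sits on
  receptive fields that touch the zero padding and lights up on dark
  frames regardless of content; it is dropped before upsampling.

Maps are ranked by spatial variance (the automated proxy for "has clear
pattern"), the top `k` (default: half the filters) averaged, upsampled,
and min-max normalized; a constant map normalizes to all-zeros. The map is
refined by adding the enhanced frame's channel mean and renormalizing,
then thresholded at its arithmetic mean, ties to foreground. Closing
(disk radius 2) and hole filling clean the mask.

Localization runs a light Chan–Vese-style two-phase contour (region means,
3×3 majority smoothing as the regularizer, 50 iterations) **on the
saliency map** inside a window 25% larger than each component: evolving on
the map rather than on image intensity makes the kept phase the *salient*
one rather than the *bright* one, which matters for dark lesions. Each
refined region is closed (radius 3) and hole-filled — an open annular
contour around a lesion with contrasting interior becomes a filled blob —
and a region that collapses below `min_area` (default 64 px at 256 scale,
32 at 64) falls back to the raw component. Boxes are 0-based, half-open;
regions sort by area, largest first. The union of region masks is the
final segmentation; crops are taken from the original frame, which keeps
the full color signal for the classifier.

## Backbone features and Bayesian optimization

`"mobilenet_v2"` is the complete MobileNetV2 topology (stem conv,
17 inverted-residual bottlenecks with expansion 6, ReLU6, 1×1 head conv to
1280, global average pool) implemented in the package's own CNN engine and
run forward-only with a trainable dropout+linear head — the embedding
width 1280 is architecture-determined and needs no pretrained weights.
Fine-tuning for this backbone trains the replaced head on frozen
embeddings (linear probing); the fully trainable path is `"tiny_cnn"`
(three conv blocks to a configurable embedding width, default 64, input
64×64), which the tests and the pipeline default use. Crops are resized to
224×224 for MobileNetV2 and 64×64 for the tiny backbone.

The CNN engine itself is plain R on BLAS: convolutions as
shift-and-multiply matrix products, exact backward passes for every
trainable layer (verified against finite differences at 1e-10 relative
error), SGD with momentum and L2 weight decay.

Hyperparameters (learning rate 1e-4–1 and L2 1e-10–1e-2 on log scales,
momentum 0.6–0.8 linear) are tuned by minimizing the validation error of a
short proxy fine-tune (3 epochs by default) under a from-scratch GP
Bayesian optimizer:

* **Kernel**: Matérn 5/2 with per-dimension length scales — the modern BO
  default; meta-parameters by marginal-likelihood maximization from three
  fixed starts (L-BFGS-B on log parameters), jitter 1e-8 on the kernel
  diagonal. The jitter implies a posterior sd of about 1e-4 at noiseless
  observations; tests bound expected improvement there accordingly.
* **Acquisition**: expected improvement, maximized over 256 uniform
  candidates with local refinement of the best five (Brent in 1D,
  Nelder-Mead otherwise). Minimization convention throughout; a
  non-finite objective value is recorded with a worse-than-worst penalty.
* **Budget**: Latin-hypercube initial design of 5 plus 15 rounds by
  default (4+10 suffices for the 1D sanity problem in the tests).

## Feature selection

Agents live in `[0, 1]^D`; a sigmoid transfer centered at 0.5 followed by
a 0.5 cut yields the column mask, with the largest-position column forced
on if a mask would be empty. The whale phase updates each agent by the
spiral rule `|Y* − Y| e^{al} cos(2πl) + Y*` (spiral constant `a = 1`,
`l ~ U[−1,1]`) when a uniform draw is at or above the **median** of the
agent's position values, and otherwise encircles the best agent
(`|W| < 1`) or a random agent (`|W| ≥ 1`), `W = 2cd − c` with `c = 2 −
2v/V` declining linearly from 2 to 0. The distance terms carry absolute
values, as in the original whale algorithm — without them the update is
not a contraction toward the target. Ties at the median go to the spiral
branch. The branch statistic can be switched to the population-fitness
median (`md_source = "fitness"`).

The Harris-Hawks refinement keeps the two exploration branches — perch
near a random agent (`Yrand − d1 |Yrand − 2 d2 Y|`) when a uniform draw is
at or above the **mean** of the agent's position values, otherwise
`(Ybest − Ymean) − d3(lb + d4(ub − lb))` with bounds `[0, 1]` — and by
default searches the *submatrix* of whale-selected columns
(`hho_scope = "full"` re-searches everything warm-started at the whale
mask). The incoming mask's fitness is the incumbent, so refinement can
never return something worse (elitism), and the best-so-far history is
monotone non-increasing across both phases.

**Fitness** is the mean holdout error rate of an ELM (100 hidden units for
the inner loop) over **three** seeded stratified 70/30 splits, plus
`1e-6 · k/D` so that equal-error masks prefer fewer columns. The
repetition count is a deliberate choice: a single 30% holdout of 200
samples measures error in steps of 1/60, and that granularity stalls the
search on plateaus; averaging three splits smooths the landscape markedly
(the planted-recovery test in the suite is run at exactly the conditions
where this matters). Fitness values are memoized per mask, so the cost of
repetition is amortized across revisits. The realized selected count is
data-dependent and simply reported — no target dimensionality is
enforced.

## Classifier

The ELM uses seeded uniform input weights and biases in `[−1, 1]`, a
sigmoid hidden layer (500 units, ridge 1e-6 by default), one-hot targets,
and an exact ridge solve; multi-class prediction is the argmax of the
class scores. Training is a single linear solve, so the whole model is
reproducible bit for bit under its seed and serializes to a JSON bundle.
The pipeline evaluates on a stratified 50:50 split by default; a 10-fold
cross-validation mode is available (`split = "tenfold"`), and the report
states which was used.

## What the synthetic data does and does not emulate

`make_frames()` renders: a mucosa-pink base with smooth value-noise
texture; elliptical lesions with a ±0.3 channel-mean contrast shift (dark
ulcer-like classes vs pale polyp-like classes, exact ellipse masks as
ground truth); small bright discs emulating specular bubbles (the
denoiser's target); an additive white haze veil of weight 0.2 (the
dehazer's target); and a radial illumination falloff of strength 0.6
(endoscope optics are strongly vignetted — and a flat, uniformly bright
background would additionally sit in the hat-fusion's degenerate regime,
which real frames do not). A generator self-check asserts the realized
lesion contrast on every call. `make_table()` plants `k` informative
columns with class-separated means (`effect` in noise-sd units) among
standard-normal noise and returns the informative indices.

Passing tests on these fixtures demonstrates that each stage does what its
contract says on data containing exactly the artifact that stage targets.
It does **not** demonstrate clinical performance: real WCE frames have
vascular texture, folds, peristalsis blur, compression artifacts, and far
subtler lesion boundaries than soft-edged ellipses, and the real datasets'
headline accuracies require full-scale pretrained transfer learning that
is out of scope here.

## Problem sizes and numerical conventions

The suite runs at fixture scale as the package's own choice of desk-scale
conditions: 64×64 frames (60 for the end-to-end run, 40 for the
segmentation floor), the tiny backbone at embedding width 64, selection at
`n = 200, D = 50, k = 5`, effect size 2, population 10 with 50 whale
iterations (scaled down from the 200-iteration default), and BO budgets of
a few dozen evaluations. Elementwise stages agree with scalar-loop oracles
to machine precision; the GP agrees with a dense linear-algebra oracle to
1e-8; expected improvement agrees with quadrature to 1e-4; swarm updates
agree with hand-stepped scalar traces under a pinned RNG. Degenerate
inputs are defined, not errors: constant images produce zero hats and
all-zero saliency maps, constant maps binarize to all-foreground (the `≥`
tie rule), empty masks localize to an empty region list, and an empty crop
list extracts a `0 × D` matrix.

## Known limitations

* The saliency CNN at 64-px fixtures reads lesions from a 14×14
  activation grid; localization accuracy is bounded by that resolution,
  which is why the segmentation floor is asserted as a mean IoU of 0.3
  rather than a per-frame guarantee.
* MobileNetV2 runs with random initialization unless weights are supplied;
  its embeddings are structure-preserving but not semantically pretrained,
  and fine-tuning it is head-only.
* The active contour is a light region-competition scheme with majority
  smoothing, not a full level-set solver; it inherits the two-phase
  assumption and can absorb salient neighbors of a lesion.
* The whale/Harris-Hawks selector is a stochastic wrapper: across seeds it
  recovers most, not always all, of a planted informative set, and the
  realized mask size varies with the data.
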