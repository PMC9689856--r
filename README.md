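# wcepipe

Automated analysis of wireless capsule endoscopy (WCE) style RGB frames:
contrast enhancement, saliency-guided lesion segmentation, deep-feature
extraction with Bayesian-optimized fine-tuning, metaheuristic feature
selection, and extreme-learning-machine classification — as one seeded,
fully testable R pipeline.

WCE produces tens of thousands of frames per patient; reviewing them
manually is slow and error-prone, and computer-aided pipelines struggle with
low lesion contrast, specular "bubble" highlights, haze veils, and the
redundancy of generic deep features. `wcepipe` addresses each of these with
a dedicated, individually testable stage. No external image collection is
required: seeded generators produce endoscopy-like frames with exact
ground-truth lesion masks, and feature tables with known informative
columns, so every claim the package makes is checked by its test suite.

## The method

1. **Hybrid contrast enhancement.** Each frame is split into channels,
   denoised per channel (exact 3×3 median by default; identity and
   non-local-means are available), then filtered with white top-hat and
   black bottom-hat transforms (disk structuring element, radius 5 at
   256×256 scale). The hats are fused with the frame
   (`I + tophat − bothat`, clamped to `[0,1]`), the fused image is dehazed
   with the dark-channel prior (`t = max(1 − 0.95·dark(I/A), 0.1)`, `A`
   from the brightest 0.1% dark-channel pixels), and a final multiplicative
   fusion `clamp(hz·(fused·top) + hz)` yields the enhanced frame.
2. **Saliency segmentation.** A compact 14-layer CNN
   (3× [conv 3×3, stride 2 → batch-norm → ReLU], max-pools after the first
   two blocks, global average pool, fully connected, softmax) is trained on
   enhanced frames with SGD (defaults: lr 0.05, momentum 0.6, batch 32,
   dropout 0.5). The second convolution's response maps — made
   polarity-invariant and ranked by spatial variance — are merged (top-k,
   default half the filters), upsampled, added to the enhanced frame's
   channel mean, and thresholded at the map mean. Morphological closing and
   hole filling, then a Chan–Vese-style active contour evolved on the
   saliency map, produce localized lesion regions.
3. **Backbone features.** Localized crops feed a backbone:
   a full MobileNetV2 topology (inverted residual bottlenecks, ReLU6,
   1280-dim average-pool embedding; forward pass with a trainable head) or
   a small fully trainable CNN for fixture-scale work. Fine-tuning
   hyperparameters — learning rate (1e-4–1, log scale), momentum
   (0.6–0.8), L2 (1e-10–1e-2, log scale) — are chosen by from-scratch
   Gaussian-process Bayesian optimization (Matérn 5/2 ARD kernel, expected
   improvement `EI = σ[γΦ(γ) + φ(γ)]`, Latin-hypercube initial design).
4. **Hybrid feature selection.** A whale-optimization phase (encircling /
   random-search / logarithmic-spiral updates; the spiral branch fires when
   a uniform draw exceeds the *median* of the agent's position values;
   coefficient `c = 2 − 2v/V` declines linearly) is followed by a
   Harris-Hawks exploration phase (branch rule on the *mean* of the
   position values). Continuous positions in `[0,1]^D` are thresholded at
   0.5 into column masks; fitness is the mean holdout error of an ELM over
   three seeded stratified splits, with ties broken toward fewer features.
5. **Classification.** A single-hidden-layer extreme learning machine:
   random sigmoid hidden layer (500 units by default), output weights from
   ridge-regularized least squares `β = (HᵀH + λI)⁻¹HᵀT`, evaluated by
   accuracy, per-class recall, and a confusion matrix on a stratified 50:50
   split (10-fold mode available).

## A worked example

```r
library(wcepipe)

cfg <- pipeline_config(seed = 1,
                       recipe = frame_recipe(n_frames = 60, size = 64,
                                             seed = 101))
report <- run_pipeline(cfg)
print(report)
```

```
pipeline run (variant=full, split=half, seed=1)
  accuracy: 0.9333  (n_train=30, n_test=30)
  features: 64 -> 1
  segmentation mean IoU: 0.346
  confusion (rows = true):
    predicted
true  1  2
   1 15  0
   2  2 13
```

Sixty synthetic frames (two lesion classes: dark ulcer-like and pale
polyp-like) are generated, enhanced, and segmented; a small backbone is
fine-tuned on the training half's localized crops; the 64-dim embeddings
pass through whale/Harris-Hawks selection (here collapsing to a single
highly discriminative column); and the ELM classifies the held-out half at
93% accuracy. The mean intersection-over-union of the localized masks
against the generator's ground truth is 0.35. Rerunning the identical
config and seed reproduces the report bit for bit.

The ablation mirror of the study design (`run_ablation(cfg,
c("raw", "enhanced", "segmented", "full"))`) runs any subset of pipeline
prefixes on one shared split for controlled comparison.

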