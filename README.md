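# irbedpose

2D sleeping-pose estimation of in-bed subjects from single-channel
long-wavelength infrared (LWIR) frames.

LWIR cameras suit patient monitoring — they work in darkness, preserve
privacy, and see body heat through thin bedding — but annotated data
exists mainly for *uncovered* subjects: once a blanket is added, limbs
fade and labelling becomes impractical. This package implements a
training pipeline for exactly that asymmetry, aimed at researchers
working on in-bed monitoring and on domain adaptation for keypoint
regression in general:

* **Statistical cover augmentation.** A cover scales emitted intensity
  by `F = exp(-αx)`. Per-frame factors are estimated from unannotated
  covered frames as `F ≈ max(lower region) / max(upper region)` (the
  head area stays uncovered) and applied to annotated uncovered frames
  within a thresholded body mask, modulated by a procedural wrinkle
  field — plus sensor noise, random occlusion and left/right-aware
  horizontal flips.
* **Heatmap pose network.** An encoder-decoder with a per-channel
  spatial softmax emits 14 keypoint probability maps, trained with the
  summed per-channel MSE `L = Σᵢ (h_Gᵢ − h_Pᵢ)²` and a Gaussian target
  radius that shrinks from 3 px to 1 px over the first 30 epochs. A
  compact CPU backbone is built in; larger encoders plug in.
* **Sub-pixel decoding.** Flip-averaged inference (mirror, swap
  left/right channels, average), argmax seeding, then 3 iterations of
  centre-of-mass refinement over a 5×5 window.
* **Semi-supervised adaptation.** Covered frames are pseudo-labelled,
  each (image, heatmap) pair is scored by a *pose discriminator* with a
  pose-attention block, and only scores strictly above τ = 0.7 are kept
  for retraining, iterated until validation stops improving.
* **Evaluation.** PCKh@t (error ≤ t × head–neck length) and the
  normalised area under the PCKh curve, `AUC% = 100 · (1/0.5) ∫₀^0.5
  pckh(t) dt`.
* **GAN cover synthesis** (optional, off the default path): a
  style-transfer generator and patch discriminator with the composite
  losses `L_G = g₁+g₂+g₃+g₄`, `L_D = 0.5(d₁+d₂)`.

Everything runs against a built-in synthetic fixture generator
(articulated 14-keypoint lying subjects rendered as warm capsules, with
covered variants produced by the package's own cover synthesis and the
true attenuation factor recorded), so the full pipeline is exercisable
on one CPU with no external data. See the methods vignette
(`vignettes/irbedpose-methods.Rmd`) for the model details and design
rationale.

## Worked example

```r
library(irbedpose)

# A small synthetic study: 12 annotated uncovered training frames,
# 2 x 8 unannotated covered frames, covered validation and test splits.
dir <- file.path(tempdir(), "demo")
manifest <- build_manifest(n_uncovered = 12, n_thin = 8, n_thick = 8,
                           n_val = 4, n_test = 4, seed = 1,
                           out_dir = dir, height = 64, width = 48)

# Estimate attenuation factors from the covered frames.
covered <- manifest_frames(manifest, split = "train",
                           cover = c("thin", "thick"))
bank <- estimate_attenuation_factors(covered)
print(bank)
#> <attenuation_bank n=16 mean=0.679 range=[0.520, 0.877]>

# Compare with the recorded ground truth the fixtures were built with:
mean(abs(bank$factors - unlist(manifest$true_factors)[1:16]))
#> [1] 0.03708901

# Encode a pose to heatmaps and decode it back, sub-pixel.
pose <- manifest$poses[["frame_0001.png"]]
stack <- encode_pose(pose, shape = c(32, 24), scale = 2, radius = 2)
decoded <- decode_pose(stack, refinement_params(d = 5, iterations = 3))
max(abs(decoded$pose - pose))
#> [1] 0.06956648

# Evaluate (here: near-perfect predictions give the ceiling).
evaluate_poses(list(decoded$pose), list(pose))
#>   pckh_05 pckh_02 auc_percent
#> 1     100     100    97.71429
```

The attenuation bank's mean of ~0.68 reflects the fixture mixture of
thin covers (F drawn from U(0.72, 0.90)) and thick covers
(U(0.42, 0.62)); the estimated factors land within a few hundredths of
the recorded truth on average (wrinkled covers bias the ratio slightly
low). The encode→decode error of 0.07 *input* pixels — with the heatmap
at half resolution — is well inside the half-heatmap-pixel decoding
contract, and the evaluation report shows the three headline columns
(PCKh@0.5, PCKh@0.2, AUC%) used throughout.

Training runs the same way at any scale:

```r
cfg <- default_config(seed = 7)           # τ = 0.7, AdamW schedules, d = 5
res <- run_training(manifest, cfg)        # priming → augmented adaptation
res$history                               #   → pseudo-label loop
```

## Command line

A thin wrapper over the same functions is installed at
`inst/cli/irbedpose`:

```sh
irbedpose fixtures --n-uncovered 30 --n-thin 25 --n-thick 25 \
          --n-val 4 --n-test 6 --seed 1 --out data/
irbedpose augment  --in data/ --out aug/ --seed 1
irbedpose train    --manifest data/ --config run.yaml --out run/
irbedpose evaluate --pred preds.json --gt gt.json --report report.csv
```

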