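# augforge

Label-preserving image data augmentation for small scientific image sets,
and an ensemble harness that turns augmentation diversity into classifier
diversity.

Small labeled image collections — electron-microscopy virus textures, bark
photographs, spectrogram-like detector glitches — are too small to finetune
a deep classifier without heavy overfitting. `augforge` implements eleven
augmentation procedures (**App1–App11**) that generate class-preserving
variants of each training image, and a harness that trains one classifier
per augmentation method and fuses the per-class softmax scores by **sum
rule**: for score matrices `S₁ … Sₖ` (rows = test samples, columns =
classes), the fused prediction for sample *i* is
`argmax_c Σₖ Sₖ[i, c]`, ties toward the lowest class index.

The methods, with the number of images each generates per input:

| family | methods | images per input |
|---|---|---|
| geometric | App1 (reflect + anisotropic scale), App2 (+ rotation, translation, shear), App3 (App2 minus shear) | 3, 6, 4 |
| subspace coefficients | App4 (PCA basis fit on training data), App5 (2-D DCT, DC never changed) | 3, 3 |
| photometric | App6 (contrast stretch, sharpen, color shift), App7 (HSV jitter, blur, sharpen, shift), App8 (histogram specification + Reinhard transfer toward a same-class target) | 3, 7, 2 |
| elastic | App9 (raw and low-pass-filtered random displacement fields) | 6 |
| transform-domain | App10 (single-level db1 wavelet coefficient perturbation), App11 (column-wise constant-Q coefficient perturbation) | 3, 3 |

App4, App5, App10 and App11 share three coefficient perturbations: random
zeroing (p = 0.5), bounded additive noise scaled to the coefficient spread,
and element swaps (p = 0.05) with five same-class peer images. The
transform-domain pair rests on exact analysis/synthesis: the Haar
decomposition reconstructs to ≤ 1e-10 and the constant-Q frame (12 bins per
octave plus a DC band, least-squares synthesis) to machine precision.

All randomness flows through seeded, forkable streams: one seed gives
bit-identical augmented sets.

## Worked example

```r
library(augforge)

# a synthetic 3-class set: oriented gratings with per-class frequency
set <- make_fixtures(n_classes = 3, per_class = 6, size = c(32, 32),
                     channels = 3, seed = 101)
set
#> <labeled_image_set: 18 images, 3 classes (class01, class02, class03), C=3>

# augment one image with the wavelet method (3 outputs, shape preserved)
rng <- rand_source(1)
out <- augment_image(set$images[[1]], "App10", rng, set = set, index = 1)
length(out)
#> [1] 3
out[[1]]
#> <raster_image 32x32x3, range [0.000, 0.928]>

# assemble a training set: originals + 3 per image under App1
aug <- build_training_set(set, "App1", rand_source(2))
length(aug$images)
#> [1] 72

# five-method ensemble vs no-augmentation baseline on held-out fixtures
test <- make_fixtures(3, 5, c(32, 32), 3, seed = 202)
res <- evaluate_ensemble(ensemble_spec("ensda_5", set), set, test,
                         train_config(epochs = 120, hidden = 8),
                         rand_source(3))
res$report
#>   member  accuracy
#> 1   App1 0.8666667
#> 2   App2 0.8666667
#> 3   App3 0.8666667
#> 4   App4 0.8666667
#> 5   App5 0.8666667
#> 6  fused 0.8666667
```

Each row is one ensemble member (a classifier trained on the base set plus
that method's augmented images) scored on the held-out fixtures; the last
row is the sum-rule fusion. Every number is deterministic under the given
seed.

A command-line interface wrapping these functions ships at
`inst/cli/augforge.R` (subcommands `fixtures`, `augment`, `inspect`,
`evaluate`).

## Scope

The package generates augmented image sets and evaluates desk-scale
ensembles. Downloading benchmark image collections and finetuning
ImageNet-pretrained deep networks on them are outside its scope; the
`train_config()` interface names a `"reference"` backbone slot for such a
network, but only the bundled tiny backbone is provided.
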