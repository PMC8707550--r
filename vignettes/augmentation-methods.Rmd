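---
title: "Augmentation methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Augmentation methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(augforge)
```

# The problem

Convolutional classifiers overfit badly on the small labeled image sets
typical of microscopy, bark/texture, and other scientific imaging problems.
Label-preserving data augmentation counters this by synthesizing variants of
each training image. `augforge` implements eleven augmentation procedures
(App1–App11) spanning five families — geometric, subspace-coefficient,
photometric, elastic, and transform-domain — plus an ensemble harness in
which one classifier is trained per augmentation method and the per-class
softmax scores are fused by sum rule. The transform-domain pair (single-level
wavelet and constant-Q coefficient perturbation) is the package's core
contribution; the rest are the strong baselines one wants alongside it.

Every augmenter maps an `H x W x C` image (reals in `[0, 1]`, `C` ∈ {1, 3})
to images of identical shape. Clipping to `[0, 1]` happens once, at the end
of each augmenter, so augmenters compose in real arithmetic. The number of
images each method emits is fixed by contract:

```{r counts}
augmentation_methods()
```

# Randomness contract

All stochastic draws go through a `rand_source(seed)` stream;
`rng_fork()` derives an independent child stream per image, so the same seed
gives bit-identical output regardless of processing order. Nothing touches
R's global generator state.

# The methods

## Geometric (App1–App3)

App1 reflects left–right and top–bottom (independent fair coins) and scales
each axis by an independent factor from `[1, 2]`. App2 adds rotation
(`[-10, 10]` degrees), translation (`[0, 5]` pixels per axis) and shear
(`[0, 30]` degrees per axis); App3 is App2 without shear. Counts are 3, 6
and 4.

Design choices the family needed:

* **Scale interval `[1, 2]`.** Upscale-only is the reading consistent with
  two distinct random factors and guarantees the implicit center crop back
  to `H x W` never exposes empty borders.
* **Composition order** reflect → scale → rotate → shear → translate, about
  the image center, as a single affine resampled once with bilinear
  interpolation; out-of-frame samples replicate the nearest edge pixel, so a
  warp can never invent intensity values.
* **Translation sign.** The `[0, 5]` interval is one-sided; shifts go toward
  positive axis directions by default, with `geo.shift_random_sign` to
  randomize the sign.
* App2's six outputs are six independent parameter draws (not designed
  sub-combinations of the operations).

## Subspace coefficients (App4–App5)

Both methods project each channel into a linear basis, perturb the
coefficients one of three ways, and reconstruct:

* **zero** — each coefficient is zeroed independently with p = 0.5;
* **noise** — each coefficient gets `(u − 0.5) · a`, `u ~ U(0,1)`, with
  amplitude `a = sd(coefficients) / 2`;
* **swap** — each coefficient is replaced with p = 0.05 by the same-index
  coefficient of one of five same-class peer images.

App4 uses PCA fit on the training set only (global, not per class — the
per-class variant has too few samples per basis on small sets). All
components above `1e-10` of the leading eigenvalue are kept, so training
images reconstruct near-losslessly; component signs are fixed by the
largest-magnitude-entry-positive convention, making the basis independent of
training order. The noise amplitude is the spread of the *projected* vector,
halved.

App5 replaces PCA with the orthonormal type-II 2-D DCT per channel. The DC
coefficient (the `(0, 0)` entry, proportional to the channel mean) is
flagged and never modified by any perturbation.

If a class has fewer than five other members, the five peers are sampled
with replacement from those available; a class with no other member is an
error.

## Photometric (App6–App8)

App6: a linear contrast stretch between drawn bounds `a ~ U{0..50}`,
`b ~ U{205..255}` on the 8-bit scale (the method takes `a < b` as inputs;
these defaults are configurable); a sharpened image; a per-channel integer
color shift from `U{−30..30}`. The sharpening is implemented as unsharp
masking (`img + (img − blur)`): the bare difference `img − blur` is a
near-black edge image that no longer resembles its class, so the literal
variant sits behind `photo.sharpen_literal`.

App7 (7 images): hue (`[0.05, 0.15]`, modulo-1 addition), saturation
(`[−0.4, −0.1]`), brightness (`[−0.3, −0.1]`) and contrast (`[1.2, 1.4]`,
multiplicative about mid-gray on the value channel) jitters in HSV; a
Gaussian blur with σ ~ U[1, 6]; unsharp sharpening with radius 1 and
strength 2; and an App6-style color shift.

App8 (2 images) draws one target from the image's class and produces the
RGB histogram specification toward it (256-bin monotone CDF matching) and
the Reinhard transfer: per-channel mean/variance matching in the Ruderman
log-opponent lαβ space, the standard stain-normalization transfer. Both
outputs share one target draw. The RGB↔lαβ matrices are the standard ones;
logarithms clamp the cone response at `1e-6` to stay finite on black
pixels.

## Elastic (App9)

Six deformations of per-pixel random displacement fields
`Δx, Δy ~ U(−1, 1)`: three raw fields with scale factors 7000, 1000 and
13000, and three fields smoothed by a circular averaging disk (radius 5), a
Gaussian low-pass (7×7, σ = 1.5) or a Laplacian of Gaussian (7×7, σ = 0.5),
each scaled by 3000. The scale factor is divided by the pixel count by
default (`elastic.alpha_mode = "per_pixel"`): a factor of 3000 on a
224×224 image then means sub-pixel-to-few-pixel displacements, which keeps
the warp a deformation rather than noise. The un-normalized reading (a
7000-pixel displacement bound) degenerates to edge-clamped noise at any
realistic resolution but remains available as `"literal"`. Field
convolution uses symmetric padding; warps clamp sampling coordinates to the
frame. The disk kernel is the normalized binary indicator of the disk
(partial-pixel area weighting at the rim is omitted; for smoothing a
uniform random field the difference is immaterial).

## Transform-domain (App10–App11)

**App10 (wavelet).** Each channel undergoes a single-level db1 (Haar)
analysis into `cA`, `cH`, `cV`, `cD`, each `⌈H/2⌉ × ⌈W/2⌉` (227 → 114).
Odd sizes use half-point symmetric extension, chosen so the synthesis is an
exact inverse (round-trip error ≤ 1e-10, the load-bearing invariant). The
three perturbations are: zeroing with p = 0.5; one additive constant
`sd(channel) + U(−0.5, 0.5)` added to every coefficient of all four
subbands; and element swaps (p = 0.05) against five same-class peers'
coefficient matrices.

**App11 (constant-Q).** Each image column is a 1-D signal expanded on a
frame of Hann-windowed complex exponentials with geometrically spaced
center frequencies (12 bins per octave from `4/N` cycles per sample to
Nyquist, constant ratio of center frequency to bandwidth), plus one DC
band so the frame is complete; frames are spaced `⌊N/8⌋` samples. Analysis
is an explicit matrix product; synthesis solves the stacked real
least-squares system through a cached QR factorization, making the
unperturbed round trip exact to machine precision (≤ 1e-6 relative is the
contract; measured ~1e-15). The block size (bins × frames) is a consequence
of the column length and the bins-per-octave setting, not a constant.
Perturbations act on complex coefficients as units (zeroing, swapping); the
additive constant `sd(channel) + U(−0.5, 0.5)` is added to real parts
(`spectral.cqt_perturb_domain = "magnitude"` switches to magnitudes).
Columns shorter than 16 samples are refused — below that the geometric
frequency ladder collapses. The transform axis is configurable
(`spectral.cqt_axis`).

## Ensemble harness

`build_training_set()` appends each method's output to the originals
(`|base| · (1 + images_per_input)` items, labels preserved). The named
configurations are `ensda_all` (one member per applicable method — the
three color methods App6–App8 drop out on grayscale sets), `ensda_5`
(App1–App5), `ensbase`/`ensbase_5` (eleven/five members all on App3, the
same-method control) and `noda` (a single unaugmented member). Fusion sums
the members' softmax score matrices; prediction is the row argmax with ties
broken toward the lowest class index. Fusion is permutation-invariant and
positively homogeneous.

The bundled backbone (`backbone = "tiny"`) is a single-hidden-layer softmax
network on per-channel block-averaged intensities plus block-averaged log
magnitude spectra (phase-invariant texture features); it separates the
synthetic texture classes in seconds on one CPU. The interface accepts a
`"reference"` backbone designation for a full pretrained deep network, but
no such network ships with the package; the harness's correctness — set
assembly, score alignment, fusion, accounting — is what the tests
establish, and headline benchmark accuracies from GPU-scale finetuning are
out of scope.

# What the synthetic fixtures emulate

`make_fixtures()` builds class-structured images: each class an oriented
sinusoidal grating (class-specific orientation and frequency, random phase
per image, channel-wise phase shifts for color structure) plus uniform
pixel noise (sd 0.05 by default). This gives classes with distinct spectral
signatures — enough for class-conditional swaps to be meaningful and for a
tiny classifier to separate classes. It does **not** emulate natural-image
statistics (no 1/f spectra, occlusion, illumination fields, or
object/background structure), so passing tests demonstrate the operators'
mathematical contracts and the harness's bookkeeping, not benchmark-level
classification behavior.

# Numerical choices

* Internal range `[0, 1]` reals; one clip at the end of each augmenter;
  8-bit only at the disk boundary (round trip bounded by 1/255).
* Orthogonal-transform round trips asserted at 1e-10 (DWT) and 1e-6
  (DCT, CQT relative); PCA reconstruction at 1e-6 for training images.
* PCA eigenvalue cutoff `1e-10 · λ₁`; degenerate (all-identical) training
  data yields a zero-component basis that reconstructs the mean.
* Argmax ties toward the lowest class index; peer draws without
  replacement when enough peers exist, with replacement otherwise.
* Problem sizes in the test-suite and worked examples: 32–64 px fixtures,
  1000-image sets for the accounting checks, 10⁴–10⁵ elements for rate
  recovery — sizes at which every contract is measurable in seconds on one
  CPU.

# Known limitations

* The working resolution at augmentation time is a free parameter: the
  wavelet/constant-Q geometry the methods were described at (227-tall
  columns) and the 224×224 input of the usual backbone differ, and the
  package takes whatever resolution it is given rather than resolving this.
* Constant-Q plans cache an `O(B·N)` complex matrix and its QR per distinct
  column length; very tall images (N in the thousands) would make
  plan-building the dominant cost.
* The Reinhard transfer assumes mid-range sRGB input; pixels at exactly 0
  are lifted by the log clamp and extreme transfers can clip, after which
  the moment-matching property is only approximate.
* `evaluate_ensemble()` trains members sequentially; at fixture scale this
  is seconds, but the harness does not parallelize.
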