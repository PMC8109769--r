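---
title: "Semi-supervised GAN classification of crop and weed imagery: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised GAN classification of crop and weed imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Discriminating grass weeds (e.g. *Eleusine indica*) from early-growth
dicot crops in nadir RGB imagery is hard for exactly the reasons that make
labels expensive: the two classes share reflectance characteristics, the
plants are small, and soil background dominates the scene. Supervised CNN
classifiers work well but need thousands of labelled patches per field.
Semi-supervised GAN (SGAN) training addresses the labelling bottleneck:
the classifier is trained on a small labelled subset *plus* the remaining
unlabelled images, with a generator supplying synthetic images that force
the discriminator to learn tighter feature representations.

# The model

## (K+1)-class discriminator

The discriminator D is a fully convolutional classifier over K+1 classes:
the K = 2 real classes (crop = 0, weed = 1) and one extra class (index K)
for generated ("fake") images. A softmax head converts its logits into a
probability vector `p`; the probability that an input is real is
`1 - p[K+1]`, which recovers the conventional GAN discriminator as a
by-product of the classifier.

Its loss is the sum of a supervised and an unsupervised term,

    L_D = L_supervised + L_unsupervised

with

    L_supervised   = -E_{(x,y)} log p(y | x, y < K+1)
    L_unsupervised = -E_{x_u} log(1 - p_fake(x_u)) - E_{z} log p_fake(G(z))

The supervised term conditions on the sample being real: the K+1
probabilities are renormalised over the K real classes before the log, so
the value is invariant to the fake-class mass (a property test asserts
this). The first unsupervised term pushes unlabelled real images away from
the fake class; the second labels generated images fake.

## Feature-matching generator

The generator G maps a 100-dimensional standard-normal latent vector
through a dense layer, a reshape to `base x base x 512`, and four 5x5
stride-2 transposed convolutions (channels 512, 256, 128, 64, then 3),
ReLU on hidden layers and Tanh at the output, so the image side is
`base * 16` (base 28 gives the full-scale 448-pixel model). Rather than
maximising the discriminator's confusion, G minimises the
feature-matching objective

    L_G = || E_real f(x) - E_fake f(G(z)) ||^2

where `f` is the discriminator's penultimate pooled activation. Feature
matching is the stable choice for semi-supervised GANs: the generator is
a regulariser for the classifier, not an image-synthesis goal in itself.

Each training iteration performs one Adam step on L_D over a minibatch of
m labelled, m unlabelled and m generated images (generator frozen), then
one Adam step on L_G with D fed m/2 real and m/2 generated images
(discriminator frozen; freeze contracts are asserted bitwise in tests).

## Evaluation

Accuracy is read off the 2x2 confusion matrix as `(TP + TN) / (P + N)`,
expressed in percent. The same statistic is called SSCA when the
classifier was trained semi-supervised (labelled + unlabelled) and SCA
when trained on labelled data only; the distinction lives in run metadata,
never in the arithmetic. Class 0 (crop) is logged as "positive"; for
K = 2 the statistic is symmetric in that choice. Validation predictions
take the argmax over the two real classes only, so the fake logit cannot
affect them.

# Architectural parameters

| Parameter | Default | Notes |
|---|---|---|
| `image_side` | 64 (desk) / 448 (full) | must be `base * 16`, divisible by 32 |
| `latent_dim` | 100 | standard-normal noise |
| `gen_kernel` / `disc_kernel` | 5 / 3 | transposed conv / stride-2 conv |
| `batch_size` m | 30 | split in halves during generator training |
| `lr_g`, `lr_d` | 1e-4 | Adam, beta1 = 0.8, beta2 = 0.999 |
| decay | 5e-4 | per-step learning-rate decay, `lr/(1 + decay * t)` |
| `dropout` | 0.3 | discriminator blocks |
| `epochs` | 1000 (full) / 150 (desk) | validation every epoch |

The discriminator is five stride-2 3x3 convolution blocks
(LeakyReLU 0.2 + dropout), global average pooling (the feature layer
`f`), and a dense map to K+1 logits. Global average pooling lets one
architecture serve any image side. The exact depth and the identity of
`f` are design choices: a five-block stack halves 448 to 14 (and 64 to 2)
and the post-pool activation is the standard feature-matching tap.

Two hyperparameter readings deserved a decision:

* **Learning rate.** Both 1e-5 and 1e-4 appear plausible from the study
  conditions; `gan_config()` exposes the rate with 1e-4 as default,
  paired with "momentum" read as Adam's beta1 = 0.8. The desk profile
  uses 1e-3 for both networks: its schedule is roughly an order of
  magnitude shorter than a full-scale 1000-epoch run, and at 1e-4 the
  desk discriminator cannot even fit its 40-image labelled subset within
  the schedule (dropout noise dominates the descent).
* **Decay.** A decay constant of 5e-4 is implemented as Keras-convention
  learning-rate decay (`lr_t = lr / (1 + decay * t)`), the meaning it has
  in the framework the original experiments ran on. Read instead as an L2
  penalty inside Adam it interacts pathologically with the per-parameter
  normalisation: once task gradients are small the penalty dominates the
  update and erodes trained weights — in a 150-epoch desk run the
  discriminator climbed well above chance and then collapsed back to 50%
  validation accuracy, which disappears under the learning-rate reading.

# Numerical choices

* **Losses from logits.** Training computes both loss terms in logit
  space with log-sum-exp stabilisation; `log(1 - p_fake)` is evaluated as
  `lse(real logits) - lse(all logits)`, which never overflows. The
  user-facing probability-space functions clamp probabilities to
  `[1e-7, 1 - 1e-7]` because the unsupervised loss is unbounded at
  p_fake of 0 or 1.
* **Initialisation.** He-scaled truncated normal, sd `sqrt(2/fan_in)`
  truncated at 2 sd, biases zero. The flat sd-0.02 DCGAN convention
  presumes batch normalisation, which this architecture does not use;
  with it, activations vanish through the five-conv stack and the
  discriminator never leaves chance level.
* **Gradient correctness.** Every layer's backward pass is checked
  against central finite differences on small networks (relative error
  below 1e-4); the transposed convolution is implemented as the exact
  adjoint of a stride-2 convolution and additionally satisfies the inner
  product identity `<conv(x), y> = <x, conv^T(y)>` to machine precision.
* **Epoch definition.** One epoch is one pass over the full training
  pool in minibatches (drop-last), so the optimisation budget does not
  depend on the labelled rate. The alternative reading — an epoch as a
  pass over the unlabelled pool — silently starves high-rate runs (at 80%
  labelled it leaves a third of the optimizer steps) and disagrees with
  the published observation that per-epoch training time grows with the
  labelled rate. Pools smaller than the batch are sampled with
  replacement; at a 100% labelled rate the labelled pool stands in for
  the empty unlabelled pool, so the adversarial part of training
  continues to operate.
* **Checkpointing.** The best-validation parameter set is retained and
  used for test evaluation; there is no early stopping.
* **Rounding.** Labelled counts are `round(rate * N)` half-up, allocated
  per class by largest remainder, which reproduces the published
  pea (N = 1300) and strawberry (N = 1400) pool tables exactly at 20, 40,
  60 and 80%.

# The synthetic field generator

The original UAV dataset is not deposited, so the package generates its
own study system: 64-pixel patches of brown soil (low-frequency
brightness field plus Gaussian pixel noise, mean channel order
R > G > B) composited with green plant sprites. Crops are rosettes of
4-8 broad elliptical leaves; grass weeds are tufts of 5-12 thin curved
blades. Both classes share the same green hue range on purpose — like the
real system, colour alone should not separate them; vegetation area and
morphology do.

A deliberately simple two-feature oracle — logistic regression on the
green-pixel fraction and the green mask's compactness (area/perimeter^2) —
is part of the package. It certifies that the synthetic classes are
learnable (above 90% held-out accuracy at default parameters) before any
neural network enters the picture, so a failing SGAN experiment indicts
the learner, not the data. Narrowing the crop leaves toward the blade
scale shrinks the morphology gap and drives the oracle toward chance,
giving a difficulty dial for stress tests.

What the generator does *not* emulate: perspective and shadows, mixed
crop/weed scenes, radiometric calibration, blur, orthomosaic seams.
Passing experiments on synthetic fields demonstrate that the training
machinery extracts the semi-supervised gain; they do not certify field
performance on real UAV imagery.

# Desk-scale experiment

The packaged experiment (`run_gain_experiment()`, also behind
`scripts/acceptance.R`) uses 64x64 images, a 200-image training pool,
100-image validation and test sets, batch size 30, 150 epochs and three
training seeds, with generator channels 48/24/12/6 and discriminator
channels 8/16/32/64/64 — a narrow-channel rendition of the architecture
sized for a single CPU. The widths matter beyond runtime: halving either
network pushed desk-scale training to chance level (an overly weak
generator gives the discriminator nothing to work against), so the
profile sits at the narrowest widths that train reliably. The validation set deliberately matches the
training pool in size order: with 40-image validation sets the per-epoch
accuracy estimate is noisy enough (about +/- 8 points) to corrupt
best-checkpoint selection. It reports mean test SSCA at 20% and 80% labelled
rates and the supervised LeNet5-style baseline's SCA on the identical 20%
labelled subset. The quantities of interest are the semi-supervised gain
(SSCA - SCA at 20%) and the growth of SSCA with the labelled rate; the
published headline accuracies belong to the undeposited UAV dataset and
are not reproduction targets.

The supervised reference is a small LeNet5-style CNN (two 5x5
convolution + average-pooling stages, dense 120-84-K head) trained with
the same optimizer settings on the labelled subset only;
`compare_label_rates()` accepts any user classifier in its place.

# Known limitations

* GAN training at this scale is noisy; single-seed comparisons are not
  meaningful, which is why every comparative claim averages at least
  three seeds.
* The generator is a regulariser here; no claim is made about the visual
  quality of generated patches.
* The CPU engine is written for clarity and desk-scale problems; the
  full 448-pixel, 512-channel configuration builds and runs but is not
  sized for routine training in R.
* Single-label patches only: the classifier decides crop vs weed per
  image; it is not a detector or segmenter.
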