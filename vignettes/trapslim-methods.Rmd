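---
title: "Designing lightweight wildlife recognition models that resist shortcut learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing lightweight wildlife recognition models that resist shortcut learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(trapslim)
```

## The problem

Camera traps are fixed, motion-triggered field cameras. Every image from
one installation shares a near-constant background, and most species are
photographed at a characteristic subset of sites. A convolutional
classifier trained on such data can therefore reach high training
accuracy by recognizing the *site* rather than the *animal* — a shortcut
that collapses the moment the species appears in front of an unfamiliar
background. A second, independent constraint is that field deployment
wants small models: a full-size ResNet50 classifier is far too heavy for
an embedded camera trap.

`trapslim` packages a complete design loop that addresses both problems
at desk scale:

1. **Mixed data augmentation** to break the animal–background coupling:
   *image synthesis* (IS) pastes segmented animal instances, randomly
   rotated and resized, onto other background frames; *regional
   background suppression* (RBS) zeroes a random rectangle strictly
   outside the animal's bounding box.
2. **Structured channel pruning** by genetic search with adaptive batch
   normalization (GA-ABN) to derive a compact student network from a
   trained teacher under a compute-budget constraint.
3. **Knowledge distillation** (primarily with an MSE loss on output
   distributions) to fine-tune the pruned student against the frozen
   teacher.
4. **Metrics**: micro-averaged accuracy (ACCcls), Grad-CAM heatmaps, and
   the *foreground ratio of heat* (FRoH) — the fraction of total
   Grad-CAM mass inside the labeled bounding box, which quantifies how
   much of the model's attention is on the animal.

## The synthetic camera-trap generator

Real camera-trap archives are large, private, and training full-size
models on them needs GPUs. The package therefore ships a scene generator
(`scene_config()`, `generate_dataset()`) that reproduces the one
statistical property the method exploits: a controllable confound
between species identity and background signature.

* Each **site** has a distinct background: a base hue drawn from evenly
  spaced positions on the hue circle, a site-specific sinusoidal texture
  (frequency and orientation), and per-image Gaussian pixel noise
  (`bg_noise_sd`, default 8 grey levels). Even a nearest-centroid probe
  on mean channel values identifies the site almost perfectly.
* Each **species** has a distinct parametric silhouette family (ellipse,
  lobed blob, regular polygon, with jittered pose per draw) filled with
  a species tint and texture whose visibility is scaled by
  `foreground_contrast` in [0, 1]; at 0 the animal is uniform neutral
  grey and literally invisible.
* `confound_strength` is the probability that a *training* image of
  species *s* comes from *s*'s home site; *test* images always pair
  species and sites uniformly. At strength 1 the background predicts the
  training label perfectly and carries no test signal — shortcut
  learning is present by construction, with exact instance masks and
  boxes available for augmentation and FRoH.

Defaults (4 species, 4 sites, 96×96 pixels, 70 training and 30 test
images per class — the 7:3 split of the original evaluation design —
contrast 0.3, perfect confound) were chosen once as a realistic desk
emulation of a small camera-trap archive. What the generator does *not*
emulate: photographic texture, lighting and day/night cycles, occlusion,
multiple animals, class imbalance. Passing tests therefore demonstrate
that the pipeline's *mechanisms* behave as designed under a controlled
confound, not that any particular accuracy transfers to real imagery.

Coordinates are 0-based and half-open (`x0, y0, x1, y1`) everywhere;
class labels are 1-based integers on the R side and converted at the
COCO-manifest boundary. Pixels are 8-bit values (0–255) so PNG
round-trips are exact.

## Models and the compute engine

The analytic side (`resnet50_descriptor()`, `count_params()`,
`count_macs()`) works on architecture descriptors — ordered layer tables
— and reproduces the full-scale teacher's printed costs exactly:
23,520,326 parameters and 16.48 G multiply–accumulates for the 6-class,
448×448 ResNet50. The MAC convention charges each convolution output
position `K²·cin + 1` operations (the `+1` is the bias slot of the
per-layer counting formula, applied uniformly), one operation per
element for batch normalization, activations and pooling windows, and
`cin·cout + cout` for the head; the doubled "FLOPs = 2·MACs" reading is
reported alongside. Both conventions are exposed because published cost
tables mix them; the headline figure here follows the one the reference
tables print.

The *trainable* family is a configurable stage CNN
(`classifier_spec()`): each stage opens with a stride-2 3×3 convolution
followed by batch normalization and ReLU, optional residual blocks
follow, and a global-average-pool plus linear head closes the network.
All widths in a stage are tied, so each stage is one prunable channel
group — this keeps residual sums shape-compatible and makes the spec
and its descriptor round-trip losslessly. The engine (im2col convolution
lowering onto BLAS matrix products, with the gather/scatter and fused
BN/ReLU inner loops in C++) implements full backpropagation, SGD with
momentum and cosine learning-rate decay, early stopping on validation
accuracy, and deterministic He initialization under a seed. Analytic
gradients are verified against finite differences in the test suite.
Instantiating the 448×448 ResNet50 itself is outside desk scope: the
descriptor covers its cost arithmetic and pruning genome algebra, while
training runs use the stage CNNs.

Training defaults follow the published recipe (SGD, momentum 0.9,
cosine decay, early stopping); the desk preset (`desk_train_config()`)
uses learning rate 0.025, batch 32, 18 epochs and patience 8, sized so
a full three-seed augmentation study finishes in minutes on one CPU.

## Mixed augmentation

`random_paste()` rotates (uniform over [0°, 360°)), scales (uniform over
[0.6, 1.4]) and places a cutout uniformly among positions that keep the
mask inside the frame; the mask is re-rasterized with nearest-neighbour
and the patch with bilinear sampling (the identity transform is exact).
Rotation precedes scaling; neither choice is canonical, so
the order is a package decision. `apply_rbs()` rejection-samples
rectangles (area fraction uniform over [0.05, 0.25], aspect log-uniform
over [1/3, 3], at most 100 tries) until one is disjoint from the
bounding box and fills it with raw pixel zero, *before* normalization.
The invariant that suppression never alters a single byte inside the
box is tested over a thousand seeded draws. `apply_cutout()` is the
deliberately unprotected contrast: its rectangle may strike the animal.

`build_augmented_set()` adds `is_fraction·N` synthesized and
`rbs_fraction·N` suppressed records to the originals, with addition
classes drawn from the original label distribution. The mixed default
(1, 1) — tripling the training set — reflects that a *perfect* confound
needs strong decorrelating pressure; the comparison study gives every
non-baseline method the same number of added records so methods differ
in kind, not amount.

## Pruning by genetic search with adaptive BN

A **genome** assigns each prune group a keep ratio from the grid
0.1–1.0. Candidates are rejection-sampled until their MAC ratio to the
teacher lies in the band `compression_target ± band_halfwidth`
(50 ± 5 % by default, mirroring the full-scale study). A candidate is
**materialized** by keeping the channels with the largest L1 filter
norms (summed across the group; the standard structured-pruning
heuristic — the source method does not specify one), slicing dependent
tensors consistently; the all-ones genome reproduces the teacher
bitwise. Its **adaptive BN** statistics are the batch mean and unbiased
(n−1) variance of each BN layer's input, averaged over `recal_batches`
calibration mini-batches, with variances floored at 1e-5; inherited
running statistics are discarded, weights untouched.

**Fitness** is selectable, because the printed formula `f = n·(p/p0)`
(accuracy times relative size) rewards *larger* sub-networks inside the
band, while the surrounding prose aims at compression with accuracy.
`literal_product` (the printed form) is the default; `accuracy_per_size`
(`n/(p/p0)`) is the alternative reading. Both are unit-tested at
hand-computed points and the choice is logged in the search results.
Inside a ±5 % band the two differ only second-order, which is why the
search outcome is stable under either.

The loop keeps the top `parents_kept` by fitness, breeds
`population_size` offspring by uniform per-gene crossover of two
distinct parents and per-gene mutation (rate 0.1, resampling from the
grid), re-checks the band, and carries parents forward (elitism — hence
the best fitness is non-decreasing, which is asserted). It stops when
the population's total fitness changes by less than `convergence_tol`
(1e-3) for `convergence_patience` (3) consecutive generations, or at
`max_generations`. Crossover operator, mutation rate, elitism and the
numerical stall criterion are package decisions — the source method
states only selection counts and the stall idea. The published search
used 20 parents / 100 offspring; the desk preset
(`desk_search_config()`) uses 12/36 with at most 15 generations.
Evaluations are memoized by genome, so elitism and re-sampled duplicates
never pay twice, and the random-sampling baseline (`random_search()`)
gets the same evaluation pipeline and budget.

The desk compression benchmark (`desk_benchmark_config("compression")`)
uses a 4-stage backbone ([8, 12, 16, 24] at 32×32): with per-stage
groups, three stages would give a feasible genome set small enough to
enumerate, making any search trivially equal to random sampling; four
groups make the band subset of the 10⁴ grid large enough that the
evolutionary mechanism matters.

## Distillation

`finetune_with_kd()` trains the student on
`CE(student, labels) + λ·KD(student, teacher)` with the teacher frozen.
`mse` is the mean squared difference of the two output probability
vectors (a logit-space variant is available as a sensitivity flag);
`soft_kl` is KL(teacher‖student) of temperature-softened distributions
scaled by T²; `hard_kl` is cross-entropy against the teacher's argmax
pseudo-labels. λ defaults to 1 and the ground-truth CE term is always
present — the source description leaves both unstated. All three
gradients are verified against finite differences.

At desk scale, distillation fine-tuning recovers a large part of the
accuracy the un-fine-tuned pruned student loses (tested over three
seeds). The finer full-scale finding that the MSE variant edges out the
two KL variants by under 1.5 accuracy points is *below the noise floor*
of an 80-image validation set and does not replicate here; the package
reports all three methods and leaves that ranking to full-scale data.

## Metrics

`acc_cls()` is ΣTPᵢ / Σ(TPᵢ+FPᵢ), which reduces to the fraction of
correct predictions; ties in the argmax resolve to the lowest class
index so results are deterministic. `grad_cam()` weights the last
convolutional stage's activations by the spatial mean of the class-logit
gradient, applies ReLU, and bilinearly upsamples; with a
global-average-pool head the gradient is exactly the class's head
weights spread over positions. Heatmaps are *not* max-normalized:
`froh()` is a ratio of sums and therefore invariant to positive
rescaling, so normalization would only add arithmetic. `dataset_froh()`
averages per-image FRoH using true-class maps by default (predicted-class
maps are a flag), and counts zero-heat images instead of dividing by
zero.

## What the studies show, and their sizes

`run_augmentation_study()` (96×96 benchmark, six variants, three seeds
in the acceptance suite): the baseline fits the confounded training set
well yet classifies the decorrelated test set near chance — the
shortcut — while mixed augmentation raises decorrelated accuracy by
tens of points and raises mean FRoH in median. `run_compression_study()`
(32×32 benchmark): the genetic search's best fitness is non-decreasing,
every evaluated sub-network satisfies the MAC band, and the genetic
student's pruned accuracy and fitness dominate the equal-budget random
baseline in median over seeds. These problem sizes (three seeds,
70/30 or 40/20 images per class, ≤ 18 epochs, 12/36 search) are the
package's desk defaults chosen so each study runs in minutes on one
CPU core.

## Known limitations

* The trainable models are compact stage CNNs; full-size bottleneck
  residual networks exist here only as analytic descriptors.
* The generator's confound is one spurious cue (background signature);
  real shortcut learning can ride on many correlated cues at once.
* Pruning groups are per stage, so within-stage per-layer width
  variation is not searched.
* FRoH depends on Grad-CAM's resolution at the last stage (here 12×12
  before upsampling for 96-pixel inputs); very small boxes are measured
  coarsely.
* No photorealism, detector heads, hardware latency objectives, or
  embedded deployment.
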