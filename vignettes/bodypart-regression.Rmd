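---
title: "Self-supervised body part regression: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised body part regression: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpregress)
```

# The problem

Whole-body CT pipelines constantly need to know *where in the body* a
given axial slice lies: to check that the right anatomy was scanned, to
route sub-volumes to specialised segmentation models, or to crop a scan
to a region of interest before expensive processing. Body part
regression (BPR) solves this without any labels: a 2-D network maps
each axial slice to a continuous score that increases from the feet
towards the head. Supervision comes entirely from the axial ordering of
slices within each volume — a property every volume carries for free.

`bpregress` implements that pipeline end to end in R: the ranking
losses, the random equidistant slice sampler and augmentation stack, a
trainable slice-scoring network, score post-processing and
organ-landmark calibration, landmark-error evaluation with paired
Wilcoxon/Bonferroni comparisons, score-driven anatomical region
cropping with Dice utilities, and a procedural CT phantom generator so
that every stage is testable without patient data.

# The self-supervised objective

A training batch holds `g` volumes; from volume `i` the sampler draws
`m` equidistant slices (default 8), whose scores form row `i` of a
`g x m` matrix `S`, ordered inferior to superior.

**Order loss.** With sigmoid `h`,

$$L_{order} = -\sum_{i=1}^{g}\sum_{j=1}^{m-1} \log h\big(S(i,j+1) - S(i,j)\big),$$

which is small exactly when each consecutive score difference is large
and positive: scores must increase towards the head. We evaluate
`log h` in the numerically stable `-softplus(-x)` form, since trained
models produce large score gaps.

**Distance loss.** With gaps $\Delta_{i,j} = S(i,j) - S(i,j-1)$ and the
smooth-L1 function `f` (quadratic below the transition point `beta`,
absolute above; `beta = 1` by default, the conventional value),

$$L_{dist} = \sum_{i=1}^{g}\sum_{j=1}^{m-2} f\big(\Delta_{i,j+2} - \Delta_{i,j+1}\big),$$

which is zero exactly when each volume's scores form an arithmetic
progression — the score grows *linearly* along an equidistant stack.

**On the sign of the distance loss.** Antecedent formulations print a
leading minus on the distance term. Taken literally, `-sum f` with
`f >= 0` would *reward* irregular spacing and be unbounded below, which
contradicts the term's stated purpose ("small spacing difference, small
loss"). We therefore implement `L_dist = +sum f` and treat the printed
minus as a typographical artifact. This is the single most consequential
interpretation in the package, so it is stated here prominently; the
total loss is `L = L_order + L_dist`, weighted 1:1.

# Slice sampling and its coverage bias

For a volume of `t` slices the sampler draws a spacing `k` uniformly
from the admissible part of `{1,2,3,4}` (`k` admissible iff
`t - 8k >= 1`) and a start `j` uniformly from `1..(t - 8k)`, selecting
slices `j + k(x-1)`, `x = 1..8`. Note the start range deliberately
stops at `t - 8k`, not `t - 8k + k`: the most superior `k` slices of a
volume are *unreachable* for spacing `k`. We preserve this faithfully
rather than "fixing" it, because the sampler's coverage bias is itself
a quantity of scientific interest: superior structures (lung apex,
esophagus end) are systematically under-sampled during training.

`selection_distribution()` quantifies the bias either by exact
enumeration over all `(k, j)` pairs or by Monte-Carlo simulation, and
summarises it as the percentage deficit of the mean selection count
over the top decile of slice positions relative to the all-slice mean.
The deficit depends strongly on `t`, which real cohorts do not fix:
exact enumeration gives ≈47% at `t = 200`, ≈42% near `t = 225`, ≈31%
at `t = 320` and ≈25% at `t = 400`, decreasing monotonically in `t`
(the unreachable top-`k` band and the decile window both scale
differently with `t`). Any single published deficit number therefore
pins down, implicitly, the slice counts it was simulated at; the
sampler tests carry this sensitivity analysis.

# The scorer

The regression head follows the published contract: the backbone's
feature map passes through a 1×1 convolution with `head_width` filters,
a ReLU, global average pooling over the spatial dimensions, and a final
affine map to one scalar. The network is applied to each slice
independently (time-distributed), so the score of a slice depends only
on that slice's pixels and the weights.

Backbones are a registry behind one interface. The published large
pretrained encoders (VGG, ResNet, DenseNet, EfficientNet, ConvNeXt)
are out of scope here; the shipped defaults are small encoders
trainable from scratch on a CPU:

* `tiny2conv` — two stride-2 3×3 convolutions (1→8→16 channels) with
  ReLU.
* `tiny4conv` — four stride-2 3×3 convolutions (1→8→16→24→32), whose
  ~31-pixel receptive field lets spatially separate structures interact
  *before* pooling. This matters because the head is, by construction,
  linear across spatial cells after GAP: any relationship *between*
  structures (e.g. "this band appears while that one is ending") must
  be computed by the backbone or it is not representable.

Both backbones carry a parallel average-pooling branch (the raw slice
plus three soft threshold maps, pooled to the final grid) concatenated
as four extra feature channels — an Inception-style pooling pathway
that hands the head plain intensity/area statistics from the first
update.

**Structured initialization.** Training these encoders from random
weights with a desk-scale budget fails in a characteristic way: the
head quickly converges to the best score available from random
features, which is weak, and the loss pins at the constant-score value
`7 log 2` per volume. The published pipeline avoids this by starting
from pretrained weights. Our equivalent is a structured initialization:
layer 1 starts as a classical filter bank (averaging, Sobel y/x,
Laplacian, and four soft intensity thresholds), deeper layers as
per-channel smoothing and local-contrast selectors, all perturbed with
small noise. Globally pooled, such channels immediately yield
discriminative slice statistics; training then refines every filter.

# Training

Each epoch draws one fresh random stack per training volume
(re-sampled each epoch, which is what lets the model generalise across
slice spacings), applies one shared set of augmentation parameters to
all slices of a stack (so relative anatomy within the stack is
preserved), groups stacks into batches of `batch_volumes` volumes, and
updates with RMSprop.

Augmentations, in order: zoom (80–120%), random y/x flips, rotation
(±0.1 rad), intensity scale (80–120%), intensity shift (0–0.08),
additive Gaussian noise (SD 0.04), min–max normalization to [0, 1],
resize to the network input. Normalization is the last intensity
operation, so augmented slices are always in [0, 1].

Defaults follow the published configuration: 400 epochs, batch of 16
volumes, RMSprop at `1e-4`. Those values presume a large pretrained
backbone that only needs fine-tuning. For the desk-scale, from-scratch
runs used in this package's own end-to-end tests we instead use
`batch_volumes = 1` (forty RMSprop updates per epoch instead of three,
from the same fixed data budget), learning rate `2e-3`, and plain
RMSprop (`momentum = 0`; momentum at these scales drove the small
networks into dead-ReLU collapse). These were chosen from the
training-loss behaviour of the tiny backbones and then frozen.

# Post-processing and landmark calibration

Raw score curves are smoothed with a 1-D Gaussian along the slice axis
(SD 10 slices, reflecting boundaries, kernel truncated at 4 SD and
renormalised so constants are preserved), then mapped to a 0–100 scale:

$$Score_{new} = \frac{(Score_{old} - MinValue) \cdot 100}{MaxValue - MinValue},$$

where `MinValue`/`MaxValue` are the training-cohort mean smoothed
scores at the lowest landmark (femoral head start) and the highest
(esophagus end). Values outside the anchors are *not* clipped — the
model's scores are intrinsically unbounded. Smoothing and
normalization are both linear, so their order is immaterial up to
floating point; the implemented order is fixed to smooth-then-normalize
for reproducibility.

A landmark is the first ("start") or last ("end") slice on which an
organ appears in the label map; sixteen organs give 32 landmarks. The
calibration table records, per landmark, the mean and SD across
training volumes of the normalized smoothed score at the true landmark
slice. On a new volume, a landmark is predicted at the slice whose
score is nearest the landmark's reference mean (ties break toward the
more inferior slice; a reference beyond the curve's range lands on the
first extremal slice). Landmark error is reported on a per-volume
rescaled axis — `|predicted - true| * 100 / t` — so it reads as percent
of scan length and is comparable across volumes with different `t`.

Model comparisons use two-sided paired Wilcoxon signed-rank tests with
Bonferroni correction (`alpha / n_comparisons`; five models give 10
comparisons and a 0.005 threshold, twenty comparisons give 0.0025).
Zero paired differences are dropped per the signed-rank convention;
the exact null distribution is used up to 25 non-zero pairs, the
normal approximation with continuity correction above; an all-zero
difference vector reports `p = 1` with a degenerate-data warning.

# Region cropping

A body region (thorax; upper abdomen; lower abdomen; pelvis) is
bounded by the calibration scores of its most inferior and most
superior organ landmarks, widened by `margin_multiplier` (default 1.5)
landmark-score SDs on each side; the score window maps back to slices
by the same nearest-score rule on the volume's normalized smoothed
curve (the rule is reused deliberately: the curve need not be strictly
monotone and the nearest-score lookup is well defined either way).
Bounding landmarks are resolved per calibration table as the
lowest/highest-scoring landmark among the region's organs, because a
fixed literal choice (e.g. "top of the heart") can conflict with the
actual score ordering (lung apices lie above the heart); explicit
landmark names remain configurable.

**What a 1.5-SD margin can and cannot guarantee.** If landmark
positions vary across subjects with SD $\sigma$ (in slices) and the
score curve primarily encodes *global* axial position, each crop bound
protrudes past the true extent with probability about
$\Phi(-m)$ for margin multiplier $m$: for $m = 1.5$ the expected
per-region containment is $1 - 2\Phi(-1.5) \approx 87\%$. Containment
beyond that requires either larger margins (95% per region needs
$m \approx 2.2$) or a score that tracks each subject's *local* anatomy
— and the σ=10 smoothing, roughly twice the phantom's landmark jitter
SD, deliberately suppresses exactly the local wiggles that would carry
such tracking. The margin is a configurable trade-off between coverage
and crop size, not a guarantee; the default stays at 1.5.

Masks predicted on a crop are re-embedded into the whole-volume frame
with `embed_mask()` (cropped-out slices count as background), and
evaluated with the Dice coefficient `2|A∩B|/(|A|+|B|)`; a label empty
in both masks scores 1 by convention, isolated in one function.

# The phantom generator

`generate_phantom()` renders axial volumes with the structure the
pipeline needs and nothing more:

* a torso disc whose **cross-sectional area grows linearly** toward the
  head (radius ∝ √z) and whose tissue brightens with z — so every
  slice carries positional information at a uniform per-slice rate;
* sixteen **organ bands** at template z-fractions (femoral head lowest,
  esophagus end highest; all 32 landmark fractions distinct), each in
  its own in-plane disc with a near-homogeneous, organ-specific
  intensity and an asymmetric along-z radius profile that tapers to a
  single voxel at the band endpoints — organ cross-sections emerge and
  vanish *continuously*, with no area jump at the landmark slices;
* **anti-aliased (1 px) edges** everywhere, so sub-voxel geometry
  changes vary pixel intensities continuously with z;
* a flat, full-intensity **bone marker** and flat air background that
  anchor each slice's intensity extremes, with all organ intensities
  strictly inside — per-slice min–max normalization then has a stable
  scale;
* **bounded (uniform) voxel noise** with SD 0.01. Both choices mirror
  real CT, where intensities are bounded and quantised and scanner
  noise is roughly 10–20 HU of a ~2000 HU air-to-bone range. The
  bounded tail matters more than it looks: min–max normalization
  divides by the slice's intensity range, and unbounded (Gaussian)
  tails make that divisor jitter by more than a slice's worth of
  anatomical change, a pathology real CT does not exhibit;
* inter-subject variability: per-subject slice counts drawn from
  [120, 400] (real slice-count statistics are unpublished; this range
  is a config default, not wired into code), and truncated-normal
  jitter (SD 0.02 of scan length) applied **independently to every
  organ endpoint**, with endpoints re-sorted so no organ degenerates.

What the phantom does *not* emulate — and hence what passing tests do
not show about real data: anatomical shapes and HU calibration,
left/right paired organs, pathology, contrast phases, metal artifacts,
inter-organ positional *correlation* (a real subject's pelvic organs
shift together; phantom endpoints jitter independently, which makes
subject-specific tracking partially impossible by construction), and
scanner-to-scanner appearance shifts. Results on phantoms bound what
the pipeline can do when its assumptions hold; they do not certify
performance on patient data.

# Numerical and interface choices

* **Indices are 1-based everywhere** (idiomatic R); the sampler's
  formulas are stated 1-based at the source, so they map directly.
  Rescaled landmark errors are differences and hence
  convention-independent.
* Axial axis is array dimension 1, slice 1 most inferior. NIfTI files
  are canonicalised to this orientation via their xform (RAS+);
  volumes without orientation metadata are assumed already
  inferior→superior, with a warning. DICOM series are sorted by
  position along the image-orientation normal, never by file name.
* Landmark extraction measures first/last occurrence on the native
  grid (no resampling).
* `predict_landmark_slice` tie-breaks toward the lower slice;
  `which.min` semantics make this exact.
* A constant-valued slice min–max-normalizes to all zeros (documented,
  no division by zero).
* Gaussian smoothing uses reflecting boundaries; the kernel truncation
  radius is 4 SD.
* Checkpoints and calibration tables are JSON with full-precision
  numbers; calibration files carry a schema tag and fail loudly on
  mismatch or on a missing normalization block.
* Seeding: one master seed fans out to derived streams (cohort,
  per-epoch sampling/augmentation, parameter initialization) so every
  end-to-end run is exactly reproducible; helpers restore the caller's
  RNG state.

# Desk-scale problem sizes

The package's own end-to-end check trains the `tiny4conv` backbone
(head width 64, input 64×64) on a 40-volume training split of a
50-subject phantom cohort at 64×64 in-plane resolution for 60 epochs,
then calibrates on the training split and evaluates landmark recovery,
raw-curve monotonicity, and four-region cropping on the 10 held-out
subjects. The sampler analyses enumerate exactly at `t` in
{16, 40, 320} and simulate with 1e5 draws. These sizes were chosen so
the full suite runs comfortably on a single CPU while leaving the
conclusions qualitatively stable under seed changes.

# Known limitations

* The shipped backbones are deliberately small; they demonstrate and
  test the framework, not state-of-the-art localization. Pretrained
  large encoders can be added through the backbone registry, including
  their own initialization and forward/backward functions.
* Scores are calibrated against a *cohort*; a single atypical subject
  (missing anchors, truncated scan) yields predictions extrapolated
  from the nearest-score rule, flagged only insofar as curves fall
  outside [0, 100].
* The sampler's superior-slice deficit means the most superior
  structures are learned from fewer training examples than average,
  so landmarks near the very top of a scan should be expected to
  recover less precisely than mid-torso ones.
* DICOM support covers uncompressed explicit-VR little-endian
  single-frame series — the common CT export — and rejects everything
  else loudly rather than guessing.
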