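---
title: "Unsupervised multiscale hierarchical deformable registration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised multiscale hierarchical deformable registration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhnet)
```

## The registration problem and the model

Deformable (nonlinear) registration aligns a moving 3D image $M$ to a
reference image $F$ through a dense displacement vector field (DVF)
$u$: every output voxel $i$ reads the moving image at $i + u(i)$.  Because
$i + u(i)$ is generally not an integer location, the warped intensity
$(M \circ \phi)(i)$ is obtained by trilinear interpolation over the eight
integer neighbours $j$ of the sample point, with weights
$\prod_{d \in \{x,y,z\}} (1 - |j_d - i'_d|)$.  This spatial-transformer
warp is differentiable in both the image and the field, which is what makes
fully unsupervised training possible: no ground-truth deformations or
segmentations are used at training time.

The network $f_\theta$ maps the channel-concatenated pair $(F, M)$ to the
field, $\phi = f_\theta(F, M)$, and is trained to minimise

$$L = \alpha\, L_{sim}(F, M, \phi) + \lambda\, L_{smooth}(\phi),$$

where $L_{sim} = -\mathrm{NCC}(F, M \circ \phi)$ is the negative local
windowed normalized cross-correlation and $L_{smooth}$ is a diffusion
penalty on the spatial gradients of the displacement components.  After
training, registering an unseen pair is a single forward pass plus one
warp (`register_pair()`), with no per-pair optimisation.

### The similarity term

`ncc()` computes, in a cubic window around every voxel (edge
`ncc_window`, default 9), the squared zero-mean cross-correlation

$$cc(i) = \frac{\left(\sum_W (f - \bar f)(w - \bar w)\right)^2}
               {\sum_W (f - \bar f)^2 \sum_W (w - \bar w)^2 + \varepsilon}$$

and averages it over voxels.  The squared local form is used because it
lies in $[0, 1]$: a plain Pearson correlation would live in $[-1, 1]$.
Numerical choices:

* windows are clipped at the image border (each voxel uses the
  intersection of its window with the domain), so self-similarity is
  exactly 1 everywhere rather than decaying at the edges;
* $\varepsilon = 10^{-5}$ stabilises the ratio; a window in which either
  image is constant contributes correlation 0 (there is no meaningful
  correlation to reward);
* the window sums are computed by separable sliding sums, so the cost is
  independent of the window edge.

A consequence worth knowing when testing on phantoms: in large exactly
flat regions (synthetic background), windows are degenerate and contribute
0, so `ncc(f, f)` of such an image is noticeably below 1.  This is by
construction; on real MR intensities, noise makes windows non-degenerate.

### The smoothness term

`smoothness_loss()` takes forward differences of each of the three
displacement components along each of the three axes (nine partials), and
averages the squared differences over the voxels that have a forward
neighbour.  Averaging rather than summing makes $\lambda$ independent of
the volume size; only the ratio $\alpha : \lambda$ is identifiable, and
the defaults $\alpha = 1$, $\lambda = 3$ follow the published setting.

## Architecture

`build_network()` assembles, from a `network_config()`:

1. **Multiscale Inception block** on the 2-channel input: parallel
   branches with cubic kernels of edge 1, 3, 5, 7, each producing
   `inception_branch_out = 4` channels (16 total).  Every branch with
   kernel > 1 is preceded by a 1×1×1 bottleneck to
   `bottleneck_channels = 1` channel; the 1×1×1 branch maps the input
   directly (a bottleneck there would only add parameters).  With the
   default configuration the weight counts are 3968 without and 1994 with
   bottlenecks (`count_inception_params()`), and the instantiated block
   carries exactly those weights — the two numbers mutually pin down the
   bottleneck placement, since bottlenecking all four branches would give
   1992, not 1994.
2. **Encoder**: four levels of (stride-2 3³ conv, stride-1 3³ conv), each
   convolution followed by a LeakyReLU (negative slope 0.2 by default, a
   conventional value; the architecture does not appear sensitive to it).
   After four levels the feature map is 1/16 of the input per axis, which
   is why input dimensions must be divisible by 16.
3. **Decoder**: four stages of trilinear ×2 upsampling, channel
   concatenation with the same-resolution encoder map (the fourth stage
   concatenates the Inception features), and a 3³ convolution.
4. **Hierarchical forecast heads**: the three coarsest decoder maps are
   upsampled to full resolution by factors 8, 4 and 2 and convolved to
   3-channel fields $\phi_{low}, \phi_{mid}, \phi_{high}$; the
   end-of-decoder map yields $\phi_{end}$; the four fields are
   channel-concatenated and fused by a 1×1×1 convolution into
   $\phi_{final}$.  The loss is applied to $\phi_{final}$ only — the
   intermediate fields influence training through the fusion, not through
   separate deep-supervision terms, which mirrors how the fusion is
   described and keeps the objective single-valued.

Channel widths per level are not pinned down by the published description;
the defaults (`enc = 16,32,32,32`, `dec = 32,32,32,16`) are
VoxelMorph-scale and fully configurable.  Ablations are first-class:
`use_inception = FALSE` replaces the block with one plain 3³ convolution
with matching channels, and `use_hierarchical = FALSE` drops the heads so
$\phi_{final} \equiv \phi_{end}$.

### Initialisation of the field convolutions

A strict zero initialisation of *all* field-producing convolutions (heads
plus fusion) looks attractive — the untrained network is then exactly the
identity transform — but it is a gradient deadlock, not just a slow start:
with the fusion weights at zero no gradient reaches the heads, and with
the head weights at zero the fusion weights receive zero gradient from the
all-zero fields, so neither can ever move.  The default
(`init_fields = "small"`) therefore draws head weights from
$N(0, 10^{-10})$ and initialises the fusion convolution to average the
four candidate fields: the untrained output is numerically negligible
(|u| ~ 1e-4 voxel, identity to tolerance) while every parameter receives
gradient from the first step.  `init_fields = "zero"` is retained for the
exact-identity contract and for ablations without the fusion path.

### Training regime

`train()` follows the published regime by default: ADAM
($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$), batch size 1,
learning rate $10^{-4}$ halved from the start of epoch 40, 70 epochs; one
optimisation step per pair per epoch, so 625 pairs give 43 750 steps.
Pair order is reshuffled each epoch under the run seed, and the loss is
asserted finite at every step.  Two runs with the same seed and
configuration are bit-identical.

## Dataset augmentation by pairwise cross-registration

With $N$ originals, every ordered pair of distinct images defines one
task: registering moving $Y$ to reference $X$ produces a new image $Y'$,
giving $M = N(N-1)$ new images and $N^2$ total ($25 \to 625$).
`run_augmentation()` accepts a pluggable backend:

* `backend_iterative()` (default) optimises a per-pair displacement field
  directly against the same total loss with ADAM — self-contained, no
  trained model needed;
* `backend_model()` uses a trained network;
* `backend_command()` shells out to an external registration tool through
  NIfTI files, for users who have one installed;
* `backend_identity()` passes the moving image through (plumbing tests).

The published pipeline used an external registration tool for this step;
the backend interface deliberately treats that as replaceable, and the
external tool itself is out of scope here.

## Evaluation

`dice()` implements $2|S_f \cap S_w| / (|S_f| + |S_w|)$ on the voxel sets
of one label; `evaluate_registration()` warps the moving labels with
nearest-neighbour sampling (trilinear would blend label identities),
scores every label present in the reference (background 0 excluded),
optionally merges left/right hemisphere label pairs by arithmetic mean,
and reports the unweighted average.  Empty-set conventions keep the
metric total: both sets empty gives 1, exactly one empty gives 0.

## The synthetic fixture generator

`make_pair()` produces desk-scale stand-ins for pre-aligned brain MR
pairs: a soft-edged ellipsoidal envelope containing several
non-overlapping soft-edged ellipsoidal structures with distinct
intensities and integer labels, deformed by a known smooth random field
(Gaussian-smoothed white noise at correlation length `deform_smoothness`,
rescaled so the maximum displacement magnitude equals
`deform_amplitude`), with additive Gaussian intensity noise (default sd
0.01 on $[0,1]$ intensities, a typical post-normalization MR noise
level).  The noise field is generated on a domain padded by the smoothing
half-width and cropped, so its variance is stationary across the volume.
Everything is deterministic per seed.

What the phantoms emulate: smooth multi-tissue intensity structure,
labelled substructures, smooth invertible-ish deformations, mild noise.
What they do not: cortical folding geometry, bias fields, modality
contrast, affine misalignment (inputs are assumed pre-aligned, here by
construction).  Tests passing on phantoms therefore demonstrate that the
optimisation and the machinery work, not that atlas-scale accuracy
transfers to clinical data.

## Desk-scale study conditions

The test suite trains at desk scale on one CPU.  The conditions, chosen
once for the suite: 8 synthetic $32^3$ pairs (amplitude 3 voxels,
correlation length 8, noise sd 0.01, seeds 101–108), the published loss
($\alpha = 1$, $\lambda = 3$, window 9), a narrow network
(`enc = 8,16,16,16`, `dec = 16,16,16,8`, 3³ head convolutions), 30 epochs
at learning rate $2 \times 10^{-3}$ halved at epoch 22 (a few hundred
steps instead of tens of thousands, hence the larger step size), training
seed 42.  Under these conditions the registered mean
Dice must exceed the unregistered overlap by at least 0.10, and the full
model must not fall behind the plain encoder-decoder ablation — the
desk-scale analogue of the published ablation ordering.  Direct per-pair
optimisation of the same objective (the iterative backend) serves as a
ceiling reference for what the loss itself supports on a given fixture.

## Other numerical choices and conventions

* **Coordinates**: 0-based voxel indices; displacements in voxel units
  added to the identity grid.  Millimetre-space fields are out of scope;
  spacing is carried through I/O for round-trip fidelity only.
* **Orientation**: volumes are used in the stored array index space; no
  reorientation is performed.  Reference and moving images must already
  be affinely aligned and identically oriented.
* **Out-of-domain sampling**: clamp-to-border by default (avoids zero
  halos at the brain boundary); a zeros mode is available.
* **Upsampling**: trilinear with half-voxel centre alignment
  (`src = (i + 0.5) * scale - 0.5`), the same convention for decoder and
  head upsampling.
* **Cropping**: centred, left margin `floor((in - out)/2)` per axis.
* **Intensity normalization**: per-volume min-max to $[0, 1]$ (constant
  volumes map to zeros); z-score is available.  Per-volume (rather than
  dataset-level) statistics were chosen because inference operates on
  single pairs.
* **Degenerate inputs**: constant images give zero similarity gradient by
  the $\varepsilon$ convention; empty label sets use the Dice conventions
  above; an all-zero displacement field is a valid identity transform.

## Known limitations

* The predicted fields are not guaranteed diffeomorphic; folding can and
  does occur locally.  No Jacobian-based metric or inverse-consistency
  constraint is provided — stricter regularisation is an explicit
  non-goal of this implementation.
* Training is single-threaded CPU R/C++; it is intended for desk-scale
  experiments and method study, not for atlas-scale training runs.
* No affine pre-alignment is performed; misaligned inputs violate the
  model's preconditions silently.
* The NCC window edge trades locality against stability; very small
  windows on noisy data make the denominator fragile even with
  $\varepsilon$.
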