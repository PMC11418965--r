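---
title: "Methods: deep-learning enhancement of cryo-EM density maps"
author: "emRestore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deep-learning enhancement of cryo-EM density maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Single-particle cryo-EM reconstructions are noisy, low-contrast 3-D scalar
fields. Post-processing ("sharpening", "enhancement") aims to make them
more interpretable and closer to the ideal density implied by the
underlying atomic structure. emRestore implements a supervised approach:
a 3-D U-Net style transformer is trained to map blocks of an experimental
map to the corresponding blocks of a *simulated* map computed from the
deposited atomic model, and a full map is enhanced by sliding-window
inference over overlapping blocks.

# The reference Gaussian simulation

The clean target for a structure with atoms at positions $x_i$ and atomic
numbers $A_i$ is

$$\rho_c(y) = \sum_i C \, A_i \, \exp(-k \, \lVert x_i - y \rVert^2),$$

with $k = \pi / (0.9 R_0)^2$ and $C = (k/\pi)^{3/2}$, where $R_0$ is the
map's resolution (conventionally the unmasked map-model FSC\@0.143
value). $C$ normalizes each atom's Gaussian to unit integral per unit
atomic number, so the simulated map's total mass equals the occupancy-
weighted sum of atomic numbers — a property the test suite checks by
numerical integration.

Three choices here were genuinely open:

* **Parenthesization of $k$.** The printed formula for $k$ is ambiguous
  (an unbalanced parenthesis). We default to $k = \pi/(0.9R_0)^2$, which
  makes $k$ an inverse squared length as the exponent requires; the
  alternative reading $(\pi/(0.9R_0))^2$ is available via
  `gaussianConstants(..., k_convention = "squared")` and is covered by
  tests.
* **Truncation.** Summing every atom at every voxel is $O(N_\text{vox}
  N_\text{atom})$. We truncate each atom's contribution where its kernel
  falls to $10^{-6}$ of peak (`tail` argument; `0`/`Inf` disables). The
  absolute error is bounded by $\text{tail} \cdot C \sum_i A_i$; at the
  default this is two orders of magnitude below $10^{-4}$ of the map
  peak. A tighter tail was preferred over the minimal $10^{-4}$ bound
  because truncation cost grows only with the cube root of its logarithm.
* **Occupancy.** Partial-occupancy atoms contribute proportionally
  (standard practice); setting all occupancies to 1 recovers the formula
  literally. Hydrogens are included when present and excludable by flag;
  waters are always excluded from parsed structures.

Simulated training targets are generated directly on the (resampled,
canonicalized) experimental grid, so voxel correspondence between input
and target is exact by construction.

# Map preprocessing

Maps are read from MRC2014/CCP4 files (modes 0/1/2/6, gzip transparently),
canonicalized so the first array index runs along crystallographic X
(`physical = origin + index * voxel_size`, 0-based voxel centers), and
rejected if the cell angles are not orthogonal. They are then resampled
to a common 1 Å grid by trilinear interpolation (tricubic available; not
default, for monotonicity) with out-of-extent values set to 0, and
normalized to $[0,1]$ by the 99.999th-percentile density value
(percentile by linear interpolation of order statistics, the `type = 7`
convention). Division alone cannot bound the range, so values above 1 are
clipped to 1 and, by default, negatives to 0. Statistics are computed
after resampling, matching the stated processing order. Only input maps
are normalized; simulated targets keep their native scale.

# Tiling

Training uses overlapping cubic blocks (the full-scale preset: 64-cubes,
stride 50, randomly cropped to 48 on the fly; the desk-scale preset:
16-cubes, stride 12). Offsets enumerate the stride lattice with the last
block clamped flush with the boundary — clamping rather than zero-padding
the boundary blocks avoids diluting edge density; maps smaller than a
block are zero-padded symmetrically and the padding is cropped at
assembly. Block pairs whose target contains no structure (no nonzero
voxel; threshold configurable as a minimum nonzero fraction) are dropped
from training only — inference and evaluation always use all blocks.

Reassembly averages all block predictions covering a voxel. Two
weightings exist: plain count-weighted mean, and a separable Hann window
that down-weights block borders. `assembleBlocks` defaults to the mean;
`enhanceMap` defaults to the Hann window because predictions near block
borders see one-sided context and are systematically worse — with uniform
averaging these border errors imprint a lattice of seams on the output
strong enough, at desk scale, to degrade the map-model FSC of an
otherwise clearly improved map. Both weightings reproduce the input
exactly when blocks are returned unmodified.

# Architecture

The enhancer is a four-level U-Net of transformer stages:

* **Encoder level $l$**: stride-2 3×3×3 convolution (channels
  $c_l = \text{base} \times (1,2,4,8)_l$), batch normalization, leaky
  ReLU, then 3 transformer blocks. The stage *input* is routed to the
  matching decoder as the skip tensor.
* **Bottleneck**: a ConvRes block — three conv + instance-norm pairs with
  two leaky ReLUs and an identity residual from the block input to the
  third pair's output.
* **Decoder level $l$**: kernel-2 stride-2 transposed convolution
  (doubling the edge, halving channels), concatenation with the skip,
  1×1×1 fusing convolution, then 3 transformer blocks.
* **Head**: 1×1×1 convolution to one channel, no output activation
  (targets are nonnegative but unbounded sums of Gaussians); an optional
  softplus head sits behind a flag. The head weights are initialized at
  1% of He scale so an untrained network starts near the zero map — the
  natural prior for sparse density targets.

Each transformer block adds a learned positional embedding, applies
efficient paired attention (EPA) with a residual connection, then a
3×3×3 convolution + batch norm + leaky ReLU + dropout path, also
residual.

**EPA.** Queries and keys are shared between two branches. The *channel*
branch computes a per-head $C/h \times C/h$ affinity
$\mathrm{softmax}(Q^\top K / \tau)$ ($\tau$ learned per head) and mixes
value channels with it. The *spatial* branch attends from all $N = DHW$
positions to a low-rank projection of the positions: tokens are
partition-pooled to $p = 64$ slots (each token contributes to exactly one
slot per axis) and mixed by a learned $p \times p$ matrix, so the cost is
$O(Np)$ rather than $O(N^2)$. Branch outputs are concatenated and fused
back to $C$ channels by a linear layer. A fixed pooling followed by a
learned slot mixer was chosen over a learned $N \times p$ projection so
that one set of weights serves every divisible input edge (the same
network instance runs on 16-, 32- and 48-cubes), and pooling keeps the
attention-weight normalization exact (rows of both branches sum to 1, a
tested invariant).

**Positional embedding.** Stored as three per-axis learned vectors
($e^{(d)}, e^{(h)}, e^{(w)} \in \mathbb{R}^{E \times C}$) added
separably, rather than one flattened $E^3 \times C$ table: the separable
form costs $3EC$ parameters instead of $E^3 C$ (which would be millions
of positional parameters at 48³ and would dominate the network's
parameter count), and resizes to other edges by 1-D linear interpolation.

Published widths, head counts and projection sizes for this architecture
family are not available; the defaults (base 32 channels, multipliers
1/2/4/8, 4 heads, $p = 64$, dropout 0.1, leaky slope 0.01) are declared
in `architectureConfig()` and stored in every checkpoint, so a network is
fully reconstructable from its checkpoint file.

There is no deep-learning framework in this package's dependency set;
layers are implemented directly on BLAS-backed matrix products with
analytic reverse-mode gradients (convolutions as im2col matrix products,
transposed convolutions as their exact adjoints). Every layer's backward
pass is validated against central finite differences in the test suite.

# Training

The loss is the masked mean-square error: voxels that are zero in *both*
the prediction and the target are masked out, and the squared error is
averaged over the remaining $N$ voxels. Exact floating-point zeros are
rare in network outputs, so "zero" for the prediction means
$|x_i| \le \varepsilon$ with $\varepsilon = 0$ by default (the literal
reading) and $10^{-6}$ as a practical preset. A fully masked batch
contributes loss 0 (counted, not NaN) and takes no optimizer step.

Optimization is Adam at an initial learning rate of $5\times10^{-4}$.
Every 5 epochs the validation loss is evaluated; after two consecutive
validations without improvement *over the running best* the rate is
halved, with a floor of $10^{-5}$. ("Improvement" against the running
best rather than the previous validation is the stricter and, we judge,
intended reading.) Augmentation applies one of the 24 proper 90°
rotations of the cube uniformly, composed with independent per-axis
mirror flips — exact voxel permutations, applied identically to input and
target, after the random 64→48 (or full-scale-equivalent) crop. The
reproduction preset uses batch size 15 and 244 epochs; the desk-scale
default is batch 4.

# Inference

`enhanceMap` resamples to 1 Å, normalizes, tiles (48-cube blocks, stride
38 by default), runs the network in inference mode (dropout off,
batch-norm running statistics), and reassembles with Hann-weighted
averaging. The output keeps the network's native scale — enhanced and
input maps are not on the same numeric range — and the normalization
divisor is recorded in the run manifest for users who want to rescale.
The output grid is 1 Å with the input's physical origin, so enhanced maps
superimpose on their inputs. Results are invariant to batch size and
block order (tested to $10^{-5}$).

# Validation metrics

The package computes the unmasked Fourier shell correlation between two
maps on shells one reciprocal voxel wide, the threshold-crossing
resolution at 0.143 and 0.5 (linear interpolation across the bracketing
shells; first downward crossing even if the curve recovers; Nyquist-
limited and degenerate cases flagged), the map-model FSC (against the
Gaussian-simulated map of a structure), and CC\_box (whole-box Pearson
correlation). These follow the standard textbook definitions and are
*not* equivalent to the external validation tools used at full scale;
mask-based correlations (CC\_mask, CC\_peaks) and Q-scores are out of
scope because their mask and peak-set constructions are tool-specific.

One caution on FSC intuition: FSC is invariant to any radially symmetric
linear filter, so blurring a map changes its FSC against a reference
only marginally. Blur degrades FSC-based resolution only in the presence
of noise (the blur suppresses signal below a fixed noise floor). The
package's degradation model applies blur *then* noise, which produces
the expected monotone resolution loss with blur strength.

# The synthetic data generator

`makeDataset` emulates the training corpus at desk scale: poly-alanine-
like backbones (N, CA, C, O per residue; ideal helix with 1.5 Å rise and
100°/residue, extended strand, or correlated-random-walk coil; CA–CA
3.8 ± 0.2 Å), their clean simulated maps at $R_0$ drawn from 3–5 Å on an
auto-fitted 1 Å grid with 5 Å padding, and degraded counterparts standing
in for deposited maps: Gaussian blur ($\sigma = 1$ Å), additive white
noise (10% of the clean peak) and a constant background offset (5% of
peak). These degradation levels were chosen once as a plausible toy
regime — enough corruption that the clean map is not recoverable by
rescaling, little enough that the task is learnable at toy scale.

What the generator does *not* emulate: CTF effects, structured/colored
noise, solvent background, masking artifacts, B-factor heterogeneity,
side chains, or conformational heterogeneity. Passing the desk-scale
study therefore shows that the implementation learns to invert the toy
degradation and that every pipeline stage composes correctly; it does not
certify performance on real EMDB maps, which requires full-scale
training (a configuration change — larger blocks, batch 15, 244 epochs —
not a code change).

# The desk-scale study

`runDeskScaleStudy` is the package's end-to-end benchmark: 11 synthetic
triples (6 training, 5 held out), a base-8 network on 16³ blocks, an
initial 30-epoch phase on 20 block pairs (whose first/final loss ratio
measures convergence), then a 20-epoch continuation over a wider pool of
48 block pairs drawn from all training maps, then enhancement of the 5
held-out maps and scoring by CC\_box and map-model FSC against the known
generating structures. The continuation widens the pair pool because
with 20 fixed noisy blocks the network begins to memorize their specific
noise realizations; drawing on all training maps' blocks measurably
improves held-out correlation. Inference uses half-block stride (8 for
16-cubes) rather than the full-scale stride ratio because at 16³ the
border region with one-sided context is a much larger fraction of each
block, and half-block overlap guarantees interior voxels are covered by
multiple well-contexted predictions.

Problem sizes throughout (16³ blocks, base-8 width, 50 total epochs, 11
maps) are the package's chosen desk-scale operating point: small enough
to run routinely on one CPU core, large enough that training
demonstrably generalizes to held-out maps.

**What the two scores can and cannot show at this scale.** Whole-box
correlation improves decisively on held-out maps (typically from
0.5–0.85 up to 0.87–0.98): the network removes the offset, the noise and
much of the blur. The map-model FSC comparison, by contrast, is
structurally biased *against* the enhanced map under this generator: the
degraded map is blur(clean) + white noise + offset where the clean map
*is* the model-calculated reference, and per-shell FSC is invariant to
the blur and the offset — so the degraded baseline sits at the
theoretical noisy-copy ceiling $1/\sqrt{1 + N/S}$ per shell, near 1
until the noise floor. A denoiser can only approach FSC = 1 from below,
and its residual reconstruction bias lowers the enhanced curve in
exactly the shells where the baseline is near-perfect, typically
shifting the 0.5-crossing a few tenths of an Angstrom against the
enhanced map even as CC\_box improves on every map. Real deposited maps
are decorrelated from model-calculated maps by systematic experimental
error, which is why full-scale enhancement has headroom on this metric
that the toy degradation model deliberately does not manufacture. A
map-model-FSC win at desk scale therefore depends on the draw of
resolutions and noise, and its absence is a property of the degradation
stand-in, not of the pipeline.

# Numerical notes and limitations

* Percentile normalization errors out on maps whose chosen percentile is
  not positive (all-zero or negative maps) rather than returning NaNs.
* `fscResolution` on a curve that never crosses returns the Nyquist
  resolution flagged `limited`; a curve starting below threshold returns
  the first shell flagged `degenerate`.
* Training reproducibility is exact for a fixed seed, configuration and
  data manifest; checkpoints store parameters, batch-norm running
  statistics and the full architecture configuration.
* The divergence guard aborts on non-finite loss and names the offending
  batch's first manifest index; gradient clipping is available but off
  by default.
* Training at full scale (48³ blocks, base 32) is computationally out of
  reach of a pure-R training loop; the code supports it, but practical
  full-scale training would motivate porting the layer kernels to
  compiled code while keeping this package's interfaces and tests.
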