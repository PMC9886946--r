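---
title: "Tree architectures and single-route pruned backpropagation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tree architectures and single-route pruned backpropagation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the model, the conventions and the design decisions
behind `treebp`, in the spirit of a methods section: what exactly is
computed, which choices were genuinely open, and what the tests do and do
not establish.

## The model

A Tree-3 network maps a `C x H x W` image to `classes` outputs through three
hidden layers:

1. **Grouped convolution.** Each input channel `c` is convolved with its own
   `K` kernels of side `f` (default 5), giving `C*K` valid-convolution maps
   of side `H - f + 1`. The same `C*K` kernels are logically shared by all
   `M` branches: activations are computed once, but for route analysis each
   branch owns its own copy of the resulting units (the per-branch
   "dendritic" graph). The activation (ReLU or Sigmoid) is applied to the
   convolution output, and non-overlapping `p x p` max-pooling (default 2)
   selects one unit per window. Because both activations are monotone
   non-decreasing, pooling after the activation selects the same unit as
   pooling before it wherever the selection is unambiguous; ties are broken
   by the first (lowest-index) window member, a fixed and documented rule so
   that runs are bit-reproducible.
2. **Tree sampling.** The pooled maps (side `s`) are cut into `J = s / r`
   non-overlapping slabs of `r` consecutive rows spanning all `s` columns.
   One tree unit exists per (slab `j`, channel `c`, branch `m`); its
   pre-activation is the sum over the slab's positions and over the `K`
   depth kernels of a private weight times the pooled value. The weight
   tensor therefore has shape `s x s x K x C x M` — one private weight per
   pooled position per branch — matching the canonical `3K x M x 14 x 14`
   size-table entry for the 32x32 RGB geometry, with output `3M x 7`.
   The slab is the reading of the "2 x 2 x 7 rectangle" as two consecutive
   rows of the 14 x 14 map: it is the only reading consistent with both the
   weight-size table and the `3M x 7` output count, so the literal
   2-column-block reading was rejected. `r = 2` for the 32x32 geometry and
   `r = 4` for the 28x28 grayscale geometry (pooled side 12, `J = 3`,
   giving the `16 x 3` second layer).
3. **Fully connected readout.** The `C*J*M` tree units connect densely to
   the outputs; softmax converts logits to class probabilities.

All layers are bias-free: the single-route gradient formula contains no bias
term, and keeping the parameter set exactly `{W_conv, W_tree, W_fc}` makes
the printed rule exact rather than approximate.

The **ten-head variant** instantiates ten single-output heads (private tree
and readout weights) over one shared convolution layer; the ten scalar
outputs feed a single softmax. The **LeNet-5** builder exists as the
multi-route reference for structural counting and route enumeration; the
training engines deliberately reject it, since the pruned engine's
correctness argument (one route per weight-output pair) does not apply.
Its first convolution mixes the three input channels (kernel depth 3): this
is the standard construction and the one consistent with the
`5*5*3*6*28*28` gradient-instance product for that layer.

## The single-route gradient and the two engines

With softmax + cross-entropy the output-layer error is exactly
`probs - onehot(target)`; there is deliberately no separate output
activation-derivative factor, which is what makes the route product

```
Δ(W_conv) = input · σ'_conv · W_tree · σ'_tree · W_fc · (output − output_desired)
```

exact. The published rule states the contribution of one route; the full
gradient of a (shared) weight is this product summed over the weight's
applications, its branch replications, and the output units. That summation
convention is the package's own and is validated by engine equivalence (see
below) rather than asserted.

Two backward passes produce the same numbers by different computations:

* `backward_reference()` — the ordinary vectorized chain rule, with
  max-pooling routing gradient only to the selected window member. It is
  the oracle: it is itself checked against central finite differences.
* `backward_pruned()` — enumerates the *active* tree units and the
  *selected, active* convolution units and forms the route products only
  there. Applications whose route crosses a non-selected pooling unit or a
  unit with zero activation derivative are never visited. With Sigmoid no
  activation-derivative zeros exist, so only pooling non-selection prunes
  structurally; magnitude thresholding (below) is then the operative
  pruning notion.

Numerical conventions: the ReLU derivative at exactly zero pre-activation
is taken as 0 (the unit is inactive), which keeps the structural-zero
bookkeeping and the gradient consistent; the two engines may differ only in
floating-point summation order, and the test suite bounds their relative
discrepancy at `1e-9` over a grid of 64 random small networks (both
activations), with the reference engine within `1e-5` of central finite
differences (step `1e-4`) on the same grid.

## Optimization

SGD with Nesterov momentum and L2 weight decay uses the common
deep-learning form: `g <- grad + α w`, `v <- μ v + g`,
`w <- w − η (g + μ v)`. Weight decay is folded into the gradient before
the momentum update; the decay constant can itself follow a schedule (the
canonical recipes change α after epoch 50). Defaults are the canonical
offline settings η = 0.075, μ = 0.965, α = 5e−5, batch 100. Schedules are
piecewise-constant over 0-based epoch intervals (e.g. 0.01 / 0.005 / 0.001
on [0,100), [100,150), [150,200]) or multiplicative
(`base · factor^(epoch %/% period)`, e.g. decay 0.6 every 20 epochs); the
training loop's 1-based epoch `e` evaluates schedules at `e − 1`. Batch
gradients use **mean** reduction, the standard convention for the mean
cross-entropy objective; a `sum` option exists for linearity checks.

## Sparsity accounting

A **gradient instance** is one per-application gradient term of a possibly
shared weight: kernel position × channel × kernel × application position ×
branch replication. The canonical Tree-3 (K = 6, M = 16, 32x32 RGB)
convolution layer has `5·5·3·6·28·28·16 = 5,644,800` instances; LeNet-5's
first convolution has `352,800`, or `88,200` counting only applications
surviving max-pooling. At an active fraction of 0.6% the Tree-3 conv layer
updates `33,869 ≈ 34,000` instances.

"Zero gradient" means **structural** zero — the route crosses a
non-selected pooling unit or an inactive unit — never a magnitude epsilon.
Magnitude thresholding is a separate, explicit policy
(`pruning_policy()`), either an absolute threshold or a kept top fraction
pooled across layers; with threshold 0 pruned-then-applied training is
bit-identical to unpruned training (asserted in the tests). Zero fractions
are profiled per sample (batch size 1), because batch averaging destroys
the structural zeros being measured; the profile reports per-layer mean and
standard deviation over the evaluated samples and the instance-weighted
whole-step fraction, which the convolution layer dominates. For Sigmoid
networks the structural profile reflects pooling only; magnitude histograms
(`gradient_magnitude_histogram()`, log-spaced bins of `|Δ|` and `|Δ/W|`)
are the relevant summary there.

## Route counting conventions

Two conventions are deliberately kept and labelled, never merged:

* **Exact DAG enumeration.** Nodes are units from the first hidden
  (post-pooling) layer onward; each pooled unit is a single
  selection-funnel node that a route enters through one window member.
  Counts obey the dynamic-programming recurrence
  `count(node) = Σ count(successors)` and are cross-checked against
  brute-force DFS enumeration on small graphs.
* **Closed form.** The published LeNet-5 arithmetic: 16 kernels × 25
  applications, divided by 4 for the second pooling, times 120 × 84 —
  1,008,000. The division by 4 is an approximation of pool-window overlap:
  exact enumeration of the same graph gives 4,032,000 for a central unit,
  because all four window members remain distinct route steps. Both numbers
  are reported with their convention tags.

Certification runs on the per-branch logical graph (each branch owns its
conv-unit copies), matching the dendritic picture; on the physical graph a
shared kernel weight would trivially have M routes. A tree is *certified*
when no (first-hidden-unit, output) pair has more than one route and every
unit reaches at least one output; the stronger `all_pairs_single` flag
(every pair exactly one) holds for the single-head tree but not for the
ten-head variant, whose heads reach only their own output.

## He-normal initialization

Every weight tensor is zero-mean Gaussian with sd `sqrt(2 / fan_in)`:
`f²` for the grouped convolution (each kernel sees one channel),
`r · s · K` for a tree unit's summed receptive field, and the input width
for fully connected layers. Initialization is deterministic given
`(spec, seed)`; the user-level seed fans out to named sub-seeds
(init / data / augmentation / shuffling) so components can be varied
independently, and the suite checks the empirical sd of a >1e5-element
layer to within 2% of the target.

## The synthetic task

The generator emulates exactly the structure the architecture is built to
detect: each class carries a fixed ±amplitude 5×5 patch pattern at a fixed
class-specific position (both deterministic functions of the class index,
independent of the data seed), over i.i.d. Gaussian pixel noise, clipped to
[−1, 1] like saturated normalized pixels. Defaults — 12×12×1 images, 10
classes, 40/20 train/test per class, amplitude 1.0, noise sd 0.3 — were
chosen once as a regime where the signal is clearly detectable by 5×5
kernels yet per-pixel noise is substantial. What it does **not** emulate:
natural-image statistics (spatial correlations, multi-scale structure,
class overlap, translation variability). Passing the learning tests
therefore shows that the engines optimize correctly and the architecture
can exploit localized 5×5 structure; it says nothing about success rates on
real image databases, which are documented separately as external
full-scale benchmarks (`full_scale_benchmarks()`) and never recomputed
here. Augmentation uses horizontal flips only (the standard reading of
"flipping" for images) and zero-fills translated borders, both documented
constants.

## Problem sizes and indexing

The test and acceptance runs use deliberately small instances: 8×8 toy
networks (K, M ≤ 2–4) for the 64-network engine-equivalence grid and finite
differences; the 12×12, K = 2, M = 4 network with 400 training images and
15 epochs for the learning check (chance 10%, the run is required to exceed
30%); the full 32×32 geometries only for structural counting and route
certification, where exact DAG dynamic programming handles the
K = 15, M = 16 graph (~1.4e5 nodes) in seconds. These sizes are the
package's choice of smallest instances that still exercise every code path
at full fidelity.

All internal indexing is 1-based (R's native convention), including class
labels `1..classes`; file formats with 0-based labels (IDX, CIFAR binary)
are shifted on read and write. Reports and witness labels print 1-based
coordinates.

## Known limitations

* The engines run on tree variants only; LeNet-5 training is out of scope
  by design (the builder serves structural and route analysis).
* The pruned engine's skipping is an algorithmic statement (inactive routes
  are never visited), not a wall-clock claim in R at these sizes.
* Arbitrary-depth architectures, skip connections, kernel-cross extensions
  and 1×1 convolution insertions are not modelled.
* Checkpoints are R serializations (`.rds`), portable across platforms but
  not across languages.
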