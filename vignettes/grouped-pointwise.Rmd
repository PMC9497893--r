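---
title: "Interleaved grouped pointwise convolutions: model, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interleaved grouped pointwise convolutions: model, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kpconv)
```

## The substitution scheme

A standard pointwise convolution with `Ic` input channels and `F`
filters computes, at every spatial position, `F` inner products of
length `Ic`; it costs `Ic·F` weights (biases are ignored throughout the
accounting — in the backbones of interest every such convolution is
followed by batch normalisation). `kpconv` replaces it with a two-layer
grouped subnetwork governed by one hyperparameter, the group width `Ch`
(channels seen by each group of filters):

* **K**: `GK1 = ⌈Ic/Ch⌉` groups. Groups take consecutive channel blocks
  of width `Ch`; when `Ch ∤ Ic` the last block is completed by
  replicating the first `d = GK1·Ch − Ic` channels (the deficit of the
  division, `0 ≤ d < Ch`). Each group holds `FgK1 = ⌊F/GK1⌋` filters;
  the remainder `GK2 = F − FgK1·GK1` becomes a second path of
  one-filter groups that reuse the leading channel blocks. Both paths
  together emit exactly `F` channels, and `GK2 < GK1` whenever
  `FgK1 ≥ 1`.
* **Interleave**: the fixed permutation `(1, 3, 5, …, 2, 4, 6, …)` (odd
  positions first; for odd `F` the odd block carries the extra channel).
  It guarantees that consecutive blocks of the permuted channels mix
  outputs of different K groups.
* **L**: the same planning applied to the `F` interleaved channels
  (`n_input = F`), present only when `Ic ≥ F`. With fewer inputs than
  filters, K already constrains each filter to a small channel budget
  and a second layer was not found useful; this inclusion rule is part
  of the scheme.
* **Sum**: the block output is `K + L` element-wise. Compared with
  concatenation, the sum makes L a residual refinement: gradients reach
  K directly even if L is uninformative.

Every filter in every path carries `Ch` weights, so the substituted
layer costs `2·F·Ch` weights with L and `F·Ch` without — independent of
how the filters are split into groups. A layer is *eligible* when
`Ch ≤ Ic/2` and `Ch ≤ F/2`; otherwise the grouped divisions collapse to
fewer than two groups and the planner refuses (the caller keeps the
original convolution).

### Replication semantics

The published description of the last, under-filled channel group is
internally inconsistent: the formula as printed would list `b` real
channels followed by `Ch − b` replicated ones with `b` the deficit,
while the worked example (14 channels, groups of 4, last group
`x13, x14, x1, x2`) keeps `Ch − b` real channels and replicates `b`.
The coincidence `b = Ch − b = 2` in the example masks the difference.
`kpconv` implements the example-consistent reading — last group = the
remaining `Ch − d` real channels followed by the first `d` channels —
which is also the only reading that never drops a real channel. A
channel gathered twice (replication) is consumed twice and owns two
independent weights; the densified equivalent matrix accumulates both.

### Degenerate cases

* `FgK1 = 0` (very small `Ch` with `Ic ≫ F`, e.g. `Ch = 2` on a
  1152→192 projection): the main path carries zero filters and all `F`
  filters move to the one-filter-per-group path. The `GK2 < GK1`
  guarantee does not apply here; only `GK2 ≤ GK1` holds.
* `Ch > n/2` inside `channel_groups()` is tolerated (indices cycle via
  `rep_len`) but lies outside the eligible regime and is never produced
  by the planner's callers.
* Indices are 1-based everywhere, the natural R convention; published
  0-based listings are translated in the tests.

## The subnetwork as a trainable object

`build_subnetwork()` materialises a plan with Glorot-uniform weights
(limit `sqrt(6/(Ch + filters))` per path, the standard convolutional
initialisation). Configuration choices and their defaults:

* `activation` (`"swish"`, β = 1 fixed): the concatenated K output is
  activated (`intermediate_activation = "after_k"`) before both the
  interleave and the residual sum. The sources describing the scheme do
  not state the in-subnetwork activation placement explicitly, but their
  ablations change the computation count when the activation changes,
  implying in-subnetwork activations exist; activating K's output is the
  minimal such placement. Linear mode (`"none"`) exists for
  oracle-equivalence testing. The activation *after* the whole
  substituted layer belongs to the enclosing block and is never applied
  by the subnetwork.
* `use_bias` (default `FALSE`): convolutions followed by batch
  normalisation are bias-free. When the original layer carried biases
  (the squeeze-excitation convolutions), each layer of the subnetwork
  keeps one bias per filter.
* `l_batch_norm` (default `FALSE` standalone, `TRUE` in whole-model
  substitution): a trainable scale/shift batch-norm on the L
  concatenation before the sum; see the convention discussion below.

Gradients are implemented analytically for every piece (grouped
convolutions with scatter-add through replicated channels, the
interleave, batch-norm, swish) and verified against central differences
in the test suite. The linear-mode forward of every planned subnetwork
equals a two-matrix computation through the densified block-sparse
equivalents to double-precision accuracy; this cross-module equivalence
is the package's core correctness guarantee.

## Whole-model substitution of EfficientNet-B0

The backbone is generated from the canonical B0 stage table (stem 32;
MBConv stages 16×1 k3 e1, 24×2 k3 e6 s2, 40×2 k5 e6 s2, 80×3 k3 e6 s2,
112×3 k5 e6, 192×4 k5 e6 s2, 320×1 k3 e6; squeeze-excitation ratio 0.25
on block input channels; head 1280; dense softmax classifier).
Trainable parameters are convolution and dense weights/biases plus
batch-norm scale/shift pairs; batch-norm running statistics are not
trainable. This reproduces the published baseline counts exactly
(4,020,358 / 4,010,110 / 4,017,796 for 10/2/8 classes).

`apply_stride_skip(desc, k)` forces the first `k` stride-2 convolutions
(stem first, then the downsampling blocks in forward order) to stride 1,
so a 32×32 input reaches the head at 16×16 with `k = 4` instead of
requiring 224×224 inputs. Parameters are unchanged. The reading "first
four stride-2 convolutions" (rather than "first four stages") is
adopted because B0 has five downsamplings and removing four of them
matches the 224/32 resolution ratio.

### The substitution convention (an open identification problem)

Which layers the published whole-model variants substitute, and what
normalisation/bias mass the substituted blocks carry, is not stated in
the sources; the only evidence is the printed whole-model totals. An
exhaustive numerical search over candidate conventions (eligibility
rules, channel-width clamps, group caps, filter padding, batch-norm and
bias placements, fitted jointly against all published totals including
the no-L ablation rows) shows that *no* combination in a very large
rule family reproduces every total exactly; in particular the strict
eligibility predicate with a bare subnetwork is off by +18% to +40% at
`Ch = 16/32`. The package therefore adopts the simplest convention that
lands within a fraction of a percent of the published counts at the
widths those models were reported:

* every 1×1 group-1 convolution is a candidate — MBConv expansion and
  projection, both squeeze-excitation convolutions, and the head;
* a layer is substituted whenever its input splits into at least two
  groups (`Ic > Ch`); a one-group K would be a plain convolution, so
  the original layer is kept (`policy = "auto"`);
* a one-group L (`F ≤ Ch`) is planned as a dense `F × F` convolution
  instead of a padded single group;
* the L concatenation carries a trainable batch-norm (2`F`
  parameters); the enclosing block's original batch-norm after the
  substituted layer is retained unchanged;
* substituted bias-carrying layers keep one bias per filter per layer.

With this convention the built models count 620,986 (`Ch = 16`, 10
classes), 951,394 (`Ch = 32`) and 610,738 (`Ch = 16`, 2 classes)
trainable parameters against published 623,226 / 950,650 / 612,978 —
residuals of −0.36%, +0.08% and −0.37%. The tests assert the exact
agreement of built weight tensors with the package's own accounting and
the 0.5% agreement with the published totals; exact reproduction of the
published substituted counts would require the original implementation
source and remains a known limitation. `policy = "strict"` exposes the
bare eligibility-rule behaviour (no in-subnet batch-norm) for users who
want the scheme exactly as described in isolation.

## Numerical choices

* Double precision throughout; the oracle-equivalence tolerance is
  1e-5 relative (generous: agreement is near machine precision).
* Batch-norm uses ε = 1e-3 and momentum 0.99 (canonical backbone
  defaults); training mode normalises with batch statistics and updates
  running statistics; backward passes use the full training-mode
  Jacobian.
* SAME padding follows the TensorFlow convention (`⌈n/s⌉` outputs, the
  extra padding on the bottom/right).
* Ceiling division for group counts, floor for filters per group —
  fixed by the scheme; ties never arise.
* Dropout is omitted (it carries no parameters and the smoke-train
  loop is not a regularisation study).

## The synthetic data and what the tests show

`generate_synthetic_set()` emulates small balanced RGB classification
sets (2–10 classes, 16–224 px): class-specific mean colour, blob count
and texture frequency with additive uniform noise. The classes are
separable from mean colour alone — verified by a linear probe — so the
sets certify *learnability*, not realism. They stand in for natural and
biomedical benchmarks at smoke scale; passing the smoke-train check
shows the substituted architecture can fit class structure through its
grouped, interleaved paths, and says nothing about accuracy on real
images, which requires full-scale training outside this package's
scope.

Problem sizes used by the shipped checks (the package's choice of smoke
scale): learnability uses 128 images of 16×16 at `Ch = 8` with four
stride skips, batch 16, RMSProp 1e-3, and exceeds the 0.25 chance level
within two epochs (typically >0.5 after one); the reproducibility check
uses 16 images for one epoch. Larger runs (512 images, 32×32, five
epochs) behave the same way, only slower.

## Known limitations

* The substituted-model parameter convention is identified only up to
  ~0.4% (above); counts are exact against the package's own accounting.
* MAC accounting counts one multiply-accumulate per convolution weight
  per output position; activation, normalisation and pooling operations
  are excluded, so MAC totals are comparable within this package but
  not directly against other tools' "computations" columns.
* Only the B0 stage table ships; the descriptor is a plain data frame
  and extensible, but other variants are untested.
* The forward/backward stack is built for correctness and moderate
  smoke-scale speed (C++ kernels for depthwise and grouped
  convolutions), not for large-scale training.
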