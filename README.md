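# kpconv

Grouped pointwise convolutions with channel interleaving, free of
divisibility constraints, for parameter-efficient image classifiers.

## The problem

In modern convolutional classifiers most trainable parameters sit in the
pointwise (1×1) convolutions that mix channels: a layer with `Ic` input
channels and `F` filters costs `Ic · F` weights, and in
EfficientNet-style backbones these layers hold over 90% of the weight
mass. Grouped convolutions cut this cost by letting each group of filters
see only a subset of the input channels, but a plain grouped layer
requires the group count to divide both `Ic` and `F`, and its groups
never exchange information.

`kpconv` implements a replacement subnetwork that removes both
limitations. Given a single hyperparameter `Ch` — the number of input
channels fed to each group of filters — a standard pointwise layer is
replaced by:

1. **Layer K** — a grouped pointwise convolution with
   `GK1 = ⌈Ic / Ch⌉` groups of `FgK1 = ⌊F / GK1⌋` filters. When `Ch`
   does not divide `Ic`, the last channel group is completed by
   *replicating* the leading input channels; when `GK1` does not divide
   `F`, a second path **K2** adds `F − FgK1·GK1` one-filter groups that
   reuse the leading channel groups. K therefore always emits exactly
   `F` channels.
2. **Interleaving** — a fixed permutation placing odd-numbered channels
   first and even-numbered channels last, so the next layer's groups mix
   outputs originating from different K groups.
3. **Layer L** — a second grouped pointwise layer planned the same way
   over the `F` interleaved channels (present when `Ic ≥ F`).
4. **Sum** — the outputs of K and L are added element-wise, giving L a
   residual role.

Every filter in every path carries exactly `Ch` weights, so a substituted
layer costs `2·F·Ch` weights with L (or `F·Ch` without) instead of
`Ic·F` — a reduction of 10–100× for typical widths. The package plans
these subnetworks for arbitrary `(Ic, F, Ch)`, builds and trains them on
plain numeric arrays, applies them wholesale to an EfficientNet-B0
backbone, and accounts for every parameter exactly.

Intended users: researchers compressing CNN classifiers for biological
and medical imaging (cell images, histology) and anyone who needs exact
parameter/MAC accounting of grouped-pointwise substitutions.

## Worked example

Plan the substitution of a pointwise layer with 14 input channels and 10
filters at `Ch = 4`:

```r
library(kpconv)
p <- substitution_plan(14, 10, 4)
p
#> substitution plan for (ic=14, f=10), Ch=4
#>   K: main 4 x 2, extra 2 x 1
#>   interleave: odd channels first (10 channels)
#>   L: main 3 x 3, extra 1 x 1, summed with K
#>   params: 80 of 140 (57.14%)
```

K has 4 groups of 2 filters plus 2 extra one-filter groups (4·2 + 2 = 10
filters); L has 3 groups of 3 plus one extra (3·3 + 1 = 10); both layers
cost 10·4 = 40 weights, 80 in total against 140 for the standard layer.
The last channel group of K is `(13, 14, 1, 2)`: channels 1 and 2 are
replicated to fill the group.

Materialise and run it:

```r
net <- build_subnetwork(p, subnet_config(), seed = 1)
x <- array(rnorm(2 * 8 * 8 * 14), c(2, 8, 8, 14))
dim(subnet_forward(net, x))
#> [1]  2  8  8 10
```

Substitute every pointwise convolution of an EfficientNet-B0 classifier:

```r
rep <- savings_report(effnet_b0(num_classes = 10), ch = 16)
rep
#> pointwise substitution at Ch = 16 (auto policy)
#>   layers substituted: 57 of 64
#>   model parameters: 4,020,358 -> 620,986 (15.4%)
#>   pointwise-conv MACs: 339,164,672 -> 73,906,720
```

The unmodified 10-class baseline has 4,020,358 trainable parameters; at
`Ch = 16` the substituted model keeps 15.4% of them, and at `Ch = 32`
23.7% — a saving of about 76%. `build_baseline()` /
`substitute_pointwise()` build the actual weight tensors, and
`model_params()` counts them; `smoke_train()` verifies the substituted
model still learns (a 4-class synthetic set is fit well beyond chance
within a few epochs), and `hflip_ensemble_predict()` provides
test-time horizontal-flip ensembling.

A thin command-line wrapper ships in `inst/cli/`:

```sh
Rscript inst/cli/kpconv plan --ic 14 --f 10 --ch 4
#> 14 10 140 4 4 2 2 3 3 1 80 57.14%
Rscript inst/cli/kpconv report --classes 10 --ch 32 --out report.json
Rscript inst/cli/kpconv selftest
```

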