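# sshapelet

Sequence shapelets for classifying sparse, variable-length, irregularly
sampled multi-variate time-series features.

## The problem

In data sources like electronic health records, each object (a patient) is
described by many features (laboratory variables), and each (object,
feature) record is a *series* of real values of arbitrary length — often of
length zero, because the test was never ordered. Such empty records are not
noise: in clinical data values are missing **not** at random, so the very
absence of a measurement predicts outcomes. Standard classifiers need a
flat numeric table, and naive summaries (mean, slope, count) destroy the
temporal shape while static imputation destroys the missingness signal.

`sshapelet` converts every record into a single number in three phases:

1. **Phase A — discretization.** Each non-empty series S is z-normalized
   (population σ), optionally compressed by piecewise aggregate
   approximation (PAA, ratio *r*, default off), and mapped by symbolic
   aggregate approximation (SAX) to a symbol string over an alphabet of
   size α whose breakpoints cut N(0,1) into equiprobable regions.
2. **Phase B — s-shapelet discovery.** Per feature, candidate subsequences
   *s* are sampled from the observed strings and scored by the information
   gain of the optimal threshold split of

   Dist(s, Ŝ) = min over windows s′ ⊆ Ŝ, |s′| = |s| of Levenshtein(s, s′),

   a sliding-window edit distance that is invariant to record length. The
   threshold δ_osp maximizing the gain is found by exhaustive scan over the
   integer distances; the best candidate across alphabet sizes
   (default {2, 3, 5}) becomes the feature's **s-shapelet** s*.
3. **Phase C — transformation.** Every record becomes Dist(s*, ·); empty
   records receive a learned encoding depending on the strategy:
   * `plain` — |s*| (length encoding; the temporal baseline),
   * `mc` — the most common training distance,
   * `lr` — 0 ("left") or the maximum training distance ("right"),
     whichever placement maximized the split gain on the training data,
     so the encoding of missingness adapts to the class distribution,
   * `sl` — baseline without shapelets: the raw number of measurements,
     with empty records encoded as 0.

The resulting n × m′ matrix feeds any classifier; the bundled evaluation
harness uses a 100-tree random forest with √m features per split, stratified
10-fold cross-validation, AUC, sparsity-tolerance (τ_sp) sweeps and Wilcoxon
signed-rank paired comparisons.

## Worked example

```r
library(sshapelet)

x <- simulateSparseSeries(n = 120, m = 4,
                          roles = c("motif", "sparsity", "noise", "noise"),
                          qPos = 0.6, qNeg = 0.15, seed = 42)
x
#> SparseSeriesSet: 120 objects x 4 features (2 classes, 37.1% empty records)
#>   features: f1.motif, f2.sparsity, f3.noise, f4.noise

model <- fitShapeletModel(x, strategy = "lr", seed = 42)
model
#> ShapeletModel (strategy lr): 4 retained features, tau_sp=1, seed=42
#>   shapelet gains: min 0.041 / median 0.138 / max 0.438 bits

model@shapelets[[1]]
#> SShapelet 'cacacac' (feature f1.motif, alpha=3): delta_osp=1, gain=0.438 bits, lr, empty -> 7 (right)

head(transformFeatures(model, x), 4)
#>   object_id f1.motif f2.sparsity f3.noise f4.noise label
#> 1        o1        7          12        0       12   neg
#> 2        o2        2          12        0        6   neg
#> 3        o3        0          19        0        3   pos
#> 4        o4        7          19        0       12   neg

crossValidate(x, "lr", folds = 10, seed = 42)$meanAUC
#> [1] 0.9096737
```

Reading the output: the generator planted an alternating high-low motif in
positive records of `f1.motif`, and discovery recovered it — the shapelet
`cacacac` (α = 3) is the SAX image of that alternation, records containing
it sit at distance 0 (object o3, a positive) while motif-free records cap
out at the shapelet length 7 (gain 0.438 bits at δ_osp = 1). For the
MNAR feature `f2.sparsity` the lr strategy placed empty records on the far
side of the split (`empty -> 19 (right)`), turning missingness itself into
signal. The transformed table is fully numeric with no missing cells, and
a 10-fold cross-validated random forest reaches AUC ≈ 0.91 on data where
37% of records are empty.

Long-format CSV I/O (`readLongCSV`/`writeLongCSV`, columns
`object_id, feature_id, time, value` plus a label table), model
serialization (`writeShapeletModel`/`readShapeletModel`, versioned JSON)
and a thin CLI (`inst/cli/sshapelet` with `simulate`, `fit`, `transform`,
`evaluate`, `sweep`, `compare` subcommands) round out the tool.

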