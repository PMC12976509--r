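# mitoscore

Patch-based deep scoring of mitochondrial morphology in live-cell
fluorescence microscopy.

## What it does, and for whom

Mitochondria swing between **fission** (fragmentation into puncta and
rings) and **fusion** (merging into long interconnected filaments); where
a cell sits on that continuum is a sensitive stress readout with direct
relevance to neurodegeneration screening. `mitoscore` is for
image-analysis and screening groups who have single-channel fluorescence
fields of mitochondria (e.g. MitoTracker-stained live cells) and want a
quantitative, reproducible morphology score per field, per dose, or per
study participant.

Each field is scored by a patch ensemble: cell foreground is segmented,
the field is tiled into 112 × 112 px windows at stride 100, windows with
less than 50 % foreground are discarded, and a compact residual CNN
classifies random 4-patch draws over 100 Monte-Carlo rounds. The averaged
softmax gives the field's probability vector over three canonical states —
hyperfission (**CCCP-score**), normal (**NC-score**), hyperfusion
(**FL3-score**):

```
score(field) = (1/R) Σ_r (1/k) Σ_{p ∈ draw_r} softmax(CNN(patch_p))
```

A classical baseline (per-organelle form factor `FF = P²/(4πA)` and
aspect ratio, plus skeleton-graph branch/junction statistics) is included
for comparison, and a stochastic-geometry simulator generates fields with
known ground truth along the fission–fusion continuum (`phi` ∈ [0, 1]),
so the whole pipeline is testable without any proprietary imaging data.
Evaluation utilities cover grouped (batch-aware) 5-fold cross-validation,
fold-score report tables, ROC/AUC by threshold sweep (equal to the
Mann-Whitney pair statistic), rank-sum group comparisons, and
participant-level prediction ROC.

## Worked example

Simulate a strongly hyperfused field and measure it with the classical
baseline:

```r
library(mitoscore)
spec <- morphologySpec(phi = 0.9, seed = 42)   # 0 = fission, 1 = fusion
fld  <- simulateField(spec)
fld
#> SimulatedField 512x512 | phi=0.900 -> FL3 | fg=23.5% | seed 42
fieldMorphometry(normalizePercentile(fld@image), truthMask(fld))
#>   object_count ff_mean ff_median ar_mean ar_median n_branches
#> 1           22    3.52         1    1.68      1.12        112
#>   mean_branch_length n_junctions
#> 1              16.98          53
```

22 segmented objects with mean form factor 3.5 and ~17 px mean branch
length describe a sparse network of long filaments; the same call on a
`phi = 0` field (seed 42) yields instead 168 near-circular objects
(mean FF 1.25) with 6.9 px mean branch length.
To train and score end-to-end on a synthetic study (30 fields per class,
grouped fold held out):

```r
runPipeline(list(seed = 1, out = "run",
                 train = list(task = "CCCP-FL3-NC")))
read.csv("run/evaluation/metrics.csv")
```

which reports held-out field-level accuracy and ROC-AUC per fold, the
per-fold mean score table with its `Average` row, and one score row per
field. A thin CLI wraps the same functions
(`inst/scripts/mitoscore simulate|patch|morphometry|train|score|run`).

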