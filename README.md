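# coexSplit

Rank-based coexpression, greedy cohort splitting and survival comparison
for gene pairs.

## The scientific problem

A transcription factor and a candidate target gene — the motivating case
is the p53-family member p63 and the collagenase MMP13 in squamous-cell
carcinoma — may be coexpressed across tumours, yet coexpression alone does
not show that the regulatory axis matters clinically. coexSplit implements
one way to ask the clinical question: split a patient cohort into a
subgroup in which the two genes' expression covaries (the *interaction*
cohort) and the removed remainder (the *no-interaction* cohort), then test
whether the two subgroups differ in survival. The package is aimed at
computational biologists analysing expression series with paired outcome
data, and at methodologists who want the selection procedure itself under
test.

## The method

**1. Per-sample percentile ranks.** Each expression value is replaced by a
within-sample rank on a 0–100 scale:

    r_ij = 100 · #{k : x_kj < x_ij} / N

for probe *i* in sample *j* with *N* probes per sample — a rank of 55
means 55 % of that sample's probes have strictly lower values. Ranks are
invariant under any strictly increasing per-sample distortion, so samples
from different platforms or normalisations become comparable.

**2. Coexpression.** The coexpression of two genes is the Pearson
correlation of their rank profiles across samples (equivalently, the
Spearman correlation of the raw profiles when ties are absent).

**3. Greedy cohort split.** Starting with all samples in cohort 1,
repeatedly compute every leave-one-out correlation and move the sample
whose removal most increases the correlation to cohort 2, while any single
removal still improves it and cohort 1 stays above a floor size
(`minCohort1`, default `max(10, ceiling(0.05 n))`). Ties break to the
lexicographically smallest sample id; an O(1)-per-candidate
sufficient-statistic fast path (`method = "downdate"`) matches the
from-scratch path to 1e-10.

**4. Survival comparison.** Kaplan–Meier curves and the two-group
log-rank test, (O₁ − E₁)²/V on 1 df, compare the two cohorts (or high vs
low expressers of a single gene, split at a configurable rank quantile).

A synthetic-data generator (planted correlated subpopulation, exponential
proportional-hazards survival, independent right-censoring) makes the
whole pipeline runnable and testable without external data. See the
methods vignette (`vignettes/coexSplit-methods.Rmd`) for parameter
rationale, numerical conventions, and known limitations — in particular
the floor-stopping behaviour of the greedy procedure.

## Worked example

Simulate a 120-sample cohort in which half the samples carry a planted
TP63–MMP13 correlation of 0.9 **and** a three-fold hazard; then recover
the subgroup and compare survival. Setting the floor to the planted size
(60) tells the greedy procedure when to stop:

```r
library(coexSplit)

cfg <- simConfig(nSamples = 120, hazardRatio = 3,
                 hazardGroup = "interaction", seed = 42)
d <- simulateDataset(cfg)
dim(d$exprs)
#> [1] 1002  120     # TP63, MMP13 and 1000 background probes

rk <- rankTransform(d$exprs)
a  <- extractProfile(rk, "TP63")
b  <- extractProfile(rk, "MMP13")
pearsonCor(a, b)
#> [1] 0.507         # full-cohort rank correlation

part <- greedySplit(a, b, minCohort1 = 60)
part
#> CohortPartition
#>   cohort 1 (interaction):    60 samples, r = 0.9797
#>   cohort 2 (no interaction): 60 samples (removal order)
#>   full-sample r = 0.5070, 60 removals accepted
#>   minCohort1 = 60, tol = 1e-12, method = recompute

cmp <- comparePartitionSurvival(part, d$surv)
cmp$logrank
#> Two-group log-rank test
#>   n = 60 vs 60, events = 50 vs 50
#>   chi-square = 7.3536 on 1 df, p = 0.006693

head(as.data.frame(cmp$km$cohort1), 4)
#>        time      surv n_risk n_event
#> 1 0.2268264 0.9830508     59       1
#> 2 0.2721095 0.9661017     58       1
#> 3 0.4709338 0.9491525     57       1
#> 4 0.5026931 0.9322034     56       1
```

The correlation-maximised cohort is significantly worse-surviving
(p ≈ 0.007), as planted. Note that with the *default* floor of 10 the
greedy procedure would shrink past the planted subgroup to a tiny,
near-perfectly-correlated core and lose most of this power — the floor is
the size prior; see the vignette.

The same analyses run end to end from files via the pipeline functions
(`runCoexpr`, `runMarkerSurvival`, `runInteractionSurvival`, each writing
TSV outputs plus a JSON manifest with seeds and checksums) or the CLI:

```sh
Rscript inst/scripts/coexsplit simulate --seed 42 --n 120 --out data/
Rscript inst/scripts/coexsplit interaction-survival \
  --matrix data/expression.tsv --surv data/survival.tsv \
  --gene-a TP63 --gene-b MMP13 --out results/
```

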