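---
title: "Methods: rank-based coexpression, greedy cohort splitting and survival comparison"
author: "coexSplit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-based coexpression, greedy cohort splitting and survival comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexSplit)
```

# The question the package addresses

A transcription factor and a candidate target gene (the motivating case is
the p53-family member p63 and the collagenase MMP13) may be coexpressed in
tumours, but coexpression alone does not establish that the regulatory axis
matters clinically. coexSplit operationalises one way of asking the clinical
question: partition a patient cohort into a subgroup in which the two genes'
expression covaries (the "interaction" cohort) and the remainder (the
"no-interaction" cohort), and test whether the two subgroups differ in
survival. If the axis drives outcome, the partition should separate the
survival curves; if it does not, the curves should be statistically
indistinguishable even though the partition, by construction, separates the
correlation.

The pipeline has four stages, each exposed as its own function and each
usable on its own.

# Stage 1: per-sample percentile ranks

Microarray (and RNA-seq) intensities from public series differ in platform
and normalisation. The pipeline therefore replaces each raw value by a
within-sample percentile rank on a 0--100 scale:

$$r_{ij} = 100 \cdot \frac{\#\{k : x_{kj} < x_{ij}\}}{N},$$

for probe $i$ in sample $j$ with $N$ probes per sample. A rank of 55 means
55 per cent of that sample's probes have strictly lower measured values.
Ranks need no cross-sample normalisation: any strictly increasing
distortion of one sample's values (scanner gain, log transformation)
leaves its ranks unchanged, which the test suite checks as an invariance
property.

Two conventions were open and are fixed as follows:

* **Tie policy.** The default (`strict_lower`) counts strictly smaller
  values, taking the defining sentence above literally, so a run of tied
  values shares the rank of its lowest member. Summarised array data can be
  heavy-tied, so a `midrank` alternative (ties centred on their
  mid-position) is available behind a flag. Untied data are unaffected by
  the choice.
* **Orientation.** Ranks ascend with expression (higher expression, higher
  rank), matching the definition; entries live in $[0, 100)$, and a sample
  whose values are all equal ranks everything 0 (nothing lies strictly
  below anything).
* **Stage order.** Ranking is computed over *all* probes of the loaded
  matrix, before any probe-to-gene collapsing, because the rank's
  denominator is "probes in the sample". The pipeline functions enforce
  rank-then-collapse.

A single-probe matrix is rejected: a percentile among one value is
meaningless.

# Stage 2: coexpression

Coexpression of two genes is the Pearson product-moment correlation of
their rank profiles across samples. Because the inputs are within-sample
ranks, this coefficient coincides with the Spearman correlation of the raw
profiles whenever ties are absent (a cross-check in the test suite). A
correlation is only reported for at least 3 samples and non-constant
profiles; degenerate requests raise errors rather than returning `NaN`, so
no downstream stage can silently consume an undefined value. Correlating
raw values instead of ranks is possible behind an explicit flag but is not
the pipeline's convention.

# Stage 3: the greedy cohort split

The core procedure. Starting with every sample in cohort 1:

1. compute the correlation $r$ of the two profiles over cohort 1;
2. for every current member, compute the correlation the cohort would have
   without that member (leave-one-out);
3. move the member whose removal *increases* the correlation the most to
   cohort 2, provided the increase exceeds a tolerance;
4. repeat until no single removal increases the correlation, or cohort 1
   has shrunk to a floor size.

Parameters, with defaults and rationale:

* `tol = 1e-12` — "increase" means an improvement beyond floating-point
  noise; prevents livelock on ties at machine precision.
* `minCohort1 = max(10, ceiling(0.05 n))` — a floor on the retained cohort.
  Correlations over a handful of samples are noise; the floor also bounds
  the number of iterations at $n - \texttt{minCohort1}$.
* Tie-break: when several members share the maximal increase, the
  lexicographically smallest sample id moves. This makes the procedure
  fully deterministic, which the suite verifies.
* `method = "recompute"` re-derives every candidate correlation from
  scratch ($O(k)$ per candidate). `method = "downdate"` subtracts the
  candidate from the cohort's sufficient statistics
  ($\sum x, \sum y, \sum x^2, \sum y^2, \sum xy$) and evaluates each
  candidate in $O(1)$; the two paths are algebraically identical and the
  suite requires their traces to agree to $10^{-10}$. The fast path makes
  Monte-Carlo studies of the whole pipeline cheap.

Cohort 2 is purely the removed complement, in removal order; no second
objective is optimised on it. The recorded correlation trace is strictly
increasing after its first entry by construction, and the class validity
check enforces this.

## A structural property worth knowing

On continuous data the maximal leave-one-out increase is almost always
positive while $r < 1$: some sample always sits slightly off the current
regression cloud. In practice the procedure therefore rarely stops of its
own accord and instead runs down to the `minCohort1` floor with a cohort-1
correlation near 1. Two consequences matter for interpretation:

* The *size* of the interaction cohort is effectively governed by
  `minCohort1`, not discovered from the data. Users who want a
  size-$k$ interaction cohort should set the floor to $k$.
* When a correlated subpopulation of known size is planted in synthetic
  data, the floored partition retains only a small, strongly-correlated
  core of it. Overall membership agreement with the planted labels is
  therefore modest — and it is limited even in principle, because a single
  bivariate observation carries only limited evidence about whether it was
  drawn from the correlated or the uncorrelated component. The acceptance
  script measures this agreement (`planted_recovery_accuracy`) together
  with the guaranteed qualitative property that the final cohort-1
  correlation exceeds the full-cohort correlation in every run.

The null behaviour, by contrast, is clean: when survival is generated
independently of expression, the greedy selection — a function of
expression alone — cannot leak into survival, and the log-rank comparison
of the two cohorts stays calibrated. The acceptance script verifies this
rejection rate over 500 replicates.

# Stage 4: survival comparison

Kaplan--Meier estimation and the two-group log-rank (Mantel--Cox) test are
computed through the `survival` package behind validated wrappers.

* The product-limit estimator $S(t) = \prod_{t_i \le t} (1 - d_i / n_i)$
  is tabulated at distinct event times; censored records enter risk sets
  only, and an event tied with a censoring at the same time is resolved
  event-first (standard convention). With no censoring the curve equals
  one minus the empirical CDF, which the suite checks exactly.
* The log-rank statistic is $(O_1 - E_1)^2 / V$ on 1 df with the usual
  hypergeometric variance including the tie correction. Two groups with
  identical survival data give a statistic of exactly 0; a comparison with
  zero variance and $O_1 = E_1$ is defined as statistic 0, $p = 1$; zero
  events overall is an error. The survival test applied throughout is this
  two-sided two-group test — the standard companion of KM curves in R.
* The single-marker mode ("high" vs "low" expressers) dichotomises at a
  configurable quantile of the gene's rank values, defaulting to the
  median — the most common convention where no threshold is prescribed.
  A cutoff that empties either group is an error suggesting a different
  quantile.

# The synthetic-data generator

`simulateDataset()` emulates the statistical structure the analysis
assumes, not any particular platform:

* a focal gene pair drawn bivariate-normal via the Cholesky construction,
  with correlation `rhoIn` inside a planted subpopulation of exactly
  $\lfloor f \cdot n\rfloor$ samples and `rhoOut` outside (defaults 0.9,
  0, $f = 0.5$, $n = 200$ — the package's reference mixture condition);
* independent Gaussian background probes (default 1000). The background
  size matters more than it may appear: ranks computed over $N$ probes
  carry binomial resolution noise of order $100\sqrt{p(1-p)/N}$ rank
  points, about 5 points at $N \approx 100$ but under 2 at $N = 1000$.
  Real arrays have tens of thousands of probes; 1000 keeps the rank noise
  realistically small at desk scale.
* exponential event times with hazard
  $\lambda = \texttt{baselineHazard} \cdot \texttt{hazardRatio}^{\text{flag}}$,
  where the flag can mark nobody, the planted members, or above-median
  expressers of gene A. The default baseline $\ln 2 / 12$ gives a median
  survival of 12 time units (months, read as an aggressive cancer cohort);
  independent exponential censoring at $\ln 2 / 24$ censors roughly one
  third of subjects under the baseline — a typical follow-up pattern.
* determinism: every stage derives its own sub-seed from the global seed,
  so a configuration reproduces its dataset bit for bit regardless of how
  other stages evolve.

What the generator deliberately does **not** emulate: probe- and
batch-effects, platform-specific intensity distributions, dependent
censoring, non-proportional hazards, and correlation structure among
background probes. Tests passing on this generator therefore demonstrate
the pipeline's statistical and algorithmic correctness under its stated
model, not robustness to real-array artefacts.

# Evaluation scales

The package's own evaluations (test suite and acceptance script) use:
100 random samples of up to 500 probes for rank exactness; 50 random
datasets of 8--200 samples for greedy step-optimality; 20 replicates of
the $n = 200$ reference mixture for recovery; 1000 replicates at
$n = 100$ per group for log-rank calibration; 500 replicates of the full
pipeline for the selection-bias null; and 20 replicates at $n = 300$ for
the marker-survival positive control. These sizes give Monte-Carlo
standard errors comfortably below the property margins being asserted.

# Known limitations

* The greedy split is a heuristic: it is step-optimal, not globally
  optimal, and no significance is attached to the achieved cohort-1
  correlation (selecting samples to maximise a correlation inflates it by
  construction).
* Because of the floor-stopping behaviour discussed above, the
  interaction/no-interaction comparison has low power to detect a hazard
  difference carried by a *large* planted subpopulation when the floor is
  far below the subpopulation's size: the retained cohort is then a small,
  purity-limited core and the two cohorts differ little in composition.
  The acceptance script reports this honestly
  (`interaction_power_hr3`) alongside the well-powered single-marker
  positive control (`marker_survival_power_hr3`).
* No multivariable adjustment, competing risks or proportional-hazards
  modelling; the survival layer is deliberately limited to KM + log-rank.
* No GEO/Oncomine client and no array preprocessing: inputs are plain TSV
  matrices and tables.
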