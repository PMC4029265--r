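---
title: "Methylator-phenotype clustering and marker-panel validation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylator-phenotype clustering and marker-panel validation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cimpanel` discovers CpG-island-methylator phenotypes (CIMP) in a tumor
cohort from genome-scale methylation, extracts a concordant
methylation–expression marker panel, and quantifies how much of that result
could be luck. This vignette documents the model, the tunable parameters,
the numerical choices, and what the bundled synthetic generator does and
does not emulate.

## Inputs and harmonization

Three tables are required: a beta-value matrix (values in [0, 1]; probes or
genes × samples on disk, TCGA level-3 style), a gene-expression matrix
(assumed log-like scale — the package deliberately does not transform
expression, because input scale conventions vary and silent re-scaling is
worse than a documented assumption), and a clinical table with survival
months and a 0/1 event indicator. Orientation on disk is an explicit flag
(`features_in_rows` default), never auto-detected, so parsing is
deterministic.

Probe-level methylation is collapsed to genes by the unweighted mean of
non-missing probe values (`aggregate_probes_to_genes()`); duplicate
expression rows for one symbol are collapsed the same way, for symmetry.
Features missing in more than 20 % of samples are dropped and the remaining
gaps are filled with the per-feature median (`impute_missing()`): the median
keeps imputed values inside [0, 1] and is robust to the skewed, bimodal
distributions beta values typically show. When a gene panel is supplied
(e.g. a stem-cell-associated gene set), both matrices are restricted to it
*after* probe aggregation — a panel is a set of gene symbols and cannot
address probe identifiers.

## Clustering model

Samples are observations; the metric is plain Euclidean distance on raw
beta values. Beta values are already bounded and on a common scale, so no
per-feature standardization is applied — standardizing would up-weight
near-constant probes, the opposite of what a methylator phenotype analysis
wants.

`kmeans_cluster()` is Lloyd's algorithm with k-means++ seeding, run
`n_restarts = 20` times (default) and keeping the lowest within-cluster sum
of squares. Convergence is declared when assignments stop changing, capped
at 300 iterations; an empty cluster is re-seeded with the point farthest
from its current centroid. The per-iteration WSS trace is retained and is
non-increasing, which the test suite asserts; on instances small enough to
enumerate every 2-partition the implementation attains the global optimum.
All randomness flows from one integer seed, so a fixed seed reproduces
labels and centroids exactly.

`k` defaults to 2 — the analysis contrasts the extreme phenotypes. For
`k > 2` the cluster with the highest centroid mean beta is CIMP-positive,
the lowest CIMP-negative, and intermediates are excluded from the two-group
analyses. An exact tie of centroid means (possible only on contrived data)
labels the larger cluster negative, with a warning — the conservative choice,
since CIMP-positive groups are typically the minority.

## Marker filter

With `Δβ` and `Δe` the positive-minus-negative differences of per-phenotype
means, the panel is the union of `Δβ ≥ δ_β & Δe ≤ −δ_e` (hypermethylated,
down-regulated) and `Δβ ≤ −δ_β & Δe ≥ δ_e` (hypomethylated, up-regulated).
Defaults: `δ_β = 0.1` — a conventional floor below which a methylation
difference is rarely biologically meaningful — and `δ_e = 0`, i.e. strict
sign concordance. Both are exposed because the appropriate expression floor
depends entirely on the platform's scale. This is an effect-size screen, not
a per-gene hypothesis test: no multiple-testing correction applies, and the
resampling nulls below are the significance machinery. The filter is
monotone in both thresholds and invariant to gene order; ties at exactly
zero in both deltas satisfy both direction rules and are excluded.

## Survival analysis

The Kaplan–Meier estimator, the two-group log-rank test and the univariate
Cox model are implemented in the package (and cross-checked against the
`survival` package and brute-force oracles in the tests, where it is a
Suggests-only dependency). Choices:

- **Ties**: Breslow handling in the Cox partial likelihood — the simplest
  standard option; censored observations tied with an event time remain at
  risk at that time.
- **Estimation**: Newton–Raphson on the single coefficient with
  step-halving; the partial log-likelihood is concave, so halving guarantees
  monotone ascent. Non-convergence in 100 iterations is an error; a monotone
  likelihood (complete separation of event orderings, or a coefficient
  running past ±15) is reported with an `infinite_hr` flag instead of a
  crash.
- **Tests**: the Wald chi-square on the fitted coefficient and the score
  test at zero are both reported. On tie-free data the score test equals the
  log-rank statistic algebraically; the suite asserts this to 1e-10. The
  log-rank test itself uses the hypergeometric variance with the
  `(n−d)/(n−1)` correction, so with ties it differs from the Breslow score
  variance — both are reported, labeled. All p-values are two-sided.

## Resampling validation

**Bootstrap stability** asks whether the clustering-gene/phenotype
relationship survives perturbation of the cohort: each of (default) 1,000
iterations resamples patients with replacement, re-clusters on the original
clustering genes (k = 2), aligns bootstrap labels to the original phenotypes
by the permutation maximizing agreement, and records the *sensitivity* —
the fraction of draws whose label matches. Alignment makes 0.5 the logical
floor. The summary p-value is the add-one-smoothed fraction of iterations
with sensitivity at or below the *chance level*, defined as the larger
original phenotype proportion. The raw per-iteration sensitivities are
always returned, so users preferring a different summary can compute it.

**The random-gene null** asks whether a same-sized random panel separates
survival as well as the discovered one: each iteration draws `panel_size`
genes uniformly from the universe, re-clusters, extreme-labels, and records
the log-rank chi-square; the empirical p is
`(1 + #{null ≥ observed}) / (iterations + 1)`, larger chi-square = more
extreme. Add-one smoothing means no empirical p can be zero: claiming
`p < 0.0001` requires at least 10,000 iterations.

One behavior worth understanding: when the gene universe is small and
saturated with strong markers — as in compact synthetic cohorts — random
panels frequently include enough markers to recover the phenotype, and the
null distribution shifts toward the observed statistic, making this p-value
conservative. On genome-scale universes (thousands of genes, tens of
markers) the contamination is mild. This is a property of the null's design
(drawing from the same universe the predictor came from), not an
implementation artifact.

Both procedures are bit-reproducible given `(seed, iterations)`; inside the
resampling loops k-means uses 5 restarts by default (`validation_restarts`),
a deliberate economy — the resampled problems are re-fits of an
already-identified structure, not fresh searches.

## Synthetic cohorts

`simulate_cohort()` plants known truth so that recovery is checkable.
Methylation is Beta-distributed per gene with mean `μ_g` (background genes:
uniform in [0.1, 0.6], shared across phenotypes; markers: shifted by
`+delta_beta` in the positive phenotype, clipped to [0.02, 0.98]) and common
precision `base_beta_dispersion = 50` — at a typical `μ ≈ 0.35` that gives a
per-probe SD of about 0.067, in the range of Infinium array noise. Marker
expression drops by `delta_expr` intensity units (default 2, on a baseline
of N(8, 1.5²) with N(0, 1) residual noise) in the positive phenotype; an
optional tranche of discordant decoys (hypermethylated but *up*-regulated)
exercises the filter's rejection side. Survival is exponential with mean
`baseline_scale_months = 60` in the negative phenotype and the hazard
multiplied by `hazard_ratio` in the positive one; censoring is
administrative-uniform with the upper bound solved numerically so the
expected censored fraction equals `censoring_rate` (default 0.2) —
non-informative by construction. Defaults (200 samples, 500 genes, 30
markers, 30 % positive, `delta_beta = 0.3`, hazard ratio 2) describe a
mid-sized cohort with a clearly established methylator phenotype.

What the generator does *not* emulate: probe-level spatial correlation
within CpG islands, copy-number confounding of both data types, batch
effects, informative censoring, and continuous (rather than two-state)
methylation gradients. Passing the planted-truth tests therefore
demonstrates correctness of the machinery, not that real cohorts will yield
panels this clean — on real data the phenotype boundary is softer and
bootstrap sensitivities well below 1 are normal.

## Pipeline, determinism and problem sizes

`run_pipeline()` executes read/align → aggregation → panel restriction →
imputation → clustering + labeling → cluster means → filter → survival
tests → bootstrap → random-gene null, with any stage failure reported under
the stage's name. The config's one seed derives per-stage seeds
arithmetically, so changing (say) the bootstrap iteration count cannot
perturb the clustering. Reports carry no timestamps and omit the output
directory from their own echo, so a fixed config yields byte-identical
output files — asserted in the tests.

The test suite and the acceptance script run on deliberately compact
problems — cohorts of 50–400 samples, 20–500 genes, 50–500 resampling
iterations — sized so the full suite completes in about a minute while
still exercising every contract at cohort scale (the planted-truth
recovery check uses 400 samples × 500 genes). Statistical checks
(null calibration of the log-rank level over 50 seeded runs,
Kolmogorov–Smirnov uniformity of the random-test p-values, hazard-ratio
recovery within 3 standard errors) use fixed seeds: they are exact
re-runs, not flaky Monte-Carlo.

## Known limitations

- Only right censoring; no multivariate Cox adjustment for clinical
  covariates, no proportional-hazards diagnostics.
- The filter compares means; a phenotype defined by a variance difference
  would pass through it silently.
- k-means with Euclidean distance assumes roughly isotropic clusters in
  beta space; strongly elongated methylation gradients may be split
  arbitrarily.
- The random-gene null draws from the analysis universe including the
  discovered markers (see above); excluding them is a stricter variant the
  user can request via `gene_universe`.
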