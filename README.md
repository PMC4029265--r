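# cimpanel

Mining and validating prognostic DNA methylation marker panels.

Aberrant CpG-island methylation is a hallmark of many tumors, and subsets of
patients often display a *CpG island methylator phenotype* (CIMP): concerted
hypermethylation across many loci, frequently with distinct clinical outcome.
`cimpanel` is for researchers who have, for one cohort, (a) a genome-scale
methylation beta-value matrix, (b) a matched gene-expression matrix and
(c) clinical follow-up, and who want to

1. **cluster** patients into methylation phenotypes,
2. **extract** a candidate marker panel — genes whose methylation and
   expression differences between phenotypes are *concordant*
   (hypermethylated & down-regulated, or hypomethylated & up-regulated), and
3. **validate** that panel against survival and against resampling nulls.

## The method

Let `B` (samples × genes, beta values in [0, 1]) and `E` (samples × genes,
log-scale intensities) be the harmonized matrices. The pipeline:

- **Clustering.** k-means (Lloyd's algorithm, k-means++ initialization,
  best of `n_restarts` runs) partitions samples on `B`; the cluster with the
  highest centroid mean beta is labeled CIMP-positive, the lowest
  CIMP-negative.
- **Marker filter.** With per-phenotype means `m⁺_g, m⁻_g` (methylation) and
  `e⁺_g, e⁻_g` (expression), write `Δβ_g = m⁺_g − m⁻_g` and
  `Δe_g = e⁺_g − e⁻_g`. The panel is
  `{g : Δβ_g ≥ δ_β and Δe_g ≤ −δ_e}` (hyper/down) ∪
  `{g : Δβ_g ≤ −δ_β and Δe_g ≥ δ_e}` (hypo/up), default `δ_β = 0.1`,
  `δ_e = 0`.
- **Survival.** Kaplan–Meier curves per phenotype; the two-group log-rank
  statistic `(Σ(O−E))² / ΣV` with the hypergeometric variance; and a
  univariate Cox proportional-hazards fit of the binary phenotype
  (Newton–Raphson on the Breslow partial likelihood), reporting the hazard
  ratio with Wald and score tests. All three are implemented in the package
  and oracle-verified in the test suite.
- **Bootstrap stability.** Patients are resampled with replacement
  (default 1,000 iterations), re-clustered on the original clustering genes,
  and the per-iteration *sensitivity* (label agreement after optimal
  alignment) is compared with the chance level.
- **Random-gene null.** Panels of the observed size are drawn uniformly from
  the gene universe, re-clustered and survival-tested; the panel's log-rank
  statistic gets an add-one-smoothed empirical p-value.

A synthetic-cohort generator with planted phenotypes, marker effects and a
true hazard ratio makes every stage testable end to end.

## Worked example

```r
library(cimpanel)
options(cimpanel.verbose = FALSE)

cohort <- simulate_cohort(n_samples = 200, n_genes = 300, n_markers = 25,
                          delta_beta = 0.3, delta_expr = 2, hazard_ratio = 2,
                          seed = 20)
config <- run_config(cohort$beta, cohort$expression, cohort$clinical,
                     seed = 101, bootstrap_iterations = 200,
                     random_test_iterations = 200)
report <- run_pipeline(config)
print(report)
```

```
== CIMP marker-panel pipeline report ==
seed: 101 | k: 2 | package: cimpanel 0.1.0
phenotype sizes: CIMP_negative = 140, CIMP_positive = 60
predictor panel: 25 gene(s)
  G0159, G0116, G0096, G0003, G0018, G0228, G0205, G0113, G0229, G0199, ...
log-rank test: chi-square = 16.67 (1 df), p = 4.448e-05
  n per group: CIMP_negative = 140, CIMP_positive = 60
Cox PH (CIMP_positive vs CIMP_negative): HR = 2.006, Wald chi-square = 16.06, p = 6.15e-05
  score test at 0: chi-square = 16.67, p = 4.448e-05
  n per group: CIMP_negative = 140, CIMP_positive = 60
bootstrap stability: 200 iteration(s), mean sensitivity = 1.000 (chance level 0.700), empirical p = 0.004975
random-gene test: 200 panel(s) of 25 gene(s); observed chi-square = 16.67, empirical p = 0.7114
```

Reading this: the 200 simulated patients split 140/60 into the two
methylation phenotypes (exactly the planted split — the adjusted Rand index
against truth is 1.0); the concordance filter returns exactly the 25 planted
marker genes; the CIMP-positive phenotype has about twice the death hazard
(HR = 2.006, true value 2), significant by both tests; every bootstrap
resample reproduces the phenotype labels perfectly (sensitivity 1.0). The
random-gene empirical p is *not* small here because random panels are drawn
from a 300-gene universe that still contains the 25 strong markers, so many
"null" panels also separate survival — see the vignette for why this is the
expected behavior of that null on saturated synthetic data.

## Command line

A thin CLI over the same functions ships in `inst/cli/cimpanel`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "cimpanel", package = "cimpanel"))')
$CLI simulate --out-dir cohort/ --n-samples 200 --n-genes 300 --seed 20
$CLI run --config config.yaml
```

Subcommands: `simulate`, `cluster`, `filter`, `survival`, `bootstrap`,
`randomtest`, `run` (YAML config, any key overridable by a flag).

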