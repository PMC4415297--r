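# subtypeCox

Feature selection for **histology-subtype-specific prognostic genes** in
non-small cell lung cancer (NSCLC) expression studies, built around a
per-gene Cox proportional-hazards filter with a subtype × expression
interaction. It is aimed at biostatisticians and computational biologists
screening microarray or RNA-seq cohorts that mix the two major NSCLC
subtypes — adenocarcinoma (AC) and squamous cell carcinoma (SCC) — for
genes whose association with survival differs between the subtypes.

## The model

For patient *i* with subtype indicator *I(SCC)* and expression value
*x<sub>g</sub>* of gene *g*, each gene is screened with its own Cox model

&nbsp;&nbsp;&nbsp;&nbsp;λ<sub>ig</sub>(t) = λ<sub>0g</sub>(t) ·
exp( β<sub>1g</sub> I(SCC) + β<sub>2g</sub> x<sub>ig</sub> +
β<sub>3g</sub> I(SCC) · x<sub>ig</sub> )

so β<sub>2g</sub> is the gene's log-hazard effect in AC and
β<sub>2g</sub> + β<sub>3g</sub> its effect in SCC. Wald tests of the two
contrasts give a p-value per subtype family; each family is corrected by
Benjamini–Hochberg across genes, and genes are labelled `AC_specific`,
`SCC_specific`, `shared_concordant`, `shared_discordant`, or `none`.
Schoenfeld-residual score tests check the proportional-hazards assumption
per gene.

Around the filter the package provides the full analysis pipeline:

* **Pre-filters** — standard-deviation filter, empirical-Bayes moderated-t
  differential expression between subtypes (FDR-controlled), probe-set
  collapse by largest fold change, and an expression-barcode frequency
  filter that protects the Cox fits from complete separation.
* **Expression barcode** — per-gene dichotomization into expressed (1) /
  silenced (0) calls via a hierarchical normal (silenced) / uniform
  (expressed) mixture fitted by EM with empirical-Bayes shrinkage, calls by
  the tail rule Φ(−(y−μ)/τ) < C.
* **Risk scores** — a multivariable Cox model on the signature genes, or a
  principal-component variant retaining the fewest PCs explaining ≥ 95% of
  the signature variance; mean-cutoff stratification into low/high risk;
  evaluation by accuracy, Mann–Whitney AUC per subtype, Kaplan–Meier curves
  and log-rank tests; likelihood-ratio tests for clinical-covariate
  adjustment.
* **Simulation** — a Cox-exponential survival simulator (unit exponential
  baseline, inverse-transform event times, censoring calibrated to a target
  rate) with presets for the two extreme designs — mutually exclusive
  subtype markers, and fully shared markers — and a harness that tabulates
  per-gene selection frequencies across replicates.

The survival-statistics engine (Newton–Raphson partial-likelihood fitting
with Efron/Breslow ties, Wald contrasts, Schoenfeld diagnostics, log-rank,
Kaplan–Meier, likelihood-ratio tests) is self-contained, with the Cox core
in C++ so that per-gene screening over hundreds of simulated cohorts runs
in seconds.

## Worked example

Screen one simulated cohort (127 AC / 42 SCC samples, 100 genes, 30%
censoring) generated under the mutually-exclusive-marker design, where
gene 1 carries a strong SCC-only effect (true coefficient 1.42):

```r
library(subtypeCox)

spec    <- preset_extreme_cases("case1", seed = 7)
expr    <- make_covariates(spec, seed = 7)
surv    <- simulate_survival(spec, expr, seed = 8)

records <- fit_gene_models(expr, surv)                 # per-gene Eq. above
records <- classify_scenarios(records, alpha = 0.05)
head(records[order(records$q_scc),
             c("gene_id", "beta_ac", "beta_scc", "q_ac", "q_scc", "scenario")])
#>    gene_id      beta_ac   beta_scc      q_ac        q_scc     scenario
#> 1   gene_1 -0.092575676  1.4826109 0.9741917 7.989088e-07 SCC_specific
#> 89 gene_89  0.203156005  0.8195087 0.6405015 3.248206e-05 SCC_specific
#> 17 gene_17  0.077208491 -1.0656927 0.9741917 3.311127e-04 SCC_specific
```

The causal gene tops the SCC family with its coefficient recovered
(1.48 vs. 1.42 truth) while its AC contrast stays null — the pattern the
filter is designed to isolate. A handful of noise genes ride along at the
0.05 FDR, matching the filter's known false-positive behaviour.

```r
sig    <- select_signature(records)
#> signature: 0 AC-specific, 11 SCC-specific, 0 shared
genes  <- union(sig$ac_all, sig$scc_all)
model  <- build_risk_model(expr, surv, genes, method = "pca")
scores <- compute_risk_scores(model, expr)
strata <- stratify_by_mean(scores, cutoff = model$cutoff)
evaluate_stratification(scores, strata, surv)
#> accuracy (%): all 59.2  AC 54.3  SCC 73.8
#> AUC (%):      all 69.8  AC 60.9  SCC 90.7
#> log-rank:     chisq = 32.619 , p = 1.12e-08
```

The SCC-specific signature stratifies SCC survival sharply (AUC 90.7%)
and, as expected, adds little in AC. A command-line front end with
`filter`, `barcode`, `risk`, `evaluate`, `simulate`, `sweep` and
`pipeline` subcommands lives at `inst/cli/subtypecox.R`.

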