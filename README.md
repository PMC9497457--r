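# m6aPatterns

Molecular-pattern discovery, diagnostic modelling and immune profiling
for RNA-methylation (m6A/m5C) regulator genes in case/control
transcriptome cohorts.

## What problem this solves

Epitranscriptomic marks — N6-methyladenosine (m6A) and 5-methylcytosine
(m5C) — are written, erased and read by a few dozen regulator genes whose
expression reshapes immune behavior in inflammatory disease. A recurring
bulk-transcriptomics design asks, for a merged multi-batch case/control
cohort:

1. Which regulators are differentially expressed, and can a small panel
   of them diagnose the disease?
2. Do cases split into distinct regulator-driven molecular patterns, and
   how do those patterns differ in immune-cell infiltration, immune
   reactions and HLA expression?
3. Which lncRNAs track the regulators of both marks, and do they define
   concordant patient clusters?
4. Can each patient's methylation state be summarized in one score?

m6aPatterns implements that entire analysis as a reusable, seeded, tested
R package, aimed at computational biologists who want the machinery
without re-deriving it: empirical-Bayes batch correction, rank-based
differential testing, a univariate-logistic + LASSO (10-fold CV)
diagnostic model with ROC/AUC (DeLong CI) and Hosmer–Lemeshow
calibration, consensus clustering with PAC-based selection of the cluster
number K, ssGSEA/GSVA sample-wise enrichment, correlation-threshold
lncRNA selection (|r| > 0.4, p < 0.001), WGCNA-style co-expression
modules, and the PCA score

> score(s) = PC1(s) + PC2(s)

over the pattern-related genes, split into high/low groups. A synthetic
cohort generator with planted ground truth (case effects, patterns,
linked lncRNAs, batch effects) makes the whole pipeline testable with no
external data, and ships the transcribed regulator catalogs (26 m6A
regulators: 9 writers / 3 erasers / 14 readers; 14 m5C regulators:
10 / 3 / 1) and published diagnostic signatures (14 regulators,
8 lncRNAs).

## Worked example

```r
library(m6aPatterns)

cfg <- simulation_config(n_cases = 90, n_controls = 60, n_batches = 3,
                         n_genes = 600, n_lncrnas = 60, seed = 7)
cohort <- simulate_cohort(cfg)
expr   <- correct_batches(cohort$expression, cohort$annotation)
regs   <- intersect(regulator_catalog("m6A")$gene, rownames(expr))

# two-stage diagnostic model on the 26-regulator panel
model <- build_diagnostic_model(expr, cohort$annotation$group, regs, seed = 7)
print(model)
#> Diagnostic logistic model: 12 features
#>   AUC 1.000 (95% CI 1.000-1.000); C-index 1.000

# consensus clustering of cases with PAC-selected K
cases    <- cohort$annotation$sample_id[cohort$annotation$group == "case"]
patterns <- select_k_and_label(expr[regs, cases], K_range = 2:5,
                               n_reps = 200, seed = 7)
print(patterns)
#> Consensus clustering over K = 2, 3, 4, 5
#>   PAC: K2=0.674  K3=0.000  K4=0.205  K5=0.280
#>   chosen K = 3
#>   cluster sizes: A:30  B:30  C:30

# per-sample methylation score and group comparison
score <- split_by_score(compute_m6ascore(expr[, cases], regs))
cmp   <- compare_scores_across(patterns$labels[cases], score)
cmp$omnibus$p_value
#> m6Ascore omnibus Kruskal-Wallis p = 6.89e-18
head(score, 3)
#>   sample_id        pc1       pc2     score score_group
#> 1  case_001  0.6839462  2.647709  3.331655        high
#> 2  case_002  0.9414746  3.210728  4.152203        high
#> 3  case_003 -3.2234350 -2.330189 -5.553624         low
```

Reading the output: the generator planted 10 diagnostic regulators and
three case patterns; the LASSO stage kept a 12-feature panel that
separates cases from controls perfectly on this synthetic cohort, PAC is
minimized (0) exactly at the planted K = 3 — K = 2 is highly ambiguous
(0.674) because the three groups cannot merge stably — and the
methylation score differs strongly across the recovered patterns.

The full pipeline (simulate → batch-correct → diagnose → cluster →
enrich → lncRNA → modules → score, with TSV/GMT/JSON outputs and a
checksummed run manifest) is one call:

```r
run_pipeline(default_pipeline_config(seed = 42), outdir = "out")
```

A thin command-line wrapper lives at `inst/scripts/m6apat.R`.

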