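---
title: "Methods: regulator-mediated molecular patterns, diagnostic models and immune profiling"
author: "m6aPatterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regulator-mediated molecular patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model of the data

m6aPatterns reimplements, as a tested pipeline, the analysis strategy used
to dissect epitranscriptomic (m6A/m5C) regulator biology in case/control
transcriptome cohorts: merge multi-batch expression data, remove batch
effects, test regulators for differential expression, build a penalized
diagnostic model, cluster cases into molecular "patterns" on regulator
expression, profile the immune microenvironment of those patterns with
sample-wise gene-set scores, select regulator-linked lncRNAs by
correlation, detect co-expression modules, and summarize each sample with
a PCA-derived methylation score.

All expression is modelled on the log2 scale. The statistical assumptions
throughout are those of post-RMA microarray data: approximately Gaussian
per-gene noise, batch effects that act additively on the mean and
multiplicatively on the residual scale, and rank-based tests wherever a
distributional assumption would be doubtful.

## The synthetic cohort generator

Because the original multi-cohort data cannot be redistributed, the
package ships a first-class generator (`simulation_config()`,
`simulate_cohort()`) whose defaults emulate the merged study design:

* 196 cases and 89 controls pooled from 5 batches;
* 26 m6A regulator genes (named from the packaged catalog), of which
  `n_diagnostic = 10` carry a uniform case/control shift of
  `case_effect = 1.5` log2 units — the regime in which penalized feature
  selection is challenged but solvable;
* 3 latent case subgroups ("patterns"), each elevating a disjoint block of
  the remaining regulators by `pattern_effect = 2`;
* per-pattern blocks of 25 background genes elevated the same way, which
  seed the synthetic immune gene sets (`make_fixture_genesets()`);
* 200 lncRNAs, half of them linked to a regulator as
  `lnc = r * z(regulator) + sqrt(1 - r^2) * noise` with `r = 0.6`, which
  hits the target correlation exactly in expectation;
* residual noise `noise_sd = 0.5`, batch offsets drawn per gene and batch
  with SD 0.5, and residual scales `exp(N(0, 0.1))`.

When the regulator panel is the full 26-gene catalog the generator also
plants the 14 m5C regulator genes, each co-expressed with a paired m6A
regulator at r of about 0.8. Linked lncRNAs therefore correlate with both
marks (at about 0.6 and 0.48), while lncRNAs linked to an unpaired m6A
regulator fail the m5C threshold — so the m6A-related, m5C-related and
overlap lncRNA sets have the nested structure the downstream intersection
analysis expects, without a separate dial for it.

Controls carry no pattern label and all clustering stages run on cases
only. Pattern sizes are balanced by design; the generator makes no attempt
to reproduce the skewed cluster sizes seen in real cohorts, and its
Gaussian noise has none of the heavy tails, probe-level artifacts or
missingness of real arrays. Passing tests therefore certify the
*algorithms* (recovery of planted structure under realistic effect sizes),
not performance on any particular real dataset.

## Batch correction

`correct_batches()` implements the parametric empirical-Bayes
location/scale adjustment: standardize each gene by its grand mean and
pooled batch-residual variance, estimate per-batch location and scale on
the standardized scale, shrink both toward method-of-moments priors
(normal for location, inverse-gamma for scale), adjust, and back-transform
with each gene's grand mean restored exactly. No biological covariate is
protected, matching the cited algorithm's default use with batch as the
only known factor. The implementation agrees with `sva::ComBat` to about
3e-4 mean absolute difference on planted-offset data (cross-checked in the
test suite).

Two properties are worth knowing. First, shrinkage means the correction is
only near-complete when batch offsets vary from gene to gene — with an
offset that is exactly constant across genes, about half of each gene's
sampling deviation survives; this is inherent to the EB model, not an
implementation artifact. Second, because (shrunken) realized batch means
are subtracted, the post-correction between-batch variance is deflated:
an ANOVA of corrected expression against batch gives F well below 1, and
rejections at or below the nominal rate. Tests assert exactly those
directions.

## Differential testing and multiplicity

Two-group comparisons use the Mann-Whitney test (exact enumeration when
both groups have at most 8 tie-free observations, otherwise the normal
approximation with midranks and continuity correction); three or more
groups use Kruskal-Wallis. Genome-wide differential expression uses
limma's moderated t with the conventional double filter |log2FC| > 1 and
BH-adjusted p < 0.05; log2FC is the difference of group means on the log2
matrix. "Adjusted p" means Benjamini-Hochberg everywhere, applied within
one named family per call. Note that the BH step-up transform is not
idempotent — re-adjusting adjusted values changes them — so adjusted
values are computed exactly once per family.

## The diagnostic model

The two-stage screen mirrors the published design: a univariate logistic
filter (Wald p < 0.05 per feature; features showing separation are kept
and flagged), then an L1-penalized logistic regression with
class-stratified 10-fold cross-validation on binomial deviance (glmnet;
100-value lambda grid). The selection rule is `lambda.min`: the published
panel retained 14 of 24 screened regulators, which is lambda.min-like
behavior, and the 1-SE rule is exposed as an option. The surviving
features enter an unpenalized logistic fit reported as odds ratios
exp(beta) with Wald 95% CIs, in-sample ROC/AUC with a DeLong CI (pROC),
the concordance index (identical to AUC for a binary outcome), and a
Hosmer-Lemeshow calibration test. The Hosmer-Lemeshow statistic is
referred to chi-square on g - 2 degrees of freedom, which presumes the
probabilities come from a model fitted to the same data; feeding it true
(unfitted) probabilities makes it anticonservative by construction.
External validation applies frozen coefficients with no refitting.

## Consensus clustering and the number of patterns

Cases are clustered on regulator expression by Monti-style consensus:
repeatedly subsample 80% of samples, partition into K groups, and record
for every pair the fraction of co-sampled runs in which it co-clustered.
K is chosen to minimize the proportion of ambiguously clustered pairs
(PAC), the empirical CDF mass of consensus values in (0.1, 0.9], with
ties broken toward smaller K; final labels come from average-linkage
hierarchical clustering of 1 - consensus. When even the best PAC exceeds
0.5 the result is flagged low-confidence.

The inner clusterer is k-means with two random restarts per replicate.
This was a deliberate design decision after measurement: with a
deterministic inner clusterer (subsampled hierarchical clustering on
correlation distance), pairwise distances are unchanged by subsampling,
so a wrong K that merges two well-separated groups is exactly as stable
as the true K and PAC cannot tell them apart. K-means restart
variability is what makes the consensus informative — at the true K all
restarts agree, at a wrong K equally good local optima alternate. The
hierarchical variant is retained as `method = "hc"` for comparability.
On the generator's default conditions the k-means consensus selects the
planted K = 3 with PAC 0 and recovers labels essentially perfectly; the
test suite checks this across seeds.

## Sample-wise enrichment

`ssgsea_scores()` implements the integrated weighted KS walk: per sample,
genes are ranked by expression (midranks for ties) and the score is the
sum of the running difference between the in-set CDF (weights
rank^alpha, alpha = 0.25) and the uniform out-set CDF. With
normalization on, the whole score matrix is divided by its global range,
making max - min exactly 1 — the convention of the reference
implementation. Scores are invariant to any strictly monotone per-sample
transform of expression.

`gsva_scores()` maps each gene's expression to a cross-sample
Gaussian-kernel CDF (bandwidth = per-gene SD / 4), ranks genes per sample
by that statistic, weights them by the symmetric rank statistic
|N/2 - rank|^tau, and scores each set by the signed sum of the walk's
maximum positive and negative deviations (the "mx.diff" convention,
chosen for interpretability; zero-variance genes are assigned the neutral
CDF value 0.5). GSVA needs at least 3 samples.

Group-difference reporting on score or expression panels (immune cells,
immune reactions, HLA-style panels, regulators) is rank-based with one BH
family per panel.

## lncRNA linkage and co-expression modules

A lncRNA is "related" to a modification when it passes |r| > 0.4 and
p < 0.001 (strict inequalities, as printed in the source analysis;
p from the t transform on n - 2 df) against at least one regulator of
that modification; all passing pairs are stored, and the m6A and m5C sets
are intersected. lncRNA identity is an explicit id list — the package
does not guess which probes are lncRNAs.

Module detection is a deliberately simplified weighted co-expression
workflow: unsigned adjacency |cor|^beta, beta chosen as the smallest
power reaching a signed scale-free fit R^2 of 0.85 (the sign convention
matters: the degree distribution must *decay*; powers that crush mean
connectivity below 1 are excluded because pure noise mimics scale-free
decay there). When no power qualifies — equal-size planted blocks are
modular but not scale-free, so this is common — the conventional unsigned
power 6 is used with a warning. Topological overlap is the standard
shared-neighbor normalization; trees are cut statically at 0.95 of the
maximum merge height (inter-module merges sit just below the top of the
TOM dissimilarity scale, intra-module merges well underneath), clusters
smaller than 30 genes fall into module 0, and eigengenes are unit-norm
first principal components oriented so the mean gene loading is positive.
This static cut replaces the reference dynamic tree cut and is adequate
for planted-block recovery; fine module splitting on real data is out of
scope.

## The methylation score

`compute_m6ascore()` standardizes the signature-gene rows (unit variance
by default, so high-variance genes do not dominate; configurable), runs a
PCA over samples and defines score = PC1 + PC2. PCA signs are arbitrary,
so each component is oriented to correlate positively with mean signature
expression, making the score deterministic. Components are centered, so
they sum to zero across samples. The high/low split defaults to the
median (the mean rule is exposed, matching the single-gene split used for
the demethylase analysis in the source work), with "high" strictly above
the threshold.

## Problem sizes and determinism

Everything is seeded: the generator is bit-reproducible given its seed,
CV folds and consensus subsampling take explicit seeds, and the pipeline
manifest records md5 checksums that reproduce across reruns. The test
suite exercises the pipeline at reduced sizes chosen to keep the full run
in the tens of seconds while leaving every planted-recovery margin wide:
cohorts of 90-200 cases, 400-600 genes, consensus with 100-250 replicates
(the headline analysis uses 1,000), and 20-seed recovery loops for
feature selection and lncRNA linkage. `scripts/acceptance.R` runs the
full default design (285 samples, 2,000 genes, 1,000 consensus
replicates) end to end.

## Known limitations

* The generator's Gaussian, balanced-pattern world is easier than real
  cohort data; recovery rates here are upper bounds.
* Batch correction is batch-only; if disease groups were confounded with
  batch, biological signal would be partially removed.
* The immune gene sets shipped by the generator are synthetic stand-ins;
  real signatures must be supplied as GMT files.
* GO/KEGG-style enrichment is a plain hypergeometric over-representation
  test over user-supplied sets; no term databases are bundled.
* CD4/CD8-style contrasts on enrichment scores should be formed as score
  differences, not ratios — ssGSEA/GSVA scores can be negative, so a
  ratio is ill-defined.
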