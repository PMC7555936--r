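---
title: "Phenotype-stratified differential methylation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype-stratified differential methylation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratmeth)
```

## The problem

Genome-wide methylation comparisons between cases and controls in clinically
heterogeneous disorders often fail to find reproducible signal: when cases
with distinct underlying biology are pooled, their group-mean methylation
differences shrink toward zero and significant loci become scarce.
`stratmeth` implements the alternative analysis strategy of *stratifying*
cases into severity-defined subphenotypes before testing, and provides the
machinery to quantify what stratification buys: a subtyping stage driven by
clinical severity scores, a per-CpG differential methylation test run both
per subgroup and on the pooled case group, gene-level annotation and
enrichment stages, and a synthetic-data generator with recorded ground truth
so the whole chain is testable without access to restricted patient data.

The intended user is an analyst with (a) a subjects-by-items ordinal severity
matrix from a diagnostic instrument, (b) case and sibling-control beta-value
matrices (or methylated/unmethylated intensities) from a methylation array,
(c) a CpG-to-gene annotation with distances to the nearest transcription
start site (TSS), and (d) gene-set and gene-list files for downstream
interpretation.

## Subtyping model

Cases are clustered with K-means (`kmeans_subtype()`) on the raw severity
scores. Scores share one ordinal scale (default alphabet 1-3), so columns
are *not* standardised by default; a z-score option exists behind the
`standardize` flag. `K` defaults to 3 — the mild / intermediate / severely
language-impaired partition this pipeline targets — and no automatic model
selection is attempted; users with different phenotype structure set `K`
explicitly. The clustering is the best of 25 random restarts by total
within-cluster sum of squares and is deterministic given a seed. Because the
distance metric, initialisation, and restart count of such clusterings are
rarely reported in applied work, all are exposed as arguments.

`label_subgroups()` converts cluster numbers into phenotype names using two
summary statistics per cluster: the mean over designated language-related
score columns and the overall mean. The cluster highest on language severity
is `severe`; of the rest, the lowest overall mean is `mild`. Ties fall back
to overall mean and then cluster index, and a completely degenerate
clustering is labelled by index with a warning rather than an error, so
pipelines never die on pathological inputs.

Two verification views accompany the assignment: `pca_severity()` (centred
PCA on the covariance matrix, consistent with unstandardised clustering;
variance fractions over all components sum to one) and `hcl_order()`
(average-linkage Euclidean hierarchical clustering by default — a
documented convention, since heatmap orderings in applied work rarely state
theirs).

## The differential methylation statistic

Methylation at a CpG is summarised by the beta value
$\beta = M / (M + U + 100)$, the methylated-probe signal as a fraction of
total signal with a stabilising offset of 100 (`compute_beta()`).

The per-CpG test (`diffscore_test()`) assumes beta values are normally
distributed among biological replicates and compares group means with
standard error

$$\mathrm{SE} = \sqrt{s_1^2/n_1 + s_2^2/n_2 + f^2},$$

where $f$ is a variance floor (default $10^{-4}$) playing the role of the
technical-error term in array error models: it keeps degenerate
zero-variance probes testable and is negligible whenever biological
variance is present. Two-sided p-values are computed against a t reference
with Welch-Satterthwaite degrees of freedom. A plain normal reference is
available (`df_method = "normal"`), but at realistic per-stratum sample
sizes (tens of replicates) the z reference is visibly anti-conservative in
the tails — with estimated variances the statistic is t-like, and
Kolmogorov-Smirnov checks on tens of thousands of null CpGs detect the
difference — so the t reference is the default.

The signed score reported for each CpG is

$$\mathrm{DiffScore} = -10\,\operatorname{sign}(\Delta\beta)\log_{10} p,$$

with $\Delta\beta$ the case-minus-control mean difference. The transform
$p = 10^{-|\mathrm{DiffScore}|/10}$ is enforced exactly on every emitted
record (it is an invariant, not a convention), which places the familiar
significance landmark at $|\mathrm{DiffScore}| = 13.0103 \iff p = 0.05$.
Magnitudes are capped at 350 (p-value floor $10^{-35}$) to guard against
underflow; the cap is far beyond any interpretable evidence level.

Multiple testing is controlled by Benjamini-Hochberg FDR (`fdr_adjust()`,
a validated wrapper over `p.adjust`), applied *within each stratum
separately* in stratified mode — each subgroup analysis stands on its own,
as per-subgroup q-values do in practice. Significance is strict:
`fdr_q < alpha` with `alpha = 0.05`.

`run_group_analysis()` orchestrates the test per subgroup or pooled. The
default comparison is unpaired (a group comparison of cases versus
controls); because sibling controls are matched, a paired variant testing
within-pair differences is available behind `paired = TRUE`. An auxiliary
`fold_change` column (case mean over control mean) is emitted for
compatibility with array-software conventions; it carries no inferential
weight. Strata with fewer than two cases or two controls are skipped with a
warning rather than poisoning the run.

## Annotation and summaries

`collect_dags()` maps significant CpGs to annotated genes and deduplicates:
the unit of downstream analysis is the unique gene (a "differentially
methylated gene", DAG), with full CpG provenance retained, including mixed
hyper/hypo contributions. Annotations are distance-based only — records
farther than 1500 bp from a TSS are rejected with a count — because every
downstream consumer here uses only the distance; no strand or coordinate
semantics are modelled.

Two distance conventions coexist deliberately. The Fig-3-style summary
(`tss_direction_summary()`) bins distances as $\le 500$, $501$-$1000$, and
$1001$-$1500$ bp (inclusive edges), while the direction-split proximal gene
lists (`proximal_direction_lists()`) use a *strict* `< 500` bp cut, the
convention of "genes with CpGs less than 500 bp from the TSS" tables. A CpG
at exactly 500 bp therefore counts in the first summary bin but not in the
proximal lists.

## Enrichment and overlap

`fisher_enrichment()` performs one-sided over-representation tests of a
query gene list against each set of a `geneset_db()`, evaluating the Fisher
exact p-value as the hypergeometric upper tail of the 2x2 table — the two
are the same computation, and the test suite asserts their exact agreement
with `fisher.test()`. Raw p-values with a 0.05 flag are reported by
default; BH adjustment sits behind a flag since curated-knowledgebase
practice reports raw Fisher p-values.

`venn_partition()` produces the full $2^m - 1$ region accounting for 2-4
gene lists, ordered deterministically by membership bitmask, and
`hypergeom_overlap()` gives the upper cumulative probability
$P(X \ge k)$ for the overlap of two lists drawn from a universe of $N$
genes. The largest ambiguity in this whole analysis class is the choice of
$N$: published overlap q-values are rarely accompanied by their universe.
The package default for methylation-derived lists is the number of distinct
genes on the methylation annotation (the assayed genes), and `N` is always
an explicit argument so users can (and should) state theirs.

## The synthetic-data generator

The generator exists to make every stage falsifiable offline; it emulates
the study design this pipeline targets rather than the full messiness of
array data.

* **Severity matrices** (`generate_severity_matrix()`): default 292
  subjects split 149/121/22 (mild/intermediate/severe) over 123 scores on
  63 items, alphabet `{1, 2, 3}` (special administrative codings of
  diagnostic instruments are not modelled). Subgroup structure enters
  through profile shifts of size `separation`: the severe subgroup is
  elevated by `separation` on a designated ~30% block of language columns,
  the mild subgroup lowered by `separation/2` everywhere. At
  `separation = 1` (the default), K-means recovery of the true labels is
  essentially perfect (adjusted Rand index > 0.9 across seeds, verified by
  simulation over 100 seeds during development); at `separation = 0` the
  subgroups are exchangeable and recovery collapses to chance.
* **Methylation matrices** (`generate_paired_methylation()`): per-CpG
  baselines are uniform on (0.15, 0.85), noise is normal on the beta scale
  (sd 0.03) clipped to (0.001, 0.999), matching the normality assumption of
  the test rather than the bimodal marginal distribution of real arrays; a
  consequence spelled out below. Planted case-minus-control effects default
  to magnitudes 0.03-0.08 — calibrated to the observation that subgroup
  effect sizes in this setting are mostly below $|\Delta\beta| = 0.05$,
  with the small severe subgroup reaching larger values — with
  subgroup-specific hypomethylation fractions (0.87 severe, 0.08
  intermediate, 0.65 mild) mirroring the direction asymmetries reported for
  such subgroups. Effect loci get unique gene symbols so that per-subgroup
  truth sets are disjoint under the `disjoint` layout; null CpGs share the
  remaining genes (a gene may own several CpGs, as on promoter-centric
  arrays). Sibling pairing is generated and recorded, but the default test
  is unpaired, matching group-comparison practice.
* **Distances to TSS** are drawn from a 65% / 30% / 5% mixture over
  [0, 500], (500, 1000], (1000, 1500] bp, so all CpGs are within 1500 bp
  and >90% within 1000 bp of a TSS, the structure reported for
  promoter-centric 27K-style arrays.
* **Gene sets and DEG lists** (`generate_genesets()`,
  `generate_deg_list()`) provide enrichment databases with an exactly
  planted signal set and expression-derived lists with controllable overlap.

What the generator does *not* emulate — batch effects, cell-type
composition, probe chemistry, bimodal beta distributions, correlated CpGs,
sex chromosomes — bounds what green tests mean: they demonstrate that the
statistical machinery is correct and well calibrated under its own model,
not that the pipeline is robust to the technical artefacts of real array
data, which should be handled upstream.

## The power-gain experiment

`power_gain_experiment()` is the package's headline instrument. For each
scenario and replicate it simulates paired methylation data, analyses it
stratified by the true subgroups and pooled, and compares unique-gene
counts: the union of per-subgroup DAGs versus the pooled DAGs. True labels
are used (rather than re-clustered ones) so the experiment isolates
differential-methylation power from subtype-recovery error; the full
pipeline (`run_full_pipeline()`) exercises the complete path including
label assignment.

The three built-in scenarios probe the theory:

* `heterogeneous` — disjoint effect sets per subgroup at the study's sizes
  (149/121/22). Pooling dilutes each subgroup's effect by its share of
  cases, so the small severe subgroup's loci drop below detectability in
  the pooled analysis while each stratum retains its own signal: the union
  reliably exceeds the pooled count. This is the mechanism behind
  stratification gains of the ~1.6x order.
* `homogeneous` — one shared effect set, equal subgroup sizes, effect
  magnitudes 0.01-0.03. The magnitudes are deliberately near the
  per-stratum detection threshold because that is the only regime in which
  the power *cost* of splitting a homogeneous cohort is visible; with
  saturating effects both analyses find everything and the comparison is
  uninformative. Here the ratio sits at or below 1.
* `null` — no effects; both counts are near zero and the ratio is reported
  as `NA` (never 0/0).

Ratios are undefined when the pooled analysis finds nothing; summaries
report means over defined ratios with 95% percentile intervals.

## Numerical and design choices

* Welch t reference by default for the per-CpG test (see above); the
  permutation oracle in the test suite confirms model p-values within
  ±0.02 of exhaustive permutation p-values on small instances.
* DiffScore cap 350 / p floor $10^{-35}$; transform identity enforced to
  $10^{-9}$.
* Variance floor $10^{-4}$ on the beta-sd scale, added in quadrature.
* Missing severity scores are not imputed by the generator (it emits
  complete matrices); users with missing items should impute by item median
  before clustering, which preserves the ordinal scale.
* Tie-breaks in subgroup labelling are total and documented (language mean,
  overall mean, cluster index), so labelling never throws on collisions.
* All randomness flows from one root seed: `run_full_pipeline()` and
  `power_gain_experiment()` derive per-stage substreams from the root seed,
  and every generator is deterministic given its own seed. Pipeline outputs
  embed a hash of the resolved configuration (excluding the output path) so
  any result file is attributable to its exact settings.
* Problem sizes in the shipped experiments — 5000 CpGs for power runs,
  10,000 CpGs for null-calibration checks, 20 replicates for scenario
  summaries — were chosen as the smallest sizes at which the Monte-Carlo
  noise of the summarised proportions is comfortably below the decision
  margins of the properties being checked.

## Known limitations

* The internal error model of the proprietary array software whose
  DiffScore convention this package mirrors is unpublished; the
  mean-comparison test with a variance floor is this package's own
  documented statistic, sharing the score convention and the normality
  assumption, not a re-implementation of that software.
* Beta values are treated as approximately normal within groups; for
  probes near the 0/1 boundaries a logit (M-value) analysis would be more
  appropriate and is not currently provided.
* Enrichment is set-membership only (no topology, no directionality), and
  symbol matching is case-sensitive with no alias resolution.
* The unpaired default ignores sibling matching; the paired variant is
  provided but loses strata with incomplete pairs.
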