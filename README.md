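# stratmeth

Phenotype-stratified differential DNA methylation analysis.

## The problem

Case-control methylation studies of clinically heterogeneous disorders
routinely come up empty: when biologically distinct cases are pooled, their
group-mean methylation differences (Δβ) partially cancel, and few CpGs
survive genome-wide multiple-testing correction. Stratifying cases into
severity-defined subphenotypes *before* testing reduces that heterogeneity,
and can multiply the number of statistically significant findings even
though each stratum is smaller than the pooled cohort.

`stratmeth` implements this strategy end to end for array methylation data
with sibling controls:

1. **Subtyping** — K-means (`K = 3` by default: mild / intermediate /
   severely language-impaired) on a subjects-by-scores ordinal clinical
   severity matrix, with PCA and hierarchical-clustering verification
   views, and data-driven mild/intermediate/severe labelling.
2. **Differential methylation** — per-CpG comparison of case and control
   mean beta values (β = M/(M + U + 100)) under a normal model with a
   technical variance floor, reported as a signed score
   `DiffScore = -10·sign(Δβ)·log10(p)` so that `p = 10^(-|DiffScore|/10)`
   holds exactly (|DiffScore| = 13.0103 ⇔ p = 0.05), with
   Benjamini–Hochberg FDR applied within each stratum; run per subgroup
   and on the pooled case group.
3. **Annotation** — mapping of significant CpGs to unique genes (DAGs),
   TSS-distance and hyper/hypo direction summaries, and strict `< 500 bp`
   proximal gene lists split by direction.
4. **Enrichment and overlap** — one-sided Fisher-exact gene-set
   enrichment, exact Venn partitioning of 2–4 DAG lists, and
   hypergeometric upper-tail tests of the overlap between DAG and
   differentially-expressed-gene lists.
5. **Synthetic data and power** — a generator that emulates the study
   design (292 case–sibling pairs split 149/121/22, 123-score severity
   matrices with a language-severity block, planted subgroup-specific
   effects with |Δβ| in 0.03–0.08, all CpGs within 1500 bp of a TSS) with
   full ground-truth bookkeeping, and a stratified-versus-pooled
   `power_gain_experiment()` quantifying the discovery gain.

See the vignette (`vignettes/stratified-methylation.Rmd`) for the models,
assumptions, parameter choices, and limitations.

## Worked example

```r
library(stratmeth)

# simulate a severity matrix at the study's subgroup sizes and subtype it
sev <- generate_severity_matrix(seed = 1)        # 292 x 123 scores
assign <- kmeans_subtype(sev$scores, K = 3, seed = 1)
assign <- label_subgroups(assign, sev$scores, sev$language_items)
assign
#> K-means subtype assignment: 292 subjects in 3 clusters
#>   intermediate n = 121
#>   mild         n = 149
#>   severe       n = 22
adjusted_rand_index(assign$cluster, sev$truth$true_subgroup)
#> [1] 1

# full pipeline: simulate -> subtype -> test stratified + pooled ->
# annotate -> enrich -> overlap
res <- run_full_pipeline(default_config(seed = 1), quiet = TRUE)
res$summary[c("dag_counts", "union_dag_count", "combined_dag_count",
              "union_vs_combined_ratio")]
#> $dag_counts           mild 51, intermediate 55, severe 44, combined 102
#> $union_dag_count      150
#> $combined_dag_count   102
#> $union_vs_combined_ratio  1.47
```

The three subgroup analyses jointly recover 150 unique differentially
methylated genes versus 102 for the pooled analysis of the *same* samples —
the stratification gain (here 1.47×) that motivates the pipeline: planted
effects confined to one subgroup (especially the small severe one, 22
pairs) are diluted below detectability when all 292 cases are pooled. The
accompanying TSS summary shows every group with >93% of significant CpGs
within 1000 bp of the TSS, and the direction split (95% hypomethylated in
the severe group, 82% hypermethylated in the intermediate group under the
default generator settings) mirrors the direction asymmetries such
subgroups exhibit:

```r
res$tss
#>          group n_cpg prop_le500 prop_501_1000 prop_1001_1500 prop_hyper prop_hypo
#>           mild    51      0.588         0.353         0.0588      0.333     0.667
#>   intermediate    55      0.618         0.345         0.0364      0.818     0.182
#>         severe    44      0.750         0.182         0.0682      0.045     0.955
#>       combined   102      0.598         0.363         0.0392      0.588     0.412

head(res$enrichment$severe[, c("set_name", "k", "K_set", "fisher_p", "enriched")], 3)
#>   set_name  k K_set     fisher_p enriched
#> 1  planted 42   150 4.060993e-49     TRUE
#> 2   set003  2    10 1.631015e-02     TRUE
#> 3   set005  1    10 1.855802e-01    FALSE
```

The planted gene set ranks first by Fisher p-value, as it should when the
differential methylation stage recovers the planted loci.

A thin command-line wrapper over the same functions is provided in
`inst/scripts/stratmeth-cli.R`:

```sh
Rscript inst/scripts/stratmeth-cli.R run-all --seed 1 --outdir run1
Rscript inst/scripts/stratmeth-cli.R power-gain --seed 1 --replicates 20 --outdir pg1
```

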