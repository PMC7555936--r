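# End-to-end orchestration: simulate -> subtype -> test (stratified and
# combined) -> annotate -> enrich -> overlap, plus the stratified-vs-pooled
# power experiment. All randomness flows from one root seed through
# per-stage substreams drawn by .stage_seeds().

.CONFIG_INT <- c("seed", "n_cpg", "n_restarts", "n_genesets", "max_proximal_distance")
.CONFIG_INT_VEC <- c("n_pairs", "n_effect", "set_size_range")
.CONFIG_NUM <- c("noise_sd", "separation", "language_item_fraction", "alpha",
                 "variance_floor")
.CONFIG_NUM_VEC <- c("delta_range", "hypo_fraction")
.CONFIG_CHR <- c("layout", "outdir")

#' Default pipeline configuration
#'
#' The defaults encode the study design this pipeline targets: 292
#' case-control sibling pairs split 149/121/22 over the mild, intermediate,
#' and severely language-impaired subgroups; 5000 CpGs with 50 planted
#' effect loci per subgroup on disjoint genes; beta-scale effect magnitudes
#' between 0.03 and 0.08 with subgroup-specific hypomethylation fractions;
#' and beta noise of 0.03 s.d.
#'
#' @param seed root seed for the whole run.
#' @param ... named overrides of any configuration field.
#' @return A named list (the run configuration).
#' @export
default_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_pairs = c(mild = 149L, intermediate = 121L, severe = 22L),
    n_cpg = 5000L,
    n_effect = c(mild = 50L, intermediate = 50L, severe = 50L),
    delta_range = c(0.03, 0.08),
    hypo_fraction = c(mild = 0.65, intermediate = 0.08, severe = 0.87),
    layout = "disjoint",
    noise_sd = 0.03,
    separation = 1,
    language_item_fraction = 0.3,
    alpha = 0.05,
    variance_floor = 1e-4,
    n_restarts = 25L,
    n_genesets = 20L,
    set_size_range = c(10L, 50L),
    max_proximal_distance = 500L,
    outdir = NULL
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown)) stop("unknown configuration fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  .normalize_config(cfg)
}

.normalize_config <- function(cfg) {
  base <- list(
    seed = 1L, n_pairs = c(mild = 149L, intermediate = 121L, severe = 22L),
    n_cpg = 5000L, n_effect = c(mild = 50L, intermediate = 50L, severe = 50L),
    delta_range = c(0.03, 0.08),
    hypo_fraction = c(mild = 0.65, intermediate = 0.08, severe = 0.87),
    layout = "disjoint", noise_sd = 0.03, separation = 1,
    language_item_fraction = 0.3, alpha = 0.05, variance_floor = 1e-4,
    n_restarts = 25L, n_genesets = 20L, set_size_range = c(10L, 50L),
    max_proximal_distance = 500L, outdir = NULL
  )
  base[names(cfg)] <- cfg
  cfg <- base
  for (f in .CONFIG_INT) cfg[[f]] <- as.integer(cfg[[f]])
  for (f in .CONFIG_NUM) cfg[[f]] <- as.numeric(cfg[[f]])
  for (f in .CONFIG_INT_VEC) {
    v <- as.integer(unlist(cfg[[f]]))
    names(v) <- names(unlist(cfg[[f]]))
    cfg[[f]] <- v
  }
  for (f in .CONFIG_NUM_VEC) {
    v <- as.numeric(unlist(cfg[[f]]))
    names(v) <- names(unlist(cfg[[f]]))
    cfg[[f]] <- v
  }
  if (!is.null(cfg$outdir)) cfg$outdir <- as.character(cfg$outdir)
  cfg$layout <- as.character(cfg$layout)
  cfg[names(base)]
}

#' Read and write run configurations as JSON
#'
#' Configurations round-trip exactly: `read_config(write_config(cfg, path))`
#' is identical to the normalised `cfg`.
#'
#' @param cfg a configuration list (see [default_config()]).
#' @param path file path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns the configuration list.
#' @export
write_config <- function(cfg, path) {
  cfg <- .normalize_config(cfg)
  out <- lapply(cfg, function(v) {
    if (!is.null(names(v))) as.list(v) else v
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  .normalize_config(jsonlite::fromJSON(path, simplifyVector = TRUE))
}

# small deterministic hash of the resolved configuration, recorded in every
# pipeline output header so runs are attributable to their settings; the
# output directory is not part of the scientific configuration and is
# excluded so identical analyses hash identically wherever they are written
.config_hash <- function(cfg) {
  cfg <- .normalize_config(cfg)
  cfg$outdir <- NULL
  s <- jsonlite::toJSON(lapply(cfg, unname),
                        auto_unbox = TRUE, digits = NA, null = "null")
  h <- 0
  for (v in utf8ToInt(as.character(s))) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.write_tsv_stamped <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Run the full stratified differential methylation pipeline
#'
#' Simulates a severity matrix and paired methylation data, recovers the
#' phenotypic subgroups by K-means, labels them, runs the DiffScore test
#' stratified by the *assigned* subgroups and on the pooled case group,
#' collects DAGs (unique genes implicated by significant CpGs) per group,
#' summarises TSS proximity and methylation direction, tests gene-set
#' enrichment against a simulated database containing the planted signal
#' set, partitions the four DAG lists into Venn regions, and tests
#' hypergeometric overlap with a simulated differentially-expressed-gene
#' list.
#'
#' When `config$outdir` is set, every stage output is written there as TSV
#' or JSON (with the resolved configuration and its hash), deterministically
#' for a given configuration.
#'
#' @param config configuration list from [default_config()].
#' @param quiet suppress per-stage messages.
#' @return Invisibly, a list with `summary` (counts per group, union vs
#'   combined DAG counts and their ratio, filter bookkeeping), `assignment`,
#'   `diffmeth` (per-group records), `dags`, `tss`, `enrichment`, `venn`,
#'   `deg_overlap`, and the resolved `config`.
#' @export
run_full_pipeline <- function(config = default_config(), quiet = FALSE) {
  cfg <- .normalize_config(config)
  say <- if (quiet) function(...) invisible(NULL) else message
  seeds <- .stage_seeds(cfg$seed, 5L)
  hash <- .config_hash(cfg)

  say("stage 1/6: simulating severity matrix")
  sev <- generate_severity_matrix(
    cfg$n_pairs, separation = cfg$separation,
    language_item_fraction = cfg$language_item_fraction, seed = seeds[1L]
  )

  say("stage 2/6: subtyping cases")
  assignment <- kmeans_subtype(sev$scores, K = 3L,
                               n_restarts = cfg$n_restarts, seed = seeds[2L])
  assignment <- label_subgroups(assignment, sev$scores, sev$language_items)
  labels <- subgroup_of(assignment)

  say("stage 3/6: simulating paired methylation data")
  sim <- generate_paired_methylation(
    cfg$n_pairs, cfg$n_cpg,
    effects = effect_config(cfg$n_effect, cfg$delta_range,
                            cfg$hypo_fraction, cfg$layout),
    noise_sd = cfg$noise_sd, seed = seeds[3L],
    subject_ids = sev$truth$subject_id
  )
  # stratify by the assigned (not true) subgroup; controls inherit the label
  # of their case sibling through the pair id
  sheet <- sim$sample_sheet
  is_case <- sheet$role == "case"
  case_label <- labels[sheet$sample_id[is_case]]
  names(case_label) <- sheet$pair_id[is_case]
  sheet$subgroup <- unname(case_label[sheet$pair_id])

  say("stage 4/6: differential methylation (stratified and combined)")
  strat <- run_group_analysis(sim$case, sim$control, sheet, "stratified",
                              alpha = cfg$alpha,
                              variance_floor = cfg$variance_floor,
                              annotation = sim$annotation)
  comb <- run_group_analysis(sim$case, sim$control, sheet, "combined",
                             alpha = cfg$alpha,
                             variance_floor = cfg$variance_floor,
                             annotation = sim$annotation)
  all_records <- c(strat, comb)

  say("stage 5/6: annotating DAGs and summarising TSS proximity")
  dags <- lapply(all_records, function(r) {
    suppressMessages(collect_dags(r, sim$annotation))
  })
  tss <- tss_direction_summary(do.call(rbind, all_records), sim$annotation)
  proximal <- lapply(all_records, function(r) {
    suppressMessages(
      proximal_direction_lists(r, sim$annotation, cfg$max_proximal_distance)
    )
  })

  union_genes <- sort(unique(unlist(lapply(dags[names(strat)], `[[`, "genes"))))
  combined_genes <- dags[["combined"]]$genes
  ratio <- if (length(combined_genes) > 0L) {
    length(union_genes) / length(combined_genes)
  } else {
    NA_real_
  }

  say("stage 6/6: enrichment and overlap analyses")
  universe <- sort(unique(sim$annotation$gene_symbol))
  planted <- true_effect_genes(sim$truth)
  db <- generate_genesets(universe, cfg$n_genesets, cfg$set_size_range,
                          planted_set = if (length(planted)) planted else NULL,
                          seed = seeds[4L])
  enrichment <- lapply(dags, function(d) {
    suppressMessages(fisher_enrichment(d$genes, db, alpha = cfg$alpha))
  })
  dag_lists <- lapply(dags, `[[`, "genes")
  venn <- if (sum(lengths(dag_lists) >= 0) >= 2 && length(dag_lists) >= 2) {
    venn_partition(dag_lists, universe_size = length(universe))
  } else {
    NULL
  }
  deg <- generate_deg_list(planted, universe, n_deg = 50L,
                           overlap_fraction = 0.5, seed = seeds[5L])
  deg_overlap <- do.call(rbind, lapply(names(dags), function(g) {
    data.frame(group = g,
               k = length(intersect(dags[[g]]$genes, deg)),
               n_dag = length(dags[[g]]$genes), n_deg = length(deg),
               N = length(universe),
               q = hypergeom_overlap(dags[[g]]$genes, deg, length(universe)),
               stringsAsFactors = FALSE)
  }))

  n_sig <- vapply(all_records, function(r) sum(r$significant), integer(1))
  summary <- list(
    config_hash = hash,
    seed = cfg$seed,
    n_cpg_tested = cfg$n_cpg,
    n_subjects = sum(cfg$n_pairs),
    subgroup_sizes = as.list(table(labels)),
    significant_cpgs = as.list(n_sig),
    dag_counts = lapply(dags, function(d) length(d$genes)),
    unannotated_cpgs = lapply(dags, `[[`, "n_unannotated"),
    union_dag_count = length(union_genes),
    combined_dag_count = length(combined_genes),
    union_vs_combined_ratio = ratio,
    top_enrichment = lapply(enrichment, function(e) {
      if (nrow(e)) e$set_name[1L] else NA_character_
    }),
    venn_regions = if (!is.null(venn)) {
      stats::setNames(as.list(venn$regions$size), venn$regions$region)
    } else {
      NULL
    }
  )

  result <- list(summary = summary, assignment = assignment, diffmeth = all_records,
                 dags = dags, tss = tss, proximal = proximal,
                 enrichment = enrichment, venn = venn, deg_overlap = deg_overlap,
                 config = cfg)

  if (!is.null(cfg$outdir)) .write_pipeline_outputs(result, sev, sim, hash)
  invisible(result)
}

.write_pipeline_outputs <- function(result, sev, sim, hash) {
  outdir <- result$config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)

  write_config(result$config, p("config.json"))
  write_severity_tsv(sev$scores, p("severity.tsv"))
  write_sample_sheet(sim$sample_sheet, p("sample_sheet.tsv"))
  write_annotation_tsv(sim$annotation, p("annotation.tsv"))

  assign_df <- data.frame(
    subject_id = names(result$assignment$cluster),
    cluster = unname(result$assignment$cluster),
    label = unname(subgroup_of(result$assignment)),
    stringsAsFactors = FALSE
  )
  .write_tsv_stamped(assign_df, p("assignment.tsv"), hash)

  for (g in names(result$diffmeth)) {
    .write_tsv_stamped(result$diffmeth[[g]], p(sprintf("diffmeth_%s.tsv", g)), hash)
    write_gene_list(result$dags[[g]]$genes, p(sprintf("dags_%s.txt", g)))
    write_gene_list(result$proximal[[g]]$hyper, p(sprintf("proximal_hyper_%s.txt", g)))
    write_gene_list(result$proximal[[g]]$hypo, p(sprintf("proximal_hypo_%s.txt", g)))
    .write_tsv_stamped(result$enrichment[[g]], p(sprintf("enrichment_%s.tsv", g)), hash)
  }
  .write_tsv_stamped(volcano_table(result$diffmeth), p("volcano.tsv"), hash)
  .write_tsv_stamped(result$tss, p("tss_summary.tsv"), hash)
  if (!is.null(result$venn)) {
    .write_tsv_stamped(result$venn$regions, p("venn_regions.tsv"), hash)
  }
  .write_tsv_stamped(result$deg_overlap, p("deg_overlap.tsv"), hash)
  jsonlite::write_json(result$summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(outdir)
}

#' Built-in scenarios for the power-gain experiment
#'
#' `heterogeneous` plants disjoint effect sets per subgroup (the condition
#' under which stratification is expected to discover more genes than the
#' pooled analysis); `homogeneous` plants one shared effect set with equal
#' subgroup sizes, using effect magnitudes near the per-stratum detection
#' threshold because that is the regime in which the power cost of
#' splitting a homogeneous cohort is visible at all (with saturating
#' effects both analyses find everything); `null` plants no effects.
#'
#' @return Named list of scenarios, each a list with `effects` (an
#'   [effect_config()]) and optionally `n_pairs`.
#' @export
default_power_scenarios <- function() {
  list(
    heterogeneous = list(
      effects = effect_config(n_effect = c(mild = 50L, intermediate = 50L, severe = 50L),
                              delta = c(0.03, 0.08), layout = "disjoint")
    ),
    homogeneous = list(
      effects = effect_config(n_effect = c(mild = 50L, intermediate = 50L, severe = 50L),
                              delta = c(0.01, 0.03), layout = "shared"),
      n_pairs = c(mild = 97L, intermediate = 97L, severe = 98L)
    ),
    null = list(
      effects = effect_config(n_effect = c(mild = 0L, intermediate = 0L, severe = 0L))
    )
  )
}

#' Stratified-versus-pooled discovery power experiment
#'
#' For each scenario and replicate, simulates paired methylation data with
#' known subgroups, runs the DiffScore analysis stratified by the true
#' subgroups and on the pooled case group, and compares the number of
#' unique genes (DAGs) discovered by the union of the per-subgroup analyses
#' with that of the pooled analysis. The per-scenario ratio of these unique
#' gene counts quantifies the discovery gain from stratification.
#'
#' True subgroup labels are used for stratification so that the experiment
#' isolates differential-methylation power from subtype-recovery error.
#'
#' @param scenarios named list of scenarios (see
#'   [default_power_scenarios()]).
#' @param n_replicates Monte-Carlo replicates per scenario (>= 2).
#' @param seed root seed; replicate seeds are derived from it.
#' @param n_pairs default subgroup pair counts (a scenario may override).
#' @param n_cpg CpGs per replicate.
#' @param noise_sd beta-scale noise standard deviation.
#' @param alpha FDR significance threshold.
#' @param variance_floor technical-error term of the DiffScore test.
#' @return A list with `summary` (one row per scenario: mean union,
#'   combined, and ratio, 95% percentile interval of the ratio, and the
#'   proportion of replicates with ratio > 1) and `replicates` (one row per
#'   scenario x replicate). Ratios are `NA` when the pooled analysis finds
#'   no DAGs.
#' @export
power_gain_experiment <- function(scenarios = default_power_scenarios(),
                                  n_replicates = 20L, seed = 1L,
                                  n_pairs = c(mild = 149L, intermediate = 121L, severe = 22L),
                                  n_cpg = 5000L, noise_sd = 0.03,
                                  alpha = 0.05, variance_floor = 1e-4) {
  if (n_replicates < 2L) stop("'n_replicates' must be at least 2")
  if (is.null(names(scenarios))) names(scenarios) <- paste0("scenario", seq_along(scenarios))
  rep_seeds <- .stage_seeds(seed, n_replicates * length(scenarios))
  rows <- list()
  i <- 0L
  for (sc in names(scenarios)) {
    spec <- scenarios[[sc]]
    np <- .per_subgroup(as.integer(spec$n_pairs %||% n_pairs), "n_pairs")
    for (r in seq_len(n_replicates)) {
      i <- i + 1L
      sim <- generate_paired_methylation(np, n_cpg, effects = spec$effects,
                                         noise_sd = noise_sd,
                                         seed = rep_seeds[i])
      strat <- run_group_analysis(sim$case, sim$control, sim$sample_sheet,
                                  "stratified", alpha = alpha,
                                  variance_floor = variance_floor,
                                  annotation = sim$annotation)
      comb <- run_group_analysis(sim$case, sim$control, sim$sample_sheet,
                                 "combined", alpha = alpha,
                                 variance_floor = variance_floor,
                                 annotation = sim$annotation)
      union_n <- length(unique(unlist(lapply(strat, function(x) {
        x$gene_symbol[x$significant]
      }))))
      comb_n <- length(unique(comb$combined$gene_symbol[comb$combined$significant]))
      rows[[i]] <- data.frame(
        scenario = sc, replicate = r, union_dags = union_n,
        combined_dags = comb_n,
        ratio = if (comb_n > 0L) union_n / comb_n else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  replicates <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(names(scenarios), function(sc) {
    d <- replicates[replicates$scenario == sc, , drop = FALSE]
    ok <- !is.na(d$ratio)
    data.frame(
      scenario = sc,
      n_replicates = nrow(d),
      mean_union = mean(d$union_dags),
      mean_combined = mean(d$combined_dags),
      mean_ratio = if (any(ok)) mean(d$ratio[ok]) else NA_real_,
      ratio_lo = if (any(ok)) unname(stats::quantile(d$ratio[ok], 0.025)) else NA_real_,
      ratio_hi = if (any(ok)) unname(stats::quantile(d$ratio[ok], 0.975)) else NA_real_,
      prop_ratio_gt1 = if (any(ok)) mean(d$ratio[ok] > 1) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  list(summary = summary, replicates = replicates)
}
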