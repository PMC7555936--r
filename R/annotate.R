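# CpG-to-gene annotation and TSS-proximity summaries. Distances are plain
# non-negative base-pair distances to the nearest TSS; no strand or
# coordinate semantics are modelled because downstream summaries consume
# only the distance.

MAX_TSS_DISTANCE <- 1500L

#' Validate a CpG annotation table
#'
#' Checks the `cpg_id` / `gene_symbol` / `distance_to_tss` columns, drops
#' records farther than 1500 bp from a TSS (with a message giving the count),
#' and rejects empty gene symbols.
#'
#' @param ann data frame with columns `cpg_id`, `gene_symbol`,
#'   `distance_to_tss`.
#' @return The validated (possibly reduced) annotation data frame.
#' @export
validate_annotation <- function(ann) {
  need <- c("cpg_id", "gene_symbol", "distance_to_tss")
  if (!is.data.frame(ann) || !all(need %in% names(ann))) {
    stop("annotation must have columns ", paste(need, collapse = ", "))
  }
  if (any(is.na(ann$gene_symbol)) || any(!nzchar(trimws(ann$gene_symbol)))) {
    stop("annotation gene symbols must be non-empty")
  }
  if (any(ann$distance_to_tss < 0)) stop("distances to TSS must be non-negative")
  far <- ann$distance_to_tss > MAX_TSS_DISTANCE
  if (any(far)) {
    message(sum(far), " annotation records beyond ", MAX_TSS_DISTANCE,
            " bp of a TSS were rejected")
    ann <- ann[!far, , drop = FALSE]
  }
  ann
}

# filter a result table down to its significant rows
.significant_records <- function(records) {
  if (!is.data.frame(records)) records <- do.call(rbind, records)
  if ("significant" %in% names(records)) {
    records[records$significant, , drop = FALSE]
  } else {
    records
  }
}

#' Collect the unique genes implicated by significant CpGs
#'
#' Maps significant differential-methylation records to their annotated
#' genes and deduplicates: a gene with several contributing CpGs (possibly
#' of mixed direction) appears once in `genes`, with every contributing CpG
#' retained in `provenance`. Significant CpGs absent from the annotation are
#' excluded and counted.
#'
#' @param records a result data frame from [run_group_analysis()] (rows with
#'   `significant == TRUE` are used; a pre-filtered table without that
#'   column is taken as-is).
#' @param ann CpG annotation table; see [validate_annotation()].
#' @return An object of class `dag_set`: list with `group`, sorted unique
#'   `genes`, a `provenance` data frame (one row per contributing CpG), and
#'   `n_unannotated`.
#' @export
collect_dags <- function(records, ann) {
  ann <- validate_annotation(ann)
  rec <- .significant_records(records)
  group <- if (nrow(rec)) unique(rec$group)[1L] else NA_character_
  idx <- match(rec$cpg_id, ann$cpg_id)
  n_unannotated <- sum(is.na(idx))
  if (n_unannotated > 0L) {
    message(n_unannotated, " significant CpGs missing from the annotation were excluded")
  }
  keep <- !is.na(idx)
  prov <- data.frame(
    cpg_id = rec$cpg_id[keep],
    gene_symbol = ann$gene_symbol[idx[keep]],
    distance_to_tss = ann$distance_to_tss[idx[keep]],
    direction = if ("direction" %in% names(rec)) rec$direction[keep] else NA_character_,
    delta_beta = if ("delta_beta" %in% names(rec)) rec$delta_beta[keep] else NA_real_,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  structure(
    list(group = group,
         genes = sort(unique(prov$gene_symbol)),
         provenance = prov,
         n_unannotated = n_unannotated),
    class = "dag_set"
  )
}

#' @export
print.dag_set <- function(x, ...) {
  cat(sprintf("DAG set [%s]: %d unique genes from %d significant CpGs\n",
              x$group, length(x$genes), nrow(x$provenance)))
  invisible(x)
}

#' TSS-distance and direction proportions per group
#'
#' Summarises significant CpGs per group as the proportion falling in the
#' distance bins 0-500 bp (inclusive at 500), 501-1000 bp, and 1001-1500 bp
#' from the TSS, alongside the proportions of hyper- and hypomethylated
#' CpGs. Within each group the bin proportions sum to one, and so do the
#' direction proportions.
#'
#' @param records result data frame(s) from [run_group_analysis()]; several
#'   groups may be present.
#' @param ann CpG annotation table.
#' @return Data frame with one row per group: `group`, `n_cpg`,
#'   `prop_le500`, `prop_501_1000`, `prop_1001_1500`, `prop_hyper`,
#'   `prop_hypo`.
#' @export
tss_direction_summary <- function(records, ann) {
  ann <- validate_annotation(ann)
  rec <- .significant_records(records)
  rec <- rec[rec$cpg_id %in% ann$cpg_id, , drop = FALSE]
  groups <- unique(rec$group)
  rows <- lapply(groups, function(g) {
    rg <- rec[rec$group == g, , drop = FALSE]
    d <- ann$distance_to_tss[match(rg$cpg_id, ann$cpg_id)]
    n <- nrow(rg)
    data.frame(
      group = g,
      n_cpg = n,
      prop_le500 = mean(d <= 500),
      prop_501_1000 = mean(d > 500 & d <= 1000),
      prop_1001_1500 = mean(d > 1000 & d <= 1500),
      prop_hyper = mean(rg$direction == "hyper"),
      prop_hypo = mean(rg$direction == "hypo"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(group = character(0), n_cpg = integer(0),
                      prop_le500 = numeric(0), prop_501_1000 = numeric(0),
                      prop_1001_1500 = numeric(0), prop_hyper = numeric(0),
                      prop_hypo = numeric(0), stringsAsFactors = FALSE)
  }
  out
}

#' Direction-specific gene lists for TSS-proximal CpGs
#'
#' Splits the genes implicated by significant CpGs strictly closer than
#' `max_distance` to the TSS into a hypermethylated and a hypomethylated
#' list. The cut is strict (`distance < max_distance`), matching the
#' convention of "< 500 bp" gene tables; a gene with proximal CpGs in both
#' directions is emitted in both lists and flagged.
#'
#' @param records result data frame from [run_group_analysis()].
#' @param ann CpG annotation table.
#' @param max_distance strict upper bound on distance to TSS, in bp.
#' @return List with sorted character vectors `hyper` and `hypo`, plus
#'   `both` (genes present in the two lists).
#' @export
proximal_direction_lists <- function(records, ann, max_distance = 500L) {
  if (max_distance < 0) stop("'max_distance' must be non-negative")
  ann <- validate_annotation(ann)
  rec <- .significant_records(records)
  idx <- match(rec$cpg_id, ann$cpg_id)
  keep <- !is.na(idx) & ann$distance_to_tss[idx] < max_distance
  rec <- rec[keep, , drop = FALSE]
  gene <- ann$gene_symbol[idx[keep]]
  hyper <- sort(unique(gene[rec$direction == "hyper"]))
  hypo <- sort(unique(gene[rec$direction == "hypo"]))
  both <- intersect(hyper, hypo)
  if (length(both)) {
    message(length(both), " genes have proximal CpGs in both directions")
  }
  list(hyper = hyper, hypo = hypo, both = both)
}
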