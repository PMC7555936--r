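#' Simulate a clinical severity-score matrix with latent subgroups
#'
#' Generates an integer severity matrix (subjects x scores) emulating a
#' diagnostic-interview scoresheet in which three latent subgroups differ in
#' overall severity and, for the most severe subgroup, in a designated block
#' of language-related score columns. The default geometry is 123 scores over
#' 63 items with the ordinal alphabet `{1, 2, 3}`.
#'
#' Expected scores are built from per-subgroup profiles on the score scale:
#' the intermediate subgroup sits at the centre of the alphabet, the mild
#' subgroup is lowered by `separation / 2` on every score, and the severe
#' subgroup is raised by `separation` on the language scores only. Observed
#' scores are the profile plus Gaussian noise, rounded and clipped to the
#' alphabet. With `separation = 0` the three subgroups are exchangeable.
#'
#' @param n_per_subgroup integer vector of length 3 (mild, intermediate,
#'   severe) giving the number of subjects per latent subgroup.
#' @param n_items number of instrument items; scores map onto items cyclically
#'   (an item may contribute more than one score column).
#' @param n_scores number of score columns; must be `>= n_items`.
#' @param separation subgroup separation in units of the score scale;
#'   `0` removes all subgroup structure.
#' @param language_item_fraction fraction of score columns designated as
#'   language-related (the columns elevated in the severe subgroup).
#' @param alphabet ordered integer score alphabet; default `1:3`.
#' @param score_sd standard deviation of the Gaussian score noise before
#'   rounding, on the score scale.
#' @param seed integer seed; identical inputs give identical output.
#'
#' @return A list with elements:
#'   * `scores`: integer matrix (subjects x `n_scores`) with subject-id row
#'     names and score-id column names;
#'   * `truth`: data frame with `subject_id` and `true_subgroup`;
#'   * `language_items`: integer indices of the language score columns;
#'   * `item_of_score`: integer vector mapping each score column to its item.
#' @export
#' @examples
#' sev <- generate_severity_matrix(c(10, 10, 5), separation = 1, seed = 1)
#' dim(sev$scores)
#' table(sev$truth$true_subgroup)
generate_severity_matrix <- function(n_per_subgroup = c(mild = 149L, intermediate = 121L, severe = 22L),
                                     n_items = 63L,
                                     n_scores = 123L,
                                     separation = 1,
                                     language_item_fraction = 0.3,
                                     alphabet = 1:3,
                                     score_sd = 0.55,
                                     seed = 1L) {
  n_per_subgroup <- .per_subgroup(n_per_subgroup, "n_per_subgroup")
  if (any(n_per_subgroup < 1)) stop("all subgroup sizes must be positive")
  if (n_scores < n_items) stop("'n_scores' must be at least 'n_items'")
  if (separation < 0) stop("'separation' must be non-negative")
  if (language_item_fraction < 0 || language_item_fraction > 1) {
    stop("'language_item_fraction' must be in [0, 1]")
  }
  alphabet <- sort(as.integer(alphabet))

  set.seed(seed)
  n <- sum(n_per_subgroup)
  base <- mean(range(alphabet))
  n_lang <- max(1L, round(language_item_fraction * n_scores))
  language_items <- sort(sample.int(n_scores, n_lang))

  profiles <- matrix(base, nrow = 3L, ncol = n_scores,
                     dimnames = list(SUBGROUPS, NULL))
  profiles["mild", ] <- base - separation / 2
  profiles["severe", language_items] <- base + separation
  lo <- min(alphabet)
  hi <- max(alphabet)
  if (any(profiles < lo) || any(profiles > hi)) {
    warning("subgroup profile means fall outside the score alphabet; clipping")
    profiles <- pmin(pmax(profiles, lo), hi)
  }

  group <- rep(SUBGROUPS, times = n_per_subgroup)
  raw <- profiles[group, , drop = FALSE] +
    matrix(stats::rnorm(n * n_scores, sd = score_sd), nrow = n)
  scores <- matrix(as.integer(pmin(pmax(round(raw), lo), hi)), nrow = n)
  rownames(scores) <- sprintf("subj%04d", seq_len(n))
  colnames(scores) <- sprintf("score%03d", seq_len(n_scores))

  list(
    scores = scores,
    truth = data.frame(subject_id = rownames(scores),
                       true_subgroup = group,
                       stringsAsFactors = FALSE),
    language_items = language_items,
    item_of_score = ((seq_len(n_scores) - 1L) %% n_items) + 1L
  )
}

#' Describe the planted differential-methylation effect layout
#'
#' Bundles the parameters that govern which CpG loci carry a true
#' case-minus-control methylation difference in each subgroup, how large the
#' differences are, and in which direction.
#'
#' Per subgroup, the entry of `delta` may be either a single signed value
#' (used as-is for every effect locus of that subgroup) or a range
#' `c(lo, hi)` of effect magnitudes from which `|delta|` is drawn uniformly,
#' with the sign drawn hypomethylated (negative) with probability
#' `hypo_fraction`.
#'
#' @param n_effect integer vector (length 1 or 3, named mild/intermediate/
#'   severe) of planted effect loci per subgroup.
#' @param delta either a numeric vector recycled per subgroup, or a list with
#'   one entry per subgroup as described above. Values are on the beta scale.
#' @param hypo_fraction probability (length 1 or 3) that an effect locus is
#'   hypomethylated in cases; ignored for fixed signed `delta` entries.
#' @param layout `"disjoint"` gives each subgroup its own effect loci (and
#'   genes); `"shared"` plants one common set of loci with identical effects
#'   in every subgroup (requires equal `n_effect`).
#' @return An object of class `effect_config`.
#' @export
#' @examples
#' effect_config(n_effect = 50, delta = c(0.03, 0.08))
#' effect_config(n_effect = c(0, 0, 50), delta = list(severe = -0.08))
effect_config <- function(n_effect = c(mild = 50L, intermediate = 50L, severe = 50L),
                          delta = c(0.03, 0.08),
                          hypo_fraction = c(mild = 0.65, intermediate = 0.08, severe = 0.87),
                          layout = c("disjoint", "shared")) {
  layout <- match.arg(layout)
  n_effect <- .per_subgroup(as.integer(n_effect), "n_effect")
  if (any(n_effect < 0)) stop("'n_effect' entries must be non-negative")
  hypo_fraction <- .per_subgroup(hypo_fraction, "hypo_fraction")
  if (!is.list(delta)) delta <- list(mild = delta, intermediate = delta, severe = delta)
  missing_g <- setdiff(SUBGROUPS, names(delta))
  for (g in missing_g) delta[[g]] <- 0
  delta <- delta[SUBGROUPS]
  for (g in SUBGROUPS) {
    if (!length(delta[[g]]) %in% 1:2) {
      stop("each 'delta' entry must be a signed scalar or a magnitude range c(lo, hi)")
    }
  }
  if (layout == "shared" && length(unique(n_effect)) != 1L) {
    stop("'shared' layout requires equal 'n_effect' in every subgroup")
  }
  structure(list(n_effect = n_effect, delta = delta,
                 hypo_fraction = hypo_fraction, layout = layout),
            class = "effect_config")
}

# draw the signed per-locus effects for one subgroup
.draw_deltas <- function(spec, n, hypo_fraction) {
  if (n == 0L) return(numeric(0))
  if (length(spec) == 1L) return(rep(as.numeric(spec), n))
  mag <- stats::runif(n, min(spec), max(spec))
  sgn <- ifelse(stats::runif(n) < hypo_fraction, -1, 1)
  sgn * mag
}

#' Simulate paired case/control methylation beta matrices with ground truth
#'
#' Draws CpG-by-sample beta-value matrices for cases and their sibling
#' controls. Each CpG has a baseline methylation level `beta0`; cases in
#' subgroup *g* are shifted by that CpG's planted effect `delta_g` (zero for
#' null loci). Values are Gaussian on the beta scale around the group mean
#' and clipped to `clip` (the working range of array beta values).
#'
#' A companion annotation assigns every CpG one gene symbol and a
#' distance-to-TSS drawn from a mixture placing 65% of mass on 0-500 bp,
#' 30% on 501-1000 bp, and 5% on 1001-1500 bp, so that all CpGs fall within
#' 1500 bp of a TSS and more than 90% within 1000 bp. Effect loci receive
#' distinct gene symbols; null loci share the remaining genes (a gene may own
#' several CpGs).
#'
#' @param n_pairs integer vector (length 3, mild/intermediate/severe) of
#'   case-control sibling pairs per subgroup.
#' @param n_cpg number of CpG loci; must cover the planted effect loci.
#' @param effects an [effect_config()] describing the planted effects.
#' @param noise_sd standard deviation of the beta-scale noise.
#' @param beta0_range range from which per-CpG baselines are drawn uniformly.
#' @param n_genes number of distinct gene symbols; defaults to roughly one
#'   gene per two CpGs.
#' @param clip lower/upper clipping bounds for emitted beta values.
#' @param subject_ids optional case sample ids (length `sum(n_pairs)`,
#'   ordered mild, intermediate, severe) to align with an external severity
#'   matrix; controls get matching `sib` ids.
#' @param seed integer seed.
#'
#' @return A list with elements `case` and `control` (beta matrices, CpG x
#'   sample), `sample_sheet` (columns `sample_id`, `role`, `pair_id`,
#'   `subgroup`), `truth` (per-CpG baseline, per-subgroup signed effects and
#'   null flag), and `annotation` (columns `cpg_id`, `gene_symbol`,
#'   `distance_to_tss`).
#' @export
#' @examples
#' sim <- generate_paired_methylation(n_pairs = c(6, 6, 6), n_cpg = 200,
#'   effects = effect_config(n_effect = 10), seed = 1)
#' dim(sim$case)
generate_paired_methylation <- function(n_pairs = c(mild = 149L, intermediate = 121L, severe = 22L),
                                        n_cpg = 5000L,
                                        effects = effect_config(),
                                        noise_sd = 0.03,
                                        beta0_range = c(0.15, 0.85),
                                        n_genes = NULL,
                                        clip = c(0.001, 0.999),
                                        subject_ids = NULL,
                                        seed = 1L) {
  n_pairs <- .per_subgroup(as.integer(n_pairs), "n_pairs")
  if (any(n_pairs < 1)) stop("all subgroup pair counts must be positive")
  if (!inherits(effects, "effect_config")) stop("'effects' must be an effect_config()")
  n_cpg <- as.integer(n_cpg)
  if (n_cpg < 1L) stop("'n_cpg' must be positive")

  set.seed(seed)
  n_eff <- effects$n_effect
  shared <- effects$layout == "shared"
  n_eff_loci <- if (shared) n_eff[[1L]] else sum(n_eff)
  if (n_cpg < n_eff_loci) stop("'n_cpg' is smaller than the number of planted effect loci")

  # signed effect per CpG per subgroup (zero means null in that subgroup)
  delta <- matrix(0, nrow = n_cpg, ncol = 3L, dimnames = list(NULL, SUBGROUPS))
  if (shared) {
    if (n_eff_loci > 0L) {
      d <- .draw_deltas(effects$delta[["mild"]], n_eff_loci, effects$hypo_fraction[["mild"]])
      delta[seq_len(n_eff_loci), ] <- d
    }
  } else {
    offset <- 0L
    for (g in SUBGROUPS) {
      if (n_eff[[g]] > 0L) {
        idx <- offset + seq_len(n_eff[[g]])
        delta[idx, g] <- .draw_deltas(effects$delta[[g]], n_eff[[g]], effects$hypo_fraction[[g]])
        offset <- offset + n_eff[[g]]
      }
    }
  }

  cpg_id <- sprintf("cg%06d", seq_len(n_cpg))
  n_genes <- as.integer(n_genes %||% max(ceiling(n_cpg / 2), n_eff_loci + 1L))
  if (n_genes < n_eff_loci) stop("'n_genes' must cover the planted effect loci")
  gene_pool <- sprintf("GENE%05d", seq_len(n_genes))
  gene_of <- character(n_cpg)
  gene_of[seq_len(n_eff_loci)] <- gene_pool[seq_len(n_eff_loci)]
  n_null <- n_cpg - n_eff_loci
  if (n_null > 0L) {
    null_genes <- if (n_genes > n_eff_loci) {
      gene_pool[(n_eff_loci + 1L):n_genes]
    } else {
      gene_pool
    }
    gene_of[(n_eff_loci + 1L):n_cpg] <- sample(null_genes, n_null, replace = TRUE)
  }

  # distance-to-TSS mixture: 65% within 500 bp, 30% in 501-1000, 5% in 1001-1500
  u <- stats::runif(n_cpg)
  dist_tss <- integer(n_cpg)
  b1 <- u < 0.65
  b2 <- !b1 & u < 0.95
  b3 <- !b1 & !b2
  dist_tss[b1] <- as.integer(round(stats::runif(sum(b1), 0, 500)))
  dist_tss[b2] <- as.integer(round(stats::runif(sum(b2), 501, 1000)))
  dist_tss[b3] <- as.integer(round(stats::runif(sum(b3), 1001, 1500)))

  beta0 <- stats::runif(n_cpg, beta0_range[1L], beta0_range[2L])
  case_mean <- beta0 + delta   # n_cpg x 3
  margin <- c(clip[1L], clip[2L])
  if (any(case_mean < margin[1L]) || any(case_mean > margin[2L])) {
    warning("some planted effects push case means outside the beta range; clipping means")
    case_mean <- pmin(pmax(case_mean, margin[1L]), margin[2L])
  }

  n_total <- sum(n_pairs)
  subgroup_of_pair <- rep(SUBGROUPS, times = n_pairs)
  if (is.null(subject_ids)) {
    subject_ids <- sprintf("case%04d", seq_len(n_total))
  } else if (length(subject_ids) != n_total) {
    stop("'subject_ids' must have one id per case-control pair")
  }
  control_ids <- paste0(subject_ids, "_sib")
  pair_ids <- sprintf("pair%04d", seq_len(n_total))

  draw <- function(mean_mat) {
    noise <- matrix(stats::rnorm(n_cpg * n_total, sd = noise_sd), nrow = n_cpg)
    pmin(pmax(mean_mat + noise, clip[1L]), clip[2L])
  }
  case <- draw(case_mean[, subgroup_of_pair, drop = FALSE])
  control <- draw(matrix(beta0, nrow = n_cpg, ncol = n_total))
  dimnames(case) <- list(cpg_id, subject_ids)
  dimnames(control) <- list(cpg_id, control_ids)

  sample_sheet <- data.frame(
    sample_id = c(subject_ids, control_ids),
    role = rep(c("case", "control"), each = n_total),
    pair_id = c(pair_ids, pair_ids),
    subgroup = c(subgroup_of_pair, subgroup_of_pair),
    stringsAsFactors = FALSE
  )

  truth <- data.frame(
    cpg_id = cpg_id,
    gene_symbol = gene_of,
    beta0 = beta0,
    delta_mild = delta[, "mild"],
    delta_intermediate = delta[, "intermediate"],
    delta_severe = delta[, "severe"],
    is_null = rowSums(delta != 0) == 0L,
    stringsAsFactors = FALSE
  )

  annotation <- data.frame(
    cpg_id = cpg_id,
    gene_symbol = gene_of,
    distance_to_tss = dist_tss,
    stringsAsFactors = FALSE
  )

  list(case = case, control = control, sample_sheet = sample_sheet,
       truth = truth, annotation = annotation)
}

#' Gene symbols carrying a planted effect
#'
#' @param truth the `truth` table returned by [generate_paired_methylation()].
#' @param subgroup optional subgroup name; default pools all subgroups.
#' @return Character vector of unique gene symbols with a non-zero effect.
#' @export
true_effect_genes <- function(truth, subgroup = NULL) {
  cols <- paste0("delta_", subgroup %||% SUBGROUPS)
  hit <- rowSums(abs(as.matrix(truth[, cols, drop = FALSE])) > 0) > 0
  sort(unique(truth$gene_symbol[hit]))
}

#' Simulate a gene-set database, optionally with a planted set
#'
#' Draws `n_sets` gene sets uniformly from a gene universe. When
#' `planted_set` is supplied, the first set (named `"planted"`) equals it
#' exactly, which supports enrichment power tests against known signal.
#'
#' @param gene_universe character vector of gene symbols (the reference
#'   population for enrichment).
#' @param n_sets number of random sets to draw.
#' @param set_size_range integer pair giving the inclusive range of set sizes.
#' @param planted_set optional character vector; must lie in the universe.
#' @param seed integer seed; identical inputs give identical databases.
#' @return A [geneset_db()] object.
#' @export
generate_genesets <- function(gene_universe, n_sets = 10L,
                              set_size_range = c(10L, 50L),
                              planted_set = NULL, seed = 1L) {
  gene_universe <- unique(trimws(gene_universe))
  if (!length(gene_universe)) stop("'gene_universe' must be non-empty")
  set_size_range <- as.integer(range(set_size_range))
  if (set_size_range[2L] > length(gene_universe)) {
    stop("set sizes cannot exceed the universe size")
  }
  set.seed(seed)
  sets <- list()
  if (!is.null(planted_set)) {
    planted_set <- unique(trimws(planted_set))
    if (!all(planted_set %in% gene_universe)) {
      stop("'planted_set' must be a subset of the gene universe")
    }
    sets[["planted"]] <- planted_set
  }
  if (n_sets > 0L) {
    sizes <- if (set_size_range[1L] == set_size_range[2L]) {
      rep(set_size_range[1L], n_sets)
    } else {
      sample(seq(set_size_range[1L], set_size_range[2L]), n_sets, replace = TRUE)
    }
    for (i in seq_len(n_sets)) {
      sets[[sprintf("set%03d", i)]] <- sort(sample(gene_universe, sizes[i]))
    }
  }
  geneset_db(sets, gene_universe)
}

#' Simulate a differentially-expressed-gene list overlapping known signal
#'
#' Builds a plain gene list in which a configurable fraction of entries is
#' drawn from a supplied set of true signal genes and the remainder from the
#' rest of the universe, for exercising hypergeometric overlap tests.
#'
#' @param signal_genes genes considered true signal (e.g. planted effect
#'   genes).
#' @param gene_universe full gene universe.
#' @param n_deg number of genes in the emitted list.
#' @param overlap_fraction fraction of the list drawn from `signal_genes`.
#' @param seed integer seed.
#' @return Character vector of unique gene symbols.
#' @export
generate_deg_list <- function(signal_genes, gene_universe, n_deg = 50L,
                              overlap_fraction = 0.5, seed = 1L) {
  signal_genes <- intersect(unique(signal_genes), gene_universe)
  background <- setdiff(gene_universe, signal_genes)
  n_deg <- as.integer(n_deg)
  n_sig <- min(length(signal_genes), round(overlap_fraction * n_deg))
  n_bg <- min(length(background), n_deg - n_sig)
  set.seed(seed)
  sort(c(sample(signal_genes, n_sig), sample(background, n_bg)))
}
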