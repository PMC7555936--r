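# DiffScore magnitudes are capped so the p-value transform never underflows:
# |DiffScore| <= 350 corresponds to p >= 1e-35.
DIFFSCORE_CAP <- 350
P_FLOOR <- 10^(-DIFFSCORE_CAP / 10)

#' Beta value from methylated/unmethylated probe intensities
#'
#' The methylation fraction at a CpG is `beta = M / (M + U + 100)`, where `M`
#' and `U` are the methylated- and unmethylated-probe signals; the constant
#' offset of 100 stabilises the ratio at low intensities, so the value lies
#' in `[0, 1)`.
#'
#' @param M,U non-negative numeric vectors of probe intensities.
#' @return Numeric vector of beta values.
#' @export
#' @examples
#' compute_beta(900, 0)   # 0.9
#' compute_beta(450, 450) # 0.45
compute_beta <- function(M, U) {
  if (any(!is.finite(M)) || any(!is.finite(U))) {
    stop("probe intensities must be finite")
  }
  if (any(M < 0) || any(U < 0)) stop("probe intensities must be non-negative")
  M / (M + U + 100)
}

#' Convert between DiffScore magnitude and p-value
#'
#' The differential methylation score maps to a two-sided p-value through
#' `p = 10^(-|DiffScore| / 10)`; the magnitude at `p = 0.05` is 13.0103.
#'
#' @param diffscore numeric vector of (possibly signed) DiffScores.
#' @param p numeric vector of p-values in `(0, 1]`.
#' @param delta_beta optional numeric vector whose sign is attached to the
#'   returned DiffScore; omitted, the unsigned magnitude is returned.
#' @return `diffscore_to_p()` returns p-values; `p_to_diffscore()` returns
#'   DiffScores.
#' @export
#' @examples
#' p_to_diffscore(0.05) # 13.0103
#' diffscore_to_p(13.0103)
diffscore_to_p <- function(diffscore) 10^(-abs(diffscore) / 10)

#' @rdname diffscore_to_p
#' @export
p_to_diffscore <- function(p, delta_beta = NULL) {
  if (any(p <= 0 | p > 1)) stop("p-values must be in (0, 1]")
  mag <- pmin(-10 * log10(p), DIFFSCORE_CAP)
  if (is.null(delta_beta)) mag else sign(delta_beta) * mag
}

# vectorised two-group test on mean beta values. m/v are per-CpG group means
# and variances; the variance floor is a technical-error term added in
# quadrature to the pooled standard error so zero-variance probes never
# divide by zero.
.diffmeth_stat <- function(m1, m2, v1, v2, n1, n2, variance_floor,
                           df_method = c("welch", "normal")) {
  df_method <- match.arg(df_method)
  delta <- m1 - m2
  a1 <- v1 / n1
  a2 <- v2 / n2
  se2 <- a1 + a2 + variance_floor^2
  tstat <- numeric(length(delta))
  pos <- se2 > 0
  tstat[pos] <- delta[pos] / sqrt(se2[pos])
  tstat[!pos & delta != 0] <- Inf * sign(delta[!pos & delta != 0])
  if (df_method == "welch") {
    df <- se2^2 / (a1^2 / (n1 - 1) + a2^2 / (n2 - 1))
    df[!is.finite(df)] <- n1 + n2 - 2   # variance dominated by the floor
    p <- 2 * stats::pt(-abs(tstat), df)
  } else {
    p <- 2 * stats::pnorm(-abs(tstat))
  }
  p <- pmin(pmax(p, P_FLOOR), 1)
  diffscore <- -10 * sign(delta) * log10(p)
  list(delta_beta = delta, diffscore = diffscore, p = p)
}

#' DiffScore test for one CpG
#'
#' Tests the difference in mean beta value between case and control samples
#' under the model that beta values are normally distributed among
#' biological replicates. The standard error of the difference is
#' `sqrt(s1^2/n1 + s2^2/n2 + floor^2)`, where the variance floor is a small
#' technical-error term that keeps degenerate zero-variance probes testable.
#' The p-value is two-sided, by default against a t reference with
#' Welch-Satterthwaite degrees of freedom (`df_method = "normal"` uses a
#' plain z reference). The signed score is
#' `DiffScore = -10 * sign(delta_beta) * log10(p)`, capped at magnitude 350,
#' so `p = 10^(-|DiffScore|/10)` holds exactly for every result.
#'
#' @param case_betas,control_betas numeric vectors of beta values in
#'   `[0, 1]`, each of length >= 2.
#' @param variance_floor technical-error standard deviation added in
#'   quadrature to the pooled standard error.
#' @param df_method reference distribution for the p-value.
#' @return A list with `delta_beta` (case mean minus control mean),
#'   `diffscore`, and `p`.
#' @export
#' @examples
#' diffscore_test(c(0.7, 0.72, 0.71), c(0.60, 0.62, 0.61))
diffscore_test <- function(case_betas, control_betas, variance_floor = 1e-4,
                           df_method = c("welch", "normal")) {
  df_method <- match.arg(df_method)
  for (v in list(case_betas, control_betas)) {
    if (length(v) < 2L) stop("each group needs at least 2 samples")
    if (any(!is.finite(v)) || any(v < 0 | v > 1)) {
      stop("beta values must lie in [0, 1]")
    }
  }
  if (variance_floor < 0) stop("'variance_floor' must be non-negative")
  res <- .diffmeth_stat(mean(case_betas), mean(control_betas),
                        stats::var(case_betas), stats::var(control_betas),
                        length(case_betas), length(control_betas),
                        variance_floor, df_method)
  list(delta_beta = res$delta_beta, diffscore = res$diffscore, p = res$p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false discovery rate adjustment; a wrapper around
#' [stats::p.adjust()] with input validation. An empty input returns an
#' empty vector.
#'
#' @param p_values numeric vector of p-values in `(0, 1]`.
#' @return Numeric vector of q-values of the same length.
#' @export
fdr_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must be in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Differential methylation analysis per subgroup or pooled
#'
#' Runs the DiffScore test for every CpG, either within each phenotypic
#' subgroup separately (`mode = "stratified"`, FDR applied within each
#' stratum) or over all case and control samples at once
#' (`mode = "combined"`). The default comparison is unpaired; `paired = TRUE`
#' instead tests the within-pair case-minus-control differences against zero
#' using the `pair_id` column of the sample sheet.
#'
#' Strata with fewer than 2 case or 2 control samples are skipped with a
#' warning. Direction is `hyper` for positive delta beta, `hypo` for
#' negative, `null` for exactly zero.
#'
#' @param case,control beta matrices (CpG x sample) whose column names are
#'   sample ids present in the sample sheet.
#' @param sample_sheet data frame with columns `sample_id`, `role`
#'   (`case`/`control`), `subgroup`, and (for paired tests) `pair_id`.
#' @param mode `"stratified"` or `"combined"`.
#' @param alpha FDR significance threshold; records with `fdr_q < alpha` are
#'   flagged significant.
#' @param variance_floor,df_method passed to the per-CpG test; see
#'   [diffscore_test()].
#' @param paired use the within-pair test.
#' @param annotation optional annotation table (`cpg_id`, `gene_symbol`, ...)
#'   used to attach gene symbols.
#' @return Named list of per-group data frames (one per stratum, or one
#'   element `combined`) with columns `cpg_id`, `group`, `gene_symbol` (if
#'   annotated), `mean_beta_case`, `mean_beta_control`, `delta_beta`,
#'   `diffscore`, `p_value`, `fdr_q`, `direction`, `fold_change`, and
#'   `significant`.
#' @export
run_group_analysis <- function(case, control, sample_sheet,
                               mode = c("stratified", "combined"),
                               alpha = 0.05, variance_floor = 1e-4,
                               df_method = c("welch", "normal"),
                               paired = FALSE, annotation = NULL) {
  mode <- match.arg(mode)
  df_method <- match.arg(df_method)
  .check_matrix(case, "case")
  .check_matrix(control, "control")
  need <- c("sample_id", "role", "subgroup")
  if (paired) need <- c(need, "pair_id")
  if (!all(need %in% names(sample_sheet))) {
    stop("sample sheet must have columns ", paste(need, collapse = ", "))
  }
  if (!all(sample_sheet$role %in% c("case", "control"))) {
    stop("sample roles must be 'case' or 'control'")
  }
  if (!identical(rownames(case), rownames(control))) {
    stop("case and control matrices must share the same CpG rows")
  }

  strata <- if (mode == "combined") {
    list(combined = sample_sheet)
  } else {
    found <- intersect(SUBGROUPS, unique(sample_sheet$subgroup))
    if (!length(found)) found <- sort(unique(sample_sheet$subgroup))
    stats::setNames(
      lapply(found, function(g) sample_sheet[sample_sheet$subgroup == g, , drop = FALSE]),
      found
    )
  }

  out <- list()
  for (g in names(strata)) {
    sheet_g <- strata[[g]]
    case_ids <- intersect(colnames(case), sheet_g$sample_id[sheet_g$role == "case"])
    ctrl_ids <- intersect(colnames(control), sheet_g$sample_id[sheet_g$role == "control"])
    if (length(case_ids) < 2L || length(ctrl_ids) < 2L) {
      warning(sprintf("stratum '%s' skipped: fewer than 2 case or control samples", g))
      next
    }
    X <- case[, case_ids, drop = FALSE]
    Y <- control[, ctrl_ids, drop = FALSE]
    m1 <- rowMeans(X)
    m2 <- rowMeans(Y)
    if (paired) {
      pair_of <- stats::setNames(sheet_g$pair_id, sheet_g$sample_id)
      ctrl_by_pair <- stats::setNames(ctrl_ids, pair_of[ctrl_ids])
      mate <- ctrl_by_pair[pair_of[case_ids]]
      keep <- !is.na(mate)
      if (sum(keep) < 2L) {
        warning(sprintf("stratum '%s' skipped: fewer than 2 complete pairs", g))
        next
      }
      D <- X[, keep, drop = FALSE] - Y[, mate[keep], drop = FALSE]
      n <- ncol(D)
      md <- rowMeans(D)
      se2 <- .row_vars(D) / n + variance_floor^2
      tstat <- md / sqrt(se2)
      p <- if (df_method == "welch") 2 * stats::pt(-abs(tstat), n - 1L) else 2 * stats::pnorm(-abs(tstat))
      p <- pmin(pmax(p, P_FLOOR), 1)
      res <- list(delta_beta = md, p = p,
                  diffscore = -10 * sign(md) * log10(p))
    } else {
      res <- .diffmeth_stat(m1, m2, .row_vars(X), .row_vars(Y),
                            ncol(X), ncol(Y), variance_floor, df_method)
    }
    q <- fdr_adjust(res$p)
    rec <- data.frame(
      cpg_id = rownames(case),
      group = g,
      mean_beta_case = m1,
      mean_beta_control = m2,
      delta_beta = res$delta_beta,
      diffscore = res$diffscore,
      p_value = res$p,
      fdr_q = q,
      direction = ifelse(res$delta_beta > 0, "hyper",
                         ifelse(res$delta_beta < 0, "hypo", "null")),
      fold_change = m1 / m2,
      significant = q < alpha,
      row.names = NULL,
      stringsAsFactors = FALSE
    )
    if (!is.null(annotation)) {
      rec$gene_symbol <- annotation$gene_symbol[match(rec$cpg_id, annotation$cpg_id)]
    }
    out[[g]] <- rec
  }
  if (!length(out)) stop("no stratum had enough samples to analyse")
  attr(out, "alpha") <- alpha
  out
}

#' Volcano-plot table of |DiffScore| against delta beta
#'
#' @param records one per-group result data frame from
#'   [run_group_analysis()], or a list of them (rows are concatenated).
#' @param alpha significance threshold applied to `fdr_q` when the records
#'   carry no `significant` column.
#' @return Data frame with one row per input record: `cpg_id`, `group`,
#'   `delta_beta`, `abs_diffscore`, `significant`.
#' @export
volcano_table <- function(records, alpha = 0.05) {
  if (is.data.frame(records)) records <- list(records)
  rec <- do.call(rbind, records)
  if (is.null(rec) || !nrow(rec)) stop("'records' must be non-empty")
  sig <- if ("significant" %in% names(rec)) rec$significant else rec$fdr_q < alpha
  data.frame(
    cpg_id = rec$cpg_id,
    group = rec$group,
    delta_beta = rec$delta_beta,
    abs_diffscore = abs(rec$diffscore),
    significant = sig,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
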