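test_that("beta values follow the offset ratio of probe intensities", {
  expect_identical(compute_beta(0, 0), 0)
  expect_identical(compute_beta(900, 0), 0.9)
  expect_identical(compute_beta(450, 450), 0.45)
  expect_equal(compute_beta(c(0, 900), c(0, 0)), c(0, 0.9))
  expect_error(compute_beta(-1, 5), "non-negative")
  expect_error(compute_beta(Inf, 5), "finite")
})

test_that("DiffScore and p-value are exact inverses with the documented threshold", {
  expect_equal(p_to_diffscore(0.05), 13.0103, tolerance = 1e-4)
  expect_equal(diffscore_to_p(13.0103), 0.05, tolerance = 1e-5)
  p <- c(1, 0.5, 0.05, 1e-10, 1e-30)
  expect_equal(diffscore_to_p(p_to_diffscore(p)), p, tolerance = 1e-12)
  # signed variant carries the delta-beta sign
  expect_equal(p_to_diffscore(0.05, delta_beta = -0.1), -13.0103, tolerance = 1e-4)
  expect_error(p_to_diffscore(0), "\\(0, 1\\]")
})

test_that("the per-CpG test behaves at the null identity and enforces the transform", {
  x <- c(0.4, 0.45, 0.5, 0.42)
  null <- diffscore_test(x, x)
  expect_identical(null$delta_beta, 0)
  expect_identical(null$p, 1)
  expect_identical(null$diffscore, 0)

  set.seed(1)
  for (i in 1:50) {
    a <- runif(5, 0.2, 0.8)
    b <- runif(5, 0.2, 0.8)
    r <- diffscore_test(a, b)
    expect_equal(10^(-abs(r$diffscore) / 10), r$p, tolerance = 1e-9)
    if (r$delta_beta != 0) expect_identical(sign(r$diffscore), sign(r$delta_beta))
  }

  # zero-variance probes are saved by the variance floor, never divide by zero
  r0 <- diffscore_test(c(0.5, 0.5, 0.5), c(0.4, 0.4, 0.4))
  expect_true(is.finite(r0$diffscore))
  expect_lte(abs(r0$diffscore), 350)
  expect_gte(r0$p, 1e-35)

  expect_error(diffscore_test(0.5, c(0.4, 0.5)), "at least 2")
  expect_error(diffscore_test(c(1.2, 0.5), c(0.4, 0.5)), "\\[0, 1\\]")
})

test_that("|DiffScore| grows with effect size and sample size at fixed noise", {
  base <- seq(-1.5, 1.5, length.out = 6) * 0.02 + 0.5
  mk <- function(shift, reps = 1) rep(base + shift, reps)
  d1 <- abs(diffscore_test(mk(0.02), mk(0))$diffscore)
  d2 <- abs(diffscore_test(mk(0.05), mk(0))$diffscore)
  d3 <- abs(diffscore_test(mk(0.08), mk(0))$diffscore)
  expect_true(d1 < d2 && d2 < d3)
  n1 <- abs(diffscore_test(mk(0.03, 1), mk(0, 1))$diffscore)
  n2 <- abs(diffscore_test(mk(0.03, 4), mk(0, 4))$diffscore)
  n3 <- abs(diffscore_test(mk(0.03, 10), mk(0, 10))$diffscore)
  expect_true(n1 < n2 && n2 < n3)
})

test_that("model p-values agree with the exhaustive permutation oracle", {
  set.seed(2)
  diffs <- replicate(20, {
    x <- pmin(pmax(0.5 + rnorm(8, sd = 0.03), 0.001), 0.999)
    y <- pmin(pmax(0.5 + rnorm(8, sd = 0.03), 0.001), 0.999)
    abs(diffscore_test(x, y)$p - perm_p_exhaustive(x, y))
  })
  expect_gte(mean(diffs <= 0.02), 0.9)
})

test_that("FDR adjustment reproduces the Benjamini-Hochberg step-up", {
  expect_identical(fdr_adjust(numeric(0)), numeric(0))
  expect_identical(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4), tolerance = 1e-12)
  expect_identical(fdr_adjust(rep(1, 5)), rep(1, 5))
  set.seed(3)
  p <- runif(200)
  expect_equal(fdr_adjust(p), bh_stepup(p), tolerance = 1e-12)
  expect_error(fdr_adjust(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("group analysis stratifies, applies FDR within stratum, and skips tiny strata", {
  sim <- generate_paired_methylation(
    n_pairs = c(mild = 10L, intermediate = 10L, severe = 22L), n_cpg = 800,
    effects = effect_config(n_effect = c(mild = 0L, intermediate = 0L, severe = 40L),
                            delta = list(severe = -0.08)),
    seed = 4
  )
  strat <- run_group_analysis(sim$case, sim$control, sim$sample_sheet, "stratified",
                              annotation = sim$annotation)
  expect_setequal(names(strat), c("mild", "intermediate", "severe"))
  for (g in names(strat)) {
    r <- strat[[g]]
    expect_identical(nrow(r), 800L)
    expect_equal(r$fdr_q, fdr_adjust(r$p_value), tolerance = 1e-12)
    expect_true(all(r$fdr_q >= r$p_value - 1e-12))
    expect_equal(10^(-abs(r$diffscore) / 10), r$p_value, tolerance = 1e-9)
    expect_identical(r$direction,
                     ifelse(r$delta_beta > 0, "hyper",
                            ifelse(r$delta_beta < 0, "hypo", "null")))
  }
  # planted severe hypomethylation is recovered with high power
  eff <- sim$truth$cpg_id[!sim$truth$is_null]
  sev <- strat$severe
  expect_gte(mean(sev$significant[match(eff, sev$cpg_id)]), 0.8)
  expect_true(all(sev$delta_beta[match(eff, sev$cpg_id)] < 0))

  # a stratum below the minimum size is skipped with a warning
  sheet_small <- sim$sample_sheet
  drop <- sheet_small$subgroup == "mild" &
    sheet_small$pair_id %in% unique(sheet_small$pair_id[sheet_small$subgroup == "mild"])[1:9]
  expect_warning(
    res <- run_group_analysis(sim$case[, , drop = FALSE], sim$control,
                              sheet_small[!drop, , drop = FALSE], "stratified"),
    "skipped"
  )
  expect_false("mild" %in% names(res))

  comb <- run_group_analysis(sim$case, sim$control, sim$sample_sheet, "combined")
  expect_named(comb, "combined")
  expect_identical(nrow(comb$combined), 800L)
})

test_that("paired testing uses within-pair differences", {
  sim <- generate_paired_methylation(
    n_pairs = c(mild = 8L, intermediate = 8L, severe = 8L), n_cpg = 200,
    effects = effect_config(n_effect = c(8L, 8L, 8L), delta = c(0.05, 0.08)),
    seed = 5
  )
  up <- run_group_analysis(sim$case, sim$control, sim$sample_sheet, "combined")
  pp <- run_group_analysis(sim$case, sim$control, sim$sample_sheet, "combined",
                           paired = TRUE)
  # same point estimate either way (balanced complete pairs), valid transform
  expect_equal(pp$combined$delta_beta, up$combined$delta_beta, tolerance = 1e-12)
  expect_equal(10^(-abs(pp$combined$diffscore) / 10), pp$combined$p_value,
               tolerance = 1e-9)
})

test_that("the volcano table mirrors records and flags near-threshold q-values", {
  rec <- data.frame(
    cpg_id = c("cg1", "cg2", "cg3"),
    group = "combined",
    delta_beta = c(0.1, 0, -0.2),
    diffscore = c(20, 0, -30),
    p_value = c(0.01, 1, 0.001),
    fdr_q = c(0.049, 1, 0.051),
    stringsAsFactors = FALSE
  )
  v <- volcano_table(rec)
  expect_identical(nrow(v), 3L)
  expect_identical(v$significant, c(TRUE, FALSE, FALSE))
  expect_identical(v$abs_diffscore, c(20, 0, 30))
  expect_identical(v$abs_diffscore[v$delta_beta == 0], 0)
  expect_error(volcano_table(rec[0, ]), "non-empty")
})
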