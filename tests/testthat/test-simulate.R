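test_that("severity generator honours sizes, alphabet, and determinism", {
  sev <- generate_severity_matrix(c(mild = 149L, intermediate = 121L, severe = 22L),
                                  n_scores = 123L, seed = 1)
  expect_identical(dim(sev$scores), c(292L, 123L))
  expect_true(all(sev$scores %in% 1:3))
  expect_identical(as.vector(table(sev$truth$true_subgroup)[c("mild", "intermediate", "severe")]),
                   c(149L, 121L, 22L))
  expect_identical(anyDuplicated(sev$truth$subject_id), 0L)

  again <- generate_severity_matrix(c(mild = 149L, intermediate = 121L, severe = 22L),
                                    n_scores = 123L, seed = 1)
  expect_identical(sev, again)

  expect_error(generate_severity_matrix(c(0, 5, 5)), "positive")
  expect_error(generate_severity_matrix(n_items = 63, n_scores = 50), "n_items")
  expect_warning(generate_severity_matrix(c(5, 5, 5), separation = 2, seed = 1),
                 "clipping")
})

test_that("zero separation removes subgroup structure from severity scores", {
  sev <- generate_severity_matrix(c(40, 40, 40), separation = 0, seed = 2)
  a <- kmeans_subtype(sev$scores, K = 3, seed = 2)
  ari <- adjusted_rand_index(a$cluster, sev$truth$true_subgroup)
  expect_lt(abs(ari), 0.1)
})

test_that("methylation generator bookkeeping: truth, pairing, annotation", {
  sim <- generate_paired_methylation(n_pairs = c(5, 5, 5), n_cpg = 300,
                                     effects = effect_config(n_effect = 10L),
                                     seed = 3)
  expect_identical(dim(sim$case), c(300L, 15L))
  expect_identical(dim(sim$control), c(300L, 15L))
  expect_true(all(sim$case > 0 & sim$case < 1))
  # every CpG has exactly one truth row and one annotation row
  expect_identical(sim$truth$cpg_id, rownames(sim$case))
  expect_identical(anyDuplicated(sim$truth$cpg_id), 0L)
  expect_identical(sim$annotation$cpg_id, sim$truth$cpg_id)
  expect_setequal(unique(sim$truth$gene_symbol), unique(sim$annotation$gene_symbol))
  # pairing is complete: every pair id has one case and one control
  tab <- table(sim$sample_sheet$pair_id, sim$sample_sheet$role)
  expect_true(all(tab == 1L))
  # disjoint layout keeps per-subgroup effect genes disjoint
  eff <- lapply(c("mild", "intermediate", "severe"),
                function(g) true_effect_genes(sim$truth, g))
  expect_length(unlist(eff), 30L)
  expect_identical(anyDuplicated(unlist(eff)), 0L)

  again <- generate_paired_methylation(n_pairs = c(5, 5, 5), n_cpg = 300,
                                       effects = effect_config(n_effect = 10L),
                                       seed = 3)
  expect_identical(sim, again)
  expect_error(generate_paired_methylation(n_pairs = c(2, 2, 2), n_cpg = 0), "positive")
  expect_error(generate_paired_methylation(n_pairs = c(2, 2, 2), n_cpg = 5,
                                           effects = effect_config(n_effect = 10L)),
               "smaller")
})

test_that("TSS distance sampler stays within 1500 bp with >90% inside 1000 bp", {
  d <- unlist(lapply(1:20, function(s) {
    generate_paired_methylation(n_pairs = c(2, 2, 2), n_cpg = 500,
                                effects = effect_config(n_effect = 0L),
                                seed = s)$annotation$distance_to_tss
  }))
  expect_true(all(d >= 0 & d <= 1500))
  expect_gt(mean(d <= 1000), 0.9)
})

test_that("planted effects reproduce the requested mean delta beta", {
  # Monte-Carlo mean-recovery: fixed signed effect of -0.08 in the severe
  # subgroup, 22 pairs, averaged over 200 replicates
  deltas <- vapply(1:200, function(s) {
    sim <- generate_paired_methylation(
      n_pairs = c(mild = 2L, intermediate = 2L, severe = 22L), n_cpg = 100,
      effects = effect_config(n_effect = c(mild = 0L, intermediate = 0L, severe = 50L),
                              delta = list(severe = -0.08)),
      noise_sd = 0.03, seed = s
    )
    sheet <- sim$sample_sheet
    ca <- sheet$sample_id[sheet$role == "case" & sheet$subgroup == "severe"]
    co <- sheet$sample_id[sheet$role == "control" & sheet$subgroup == "severe"]
    eff <- !sim$truth$is_null
    mean(rowMeans(sim$case[eff, ca]) - rowMeans(sim$control[eff, co]))
  }, numeric(1))
  expect_lt(abs(mean(deltas) - (-0.08)), 0.01)
})

test_that("global-null methylation data yield uniform-looking p-values", {
  sim <- null_methylation(seed = 7, n_cpg = 2000L)
  res <- run_group_analysis(sim$case, sim$control, sim$sample_sheet, "combined")
  p <- res$combined$p_value
  frac <- mean(p < 0.05)
  bound <- 2.58 * sqrt(0.05 * 0.95 / length(p))  # binomial 99% bounds
  expect_lt(abs(frac - 0.05), bound + 1e-12)
})

test_that("gene-set generator plants sets, respects sizes, and is reproducible", {
  uni <- sprintf("G%03d", 1:200)
  db <- generate_genesets(uni, n_sets = 4, set_size_range = c(5, 5),
                          planted_set = uni[1:10], seed = 9)
  expect_s3_class(db, "geneset_db")
  expect_identical(db$sets[["planted"]], uni[1:10])
  expect_true(all(lengths(db$sets[names(db$sets) != "planted"]) == 5L))
  expect_true(all(unlist(db$sets) %in% db$universe))

  f1 <- tempfile(fileext = ".gmt")
  f2 <- tempfile(fileext = ".gmt")
  write_gmt(db, f1)
  write_gmt(generate_genesets(uni, n_sets = 4, set_size_range = c(5, 5),
                              planted_set = uni[1:10], seed = 9), f2)
  expect_identical(readLines(f1), readLines(f2))

  back <- read_gmt(f1, universe = uni)
  expect_identical(back$sets, db$sets)
  expect_error(generate_genesets(character(0)), "non-empty")
  expect_error(generate_genesets(uni[1:3], set_size_range = c(5, 5)), "universe")
})
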