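test_that("K-means separates exactly duplicated row blocks with zero within-ss", {
  block <- function(v, n) matrix(rep(v, each = n), nrow = n)
  m <- rbind(block(c(1, 1, 1, 1), 4), block(c(2, 2, 2, 2), 4), block(c(3, 3, 3, 3), 4))
  rownames(m) <- sprintf("s%02d", 1:12)
  a <- kmeans_subtype(m, K = 3, seed = 1)
  expect_identical(a$tot_withinss, 0)
  expect_identical(length(unique(a$cluster[1:4])), 1L)
  expect_identical(length(unique(a$cluster[5:8])), 1L)
  expect_identical(length(unique(a$cluster[9:12])), 1L)
  expect_identical(length(unique(a$cluster[c(1, 5, 9)])), 3L)
  expect_error(kmeans_subtype(m[c(1, 1, 2), ], K = 3), "distinct")
})

test_that("K-means assignment is a fixed point of nearest-centroid reassignment", {
  sev <- generate_severity_matrix(c(20, 20, 10), separation = 0.5, seed = 4)
  a <- kmeans_subtype(sev$scores, K = 3, seed = 4)
  d2 <- vapply(seq_len(a$K), function(k) {
    rowSums(sweep(sev$scores, 2, a$centers[k, ])^2)
  }, numeric(nrow(sev$scores)))
  nearest <- max.col(-d2, ties.method = "first")
  expect_identical(unname(a$cluster), nearest)
})

test_that("subtype recovery at separation 1 is near-perfect and agrees with mclust", {
  sev <- generate_severity_matrix(separation = 1, seed = 5)
  a <- kmeans_subtype(sev$scores, K = 3, seed = 5)
  ari <- adjusted_rand_index(a$cluster, sev$truth$true_subgroup)
  expect_gt(ari, 0.9)
  expect_identical(length(unique(a$cluster)), 3L)
  expect_identical(length(a$cluster), 292L)
  skip_if_not_installed("mclust")
  expect_equal(ari,
               mclust::adjustedRandIndex(a$cluster, sev$truth$true_subgroup),
               tolerance = 1e-12)
})

test_that("recovery improves with generator separation", {
  mean_ari <- function(sep) {
    mean(vapply(1:20, function(s) {
      sev <- generate_severity_matrix(c(30, 30, 15), separation = sep, seed = s)
      a <- kmeans_subtype(sev$scores, K = 3, seed = s)
      adjusted_rand_index(a$cluster, sev$truth$true_subgroup)
    }, numeric(1)))
  }
  a0 <- mean_ari(0)
  a5 <- mean_ari(0.5)
  a1 <- mean_ari(1)
  expect_lt(a0, 0.2)
  expect_gte(a5, a0)
  expect_gte(a1 + 0.02, a5)
  expect_gt(a1, 0.9)
})

test_that("subgroup labelling follows language and overall severity means", {
  # three clusters whose language-item means are ordered 1.2 < 2.0 < 2.9
  set.seed(6)
  mk <- function(lang_mean, n) {
    cbind(matrix(round(lang_mean), n, 3),            # language columns 1:3
          matrix(rep(round(lang_mean), 3 * n), n, 3)) # overall tracks language
  }
  m <- rbind(mk(1.2, 5), mk(2.0, 5), mk(2.9, 5))
  rownames(m) <- sprintf("s%02d", 1:15)
  a <- kmeans_subtype(m, K = 3, seed = 6)
  a <- label_subgroups(a, m, language_items = 1:3)
  lab <- subgroup_of(a)
  expect_identical(unname(lab[1:5]), rep("mild", 5))
  expect_identical(unname(lab[6:10]), rep("intermediate", 5))
  expect_identical(unname(lab[11:15]), rep("severe", 5))

  # joint recovery: cluster + label matches truth for >90% of subjects
  sev <- generate_severity_matrix(separation = 1, seed = 7)
  b <- label_subgroups(kmeans_subtype(sev$scores, K = 3, seed = 7),
                       sev$scores, sev$language_items)
  acc <- mean(subgroup_of(b)[sev$truth$subject_id] == sev$truth$true_subgroup)
  expect_gt(acc, 0.9)
})

test_that("degenerate identical clusters are labelled by index with a warning", {
  # three distinct profiles with identical overall and language means
  m <- rbind(
    matrix(rep(c(1L, 3L, 2L, 2L), each = 3), nrow = 3),
    matrix(rep(c(3L, 1L, 2L, 2L), each = 3), nrow = 3),
    matrix(rep(c(2L, 2L, 1L, 3L), each = 3), nrow = 3)
  )
  rownames(m) <- sprintf("s%d", 1:9)
  a <- kmeans_subtype(m, K = 3, seed = 8)
  expect_warning(b <- label_subgroups(a, m, language_items = seq_len(ncol(m))),
                 "indistinguishable")
  expect_setequal(unname(b$labels), c("mild", "intermediate", "severe"))
})

test_that("PCA variance accounting is conserved and matches eigendecomposition", {
  # rank-1 matrix: first component carries all variance
  r1 <- outer(1:6, c(1, 2, 3, 4)) + 0
  rownames(r1) <- sprintf("s%d", 1:6)
  p1 <- pca_severity(r1, n_components = 2)
  expect_equal(p1$variance_fraction[1], 1, tolerance = 1e-12)

  set.seed(9)
  m <- matrix(rnorm(50), 10, 5)
  rownames(m) <- sprintf("s%02d", 1:10)
  p <- pca_severity(m, n_components = 5)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(p$variance_fraction) <= 1e-12))

  # linear-algebra oracle: scores equal centred data projected on
  # covariance eigenvectors, up to per-component sign
  eig <- eigen(stats::cov(m), symmetric = TRUE)
  proj <- scale(m, center = TRUE, scale = FALSE) %*% eig$vectors
  for (j in 1:5) {
    expect_true(isTRUE(all.equal(p$component_scores[, j], proj[, j],
                                 check.attributes = FALSE, tolerance = 1e-8)) ||
                isTRUE(all.equal(p$component_scores[, j], -proj[, j],
                                 check.attributes = FALSE, tolerance = 1e-8)))
  }

  expect_warning(pca_severity(matrix(1, 4, 3), n_components = 2), "constant")
})

test_that("hierarchical-clustering order is a complete permutation with sane ties", {
  set.seed(10)
  m <- matrix(rnorm(40), 8, 5)
  m[2, ] <- m[1, ]  # identical pair must end up adjacent
  rownames(m) <- sprintf("s%d", 1:8)
  ord <- hcl_order(m)
  expect_setequal(ord, rownames(m))
  expect_identical(abs(diff(match(c("s1", "s2"), ord))), 1L)
  expect_error(hcl_order(m, linkage = "nope"))
  expect_error(hcl_order(m[1, , drop = FALSE]), "2 subjects")
})

test_that("average-linkage cophenetic distances match a naive agglomerative oracle", {
  set.seed(11)
  m <- matrix(rnorm(24), 6, 4)
  rownames(m) <- sprintf("s%d", 1:6)
  ord <- hcl_order(m, linkage = "average")
  coph <- as.matrix(stats::cophenetic(attr(ord, "tree")))
  brute <- upgma_cophenetic_brute(stats::dist(m))
  dimnames(brute) <- dimnames(coph)
  expect_equal(coph, brute, tolerance = 1e-10)
})
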