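# Independent oracles used across the suite. Each deliberately re-derives
# its quantity by brute force or closed form, on instances small enough to
# enumerate, so that agreement with the package is informative.

# exhaustive two-group permutation p-value of the |t|-like statistic
# (all C(n1+n2, n1) relabellings)
perm_p_exhaustive <- function(x, y, variance_floor = 1e-4) {
  pooled <- c(x, y)
  n1 <- length(x)
  n <- length(pooled)
  stat <- function(a, b) {
    abs((mean(a) - mean(b)) /
          sqrt(var(a) / length(a) + var(b) / length(b) + variance_floor^2))
  }
  tobs <- stat(x, y)
  idx <- utils::combn(n, n1)
  tperm <- apply(idx, 2, function(ii) stat(pooled[ii], pooled[-ii]))
  mean(tperm >= tobs - 1e-12)
}

# hand-rolled Benjamini-Hochberg step-up
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(q, 1)[order(o)]
}

# hypergeometric upper tail P(X >= k) by direct pmf summation
hyper_upper_enum <- function(k, K, N, n) {
  xs <- max(0, k):min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Venn region sizes by direct set algebra over all membership masks
venn_brute <- function(lists) {
  m <- length(lists)
  masks <- seq_len(2^m - 1)
  vapply(masks, function(mask) {
    inside <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    outside <- setdiff(seq_len(m), inside)
    region <- Reduce(intersect, lists[inside])
    for (j in outside) region <- setdiff(region, lists[[j]])
    length(region)
  }, integer(1))
}

# naive UPGMA (average linkage) cophenetic distance matrix
upgma_cophenetic_brute <- function(d) {
  D <- as.matrix(d)
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  coph <- matrix(0, n, n)
  while (sum(active) > 1) {
    act <- which(active)
    best <- NULL
    bestd <- Inf
    for (i in act) {
      for (j in act) {
        if (i < j) {
          dd <- mean(D[clusters[[i]], clusters[[j]], drop = FALSE])
          if (dd < bestd) {
            bestd <- dd
            best <- c(i, j)
          }
        }
      }
    }
    ci <- clusters[[best[1]]]
    cj <- clusters[[best[2]]]
    coph[ci, cj] <- bestd
    coph[cj, ci] <- bestd
    clusters[[best[1]]] <- c(ci, cj)
    active[best[2]] <- FALSE
  }
  coph
}

# small null methylation fixture shared by several tests
null_methylation <- function(seed, n_cpg = 1000L,
                             n_pairs = c(mild = 7L, intermediate = 7L, severe = 6L)) {
  generate_paired_methylation(
    n_pairs = n_pairs, n_cpg = n_cpg,
    effects = effect_config(n_effect = c(mild = 0L, intermediate = 0L, severe = 0L)),
    seed = seed
  )
}
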