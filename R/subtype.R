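#' Partition cases into phenotypic subgroups by K-means
#'
#' Clusters subjects on their raw severity scores (all scores share one
#' ordinal scale, so no standardisation is applied by default). The best of
#' `n_restarts` random starts by total within-cluster sum of squares is kept,
#' and the result is deterministic given `seed`.
#'
#' @param scores numeric matrix, subjects x scores, with subject-id row
#'   names.
#' @param K number of clusters; the default of 3 reflects the
#'   mild/intermediate/severe subgrouping this pipeline targets.
#' @param n_restarts number of random restarts.
#' @param seed integer seed.
#' @param standardize if `TRUE`, columns are z-scored before clustering
#'   (zero-variance columns are left untouched).
#' @return An object of class `subtype_assignment`: a list with `K`,
#'   `cluster` (named integer vector, subject -> cluster in `1:K`),
#'   `centers`, `withinss`, `tot_withinss`, and `labels` (`NULL` until
#'   [label_subgroups()] is applied).
#' @seealso [label_subgroups()], [pca_severity()], [hcl_order()]
#' @export
#' @examples
#' sev <- generate_severity_matrix(c(10, 10, 5), seed = 1)
#' a <- kmeans_subtype(sev$scores, K = 3, seed = 1)
#' table(a$cluster)
kmeans_subtype <- function(scores, K = 3L, n_restarts = 25L, seed = 1L,
                           standardize = FALSE) {
  .check_matrix(scores, "scores")
  if (nrow(scores) < K) stop("fewer subjects than clusters")
  if (standardize) {
    sds <- apply(scores, 2L, stats::sd)
    sds[sds == 0] <- 1
    scores <- scale(scores, center = TRUE, scale = sds)
  }
  ux <- unique(scores)
  if (nrow(ux) < K) {
    stop(sprintf("K = %d exceeds the number of distinct severity profiles (%d)",
                 K, nrow(ux)))
  }
  set.seed(seed)
  km <- tryCatch(
    stats::kmeans(scores, centers = K, nstart = n_restarts, iter.max = 100L),
    error = function(e) {
      # random starts can draw duplicated rows as centres; fall back to
      # K distinct profiles
      ctr <- ux[sample.int(nrow(ux), K), , drop = FALSE]
      stats::kmeans(scores, centers = ctr, iter.max = 100L)
    }
  )
  structure(
    list(K = as.integer(K),
         cluster = stats::setNames(km$cluster, rownames(scores)),
         centers = km$centers,
         withinss = km$withinss,
         tot_withinss = km$tot.withinss,
         labels = NULL),
    class = "subtype_assignment"
  )
}

#' Name the three clusters mild, intermediate, and severe
#'
#' Assigns phenotype labels to a `K = 3` clustering: the cluster with the
#' highest mean on the language score columns is called `severe`; of the
#' remaining clusters, the one with the lowest overall mean score is `mild`
#' and the other is `intermediate`. Ties are broken by overall mean and then
#' by cluster index; a complete tie (all clusters indistinguishable) falls
#' back to labelling by cluster index with a warning.
#'
#' @param assignment a `subtype_assignment` from [kmeans_subtype()] with
#'   `K = 3`.
#' @param scores the severity matrix used for clustering.
#' @param language_items non-empty integer indices of the language score
#'   columns.
#' @return The assignment with `labels` (cluster -> label) and
#'   `cluster_means` (per-cluster overall and language means) filled in.
#' @export
label_subgroups <- function(assignment, scores, language_items) {
  if (!inherits(assignment, "subtype_assignment")) {
    stop("'assignment' must come from kmeans_subtype()")
  }
  if (assignment$K != 3L) stop("labelling requires K = 3")
  .check_matrix(scores, "scores")
  language_items <- as.integer(language_items)
  if (!length(language_items) || any(language_items < 1L) ||
      any(language_items > ncol(scores))) {
    stop("'language_items' must be a non-empty subset of the score columns")
  }
  cl <- assignment$cluster[rownames(scores)]
  lang_mean <- tapply(rowMeans(scores[, language_items, drop = FALSE]), cl, mean)
  overall_mean <- tapply(rowMeans(scores), cl, mean)
  ks <- as.integer(names(lang_mean))

  if (length(unique(lang_mean)) == 1L && length(unique(overall_mean)) == 1L) {
    warning("clusters are indistinguishable on severity; labels assigned by cluster index")
    labels <- stats::setNames(SUBGROUPS, as.character(sort(ks)))
  } else {
    severe <- ks[order(-lang_mean, -overall_mean, ks)][1L]
    rest <- setdiff(ks, severe)
    mild <- rest[order(overall_mean[as.character(rest)],
                       lang_mean[as.character(rest)], rest)][1L]
    intermediate <- setdiff(rest, mild)
    labels <- stats::setNames(
      c("mild", "intermediate", "severe"),
      as.character(c(mild, intermediate, severe))
    )
  }
  assignment$labels <- labels[as.character(sort(ks))]
  assignment$cluster_means <- data.frame(
    cluster = ks,
    label = unname(assignment$labels[as.character(ks)]),
    overall_mean = as.numeric(overall_mean),
    language_mean = as.numeric(lang_mean)
  )
  assignment
}

#' Per-subject subgroup labels
#'
#' @param assignment a labelled `subtype_assignment`.
#' @return Named character vector mapping each subject to its subgroup label
#'   (or to its cluster number, as character, if unlabelled).
#' @export
subgroup_of <- function(assignment) {
  if (!inherits(assignment, "subtype_assignment")) {
    stop("'assignment' must come from kmeans_subtype()")
  }
  cl <- assignment$cluster
  if (is.null(assignment$labels)) {
    return(stats::setNames(as.character(cl), names(cl)))
  }
  stats::setNames(unname(assignment$labels[as.character(cl)]), names(cl))
}

#' @export
print.subtype_assignment <- function(x, ...) {
  cat(sprintf("K-means subtype assignment: %d subjects in %d clusters\n",
              length(x$cluster), x$K))
  if (!is.null(x$labels)) {
    tab <- table(x$labels[as.character(x$cluster)])
    for (g in names(tab)) cat(sprintf("  %-12s n = %d\n", g, tab[[g]]))
  } else {
    print(table(cluster = x$cluster))
  }
  invisible(x)
}

#' Principal components analysis of the severity matrix
#'
#' Centred PCA on the covariance matrix of the raw scores (consistent with
#' unstandardised clustering). Variance fractions are reported over all
#' returned components and sum to one unless the matrix is constant, in
#' which case they are all zero and a warning is emitted.
#'
#' @param scores numeric severity matrix, subjects x scores.
#' @param n_components number of component score columns to return.
#' @return An object of class `severity_pca` with `component_scores`
#'   (subjects x `n_components`), `variance_fraction` (all components), and
#'   `cumulative` (cumulative variance fractions).
#' @export
pca_severity <- function(scores, n_components = 3L) {
  .check_matrix(scores, "scores")
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > min(dim(scores))) {
    stop("'n_components' must be between 1 and min(subjects, scores)")
  }
  pr <- stats::prcomp(scores, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  total <- sum(ev)
  if (total < 1e-12) {
    warning("severity matrix is constant; all variance fractions are zero")
    vf <- rep(0, length(ev))
  } else {
    vf <- ev / total
  }
  structure(
    list(component_scores = pr$x[, seq_len(min(n_components, ncol(pr$x))), drop = FALSE],
         variance_fraction = vf,
         cumulative = cumsum(vf)),
    class = "severity_pca"
  )
}

#' @export
print.severity_pca <- function(x, ...) {
  k <- min(3L, length(x$variance_fraction))
  cat(sprintf("severity PCA: first %d components explain %.2f%% of variance\n",
              k, 100 * x$cumulative[k]))
  invisible(x)
}

#' Hierarchical-clustering leaf order of subjects
#'
#' Orders subjects by agglomerative hierarchical clustering for heatmap-style
#' verification of a subtype assignment. The leaf order is deterministic for
#' a given matrix, linkage, and metric.
#'
#' @param scores numeric severity matrix with subject-id row names.
#' @param linkage agglomeration method.
#' @param metric distance metric.
#' @return Character vector of subject ids in leaf order, with the fitted
#'   `hclust` tree attached as attribute `"tree"`.
#' @export
hcl_order <- function(scores,
                      linkage = c("average", "complete", "single", "ward.D2"),
                      metric = c("euclidean", "manhattan", "maximum")) {
  linkage <- match.arg(linkage)
  metric <- match.arg(metric)
  .check_matrix(scores, "scores")
  if (nrow(scores) < 2L) stop("at least 2 subjects are required")
  hc <- stats::hclust(stats::dist(scores, method = metric), method = linkage)
  ids <- rownames(scores) %||% as.character(seq_len(nrow(scores)))
  structure(ids[hc$order], tree = hc)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labellings of the same subjects;
#' 1 means identical partitions, 0 the expected agreement of random
#' partitions.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return Adjusted Rand index in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("'a' and 'b' must have the same length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}
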