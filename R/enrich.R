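# Gene-set enrichment and gene-list overlap statistics. The Fisher
# over-representation p-value and the hypergeometric upper tail are the same
# computation on a 2x2 table; both are evaluated through phyper(), which
# sums the exact hypergeometric pmf in a numerically stable way.

#' Construct a gene-set database
#'
#' @param sets named list of character vectors (gene sets); every symbol
#'   must belong to the universe.
#' @param universe character vector of gene symbols forming the reference
#'   population.
#' @return An object of class `geneset_db` with elements `sets` and
#'   `universe`. Symbols are whitespace-trimmed and deduplicated; comparison
#'   is case-sensitive.
#' @export
geneset_db <- function(sets, universe) {
  universe <- unique(trimws(universe))
  universe <- universe[nzchar(universe)]
  if (!length(universe)) stop("'universe' must be non-empty")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- sprintf("set%03d", seq_along(sets))
  }
  sets <- lapply(sets, function(s) unique(trimws(s)))
  bad <- vapply(sets, function(s) !all(s %in% universe), logical(1))
  if (any(bad)) {
    stop("gene sets contain symbols outside the universe: ",
         paste(names(sets)[bad], collapse = ", "))
  }
  structure(list(sets = sets, universe = universe), class = "geneset_db")
}

#' @export
print.geneset_db <- function(x, ...) {
  cat(sprintf("gene-set database: %d sets over a universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Fisher-exact over-representation test of a gene list against a database
#'
#' For each set, the one-sided (over-representation) Fisher exact p-value of
#' the overlap between the query list and the set within the universe is
#' computed from the hypergeometric upper tail of the 2x2 table
#' `(k, n_query - k, K_set - k, N - n_query - K_set + k)`. Query symbols
#' outside the universe are dropped with a message. No multiple-testing
#' correction is applied to enrichment p-values by default (`adjust = TRUE`
#' adds a Benjamini-Hochberg column).
#'
#' @param query character vector of gene symbols.
#' @param db a [geneset_db()].
#' @param alpha records with `fisher_p <= alpha` are flagged enriched.
#' @param adjust add a `fdr_q` column of BH-adjusted p-values.
#' @return Data frame sorted by `fisher_p` with columns `set_name`, `k`,
#'   `K_set`, `n_query`, `N`, `fisher_p`, `enriched`, `overlap_genes`
#'   (comma-separated).
#' @export
fisher_enrichment <- function(query, db, alpha = 0.05, adjust = FALSE) {
  if (!inherits(db, "geneset_db")) stop("'db' must be a geneset_db()")
  query <- unique(trimws(query))
  query <- query[nzchar(query)]
  outside <- setdiff(query, db$universe)
  if (length(outside)) {
    message(length(outside), " query symbols outside the universe were dropped")
  }
  q <- intersect(query, db$universe)
  N <- length(db$universe)
  nq <- length(q)
  rows <- lapply(names(db$sets), function(nm) {
    s <- db$sets[[nm]]
    ov <- intersect(q, s)
    k <- length(ov)
    p <- stats::phyper(k - 1, length(s), N - length(s), nq, lower.tail = FALSE)
    data.frame(set_name = nm, k = k, K_set = length(s), n_query = nq, N = N,
               fisher_p = p, enriched = p <= alpha,
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$fisher_p, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  if (adjust) out$fdr_q <- fdr_adjust(out$fisher_p)
  out
}

#' Venn partition of 2-4 gene lists
#'
#' Counts every region of the Venn partition of the input lists. Regions
#' are identified by a membership bitmask over the lists (list `i`
#' contributes bit `2^(i-1)`) and ordered by that mask, so the output is
#' deterministic. When `universe_size` is given, pairwise hypergeometric
#' upper-tail overlap q-values are computed as well.
#'
#' @param lists named list of 2-4 character vectors of gene symbols.
#' @param universe_size optional total number of genes in the universe for
#'   pairwise overlap tests.
#' @return An object of class `overlap_result`: list with `regions` (data
#'   frame `mask`, `region`, `size`), `pairwise` (data frame or `NULL`),
#'   `union_size`, and `n_lists`.
#' @export
venn_partition <- function(lists, universe_size = NULL) {
  m <- length(lists)
  if (m < 2L || m > 4L) stop("between 2 and 4 lists are required")
  if (is.null(names(lists)) || any(!nzchar(names(lists)))) {
    names(lists) <- paste0("list", seq_len(m))
  }
  lists <- lapply(lists, function(x) unique(trimws(x)))
  all_genes <- unique(unlist(lists))
  membership <- vapply(lists, function(s) all_genes %in% s, logical(length(all_genes)))
  if (length(all_genes) == 1L) membership <- matrix(membership, nrow = 1L)
  if (length(all_genes) == 0L) membership <- matrix(logical(0), ncol = m)
  mask <- as.integer(membership %*% 2^(seq_len(m) - 1L))
  masks <- seq_len(2L^m - 1L)
  regions <- data.frame(
    mask = masks,
    region = vapply(masks, function(mm) {
      paste(names(lists)[bitwAnd(mm, 2^(seq_len(m) - 1L)) > 0], collapse = "&")
    }, character(1)),
    size = vapply(masks, function(mm) sum(mask == mm), integer(1)),
    stringsAsFactors = FALSE
  )
  pairwise <- NULL
  if (!is.null(universe_size)) {
    pairs <- utils::combn(names(lists), 2L)
    pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- lists[[pairs[1L, j]]]
      b <- lists[[pairs[2L, j]]]
      data.frame(list_a = pairs[1L, j], list_b = pairs[2L, j],
                 k = length(intersect(a, b)),
                 n_a = length(a), n_b = length(b), N = universe_size,
                 q = hypergeom_overlap(a, b, universe_size),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(
    list(regions = regions, pairwise = pairwise,
         union_size = length(all_genes), n_lists = m),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Venn partition of %d lists (union of %d genes)\n",
              x$n_lists, x$union_size))
  print(x$regions[x$regions$size > 0, c("region", "size")], row.names = FALSE)
  invisible(x)
}

#' Hypergeometric upper-tail test of the overlap between two gene lists
#'
#' The probability of observing at least the realised overlap when one list
#' is drawn at random from a universe of `N` genes:
#' `q = P(X >= k)` with `X ~ Hypergeometric(N, |a|, |b|)`. The computation
#' is symmetric in `a` and `b`.
#'
#' @param a,b character vectors of gene symbols (deduplicated internally).
#' @param N universe size; must be at least `|a U b|`.
#' @return Upper cumulative probability in `(0, 1]`.
#' @export
#' @examples
#' hypergeom_overlap(letters[1], letters[1], N = 10) # 0.1
hypergeom_overlap <- function(a, b, N) {
  a <- unique(trimws(a))
  b <- unique(trimws(b))
  if (N < length(union(a, b))) {
    stop("universe size N is smaller than the union of the two lists")
  }
  k <- length(intersect(a, b))
  stats::phyper(k - 1, length(a), N - length(a), length(b), lower.tail = FALSE)
}

#' Read and write GMT gene-set files
#'
#' GMT is a tab-separated format with one set per line: set name, a
#' description field, then the member symbols.
#'
#' @param db a [geneset_db()].
#' @param path file path.
#' @param universe optional universe for the database read back; defaults
#'   to the union of all sets.
#' @return `write_gmt()` returns `path` invisibly; `read_gmt()` returns a
#'   [geneset_db()].
#' @export
write_gmt <- function(db, path) {
  if (!inherits(db, "geneset_db")) stop("'db' must be a geneset_db()")
  lines <- vapply(names(db$sets), function(nm) {
    paste(c(nm, "na", db$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  if (is.null(universe)) universe <- unique(unlist(sets))
  geneset_db(sets, universe)
}

#' Read and write plain gene-list files (one symbol per line)
#'
#' @param genes character vector of gene symbols.
#' @param path file path.
#' @return `write_gene_list()` returns `path` invisibly; `read_gene_list()`
#'   returns a character vector.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' @rdname write_gene_list
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}
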