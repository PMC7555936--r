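# Plain TSV readers and writers for the pipeline's tabular interfaces.
# All writers are deterministic (no timestamps), so identical inputs give
# byte-identical files.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read and write severity matrices as TSV
#'
#' Subjects are rows; the first column holds subject ids and the remaining
#' columns one severity score each.
#'
#' @param scores integer severity matrix with subject-id row names.
#' @param path file path.
#' @return `write_severity_tsv()` returns `path` invisibly;
#'   `read_severity_tsv()` returns an integer matrix.
#' @export
write_severity_tsv <- function(scores, path) {
  .write_tsv(data.frame(subject_id = rownames(scores), scores,
                        check.names = FALSE, stringsAsFactors = FALSE),
             path)
}

#' @rdname write_severity_tsv
#' @export
read_severity_tsv <- function(path) {
  df <- .read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "integer"
  m
}

#' Read and write beta-value matrices as TSV
#'
#' CpGs are rows; the first column holds CpG ids and the remaining columns
#' one sample each.
#'
#' @param beta numeric beta matrix with CpG-id row names.
#' @param path file path.
#' @return `write_beta_tsv()` returns `path` invisibly; `read_beta_tsv()`
#'   returns a numeric matrix.
#' @export
write_beta_tsv <- function(beta, path) {
  .write_tsv(data.frame(cpg_id = rownames(beta), beta,
                        check.names = FALSE, stringsAsFactors = FALSE),
             path)
}

#' @rdname write_beta_tsv
#' @export
read_beta_tsv <- function(path) {
  df <- .read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Read and write sample sheets as TSV
#'
#' A sample sheet has columns `sample_id`, `role` (`case`/`control`),
#' `pair_id`, and `subgroup`.
#'
#' @param sheet sample sheet data frame.
#' @param path file path.
#' @return `write_sample_sheet()` returns `path` invisibly;
#'   `read_sample_sheet()` returns a data frame.
#' @export
write_sample_sheet <- function(sheet, path) .write_tsv(sheet, path)

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) .read_tsv(path)

#' Read and write CpG annotation tables as TSV
#'
#' Columns are `cpg_id`, `gene_symbol`, `distance_to_tss` (non-negative
#' integer base pairs). Reading validates the table with
#' [validate_annotation()], rejecting records farther than 1500 bp from a
#' TSS.
#'
#' @param ann annotation data frame.
#' @param path file path.
#' @return `write_annotation_tsv()` returns `path` invisibly;
#'   `read_annotation_tsv()` returns the validated data frame.
#' @export
write_annotation_tsv <- function(ann, path) .write_tsv(ann, path)

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path) validate_annotation(.read_tsv(path))

#' Write per-group differential methylation results as TSV
#'
#' @param records a result data frame from [run_group_analysis()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(records, path) .write_tsv(records, path)
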