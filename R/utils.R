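# internal helpers shared across modules

SUBGROUPS <- c("mild", "intermediate", "severe")

`%||%` <- function(a, b) if (is.null(a)) b else a

# unbiased per-row variance of a numeric matrix; ncol >= 2 required upstream
.row_vars <- function(x) {
  rowSums((x - rowMeans(x))^2) / (ncol(x) - 1L)
}

# coerce a length-3 quantity to a vector named mild/intermediate/severe
.per_subgroup <- function(x, what) {
  if (length(x) == 1L) x <- rep(x, 3L)
  if (length(x) != 3L) {
    stop(sprintf("'%s' must have length 1 or 3 (one per subgroup)", what))
  }
  if (is.null(names(x))) {
    names(x) <- SUBGROUPS
  } else if (!setequal(names(x), SUBGROUPS)) {
    stop(sprintf("names of '%s' must be %s", what,
                 paste(SUBGROUPS, collapse = ", ")))
  }
  x[SUBGROUPS]
}

.check_matrix <- function(x, what) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("'%s' must be a numeric matrix", what))
  }
  invisible(x)
}

# stage seeds derived from one root seed so every pipeline stage has its own
# reproducible substream; kept strictly below 2^31
.stage_seeds <- function(seed, n) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) return(invisible(NULL))
  assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
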