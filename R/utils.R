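# Internal helpers for moving between the wide-tibble API surface
# (sample_id + one column per probe/protein/score) and the numeric
# matrices used internally.

# Coerce a wide tibble (first column sample IDs) or a rownamed matrix to a
# numeric matrix with sample IDs as rownames. Duplicate sample or feature
# identifiers are contract violations everywhere in the package.
as_sample_matrix <- function(x, what = "matrix", id_col = "sample_id") {
  if (is.matrix(x)) {
    m <- x
    if (is.null(rownames(m))) {
      abort(sprintf("%s: a matrix input must carry sample IDs as rownames", what))
    }
  } else if (is.data.frame(x)) {
    idc <- if (id_col %in% names(x)) id_col else names(x)[1]
    ids <- as.character(x[[idc]])
    cols <- setdiff(names(x), idc)
    m <- as.matrix(x[cols])
    if (!is.numeric(m)) {
      abort(sprintf("%s: non-numeric value columns: %s", what,
                    paste(cols[!vapply(x[cols], is.numeric, logical(1))],
                          collapse = ", ")))
    }
    rownames(m) <- ids
  } else {
    abort(sprintf("%s must be a data frame or a matrix", what))
  }
  if (anyDuplicated(rownames(m)) > 0) {
    abort(sprintf("%s: duplicate sample identifiers", what))
  }
  if (anyDuplicated(colnames(m)) > 0) {
    abort(sprintf("%s: duplicate column identifiers", what))
  }
  m
}

matrix_to_tibble <- function(m, id_col = "sample_id") {
  out <- as_tibble(m, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble(!!id_col := rownames(m)), out)
  out
}

# Align two sample-rowed matrices on their shared sample IDs, in the order of
# the first. Errors if there is no overlap.
align_samples <- function(a, b, what_a = "first table", what_b = "second table",
                          require_all = FALSE) {
  shared <- intersect(rownames(a), rownames(b))
  if (length(shared) == 0) {
    abort(sprintf("no overlapping samples between %s and %s", what_a, what_b))
  }
  if (require_all && length(shared) < nrow(a)) {
    abort(sprintf("%d samples of %s are missing from %s",
                  nrow(a) - length(shared), what_a, what_b))
  }
  list(a = a[shared, , drop = FALSE], b = b[shared, , drop = FALSE])
}

check_finite <- function(x, what) {
  if (any(!is.finite(x))) abort(sprintf("%s contains non-finite values", what))
  invisible(x)
}

`%||%` <- rlang::`%||%`
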