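geomean <- function(x) exp(mean(log(x)))

# wide expression tibble (first column = mirna, rest = samples) -> matrix
expr_matrix <- function(expr) {
  stopifnot(is.data.frame(expr), ncol(expr) >= 2)
  first <- names(expr)[1]
  ids <- as.character(expr[[first]])
  if (anyDuplicated(ids)) abort("duplicate miRNA identifiers in expression table")
  m <- as.matrix(expr[, -1, drop = FALSE])
  if (!is.numeric(m)) abort("expression values must be numeric")
  if (any(!is.finite(m)) || any(m < 0)) abort("expression values must be finite and non-negative")
  rownames(m) <- ids
  m
}

matrix_to_expr <- function(m) {
  bind_cols(tibble(mirna = rownames(m)), as_tibble(m))
}

check_annotations <- function(annot, samples, required) {
  stopifnot(is.data.frame(annot))
  if (!"sample" %in% names(annot)) abort("annotation table needs a 'sample' column")
  missing_cols <- setdiff(required, names(annot))
  if (length(missing_cols) > 0) {
    abort(paste0("annotation table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  missing_samples <- setdiff(samples, annot$sample)
  if (length(missing_samples) > 0) {
    abort(paste0("no annotation for sample(s): ",
                 paste(missing_samples, collapse = ", ")))
  }
  invisible(annot)
}
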