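#' Read and write pipeline tables
#'
#' All tabular inputs are plain TSV. An expression table has miRNA
#' identifiers in the first column and one column per sample; an annotation
#' table has a `sample` column plus experiment keys (`cell_line` and
#' `condition` in {parental, exposed} for paired cell-line designs, or
#' `tissue` in {tumor, normal} with optional `purity` in (0, 1] for cohort
#' designs). Pathway collections use the standard GMT layout (name,
#' description, then member genes, tab-separated).
#'
#' @param path File path.
#' @param pathways Named list of character vectors (gene sets) for
#'   `write_gmt()`.
#' @param x A data frame for `write_tsv_report()`.
#' @return Tibbles (`read_expression()`, `read_annotations()`), a named list
#'   of character vectors (`read_gmt()`), or the input invisibly for writers.
#' @examples
#' gmt <- tempfile(fileext = ".gmt")
#' write_gmt(list(pA = c("TP53", "KRAS"), pB = c("VEGFA")), gmt)
#' read_gmt(gmt)
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_expression <- function(path) {
  expr <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  expr_matrix(expr) # validates
  names(expr)[1] <- "mirna"
  expr
}

#' @rdname pipeline_io
#' @export
read_annotations <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname pipeline_io
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname pipeline_io
#' @export
write_gmt <- function(pathways, path) {
  stopifnot(is.list(pathways), !is.null(names(pathways)))
  lines <- imap(pathways, function(genes, name) {
    paste(c(name, name, genes), collapse = "\t")
  })
  writeLines(unlist(lines), path)
  invisible(pathways)
}

#' @rdname pipeline_io
#' @export
write_tsv_report <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(x)
}

#' Packaged panel tables
#'
#' Transcriptions of the published OncomiR (39 rows) and TSmiR (45 rows)
#' panel tables ship with the package: per miRNA, the tumor/normal
#' fold-regulation (`tn_fr`), its t-test p-value (`p`), the per-cell-line
#' fold changes under chronic areca nut extract exposure (`oec_fc` for
#' OECM1, `sas_fc` for SAS), and the printed panel average (`avg_fc`).
#' The OncomiR table prints the ratio dialect (values below 1 appear
#' as-is, e.g. 0.91); the TSmiR table prints the signed dialect, including
#' the legacy sub-unit quirk (e.g. -0.88, meaning ratio 1/0.88). See
#' [fold_regulation].
#'
#' @param which `"oncomir"` or `"tsmir"`.
#' @return A tibble with columns mirna, tn_fr, p, oec_fc, sas_fc, avg_fc and
#'   a `dialect` attribute (`"ratio"` or `"signed"`).
#' @examples
#' oncomirs <- load_panel_table("oncomir")
#' head(oncomirs, 3)
#' @export
load_panel_table <- function(which = c("oncomir", "tsmir")) {
  which <- match.arg(which)
  file <- switch(which,
    oncomir = "table1_oncomirs.tsv",
    tsmir = "table2_tsmirs.tsv"
  )
  path <- system.file("extdata", file, package = "arecamir", mustWork = TRUE)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  attr(tab, "dialect") <- if (which == "oncomir") "ratio" else "signed"
  tab
}
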