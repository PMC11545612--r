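#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability P(X >= k) of drawing at least k pathway members
#' in a query of size n from a universe of N genes containing K pathway
#' members.
#'
#' @param k Overlap size between query and pathway.
#' @param K Pathway size within the universe.
#' @param n Query size within the universe.
#' @param N Universe size.
#' @return p-value in \[0, 1\].
#' @examples
#' hypergeom_overrep(2, 2, 2, 4) # 1/6
#' @export
hypergeom_overrep <- function(k, K, n, N) {
  if (any(k < 0) || any(K > N) || any(n > N) || any(k > pmin(K, n))) {
    abort("inconsistent counts: need 0 <= k <= min(K, n) <= N")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Conservative (EASE-style) over-representation score
#'
#' The hypergeometric tail computed after removing one gene from the
#' observed overlap, P(X >= k - 1); always at least the plain p-value, and
#' 1 when k <= 1.
#'
#' @inheritParams hypergeom_overrep
#' @export
ease_score <- function(k, K, n, N) {
  ifelse(k <= 0, 1, hypergeom_overrep(pmax(k - 1, 0), K, n, N))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate control; order-preserving and capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Packaged phenotype-module map
#'
#' Assigns each of the ten pathways recurrently enriched for areca
#' nut-modulated miRNA targets to a phenotype module: adherens junction and
#' focal adhesion to cell motility; EGFR TKI resistance, p53 signaling,
#' cellular senescence and cell cycle to cell survival; PI3K-AKT, Rap1,
#' MAPK and Ras signaling to both.
#'
#' @return Tibble: pathway, module in {motility, survival, both}.
#' @export
phenotype_modules <- function() {
  tibble(
    pathway = c(
      "Adherens junction", "Focal adhesion",
      "EGFR tyrosine kinase inhibitor resistance", "p53 signaling pathway",
      "Cellular senescence", "Cell cycle",
      "PI3K-Akt signaling pathway", "Rap1 signaling pathway",
      "MAPK signaling pathway", "Ras signaling pathway"
    ),
    module = c(
      "motility", "motility",
      "survival", "survival", "survival", "survival",
      "both", "both", "both", "both"
    )
  )
}

# loose pathway-name matching: case/punctuation-insensitive, "signaling
# pathway" suffix optional
normalize_pathway <- function(x) {
  x <- tolower(gsub("[^a-z0-9 ]", "", tolower(x)))
  x <- gsub("\\s*(signaling)?\\s*(pathway)?\\s*$", "", x)
  trimws(gsub("\\s+", " ", x))
}

assign_module <- function(pathway, module_map = phenotype_modules()) {
  idx <- match(normalize_pathway(pathway), normalize_pathway(module_map$pathway))
  ifelse(is.na(idx), "unassigned", module_map$module[idx])
}

#' Pathway over-representation analysis with phenotype modules
#'
#' Hypergeometric ORA of a query gene set against a GMT collection.
#' The universe defaults to all genes appearing in the collection (the
#' usual annotation-tool background when none is supplied); pathways with
#' zero overlap are omitted. Results are ranked by p-value, BH-adjusted,
#' and each pathway is rolled up to a phenotype module via the packaged
#' [phenotype_modules()] map (or a user map with columns pathway, module).
#'
#' @param query_genes Character vector of query gene symbols.
#' @param pathways Named list of gene-identifier vectors (see [read_gmt()]).
#' @param universe Background gene set (default: union of all pathway
#'   genes). Must contain the query after restriction.
#' @param top_m Keep the top m pathways by p (default all).
#' @param statistic `"hypergeometric"` (default) or `"ease"`.
#' @param module_map Data frame mapping pathway names to modules.
#' @return An object of class `mirna_ora`: list with `records` (tibble:
#'   pathway, k, K, n, N, p, fdr, module, overlap_genes) plus settings.
#' @examples
#' gmt <- list(hit = paste0("g", 1:10), decoy = paste0("g", 50:60))
#' run_ora(paste0("g", 1:8), gmt)
#' @export
run_ora <- function(query_genes, pathways, universe = NULL, top_m = Inf,
                    statistic = c("hypergeometric", "ease"),
                    module_map = phenotype_modules()) {
  statistic <- match.arg(statistic)
  stopifnot(is.list(pathways), !is.null(names(pathways)))
  universe <- unique(universe %||% unlist(pathways, use.names = FALSE))
  if (length(universe) == 0) abort("universe is empty")
  query <- unique(intersect(query_genes, universe))
  n <- length(query)
  N <- length(universe)

  records <- imap(pathways, function(genes, name) {
    members <- intersect(unique(genes), universe)
    overlap <- intersect(query, members)
    tibble(
      pathway = name, k = length(overlap), K = length(members),
      n = n, N = N,
      overlap_genes = paste(sort(overlap), collapse = ",")
    )
  }) |>
    list_rbind() |>
    filter(.data$k >= 1)
  pfun <- if (statistic == "ease") ease_score else hypergeom_overrep
  records <- records |>
    mutate(
      p = pfun(.data$k, .data$K, .data$n, .data$N),
      fdr = adjust_bh(.data$p),
      module = assign_module(.data$pathway, module_map)
    ) |>
    arrange(.data$p) |>
    head(n = top_m) |>
    relocate("overlap_genes", .after = "module")

  structure(
    list(records = records, statistic = statistic, universe_size = N,
         query_size = n),
    class = "mirna_ora"
  )
}

#' Phenotype-module rollup of enriched pathways
#'
#' Counts enriched pathways per phenotype module.
#'
#' @param ora A `mirna_ora` object, or a tibble with a `module` column.
#' @return Tibble: module, n_pathways.
#' @examples
#' module_rollup(phenotype_modules())
#' @export
module_rollup <- function(ora) {
  records <- if (inherits(ora, "mirna_ora")) ora$records else ora
  records |>
    count(.data$module, name = "n_pathways") |>
    arrange(.data$module)
}

#' @export
print.mirna_ora <- function(x, ...) {
  cat("Pathway over-representation (", x$statistic, "): ", nrow(x$records),
      " pathways with overlap, query ", x$query_size, " of universe ",
      x$universe_size, "\n", sep = "")
  invisible(x)
}
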