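#' Load and de-duplicate miRNA-target assertion tables
#'
#' Each source database contributes rows (source, mirna, gene, evidence)
#' with evidence `"validated"` or `"predicted"`. Identifiers are
#' case-normalized (genes upper-case, miRNA names lower-cased apart from the
#' canonical "miR"/"let" prefixes kept as printed) and duplicates within a
#' source are collapsed, so each (source, mirna, gene) triple appears once.
#'
#' @param tables A data frame with columns source, mirna, gene, evidence, or
#'   a character vector of TSV paths with those columns.
#' @return Tibble of unique assertions.
#' @export
load_target_sources <- function(tables) {
  if (is.character(tables)) {
    tables <- purrr::map(tables, readr::read_tsv,
                         show_col_types = FALSE, progress = FALSE) |>
      list_rbind()
  }
  need <- c("source", "mirna", "gene", "evidence")
  if (!all(need %in% names(tables))) {
    abort(paste("assertion tables need columns:", paste(need, collapse = ", ")))
  }
  bad <- setdiff(unique(tables$evidence), c("validated", "predicted"))
  if (length(bad) > 0) {
    abort(paste0("unknown evidence tag(s): ", paste(bad, collapse = ", ")))
  }
  as_tibble(tables) |>
    mutate(gene = toupper(.data$gene), mirna = normalize_mirna(.data$mirna)) |>
    distinct(.data$source, .data$mirna, .data$gene, .keep_all = TRUE)
}

normalize_mirna <- function(x) {
  x <- tolower(trimws(x))
  sub("^mir-", "miR-", x)
}

#' Consensus voting over target sources
#'
#' Keeps miRNA-gene links asserted by at least `min_votes` distinct source
#' databases (the published screen used at least 4 of 11), restricted to a
#' query miRNA set. With `validated_override = TRUE` a link backed by any
#' experimentally validated source is kept regardless of its vote count.
#'
#' @param assertions Assertion tibble from [load_target_sources()].
#' @param mirnas Non-empty character vector of query miRNAs.
#' @param min_votes Minimum number of supporting sources (default 4).
#' @param validated_override Keep any validated link (default FALSE).
#' @return Tibble of consensus edges: mirna, gene, votes, sources
#'   (comma-joined), any_validated; sorted by votes descending.
#' @export
consensus_vote <- function(assertions, mirnas, min_votes = 4,
                           validated_override = FALSE) {
  if (length(mirnas) == 0) abort("query miRNA set is empty")
  if (min_votes < 1) abort("min_votes must be >= 1")
  mirnas <- normalize_mirna(mirnas)
  edges <- assertions |>
    filter(.data$mirna %in% mirnas) |>
    summarise(
      votes = dplyr::n_distinct(.data$source),
      sources = paste(sort(unique(.data$source)), collapse = ","),
      any_validated = any(.data$evidence == "validated"),
      .by = c("mirna", "gene")
    )
  keep <- edges$votes >= min_votes
  if (validated_override) keep <- keep | edges$any_validated
  edges |>
    filter(keep) |>
    arrange(desc(.data$votes), .data$mirna, .data$gene)
}

#' Target union and cross-regulation degree
#'
#' Union of target genes over the query miRNAs, with the number of distinct
#' regulating miRNAs per gene (cross-regulation degree).
#'
#' @param edges Consensus-edge tibble from [consensus_vote()].
#' @param mirnas Optional restriction to a miRNA subset.
#' @return Tibble: gene, n_mirnas, mirnas (comma-joined), sorted by degree
#'   descending.
#' @export
union_targets <- function(edges, mirnas = NULL) {
  if (!is.null(mirnas)) {
    edges <- filter(edges, .data$mirna %in% normalize_mirna(mirnas))
  }
  edges |>
    summarise(
      n_mirnas = dplyr::n_distinct(.data$mirna),
      mirnas = paste(sort(unique(.data$mirna)), collapse = ","),
      .by = "gene"
    ) |>
    arrange(desc(.data$n_mirnas), .data$gene)
}

#' Export a bipartite miRNA-gene network
#'
#' Writes a tab-separated edge list (mirna, gene, votes, any_validated)
#' loadable by standard network tools, and a node table with a `type`
#' column distinguishing miRNA from gene nodes.
#'
#' @param edges Consensus-edge tibble.
#' @param edges_path Path for the edge list TSV.
#' @param nodes_path Optional path for the node table TSV.
#' @return Invisibly, list(edges, nodes).
#' @export
export_network <- function(edges, edges_path, nodes_path = NULL) {
  out <- edges |> select("mirna", "gene", "votes", "any_validated")
  readr::write_tsv(out, edges_path, progress = FALSE)
  nodes <- bind_rows(
    tibble(node = unique(edges$mirna), type = "mirna"),
    tibble(node = unique(edges$gene), type = "gene")
  )
  if (!is.null(nodes_path)) readr::write_tsv(nodes, nodes_path, progress = FALSE)
  invisible(list(edges = out, nodes = nodes))
}

#' @rdname export_network
#' @param path Path of an exported edge list.
#' @export
read_network_edges <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
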