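#' Pipeline configuration
#'
#' Collects every published cutoff as a named default so no threshold is
#' hard-coded downstream: exposure-panel and cohort fold-regulation
#' thresholds 1.2, raw alpha 0.05, two-axis signature threshold 2 with
#' strict comparison, consensus minimum 4 votes. The resolved configuration
#' travels with every report bundle.
#'
#' @param ane_fr,cohort_fr Fold-regulation thresholds for the two screens.
#' @param alpha Raw p-value cutoff for the cohort screen.
#' @param signature Two-axis signature threshold.
#' @param strict Strict (>) signature comparison (see
#'   [select_signatures()]).
#' @param min_votes Consensus vote minimum for target edges.
#' @param calibrate Purity calibration mode for [build_cohort_panel()].
#' @param ease Use the conservative EASE statistic for ORA.
#' @param bh Report BH-adjusted p-values alongside the cohort screen.
#' @param seed Optional integer recorded for provenance.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(ane_fr = 1.2, cohort_fr = 1.2, alpha = 0.05,
                            signature = 2.0, strict = TRUE, min_votes = 4,
                            calibrate = "auto", ease = FALSE, bh = FALSE,
                            seed = NULL) {
  stopifnot(ane_fr > 1, cohort_fr > 1, alpha > 0, signature > 0, min_votes >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the integrative miRNA-panel pipeline
#'
#' End-to-end orchestration: paired-exposure panel, cohort screen,
#' concordance integration with signature selection, consensus target
#' voting and network union for the signature TSmiRs, and pathway
#' over-representation with phenotype-module rollup. Stages whose inputs
#' are `NULL` are skipped. Per-stage record counts are logged via
#' `message()` and kept in the returned bundle.
#'
#' @param ane_expr,ane_annot Paired-exposure expression/annotation tibbles.
#' @param cohort_expr,cohort_annot Cohort expression/annotation tibbles.
#' @param target_sources Assertion table for [load_target_sources()], or
#'   NULL to skip target/enrichment stages.
#' @param pathways Named list of gene sets (see [read_gmt()]), or NULL.
#' @param config A [pipeline_config()].
#' @param admix_signatures Optional stromal/immune signature list for the
#'   purity-estimation path.
#' @param target_mirnas Query miRNAs for consensus voting (default: the
#'   signature TSmiRs from the integration stage).
#' @param universe Optional ORA background.
#' @param output_dir Optional directory; when given the bundle is written
#'   there via [write_pipeline_bundle()].
#' @return A list of class `pipeline_bundle` with elements ane, cohort,
#'   integration, signatures, edges, targets, ora, config, log.
#' @export
run_pipeline <- function(ane_expr, ane_annot, cohort_expr, cohort_annot,
                         target_sources = NULL, pathways = NULL,
                         config = pipeline_config(),
                         admix_signatures = NULL, target_mirnas = NULL,
                         universe = NULL, output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character()
  note <- function(...) {
    msg <- paste0(...)
    message(msg)
    log <<- c(log, msg)
  }

  ane <- build_ane_panel(ane_expr, ane_annot, threshold = config$ane_fr)
  note("exposure panel: ", nrow(ane$panel), " miRNAs, ",
       length(ane$sets$up_any), " up / ", length(ane$sets$down_any), " down")

  cohort <- build_cohort_panel(
    cohort_expr, cohort_annot, fr_threshold = config$cohort_fr,
    alpha = config$alpha, calibrate = config$calibrate,
    signatures = admix_signatures, bh = config$bh
  )
  note("cohort screen: ", nrow(cohort$records), " miRNAs, ",
       sum(cohort$records$selected), " selected")

  integration <- integrate_panels(ane, cohort,
                                  signature_threshold = config$signature,
                                  strict = config$strict)
  sig <- filter(integration$records, .data$signature)
  note("integration: ", sum(integration$records$class == "OncomiR"),
       " OncomiRs, ", sum(integration$records$class == "TSmiR"),
       " TSmiRs, ", nrow(sig), " signatures")

  edges <- targets <- ora <- NULL
  if (!is.null(target_sources)) {
    qm <- target_mirnas %||%
      sig$mirna[sig$class == "TSmiR"] %||% character()
    if (length(qm) > 0) {
      assertions <- load_target_sources(target_sources)
      edges <- consensus_vote(assertions, qm, min_votes = config$min_votes)
      targets <- union_targets(edges)
      note("targets: ", nrow(edges), " consensus edges over ",
           nrow(targets), " genes")
      if (!is.null(pathways) && nrow(targets) > 0) {
        ora <- run_ora(targets$gene, pathways, universe = universe,
                       statistic = if (config$ease) "ease" else "hypergeometric")
        note("enrichment: ", nrow(ora$records), " pathways with overlap")
      }
    } else {
      note("targets: no query miRNAs; stage skipped")
    }
  }

  bundle <- structure(
    list(ane = ane, cohort = cohort, integration = integration,
         signatures = sig, edges = edges, targets = targets, ora = ora,
         config = config, log = log),
    class = "pipeline_bundle"
  )
  if (!is.null(output_dir)) write_pipeline_bundle(bundle, output_dir)
  bundle
}

#' Write a pipeline report bundle
#'
#' Writes every stage's table as TSV plus the resolved configuration as
#' YAML (provenance: published cutoffs are config values, never
#' hard-coded).
#'
#' @param bundle A `pipeline_bundle` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return The bundle, invisibly.
#' @export
write_pipeline_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "pipeline_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_tsv_report(bundle$ane$panel, p("ane_panel.tsv"))
  write_tsv_report(bundle$cohort$records, p("cohort_panel.tsv"))
  write_tsv_report(render_panel_table(bundle$integration$records),
                   p("integrated_panel.tsv"))
  write_tsv_report(bundle$signatures, p("signatures.tsv"))
  if (!is.null(bundle$edges)) {
    export_network(bundle$edges, p("network_edges.tsv"), p("network_nodes.tsv"))
    write_tsv_report(bundle$targets, p("targets.tsv"))
  }
  if (!is.null(bundle$ora)) {
    write_tsv_report(bundle$ora$records, p("enrichment.tsv"))
    write_tsv_report(module_rollup(bundle$ora), p("module_rollup.tsv"))
  }
  writeLines(yaml::as.yaml(unclass(bundle$config)), p("config.yaml"))
  writeLines(bundle$log, p("run_log.txt"))
  invisible(bundle)
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat("Pipeline report bundle\n")
  for (line in x$log) cat(" -", line, "\n")
  invisible(x)
}
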