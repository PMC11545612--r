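#' Plot methods
#'
#' `autoplot()` methods give each result type its standard view:
#' the paired-exposure panel as a two-line log2 fold-change scatter
#' colored by region, the cohort screen as a volcano plot, the integrated
#' panel as the two-axis exposure-vs-tumor scatter with signatures
#' highlighted, and an ORA result as a dot plot colored by phenotype
#' module. `plot_*()` wrappers are provided for pipe-free use.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name arecamir_plots
NULL

#' @rdname arecamir_plots
#' @method autoplot ane_panel
#' @export
autoplot.ane_panel <- function(object, ...) {
  l1 <- paste0("fc_", object$lines[1])
  l2 <- paste0("fc_", object$lines[2])
  ggplot2::ggplot(object$panel, ggplot2::aes(
    x = log2(.data[[l1]]), y = log2(.data[[l2]]), color = .data$region
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * log2(object$threshold),
                        linetype = "dashed", color = "grey50") +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(object$threshold),
                        linetype = "dashed", color = "grey50") +
    ggplot2::labs(
      x = paste0("log2 FC (", object$lines[1], ", exposed/parental)"),
      y = paste0("log2 FC (", object$lines[2], ", exposed/parental)"),
      title = "Paired-exposure dysregulation regions"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname arecamir_plots
#' @method autoplot cohort_panel
#' @export
autoplot.cohort_panel <- function(object, ...) {
  ggplot2::ggplot(object$records, ggplot2::aes(
    x = sign(.data$tn_fr) * log2(abs(.data$tn_fr)),
    y = -log10(.data$p), color = .data$direction
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(object$alpha),
                        linetype = "dashed", color = "grey50") +
    ggplot2::labs(x = "signed log2 |T/N fold-regulation|",
                  y = "-log10 p", title = "Tumor/normal cohort screen") +
    ggplot2::theme_minimal()
}

#' @rdname arecamir_plots
#' @method autoplot mirna_integration
#' @export
autoplot.mirna_integration <- function(object, ...) {
  ggplot2::ggplot(object$records, ggplot2::aes(
    x = .data$avg_fc, y = .data$tn_fr,
    color = .data$class, shape = .data$signature
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * object$signature_threshold,
                        linetype = "dashed", color = "grey50") +
    ggplot2::geom_vline(xintercept = c(-1, 1) * object$signature_threshold,
                        linetype = "dashed", color = "grey50") +
    ggplot2::labs(x = "exposure-panel average fold-regulation",
                  y = "tumor/normal fold-regulation",
                  title = "Two-axis panel integration") +
    ggplot2::theme_minimal()
}

#' @rdname arecamir_plots
#' @method autoplot mirna_ora
#' @export
autoplot.mirna_ora <- function(object, ...) {
  rec <- object$records
  rec$pathway <- factor(rec$pathway, levels = rev(rec$pathway))
  ggplot2::ggplot(rec, ggplot2::aes(
    x = -log10(.data$p), y = .data$pathway,
    size = .data$k, color = .data$module
  )) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "-log10 p", y = NULL,
                  title = "Pathway over-representation") +
    ggplot2::theme_minimal()
}

#' @rdname arecamir_plots
#' @param x A result object.
#' @export
plot_ane_panel <- function(x, ...) autoplot.ane_panel(x, ...)

#' @rdname arecamir_plots
#' @export
plot_cohort_panel <- function(x, ...) autoplot.cohort_panel(x, ...)

#' @rdname arecamir_plots
#' @export
plot_integration <- function(x, ...) autoplot.mirna_integration(x, ...)

#' @rdname arecamir_plots
#' @export
plot_enrichment <- function(x, ...) autoplot.mirna_ora(x, ...)
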