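#' Tidy and glance methods
#'
#' `tidy()` returns the per-record table of a result object; `glance()` a
#' one-row summary.
#'
#' @param x An `ane_panel`, `cohort_panel`, `mirna_integration` or
#'   `mirna_ora` object.
#' @param ... Unused.
#' @return A tibble.
#' @name arecamir_tidiers
NULL

#' @rdname arecamir_tidiers
#' @method tidy ane_panel
#' @export
tidy.ane_panel <- function(x, ...) as_tibble(x$panel)

#' @rdname arecamir_tidiers
#' @method glance ane_panel
#' @export
glance.ane_panel <- function(x, ...) {
  tibble(
    n_mirnas = nrow(x$panel),
    n_up_any = length(x$sets$up_any),
    n_down_any = length(x$sets$down_any),
    n_common_up = length(x$sets$common_up),
    n_common_down = length(x$sets$common_down),
    n_discordant = length(x$sets$discordant),
    n_center = length(x$sets$center),
    threshold = x$threshold
  )
}

#' @rdname arecamir_tidiers
#' @method tidy cohort_panel
#' @export
tidy.cohort_panel <- function(x, ...) as_tibble(x$records)

#' @rdname arecamir_tidiers
#' @method glance cohort_panel
#' @export
glance.cohort_panel <- function(x, ...) {
  tibble(
    n_mirnas = nrow(x$records),
    n_selected = sum(x$records$selected),
    n_over = sum(x$records$direction == "over"),
    n_under = sum(x$records$direction == "under"),
    calibrated = all(x$records$calibrated),
    fr_threshold = x$fr_threshold,
    alpha = x$alpha
  )
}

#' @rdname arecamir_tidiers
#' @method tidy mirna_integration
#' @export
tidy.mirna_integration <- function(x, ...) as_tibble(x$records)

#' @rdname arecamir_tidiers
#' @method glance mirna_integration
#' @export
glance.mirna_integration <- function(x, ...) {
  tibble(
    n_oncomir = sum(x$records$class == "OncomiR"),
    n_tsmir = sum(x$records$class == "TSmiR"),
    n_signature = sum(x$records$signature),
    signature_threshold = x$signature_threshold,
    strict = x$strict
  )
}

#' @rdname arecamir_tidiers
#' @method tidy mirna_ora
#' @export
tidy.mirna_ora <- function(x, ...) as_tibble(x$records)

#' @rdname arecamir_tidiers
#' @method glance mirna_ora
#' @export
glance.mirna_ora <- function(x, ...) {
  tibble(
    n_pathways = nrow(x$records),
    n_fdr_05 = sum(x$records$fdr < 0.05),
    n_motility = sum(x$records$module == "motility"),
    n_survival = sum(x$records$module == "survival"),
    n_both = sum(x$records$module == "both"),
    statistic = x$statistic
  )
}
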