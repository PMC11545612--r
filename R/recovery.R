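#' Planted-effect recovery metrics for a cohort screen
#'
#' Compares a cohort screen against generator truth. With `fdr_cap = NULL`
#' the screen's own selection rule is scored: sensitivity is the fraction
#' of planted miRNAs selected in the correct direction, and the empirical
#' FDR the fraction of selected miRNAs that were not planted. With a
#' numeric `fdr_cap`, candidates passing the fold-regulation gate are
#' ranked by p-value and the largest prefix whose empirical FDR stays at or
#' below the cap is scored instead — sensitivity at matched FDR, the metric
#' used to compare calibrated and uncalibrated screens on an equal
#' false-discovery footing.
#'
#' Features listed in `ignore` (typically the stromal/immune admixture
#' signature features, which are genuinely differential between
#' tumor-intrinsic and normal tissue but are not planted effects) are
#' masked from the evaluation entirely: they count neither as hits nor as
#' false discoveries.
#'
#' @param cohort A `cohort_panel` object.
#' @param truth_up,truth_down Character vectors of planted up/down miRNAs.
#' @param fdr_cap Optional FDR cap for matched-FDR scoring.
#' @param ignore Features masked from the evaluation.
#' @return One-row tibble: sensitivity, fdr, n_selected.
#' @export
recovery_metrics <- function(cohort, truth_up, truth_down, fdr_cap = NULL,
                             ignore = character()) {
  stopifnot(inherits(cohort, "cohort_panel"))
  rec <- filter(cohort$records, !.data$mirna %in% ignore)
  planted <- c(truth_up, truth_down)
  correct <- function(mirna, direction) {
    (mirna %in% truth_up & direction == "over") |
      (mirna %in% truth_down & direction == "under")
  }
  if (is.null(fdr_cap)) {
    sel <- rec[rec$selected, ]
    hit <- correct(sel$mirna, sel$direction)
    return(tibble(
      sensitivity = sum(hit) / length(planted),
      fdr = if (nrow(sel) == 0) 0 else mean(!sel$mirna %in% planted),
      n_selected = nrow(sel)
    ))
  }
  cand <- rec |>
    filter(abs(.data$tn_fr) >= cohort$fr_threshold) |>
    arrange(.data$p) |>
    mutate(dir = ifelse(.data$tn_fr > 0, "over", "under"))
  if (nrow(cand) == 0) {
    return(tibble(sensitivity = 0, fdr = 0, n_selected = 0L))
  }
  false_cum <- cumsum(!cand$mirna %in% planted)
  fdr_cum <- false_cum / seq_len(nrow(cand))
  ok <- which(fdr_cum <= fdr_cap)
  k <- if (length(ok) == 0) 0L else max(ok)
  if (k == 0) return(tibble(sensitivity = 0, fdr = 0, n_selected = 0L))
  kept <- cand[seq_len(k), ]
  tibble(
    sensitivity = sum(correct(kept$mirna, kept$dir)) / length(planted),
    fdr = fdr_cum[k],
    n_selected = k
  )
}
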