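#' Median normalization of an expression matrix
#'
#' Equalizes the per-sample median of log-intensities across samples (each
#' sample is rescaled by a single factor so that its median log-intensity
#' equals the grand median), which removes per-chip scale differences while
#' leaving within-sample ratios untouched. Zero intensities are floored at
#' `epsilon_frac` times the global median of positive values before taking
#' logs, so an absent probe cannot produce an infinite ratio downstream.
#'
#' @param expr Expression tibble (first column miRNA ids, one column per
#'   sample), non-negative values.
#' @param epsilon_frac Zero floor as a fraction of the global positive
#'   median (default 1e-6).
#' @return A tibble of the same shape with normalized intensities. The
#'   per-sample scale factors that were divided out are attached as
#'   attribute `"scale_factors"`.
#' @examples
#' expr <- tibble::tibble(mirna = c("a", "b"), s1 = c(1, 4), s2 = c(20, 80))
#' normalize_expression(expr)
#' @export
normalize_expression <- function(expr, epsilon_frac = 1e-6) {
  m <- expr_matrix(expr)
  if (any(colSums(m) == 0)) {
    abort(paste0("sample(s) with all-zero intensities: ",
                 paste(colnames(m)[colSums(m) == 0], collapse = ", ")))
  }
  eps <- epsilon_frac * median(m[m > 0])
  m[m == 0] <- eps
  logm <- log(m)
  med <- apply(logm, 2, median)
  target <- median(med)
  norm <- exp(sweep(logm, 2, med - target, `-`))
  out <- matrix_to_expr(norm)
  names(out) <- names(expr)
  attr(out, "scale_factors") <- exp(med - target)
  out
}

#' Per-miRNA group ratio between two conditions of one cell line
#'
#' The group summary is the geometric mean (microarray intensities are
#' approximately log-normal); an arithmetic-mean variant is available.
#' Singleton groups are allowed (the original screen ran one chip per
#' condition) and flagged via the `n_num`/`n_den` columns.
#'
#' @param expr,annot Expression and annotation tibbles (annotation needs
#'   `sample`, `cell_line`, `condition`).
#' @param cell_line Cell line to compare within.
#' @param numerator,denominator Condition labels (default exposed/parental).
#' @param summary `"geometric"` (default) or `"arithmetic"` group mean.
#' @return Tibble with columns mirna, ratio, n_num, n_den.
#' @export
group_ratio <- function(expr, annot, cell_line,
                        numerator = "exposed", denominator = "parental",
                        summary = c("geometric", "arithmetic")) {
  summary <- match.arg(summary)
  m <- expr_matrix(expr)
  check_annotations(annot, colnames(m), c("cell_line", "condition"))
  pick <- function(cond) {
    s <- annot$sample[annot$cell_line == cell_line & annot$condition == cond]
    s <- intersect(colnames(m), s)
    if (length(s) == 0) {
      abort(paste0("no samples for cell line '", cell_line,
                   "', condition '", cond, "'"))
    }
    s
  }
  num <- pick(numerator)
  den <- pick(denominator)
  avg <- if (summary == "geometric") {
    function(x) exp(rowMeans(log(x)))
  } else {
    rowMeans
  }
  # floor zeros as in normalize_expression so ratios stay finite
  eps <- 1e-6 * median(m[m > 0])
  m[m == 0] <- eps
  tibble(
    mirna = rownames(m),
    ratio = unname(avg(m[, num, drop = FALSE]) / avg(m[, den, drop = FALSE])),
    n_num = length(num),
    n_den = length(den)
  )
}

#' Dysregulation call from a linear ratio
#'
#' A miRNA is called `up` when its ratio reaches the threshold, `down` when
#' it reaches the reciprocal threshold, and `none` otherwise. Boundaries are
#' inclusive, matching the published "absolute fold-regulation >= 1.2" rule.
#'
#' @param r Positive numeric vector of ratios.
#' @param threshold Dysregulation threshold on the ratio scale (> 1,
#'   default 1.2).
#' @return Character vector in {"up", "down", "none"}.
#' @examples
#' classify_dysregulation(c(1.2, 1 / 1.2, 1.0))
#' @export
classify_dysregulation <- function(r, threshold = 1.2) {
  if (threshold <= 1) abort("threshold must be > 1")
  if (any(r <= 0)) abort("ratios must be positive")
  dplyr::case_when(
    r >= threshold ~ "up",
    r <= 1 / threshold ~ "down",
    .default = "none"
  )
}

# ordered-pair call -> region lookup; the 3x3 grid minus its center.
# R2 (both up) and R6 (both down) are fixed by the published counts; the
# remaining numbering walks the grid so that R1-R3 are up in at least one
# line, R5-R7 down in at least one line, and R4/R8 are the discordant cells.
region_grid <- c(
  "up.none" = "R1", "up.up" = "R2", "none.up" = "R3", "down.up" = "R4",
  "down.none" = "R5", "down.down" = "R6", "none.down" = "R7",
  "up.down" = "R8", "none.none" = "CENTER"
)

#' Joint two-line region label
#'
#' Classifies each miRNA by the ordered pair of per-line dysregulation
#' calls into eight regions plus a center: R2/R6 are the concordant up/down
#' cells, R1/R3 (R5/R7) are up (down) in exactly one line, R4/R8 are the
#' discordant corners, and (none, none) is CENTER.
#'
#' @param call1,call2 Character vectors of calls in {"up", "down", "none"}
#'   for the first and second cell line.
#' @return Character vector of labels R1..R8 or CENTER.
#' @examples
#' assign_region("up", "up")    # "R2"
#' assign_region("none", "none") # "CENTER"
#' @export
assign_region <- function(call1, call2) {
  ok <- c("up", "down", "none")
  if (!all(call1 %in% ok) || !all(call2 %in% ok)) {
    abort("calls must be one of 'up', 'down', 'none'")
  }
  unname(region_grid[paste(call1, call2, sep = ".")])
}

#' Build the paired cell-line exposure panel
#'
#' Runs the full paired profiling stage: per-line exposed/parental ratios,
#' inclusive-threshold dysregulation calls, and the joint region
#' classification across the first two cell lines. Derived sets follow the
#' published arithmetic: `up_any` = R1+R2+R3 (up in at least one line),
#' `down_any` = R5+R6+R7, `common_up` = R2, `common_down` = R6,
#' `discordant` = R4+R8.
#'
#' @inheritParams group_ratio
#' @param lines Character vector of >= 2 cell lines (default: all annotated
#'   lines, in annotation order). Regions use the first two.
#' @param threshold Ratio-scale dysregulation threshold (default 1.2).
#' @param normalize Median-normalize first (default TRUE).
#' @return An object of class `ane_panel`: list with `panel` (tibble: mirna,
#'   fc_<line> and call_<line> per line, region), `sets` (named list of
#'   miRNA id vectors), `lines`, `threshold`.
#' @examples
#' sim <- simulate_ane_experiment(sim_config(n_mirnas = 50, seed = 1))
#' pan <- build_ane_panel(sim$expr, sim$annot)
#' glance(pan)
#' @export
build_ane_panel <- function(expr, annot, lines = NULL, threshold = 1.2,
                            summary = c("geometric", "arithmetic"),
                            normalize = TRUE) {
  summary <- match.arg(summary)
  check_annotations(annot, names(expr)[-1], c("cell_line", "condition"))
  lines <- lines %||% unique(annot$cell_line)
  if (length(lines) < 2) abort("need at least 2 cell lines")
  if (normalize) expr <- normalize_expression(expr)

  per_line <- map(lines, function(ln) {
    group_ratio(expr, annot, ln, summary = summary) |>
      mutate(call = classify_dysregulation(.data$ratio, threshold)) |>
      select("mirna", "ratio", "call") |>
      rename_with(~ paste0(c("fc_", "call_"), ln), c("ratio", "call"))
  })
  panel <- purrr::reduce(per_line, left_join, by = "mirna")
  panel$region <- assign_region(
    panel[[paste0("call_", lines[1])]],
    panel[[paste0("call_", lines[2])]]
  )

  in_region <- function(regions) panel$mirna[panel$region %in% regions]
  sets <- list(
    up_any = in_region(c("R1", "R2", "R3")),
    down_any = in_region(c("R5", "R6", "R7")),
    common_up = in_region("R2"),
    common_down = in_region("R6"),
    discordant = in_region(c("R4", "R8")),
    center = in_region("CENTER")
  )
  structure(
    list(panel = panel, sets = sets, lines = lines, threshold = threshold),
    class = "ane_panel"
  )
}

#' @export
print.ane_panel <- function(x, ...) {
  cat("Paired-exposure miRNA panel (", length(x$lines), " lines, threshold ",
      x$threshold, ")\n", sep = "")
  cat("  ", nrow(x$panel), " miRNAs: ",
      length(x$sets$up_any), " up in >=1 line, ",
      length(x$sets$down_any), " down in >=1 line (",
      length(x$sets$common_up), " common up, ",
      length(x$sets$common_down), " common down, ",
      length(x$sets$discordant), " discordant)\n", sep = "")
  invisible(x)
}
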