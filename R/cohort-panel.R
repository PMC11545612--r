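#' Single-sample rank-enrichment score
#'
#' A rank running-sum statistic for one sample: features are ordered by
#' decreasing expression and the cumulative in-set fraction is compared to
#' the cumulative out-of-set fraction along the list; the score is the mean
#' difference (positive when set members concentrate at the top). With the
#' default exponent 0 the statistic depends only on feature ranks, so it is
#' invariant to monotone transforms of the expression values and has exactly
#' zero expectation for a random set. A positive exponent weights in-set
#' increments by descending-rank importance, as in weighted single-sample
#' enrichment variants.
#'
#' @param values Named numeric vector: expression of one sample, names are
#'   feature identifiers.
#' @param gene_set Character vector of set members; at least 10 must overlap
#'   `names(values)`.
#' @param exponent Rank-weighting exponent (default 0 = unweighted).
#' @return A single numeric score, roughly in (-1, 1).
#' @examples
#' v <- setNames(seq(100, 1), paste0("g", 1:100))
#' ssgsea_score(v, paste0("g", 1:15)) > 0
#' @export
ssgsea_score <- function(values, gene_set, exponent = 0) {
  overlap <- intersect(names(values), gene_set)
  if (length(overlap) < 10) {
    abort("fewer than 10 gene-set members overlap the sample's features")
  }
  n <- length(values)
  ord <- order(values, decreasing = TRUE)
  in_set <- names(values)[ord] %in% overlap
  w <- (n - seq_len(n) + 1)^exponent
  p_hit <- cumsum(ifelse(in_set, w, 0)) / sum(w[in_set])
  p_miss <- cumsum(!in_set) / (n - length(overlap))
  mean(p_hit - p_miss)
}

#' Stromal and immune admixture scores for a cohort
#'
#' @param expr Expression tibble (features x samples).
#' @param signatures List with character vectors `stromal` and `immune`
#'   (feature identifiers enriched in non-malignant admixture).
#' @param exponent Passed to [ssgsea_score()].
#' @return Tibble: sample, stromal, immune, combined.
#' @export
admixture_scores <- function(expr, signatures, exponent = 0) {
  stopifnot(all(c("stromal", "immune") %in% names(signatures)))
  m <- expr_matrix(expr)
  score <- function(set) {
    apply(m, 2, function(col) ssgsea_score(setNames(col, rownames(m)), set,
                                           exponent = exponent))
  }
  tibble(
    sample = colnames(m),
    stromal = score(signatures$stromal),
    immune = score(signatures$immune)
  ) |>
    mutate(combined = .data$stromal + .data$immune)
}

#' Tumor purity from combined admixture scores
#'
#' Maps the combined (stromal + immune) score monotonically down to a purity
#' in (0.05, 1]. The default `"anchor"` method calibrates linearly on the
#' cohort: the score of a contamination-free tumor (`zero_score`, by default
#' the cohort minimum) maps to purity 1 and the mean score of the normal
#' samples (`reference_score`, pure admixture) maps to purity 0. The
#' `"rank"` method uses the within-cohort rank percentile instead, which is
#' robust to score nonlinearity when the cohort spans the contamination
#' range evenly.
#'
#' @param combined Numeric vector of combined scores (tumor samples).
#' @param reference_score Score level corresponding to full contamination
#'   (required for the anchor method; e.g. mean score of normal samples).
#' @param zero_score Score level corresponding to a pure tumor (default
#'   `min(combined)`).
#' @param method `"anchor"` or `"rank"`.
#' @param floor Lower clip for purity (default 0.05).
#' @return Numeric vector of purities in (floor, 1].
#' @export
estimate_purity <- function(combined, reference_score = NULL,
                            zero_score = min(combined),
                            method = c("anchor", "rank"), floor = 0.05) {
  method <- match.arg(method)
  if (any(!is.finite(combined))) abort("combined scores must be finite")
  if (method == "anchor") {
    if (is.null(reference_score)) {
      abort("anchor calibration needs a reference_score (full-admixture score level)")
    }
    if (reference_score <= zero_score) {
      abort("reference_score must exceed zero_score")
    }
    purity <- 1 - (combined - zero_score) / (reference_score - zero_score)
  } else {
    n <- length(combined)
    purity <- if (n == 1) 1 else 1 - (rank(combined, ties.method = "average") - 1) / (n - 1)
  }
  pmin(pmax(purity, floor + 1e-9), 1)
}

#' Linear de-mixing of observed tumor expression
#'
#' Inverts the mixture model observed = purity * tumor + (1 - purity) *
#' normal_reference: adjusted = (observed - (1 - purity) * reference) /
#' purity, floored at 0. With exact purity and reference this is the exact
#' algebraic inverse.
#'
#' @param observed Numeric vector or matrix (features x samples) of observed
#'   tumor expression.
#' @param purity Purity in (0, 1]; scalar or one value per sample column.
#' @param normal_reference Numeric vector: per-feature reference level of
#'   the non-malignant admixture.
#' @return Adjusted values, same shape as `observed`.
#' @examples
#' truth <- c(10, 4); normal <- c(2, 8)
#' obs <- 0.6 * truth + 0.4 * normal
#' purity_adjust(obs, 0.6, normal)
#' @export
purity_adjust <- function(observed, purity, normal_reference) {
  if (any(purity <= 0) || any(purity > 1)) abort("purity must be in (0, 1]")
  if (is.matrix(observed)) {
    stopifnot(length(purity) %in% c(1, ncol(observed)),
              length(normal_reference) == nrow(observed))
    adj <- sweep(observed - outer(normal_reference, 1 - purity), 2, purity, `/`)
  } else {
    adj <- (observed - (1 - purity) * normal_reference) / purity
  }
  pmax(adj, 0)
}

#' Two-sided unpaired t-test p-value on log-scale expression
#'
#' Welch's variant by default (the cohorts it is used on are heavily
#' unbalanced); Student's pooled-variance variant behind the flag. Values
#' are log2-transformed (with a small floor for zeros) before testing.
#' Degenerate input (both groups constant and equal) returns p = 1.
#'
#' @param group_a,group_b Numeric vectors (n >= 2 each) of linear-scale
#'   expression.
#' @param variant `"welch"` or `"student"`.
#' @param log_transform Log2-transform before testing (default TRUE).
#' @return Two-sided p-value.
#' @export
unpaired_t <- function(group_a, group_b, variant = c("welch", "student"),
                       log_transform = TRUE) {
  variant <- match.arg(variant)
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least 2 observations")
  }
  if (any(!is.finite(group_a)) || any(!is.finite(group_b))) {
    abort("values must be finite")
  }
  if (log_transform) {
    eps <- 1e-9
    group_a <- log2(pmax(group_a, eps))
    group_b <- log2(pmax(group_b, eps))
  }
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    return(if (isTRUE(all.equal(mean(group_a), mean(group_b)))) 1 else 0)
  }
  t.test(group_a, group_b, var.equal = (variant == "student"))$p.value
}

#' Tumor/normal cohort differential screen
#'
#' Per-miRNA signed tumor/normal fold-regulation (ratio of group geometric
#' means, signed dialect) and unpaired t-test p-value, with optional
#' purity calibration of the tumor samples by linear de-mixing against the
#' normal-sample geometric-mean reference. Selection keeps miRNAs with
#' |fold-regulation| >= `fr_threshold` (inclusive) and p < `alpha` (raw p,
#' matching the published screen; Benjamini-Hochberg values are reported
#' alongside when `bh = TRUE`).
#'
#' Purity comes from, in order of preference: the `purity` annotation
#' column (`calibrate = "supplied"` or `"auto"`), or estimation from
#' admixture `signatures` via [admixture_scores()] and [estimate_purity()]
#' (`calibrate = "estimate"`, or `"auto"` when no purity column exists and
#' signatures are given). `calibrate = "none"` skips calibration.
#'
#' @param expr,annot Expression and annotation tibbles; annotation needs
#'   `sample` and `tissue` in {tumor, normal}, optionally `purity`.
#' @param fr_threshold Signed fold-regulation magnitude cutoff (default 1.2).
#' @param alpha Raw p-value cutoff (default 0.05).
#' @param calibrate `"auto"`, `"supplied"`, `"estimate"`, or `"none"`.
#' @param signatures Optional list(stromal=, immune=) of admixture signature
#'   features for the estimation path.
#' @param variant t-test variant, see [unpaired_t()].
#' @param bh Also report Benjamini-Hochberg adjusted p-values (default
#'   FALSE; never used for the default selection).
#' @param min_purity Tumor samples below this purity are dropped from a
#'   calibrated screen (default 0.2): linear de-mixing divides by purity,
#'   so near-zero-purity samples contribute almost pure noise
#'   amplification. Ignored when not calibrating.
#' @return An object of class `cohort_panel`: list with `records` (tibble:
#'   mirna, tn_fr, p, fdr?, selected, direction, calibrated), `purity`
#'   (tibble sample/purity or NULL), and the thresholds used.
#' @examples
#' sim <- simulate_cohort(sim_config(n_mirnas = 60, seed = 1))
#' cp <- build_cohort_panel(sim$expr, sim$annot)
#' glance(cp)
#' @export
build_cohort_panel <- function(expr, annot, fr_threshold = 1.2, alpha = 0.05,
                               calibrate = c("auto", "supplied", "estimate", "none"),
                               signatures = NULL,
                               variant = c("welch", "student"), bh = FALSE,
                               min_purity = 0.2) {
  calibrate <- match.arg(calibrate)
  variant <- match.arg(variant)
  m <- expr_matrix(expr)
  check_annotations(annot, colnames(m), "tissue")
  ann <- annot[match(colnames(m), annot$sample), ]
  tumor <- colnames(m)[ann$tissue == "tumor"]
  normal <- colnames(m)[ann$tissue == "normal"]
  if (length(tumor) < 2 || length(normal) < 2) {
    abort("need at least 2 tumor and 2 normal samples")
  }

  eps <- 1e-6 * median(m[m > 0])
  m[m == 0] <- eps
  normal_ref <- exp(rowMeans(log(m[, normal, drop = FALSE])))

  purity <- NULL
  if (calibrate == "auto") {
    calibrate <- if ("purity" %in% names(annot) &&
                     !all(is.na(ann$purity[ann$tissue == "tumor"]))) {
      "supplied"
    } else if (!is.null(signatures)) "estimate" else "none"
  }
  if (calibrate == "supplied") {
    if (!"purity" %in% names(annot)) abort("calibrate='supplied' but no purity column")
    purity <- setNames(ann$purity[match(tumor, ann$sample)], tumor)
    if (any(is.na(purity) | purity <= 0 | purity > 1)) {
      abort("supplied purity must be in (0, 1] for every tumor sample")
    }
  } else if (calibrate == "estimate") {
    if (is.null(signatures)) abort("calibrate='estimate' needs admixture signatures")
    sc <- admixture_scores(expr, signatures)
    tumor_sc <- sc$combined[match(tumor, sc$sample)]
    normal_sc <- sc$combined[match(normal, sc$sample)]
    purity <- setNames(
      estimate_purity(tumor_sc, reference_score = mean(normal_sc)),
      tumor
    )
  }

  if (!is.null(purity) && any(purity < min_purity)) {
    drop <- names(purity)[purity < min_purity]
    if (length(tumor) - length(drop) < 2) {
      abort("fewer than 2 tumor samples remain above min_purity")
    }
    tumor <- setdiff(tumor, drop)
    purity <- purity[tumor]
  }
  tumor_m <- m[, tumor, drop = FALSE]
  if (!is.null(purity)) {
    tumor_m <- purity_adjust(tumor_m, purity, normal_ref)
    tumor_m[tumor_m == 0] <- eps
  }

  tumor_gm <- exp(rowMeans(log(tumor_m)))
  ratio <- tumor_gm / normal_ref
  pvals <- vapply(seq_len(nrow(m)), function(i) {
    unpaired_t(tumor_m[i, ], m[i, normal], variant = variant)
  }, numeric(1))

  records <- tibble(
    mirna = rownames(m),
    tn_fr = fr_from_ratio(ratio, "signed"),
    p = pvals,
    calibrated = !is.null(purity)
  )
  if (bh) records$fdr <- adjust_bh(records$p)
  records <- records |>
    mutate(
      selected = abs(.data$tn_fr) >= fr_threshold & .data$p < alpha,
      direction = dplyr::case_when(
        .data$selected & .data$tn_fr > 0 ~ "over",
        .data$selected & .data$tn_fr < 0 ~ "under",
        .default = "none"
      )
    )

  structure(
    list(
      records = records,
      purity = if (is.null(purity)) NULL else tibble(sample = names(purity), purity = unname(purity)),
      fr_threshold = fr_threshold, alpha = alpha, calibrate = calibrate
    ),
    class = "cohort_panel"
  )
}

#' @export
print.cohort_panel <- function(x, ...) {
  cat("Tumor/normal cohort miRNA screen (|FR| >= ", x$fr_threshold,
      ", p < ", x$alpha, ", calibration: ", x$calibrate, ")\n", sep = "")
  cat("  ", nrow(x$records), " miRNAs, ", sum(x$records$selected),
      " selected (", sum(x$records$direction == "over"), " over, ",
      sum(x$records$direction == "under"), " under)\n", sep = "")
  invisible(x)
}
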