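#' Signed fold-regulation algebra
#'
#' Expression changes circulate in two printed dialects built on the same
#' underlying linear ratio (treated/reference or tumor/normal):
#'
#' * `"ratio"` — the ratio itself; down-regulation appears as a value below 1
#'   (e.g. 0.91).
#' * `"signed"` — fold-regulation; a ratio r < 1 is written as the negative
#'   reciprocal −1/r, so a halving prints as −2 rather than 0.5.
#'
#' `fr_from_ratio()` and `fr_to_ratio()` convert between the two;
#' `average_fold_regulation()` averages a set of values *on the linear ratio
#' scale* (the only averaging rule consistent with published panel tables,
#' e.g. two concordant negatives −5.68 and −4.08 average to −4.75, a
#' harmonic-mean-like behaviour) and re-expresses the mean in the requested
#' dialect; `render_report_value()` formats with decimal half-up rounding for
#' report parity.
#'
#' One dialect quirk is accepted on input: legacy signed-dialect tables print
#' magnitudes below 1 (e.g. −0.88) meaning ratio = 1/0.88, i.e. the negative
#' reciprocal applied to a ratio slightly above 1. `fr_to_ratio()` therefore
#' maps any negative signed value v to −1/v. Such values are never produced
#' on output.
#'
#' @param r Positive numeric vector of linear expression ratios.
#' @param v Numeric vector of fold-regulation values.
#' @param dialect One of `"signed"` or `"ratio"`.
#' @param values Numeric vector of fold-regulation values to average.
#' @param in_dialect,out_dialect Dialects of `values` and of the result.
#' @param decimals Non-negative integer; decimals kept by
#'   `render_report_value()` (default 2, matching published tables).
#'
#' @return `fr_from_ratio()` and `average_fold_regulation()` return numeric
#'   vectors in the requested dialect; `fr_to_ratio()` returns positive
#'   ratios; `render_report_value()` returns character.
#'
#' @examples
#' fr_from_ratio(c(2, 0.5), "signed")          # 2, -2
#' fr_to_ratio(-4.08, "signed")                # 0.2451
#' average_fold_regulation(c(-5.68, -4.08), "signed")  # -4.749
#' render_report_value(-4.749)                 # "-4.75"
#' @name fold_regulation
NULL

fr_dialects <- c("signed", "ratio")

#' @rdname fold_regulation
#' @export
fr_from_ratio <- function(r, dialect = c("signed", "ratio")) {
  dialect <- match.arg(dialect)
  if (!is.numeric(r) || any(!is.finite(r)) || any(r <= 0)) {
    abort("ratios must be finite and strictly positive")
  }
  if (dialect == "ratio") return(as.numeric(r))
  ifelse(r >= 1, r, -1 / r)
}

#' @rdname fold_regulation
#' @export
fr_to_ratio <- function(v, dialect = c("signed", "ratio")) {
  dialect <- match.arg(dialect)
  if (!is.numeric(v) || any(!is.finite(v))) {
    abort("fold-regulation values must be finite numbers")
  }
  if (dialect == "ratio") {
    if (any(v <= 0)) abort("ratio-dialect values must be strictly positive")
    return(as.numeric(v))
  }
  if (any(v == 0)) abort("signed-dialect fold-regulation cannot be 0")
  ifelse(v > 0, v, -1 / v)
}

#' @rdname fold_regulation
#' @export
average_fold_regulation <- function(values,
                                    in_dialect = c("signed", "ratio"),
                                    out_dialect = in_dialect) {
  in_dialect <- match.arg(in_dialect)
  out_dialect <- match.arg(out_dialect, fr_dialects)
  if (length(values) == 0) abort("cannot average an empty set of fold-regulations")
  fr_from_ratio(mean(fr_to_ratio(values, in_dialect)), out_dialect)
}

#' @rdname fold_regulation
#' @export
render_report_value <- function(v, decimals = 2L) {
  stopifnot(is.numeric(v), decimals >= 0)
  sprintf(paste0("%.", decimals, "f"), round_half_up(v, decimals))
}

# Decimal half-up rounding (base round() is half-even). The epsilon absorbs
# binary representation error in values derived from 2-decimal inputs, e.g.
# mean(c(39.40, 26.15)) which sits one ulp below 32.775.
round_half_up <- function(x, decimals = 2L) {
  scale <- 10^decimals
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}
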