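#' Benjamini-Hochberg step-up FDR adjustment
#'
#' One p per gene — the gene's selected (minimum or median-cut) log-rank
#' p — adjusted across all genes that completed scanning. The within-gene
#' multiplicity of the ~166 serial cuts is deliberately not corrected here;
#' the gene-wise family is the unit of the screen. Delegates to
#' [stats::p.adjust()].
#'
#' @param raw p-value vector, values in (0, 1].
#' @return FDR-adjusted vector, same order, capped at 1.
#' @export
bh_adjust <- function(raw) {
  if (length(raw) == 0L) return(numeric())
  stopifnot(all(raw > 0), all(raw <= 1))
  stats::p.adjust(raw, method = "BH")
}

#' Bonferroni adjustment with an explicit family size
#'
#' `min(1, p * m)` elementwise. The multiplier `m` defaults to the number
#' of p values supplied (genes that completed the scan) but is exposed
#' because the appropriate family can be larger than the vector at hand
#' (e.g. all genes attempted rather than all genes that succeeded).
#'
#' @param raw p-value vector in (0, 1].
#' @param m family size, at least `length(raw)`.
#' @return adjusted vector capped at 1.
#' @export
bonferroni_adjust <- function(raw, m = length(raw)) {
  if (length(raw) == 0L) return(numeric())
  stopifnot(all(raw > 0), all(raw <= 1))
  if (m < length(raw)) stop("family size m smaller than the number of p values")
  pmin(1, raw * m)
}

#' Adjust a gene-wise p-value family both ways
#'
#' @param raw p-value vector.
#' @param m Bonferroni family size (default `length(raw)`).
#' @return data.frame (raw, fdr, bonferroni) with `m` as an attribute;
#'   elementwise raw <= fdr <= bonferroni.
#' @export
adjust_pvalues <- function(raw, m = length(raw)) {
  out <- data.frame(raw = raw, fdr = bh_adjust(raw),
                    bonferroni = bonferroni_adjust(raw, m))
  attr(out, "m") <- m
  out
}
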