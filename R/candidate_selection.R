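#' Default candidate-selection criteria
#'
#' Significance below 0.05 after adjustment (FDR at the screening stage,
#' Bonferroni for final candidates) plus an effect-size gate: hazard ratio
#' at least 1.8 or at most 0.6 in both the univariate and the multivariate
#' Cox model, on the same side in both.
#'
#' @param fdr_threshold,bonferroni_threshold adjusted-p thresholds.
#' @param hr_low,hr_high protective/harmful hazard-ratio gates,
#'   `0 < hr_low < 1 < hr_high`.
#' @return list of thresholds used by [apply_gates()].
#' @export
candidate_criteria <- function(fdr_threshold = 0.05,
                               bonferroni_threshold = 0.05,
                               hr_low = 0.6, hr_high = 1.8) {
  stopifnot(hr_low > 0, hr_low < 1, hr_high > 1)
  list(fdr_threshold = fdr_threshold,
       bonferroni_threshold = bonferroni_threshold,
       hr_low = hr_low, hr_high = hr_high)
}

# direction of a gene effect given its two HRs under the gate, or NA
hr_gate_direction <- function(uni_hr, multi_hr, hr_low, hr_high) {
  harmful <- uni_hr >= hr_high & multi_hr >= hr_high
  protective <- uni_hr <= hr_low & multi_hr <= hr_low
  ifelse(harmful, "harmful", ifelse(protective, "protective", NA_character_))
}

#' Apply the significance and effect-size gates to per-gene results
#'
#' A gene is selected iff its stage-appropriate adjusted p (FDR at the
#' screening stage, Bonferroni at the candidate stage) is below threshold
#' AND both Cox hazard ratios clear the effect-size gate on the same side
#' (both >= 1.8, or both <= 0.6); mixed directions are rejected.
#'
#' @param results data.frame with columns `gene`, `fdr_p`, `bonferroni_p`,
#'   `uni_hr`, `multi_hr` (other columns carried through). Genes with a
#'   missing HR (Cox not estimable) never pass.
#' @param criteria list from [candidate_criteria()].
#' @param stage which adjusted p gates significance: `"bonferroni"`
#'   (default, candidate stage) or `"fdr"` (screening stage).
#' @return the selected rows, with a `direction` column appended.
#' @export
apply_gates <- function(results, criteria = candidate_criteria(),
                        stage = c("bonferroni", "fdr")) {
  stage <- match.arg(stage)
  if (nrow(results) == 0L) {
    results$direction <- character(0)
    return(results)
  }
  p <- if (stage == "fdr") results$fdr_p else results$bonferroni_p
  thr <- if (stage == "fdr") criteria$fdr_threshold else criteria$bonferroni_threshold
  dir <- hr_gate_direction(results$uni_hr, results$multi_hr,
                           criteria$hr_low, criteria$hr_high)
  keep <- !is.na(p) & p < thr & !is.na(dir)
  out <- results[keep, , drop = FALSE]
  out$direction <- dir[keep]
  rownames(out) <- NULL
  out
}

#' Two-cohort consensus candidate list
#'
#' Intersects discovery candidates (optimal-cut screen, Bonferroni-gated)
#' with genes that independently pass in the validation cohort under
#' median cutpoints (FDR < threshold plus the same HR gate) with the same
#' effect direction. Discovery genes absent from the validation cohort, or
#' flipping direction, are recorded as not validated rather than erroring.
#'
#' @param discovery data.frame from [apply_gates()] on the discovery
#'   cohort (must carry `gene` and `direction`).
#' @param validation data.frame of per-gene validation results with
#'   `gene`, `fdr_p`, `uni_hr`, `multi_hr`.
#' @param criteria list from [candidate_criteria()].
#' @return data.frame, one row per discovery candidate: gene, discovery
#'   direction, `validated` flag, `validation_status`
#'   (`validated` / `direction-flip` / `not-significant` /
#'   `absent-from-validation` / `hr-gate-failed`), and the validation
#'   HRs/p where available. The consensus list is the `validated` subset.
#' @export
consensus <- function(discovery, validation, criteria = candidate_criteria()) {
  if (nrow(discovery) == 0L) {
    return(data.frame(gene = character(), direction = character(),
                      validated = logical(), validation_status = character()))
  }
  idx <- match(discovery$gene, validation$gene)
  v_fdr <- validation$fdr_p[idx]
  v_uni <- validation$uni_hr[idx]
  v_multi <- validation$multi_hr[idx]
  v_dir <- hr_gate_direction(v_uni, v_multi, criteria$hr_low, criteria$hr_high)

  status <- ifelse(
    is.na(idx), "absent-from-validation",
    ifelse(is.na(v_fdr) | v_fdr >= criteria$fdr_threshold, "not-significant",
    ifelse(is.na(v_dir), "hr-gate-failed",
    ifelse(v_dir != discovery$direction, "direction-flip", "validated")))
  )
  data.frame(
    gene = discovery$gene,
    direction = discovery$direction,
    validated = status == "validated",
    validation_status = status,
    validation_fdr_p = v_fdr,
    validation_uni_hr = v_uni,
    validation_multi_hr = v_multi
  )
}

#' Compare the optimal-cut and median-cut screening strategies
#'
#' Runs the screen twice on the same dataset — sliding-window optimal
#' cutpoints versus fixed median cutpoints — and tabulates how many genes
#' reach raw p < `sig_level` and FDR-adjusted p < `sig_level` under each.
#' Because the minimum over the cut grid is never larger than the p at any
#' single cut, the optimal strategy's raw count always dominates the
#' median strategy's on genes where the median cut is admissible.
#'
#' @param dataset an `analysis_dataset`.
#' @param lo_frac,hi_frac cut-grid band.
#' @param sig_level significance level for the counts.
#' @return list with the four counts (`optimal_raw`, `optimal_fdr`,
#'   `median_raw`, `median_fdr`), the number of genes scanned under each
#'   strategy, and both `screen_result`s.
#' @export
compare_strategies <- function(dataset, lo_frac = 0.30, hi_frac = 0.70,
                               sig_level = 0.05) {
  opt <- scan_all(dataset, lo_frac, hi_frac, sig_level, mode = "optimal")
  med <- scan_all(dataset, lo_frac, hi_frac, sig_level, mode = "median")
  count2 <- function(sr) {
    p <- sr$cuts$p_min
    c(raw = sum(p < sig_level), fdr = sum(bh_adjust(p) < sig_level))
  }
  co <- count2(opt); cm <- count2(med)
  list(optimal_raw = unname(co["raw"]), optimal_fdr = unname(co["fdr"]),
       median_raw = unname(cm["raw"]), median_fdr = unname(cm["fdr"]),
       n_optimal = nrow(opt$cuts), n_median = nrow(med$cuts),
       optimal = opt, median = med)
}

#' Hazard-ratio concordance between two cohorts
#'
#' Pearson product-moment correlation of per-gene hazard ratios estimated
#' in a discovery and a validation cohort, on the HR scale as concordance
#' scatter plots are conventionally drawn; correlation of log HRs is
#' available because ratios are scale-asymmetric around 1.
#'
#' @param hr_discovery,hr_validation paired HR vectors, length >= 3.
#' @param log_scale correlate log HRs instead (default FALSE).
#' @return Pearson correlation coefficient.
#' @export
hr_concordance <- function(hr_discovery, hr_validation, log_scale = FALSE) {
  stopifnot(length(hr_discovery) == length(hr_validation),
            length(hr_discovery) >= 3)
  x <- if (log_scale) log(hr_discovery) else hr_discovery
  y <- if (log_scale) log(hr_validation) else hr_validation
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in hazard ratios; correlation undefined")
  }
  stats::cor(x, y, method = "pearson")
}

#' Volcano-plot table
#'
#' One row per gene with the log10 adjusted p (x axis) and the hazard
#' ratio (y axis), flagged harmful (HR > 1) or protective (HR < 1).
#'
#' @param results per-gene data.frame with `gene`, an adjusted p column
#'   and an HR column.
#' @param p_col,hr_col column names to use (defaults `fdr_p`, `multi_hr`).
#' @return data.frame (gene, log10_adj_p, hr, direction).
#' @export
volcano_data <- function(results, p_col = "fdr_p", hr_col = "multi_hr") {
  if (nrow(results) == 0L) {
    return(data.frame(gene = character(), log10_adj_p = numeric(),
                      hr = numeric(), direction = character()))
  }
  hr <- results[[hr_col]]
  data.frame(
    gene = results$gene,
    log10_adj_p = log10(results[[p_col]]),
    hr = hr,
    direction = ifelse(hr > 1, "harmful", ifelse(hr < 1, "protective", "null"))
  )
}
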