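# write a TSV with provenance comment lines ("# key: value") above the
# header; deliberately no timestamps so identical runs are byte-identical
write_tsv_report <- function(df, path, meta = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(meta)) {
    writeLines(sprintf("# %s: %s", nm, paste(meta[[nm]], collapse = " ")), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# low/high group indicator for a gene at a rank cut, reconstructed with the
# same deterministic ordering the scan used; returns NA for null-masked
# patients
gene_group_indicator <- function(dataset, gene, rank_k) {
  gi <- match(gene, rownames(dataset$expression))
  if (is.na(gi)) stop("gene not present in dataset: ", gene)
  mask <- attr(dataset$expression, "null_mask")[gi, ]
  obs <- which(!mask)
  vals <- dataset$expression[gi, obs]
  ids <- dataset$clinical$patient_id[obs]
  ord <- rank_patients(vals, ids)
  high <- rep(NA_integer_, ncol(dataset$expression))
  high[obs[ord]] <- rep(c(0L, 1L), c(rank_k, length(obs) - rank_k))
  high
}

# Univariate + multivariate Cox for a set of genes at their selected cuts.
# Clinical covariates constant in a gene's observed subset are dropped from
# that multivariate fit (e.g. distant metastasis in a cohort with no M1
# patients) and recorded.
cox_gene_results <- function(dataset, cuts, genes, tobacco_split = NULL) {
  if (is.null(tobacco_split)) tobacco_split <- tobacco_median_split(dataset$clinical)
  binaries <- dichotomize(dataset$clinical, tobacco_split)
  times <- dataset$clinical$time
  events <- dataset$clinical$event
  out <- data.frame(gene = genes, uni_hr = NA_real_, uni_lo = NA_real_,
                    uni_hi = NA_real_, uni_p = NA_real_, multi_hr = NA_real_,
                    multi_lo = NA_real_, multi_hi = NA_real_,
                    multi_p = NA_real_, cox_note = "")
  fails <- list()
  for (i in seq_along(genes)) {
    g <- genes[i]
    k <- cuts$rank_k[match(g, cuts$gene)]
    res <- tryCatch({
      high <- gene_group_indicator(dataset, g, k)
      obs <- !is.na(high)
      covs <- binaries[obs, , drop = FALSE]
      keep <- vapply(covs, function(z) length(unique(z)) > 1L, TRUE)
      uni <- cox_fit(data.frame(gene_high = high[obs]), times[obs], events[obs])
      multi <- suppressWarnings(
        multivariate_fit(covs[, keep, drop = FALSE], high[obs],
                         times[obs], events[obs])
      )
      mrow <- multi$table[multi$table$term == "gene_high", ]
      note <- if (all(keep)) "" else
        paste0("dropped constant covariate(s): ",
               paste(names(covs)[!keep], collapse = ","))
      if (!uni$converged || !multi$converged) {
        note <- paste(note, "non-converged fit", sep = if (nzchar(note)) "; " else "")
      }
      list(uni = uni$table, multi = mrow, note = note)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      category <- if (inherits(res, "survscreen_one_group_error")) {
        res$category %||% "one-group-cox"
      } else "unknown"
      fails[[g]] <- data.frame(gene = g, category = category,
                               message = conditionMessage(res))
    } else {
      out[i, c("uni_hr", "uni_lo", "uni_hi", "uni_p")] <-
        res$uni[, c("hr", "ci_lo", "ci_hi", "p")]
      out[i, c("multi_hr", "multi_lo", "multi_hi", "multi_p")] <-
        res$multi[, c("hr", "ci_lo", "ci_hi", "p")]
      out$cox_note[i] <- res$note
    }
  }
  list(table = out,
       failures = if (length(fails)) do.call(rbind, c(fails, make.row.names = FALSE))
                  else data.frame(gene = character(), category = character(),
                                  message = character()))
}

#' Run the discovery screen end to end
#'
#' Optimal-cut scan of every gene, gene-wise FDR and Bonferroni adjustment
#' of the selected p values, univariate and multivariate Cox fits at the
#' selected cutpoints, and the significance + effect-size gates. Cox
#' models are fitted for the genes whose stage-adjusted p clears the
#' significance threshold (`cox_genes = "significant"`, the default, which
#' is what the gates can ever select) or for every scanned gene
#' (`"all"`, for full volcano plots at genome scale cost).
#'
#' @param dataset an `analysis_dataset` (already merged and null-filtered).
#' @param lo_frac,hi_frac cut-grid percentile band (defaults 0.30, 0.70).
#' @param sig_level raw significance level for the median-fallback rule.
#' @param criteria gates from [candidate_criteria()].
#' @param stage which adjusted p gates candidacy: `"bonferroni"` (default)
#'   or `"fdr"`.
#' @param bonferroni_m Bonferroni family size; default = number of genes
#'   that completed the scan.
#' @param cox_genes `"significant"` or `"all"`.
#' @param tobacco_split pack-years split for the tobacco covariate;
#'   default = cohort median.
#' @param out_dir if non-NULL, write `gene_results.tsv`, `candidates.tsv`,
#'   `volcano.tsv` and `run_log.json` there.
#' @return object of class `discovery_run`: list with `results` (per-gene
#'   table: cut, raw/fdr/bonferroni p, HRs), `candidates` (gate-passing
#'   rows with direction), `screen` (the `screen_result`), `run_log`
#'   (failure categories and proportions), and the configuration used.
#' @export
run_discovery <- function(dataset, lo_frac = 0.30, hi_frac = 0.70,
                          sig_level = 0.05,
                          criteria = candidate_criteria(),
                          stage = c("bonferroni", "fdr"),
                          bonferroni_m = NULL,
                          cox_genes = c("significant", "all"),
                          tobacco_split = NULL, out_dir = NULL) {
  stage <- match.arg(stage)
  cox_genes <- match.arg(cox_genes)
  screen <- scan_all(dataset, lo_frac, hi_frac, sig_level, mode = "optimal")
  cuts <- screen$cuts
  m <- bonferroni_m %||% nrow(cuts)
  adj <- adjust_pvalues(cuts$p_min, m = m)
  results <- data.frame(
    gene = cuts$gene, n_used = cuts$n_used, rank_k = cuts$rank_k,
    n_low = cuts$n_low, n_high = cuts$n_high,
    cutoff_value = cuts$cutoff_value, used_fallback = cuts$used_fallback,
    raw_p = adj$raw, fdr_p = adj$fdr, bonferroni_p = adj$bonferroni
  )
  thr <- if (stage == "fdr") criteria$fdr_threshold else criteria$bonferroni_threshold
  stage_p <- if (stage == "fdr") results$fdr_p else results$bonferroni_p
  sel <- if (cox_genes == "all") results$gene else results$gene[stage_p < thr]
  cox <- cox_gene_results(dataset, cuts, sel, tobacco_split)
  results <- merge(results, cox$table, by = "gene", all.x = TRUE, sort = FALSE)
  results <- results[order(results$raw_p, results$gene), ]
  rownames(results) <- NULL
  candidates <- apply_gates(results, criteria, stage)

  failures <- rbind(screen$failures, cox$failures)
  run_log <- list(
    n_genes_input = nrow(dataset$expression),
    n_scanned = nrow(cuts),
    n_failed = nrow(failures),
    failure_counts = as.list(table(failures$category)),
    failure_proportions = if (nrow(failures))
      as.list(prop.table(table(failures$category))) else list(),
    excluded_genes = failures$gene
  )
  run <- structure(
    list(results = results, candidates = candidates, screen = screen,
         failures = failures, run_log = run_log,
         config = list(mode = "optimal", lo_frac = lo_frac, hi_frac = hi_frac,
                       sig_level = sig_level, stage = stage, bonferroni_m = m,
                       criteria = criteria)),
    class = "discovery_run"
  )
  if (!is.null(out_dir)) write_discovery(run, out_dir)
  run
}

#' @export
print.discovery_run <- function(x, ...) {
  cat(sprintf("Discovery run (%s gating): %d genes scanned, %d candidates\n",
              x$config$stage, nrow(x$results), nrow(x$candidates)))
  if (nrow(x$candidates)) {
    print(x$candidates[, c("gene", "raw_p", "fdr_p", "bonferroni_p",
                           "uni_hr", "multi_hr", "direction")],
          row.names = FALSE)
  }
  invisible(x)
}

write_discovery <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    pipeline = "survscreen discovery",
    mode = run$config$mode,
    band = sprintf("%.2f-%.2f", run$config$lo_frac, run$config$hi_frac),
    stage = run$config$stage,
    bonferroni_m = run$config$bonferroni_m
  )
  write_tsv_report(run$results, file.path(out_dir, "gene_results.tsv"), meta)
  write_tsv_report(run$candidates, file.path(out_dir, "candidates.tsv"), meta)
  has_hr <- !is.na(run$results$multi_hr)
  write_tsv_report(volcano_data(run$results[has_hr, , drop = FALSE]),
                   file.path(out_dir, "volcano.tsv"), meta)
  jsonlite::write_json(run$run_log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Run the validation screen and form the consensus list
#'
#' The validation cohort is screened under fixed median cutpoints with
#' FDR correction (no optimal-cut selection, so its p values carry no
#' minimum-p optimism), Cox models are fitted for the union of
#' FDR-significant genes and the discovery candidates, and the consensus
#' is the set of discovery candidates that independently pass
#' (FDR p < threshold, HR gate, same direction) in validation.
#'
#' @param dataset the validation `analysis_dataset`.
#' @param discovery a `discovery_run` (or its `candidates` data.frame).
#' @param lo_frac,hi_frac band (only used for grid bookkeeping).
#' @param criteria gates from [candidate_criteria()].
#' @param tobacco_split pack-years split (default: validation cohort median).
#' @param out_dir if non-NULL, write `validation_results.tsv` and
#'   `consensus.tsv` there.
#' @return object of class `validation_run`: list with `results`
#'   (per-gene median-cut table), `consensus` (per discovery candidate),
#'   `consensus_genes` (validated subset), `screen`, `run_log`.
#' @export
run_validation <- function(dataset, discovery, lo_frac = 0.30, hi_frac = 0.70,
                           criteria = candidate_criteria(),
                           tobacco_split = NULL, out_dir = NULL) {
  cand <- if (inherits(discovery, "discovery_run")) discovery$candidates
          else discovery
  screen <- scan_all(dataset, lo_frac, hi_frac, mode = "median")
  cuts <- screen$cuts
  adj <- adjust_pvalues(cuts$p_min, m = nrow(cuts))
  results <- data.frame(
    gene = cuts$gene, n_used = cuts$n_used, rank_k = cuts$rank_k,
    cutoff_value = cuts$cutoff_value,
    raw_p = adj$raw, fdr_p = adj$fdr, bonferroni_p = adj$bonferroni
  )
  sel <- union(results$gene[results$fdr_p < criteria$fdr_threshold],
               intersect(cand$gene, results$gene))
  cox <- cox_gene_results(dataset, cuts, sel, tobacco_split)
  results <- merge(results, cox$table, by = "gene", all.x = TRUE, sort = FALSE)
  cons <- consensus(cand, results, criteria)
  failures <- rbind(screen$failures, cox$failures)
  run <- structure(
    list(results = results, consensus = cons,
         consensus_genes = cons$gene[cons$validated],
         screen = screen,
         run_log = list(n_scanned = nrow(cuts), n_failed = nrow(failures),
                        failure_counts = as.list(table(failures$category))),
         config = list(mode = "median", criteria = criteria)),
    class = "validation_run"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    meta <- list(pipeline = "survscreen validation", mode = "median")
    write_tsv_report(run$results, file.path(out_dir, "validation_results.tsv"), meta)
    write_tsv_report(run$consensus, file.path(out_dir, "consensus.tsv"), meta)
  }
  run
}

#' @export
print.validation_run <- function(x, ...) {
  cat(sprintf("Validation run (median cutpoints): %d genes, %d/%d candidates validated\n",
              nrow(x$results), sum(x$consensus$validated), nrow(x$consensus)))
  invisible(x)
}

#' Per-feature survival table for one gene
#'
#' The conventional cohort-table layout: one row per dichotomized clinical
#' feature plus the gene's low/high indicator, with unadjusted
#' (univariate) and adjusted (multivariate) hazard ratios, 95\% CIs and
#' Wald p values side by side.
#'
#' @param dataset an `analysis_dataset`.
#' @param gene gene symbol.
#' @param rank_k low-group size defining the gene's cutpoint.
#' @param tobacco_split pack-years split (default cohort median).
#' @return data.frame (feature, level, uni_hr, uni_ci, uni_p, multi_hr,
#'   multi_ci, multi_p).
#' @export
feature_table <- function(dataset, gene, rank_k, tobacco_split = NULL) {
  if (is.null(tobacco_split)) tobacco_split <- tobacco_median_split(dataset$clinical)
  binaries <- dichotomize(dataset$clinical, tobacco_split)
  high <- gene_group_indicator(dataset, gene, rank_k)
  obs <- !is.na(high)
  times <- dataset$clinical$time[obs]
  events <- dataset$clinical$event[obs]
  covs <- binaries[obs, , drop = FALSE]
  uni <- univariate_table(covs, high[obs], times, events)
  keep <- vapply(covs, function(z) length(unique(z)) > 1L, TRUE)
  multi <- suppressWarnings(
    multivariate_fit(covs[, keep, drop = FALSE], high[obs], times, events)
  )
  levels_map <- c(
    male = "male", age_gt_65 = ">65y", t34 = "T3+T4", n_positive = "N+",
    m1 = "M1", late_stage = "stage III+IV", margin_positive = "positive",
    tobacco_high = "high pack-years", gene_high = "high expression"
  )
  ut <- uni$table
  mt <- multi$table
  fmt_ci <- function(lo, hi) sprintf("%.3f-%.3f", lo, hi)
  idx <- match(ut$term, mt$term)
  data.frame(
    feature = ut$term,
    level = ifelse(is.na(levels_map[ut$term]), ut$term,
                   unname(levels_map[ut$term])),
    uni_hr = round(ut$hr, 3),
    uni_ci = fmt_ci(ut$ci_lo, ut$ci_hi),
    uni_p = signif(ut$p, 3),
    multi_hr = round(mt$hr[idx], 3),
    multi_ci = ifelse(is.na(idx), NA, fmt_ci(mt$ci_lo[idx], mt$ci_hi[idx])),
    multi_p = signif(mt$p[idx], 3)
  )
}
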