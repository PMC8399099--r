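# Default clinical covariate structure for simulated cohorts: prevalence of
# the "1" level and its log hazard ratio. Prevalences loosely follow a large
# head-and-neck OS cohort (mostly male, mostly late stage, distant metastasis
# rare); effects are modest so the gene signal, not the confounders,
# dominates survival.
DEFAULT_COV_PREVALENCE <- c(
  male = 0.73, age_gt_65 = 0.36, t34 = 0.67, n_positive = 0.68, m1 = 0.01,
  late_stage = 0.79, margin_positive = 0.35, tobacco_high = 0.50
)
DEFAULT_COV_LOG_HR <- c(
  male = 0, age_gt_65 = log(1.4), t34 = log(1.5), n_positive = log(1.2),
  m1 = 0, late_stage = log(1.2), margin_positive = log(1.6),
  tobacco_high = log(1.3)
)

#' Build a gene-effect specification table
#'
#' @param n_null number of null genes (expression independent of survival).
#' @param threshold `NULL`, or a data.frame with one row per planted gene:
#'   `q` (true cut percentile in (0,1)) and `hr` (true hazard ratio of the
#'   above-threshold group, different from 1).
#' @return data.frame (gene, kind, q, hr); planted genes named `SIG01`...,
#'   nulls `NULL0001`...
#' @export
gene_effects <- function(n_null, threshold = NULL) {
  eff <- data.frame(gene = character(), kind = character(),
                    q = numeric(), hr = numeric())
  if (!is.null(threshold) && nrow(threshold)) {
    stopifnot(all(threshold$q > 0), all(threshold$q < 1),
              all(threshold$hr > 0), all(threshold$hr != 1))
    eff <- data.frame(
      gene = if (!is.null(threshold$gene)) threshold$gene
             else sprintf("SIG%02d", seq_len(nrow(threshold))),
      kind = "threshold", q = threshold$q, hr = threshold$hr
    )
  }
  if (n_null > 0) {
    eff <- rbind(eff, data.frame(gene = sprintf("NULL%04d", seq_len(n_null)),
                                 kind = "null", q = NA_real_, hr = NA_real_))
  }
  eff
}

#' Simulation configuration for a synthetic survival cohort
#'
#' Defines a cohort generated under the proportional-hazards model the
#' screen assumes: per-patient hazard
#' `baseline_rate * exp(sum(covariate effects) + sum(threshold-gene effects))`
#' with exponential event times (constant baseline hazard, so means and
#' event fractions have closed forms for checking), independent
#' exponential dropout, and administrative censoring at a fixed horizon.
#' A threshold gene multiplies the hazard by `hr` for patients whose
#' log2-scale expression (Gaussian) exceeds the gene's `q` empirical
#' quantile — the step effect the cutoff engine is built to find.
#'
#' @param n_patients cohort size.
#' @param effects gene-effect table from [gene_effects()].
#' @param baseline_rate baseline hazard, events per day. The default
#'   1.2e-4/day with a 5-year administrative horizon, light dropout and
#'   the default covariate load yields a realized censoring fraction near
#'   55-60\%, typical of an overall-survival cohort of this kind.
#' @param covariate_prevalence,covariate_log_hr named vectors over the
#'   eight binary clinical covariates.
#' @param admin_censor_time administrative censoring horizon in days
#'   (default 1826, five years).
#' @param dropout_rate exponential dropout hazard per day (0 disables).
#' @param null_value_fraction fraction of expression entries masked as
#'   not-expressed/missing.
#' @param expression_location,expression_scale mean and sd of the
#'   Gaussian log2-scale expression per gene.
#' @param tobacco_split pack-years split used when generating tobacco
#'   exposure, so the generated cohort dichotomizes consistently.
#' @param seed integer RNG seed; every draw is reproducible given it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 400,
                       effects = gene_effects(300),
                       baseline_rate = 1.2e-4,
                       covariate_prevalence = DEFAULT_COV_PREVALENCE,
                       covariate_log_hr = DEFAULT_COV_LOG_HR,
                       admin_censor_time = DAYS_5YR,
                       dropout_rate = 5e-5,
                       null_value_fraction = 0,
                       expression_location = 0,
                       expression_scale = 1,
                       tobacco_split = 40,
                       seed = 1L) {
  stopifnot(n_patients >= 1, baseline_rate > 0, admin_censor_time > 0,
            dropout_rate >= 0, null_value_fraction >= 0,
            null_value_fraction < 1, expression_scale > 0)
  stopifnot(all(covariate_prevalence > 0), all(covariate_prevalence < 1))
  if (baseline_rate * admin_censor_time < 1e-3) {
    warning("configuration implies almost no events before the censoring horizon")
  }
  structure(
    list(n_patients = as.integer(n_patients), effects = effects,
         baseline_rate = baseline_rate,
         covariate_prevalence = covariate_prevalence,
         covariate_log_hr = covariate_log_hr,
         admin_censor_time = admin_censor_time, dropout_rate = dropout_rate,
         null_value_fraction = null_value_fraction,
         expression_location = expression_location,
         expression_scale = expression_scale,
         tobacco_split = tobacco_split, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# run expr with the RNG seeded, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate an analysis dataset with known per-gene truth
#'
#' @param config a `sim_config`.
#' @return list with `dataset` (an `analysis_dataset`, same structure the
#'   readers produce) and `truth`: the gene-effect table, the per-patient
#'   true above-threshold indicator for each planted gene (`groups`,
#'   patients x planted genes), the realized censoring fraction and the
#'   tobacco split.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    N <- config$n_patients
    ids <- sprintf("SYN-%04d", seq_len(N))

    # binary clinical covariates, then raw profiles consistent with them
    cov_names <- names(config$covariate_prevalence)
    Z <- vapply(cov_names,
                function(nm) stats::rbinom(N, 1, config$covariate_prevalence[[nm]]),
                integer(N))
    Z <- matrix(Z, nrow = N, dimnames = list(NULL, cov_names))
    pick <- function(cond, yes, no) {
      out <- character(N)
      out[cond == 1] <- sample(yes, sum(cond == 1), replace = TRUE)
      out[cond == 0] <- sample(no, sum(cond == 0), replace = TRUE)
      out
    }
    clinical <- data.frame(
      patient_id = ids,
      time = NA_real_, event = NA_real_,
      gender = ifelse(Z[, "male"] == 1, "male", "female"),
      age_years = round(ifelse(Z[, "age_gt_65"] == 1,
                               stats::runif(N, 66, 88),
                               stats::runif(N, 30, 65)), 1),
      clinical_t = pick(Z[, "t34"], c("T3", "T4"), c("T1", "T2")),
      clinical_n = pick(Z[, "n_positive"], c("N1", "N2", "N3"), "N0"),
      clinical_m = ifelse(Z[, "m1"] == 1, "M1", "M0"),
      stage = pick(Z[, "late_stage"], c("III", "IV"), c("I", "II")),
      margin = ifelse(Z[, "margin_positive"] == 1, "positive", "negative"),
      tobacco_pack_years = round(ifelse(Z[, "tobacco_high"] == 1,
                                        config$tobacco_split + 0.1 +
                                          stats::rexp(N, 1 / 25),
                                        stats::runif(N, 0, config$tobacco_split)),
                                 1)
    )

    # expression: Gaussian on the log2 scale, one row per gene
    eff <- config$effects
    G <- nrow(eff)
    expr <- matrix(stats::rnorm(G * N, config$expression_location,
                                config$expression_scale),
                   nrow = G, ncol = N, dimnames = list(eff$gene, ids))

    # planted step effects on the hazard
    is_thr <- eff$kind == "threshold"
    groups <- NULL
    log_risk <- as.numeric(Z %*% config$covariate_log_hr[cov_names])
    if (any(is_thr)) {
      groups <- vapply(which(is_thr), function(gi) {
        as.integer(expr[gi, ] > stats::quantile(expr[gi, ], eff$q[gi], type = 7))
      }, integer(N))
      colnames(groups) <- eff$gene[is_thr]
      log_risk <- log_risk + as.numeric(groups %*% log(eff$hr[is_thr]))
    }

    hazard <- config$baseline_rate * exp(log_risk)
    t_event <- stats::rexp(N, rate = hazard)
    t_drop <- if (config$dropout_rate > 0) stats::rexp(N, config$dropout_rate)
              else rep(Inf, N)
    obs <- pmin(t_event, t_drop, config$admin_censor_time)
    clinical$time <- round(obs, 1)
    clinical$event <- as.integer(t_event <= pmin(t_drop, config$admin_censor_time))
    if (sum(clinical$event) == 0) {
      warning("simulated cohort has zero events")
    }

    # mask a fraction of entries as not-expressed
    mask <- matrix(FALSE, nrow = G, ncol = N)
    if (config$null_value_fraction > 0 && G > 0) {
      n_mask <- round(config$null_value_fraction * G * N)
      mask[sample.int(G * N, n_mask)] <- TRUE
    }
    expr <- as_expression_matrix(expr, null_mask = mask)

    clinical$complete <- TRUE
    dataset <- structure(
      list(clinical = clinical, expression = expr, dropped = character(),
           required_fields = c("gender", "age_years", "clinical_t",
                               "clinical_n", "clinical_m", "stage", "margin")),
      class = "analysis_dataset"
    )
    truth <- list(
      effects = eff,
      groups = groups,
      covariates = Z,
      censoring_fraction = 1 - mean(clinical$event),
      tobacco_split = config$tobacco_split,
      config = config
    )
    list(dataset = dataset, truth = truth)
  })
}

#' Simulate an all-null screening cohort
#'
#' Every gene's expression is independent of survival and no clinical
#' covariate carries an effect — the global-null configuration used to
#' characterize minimum-p inflation of the optimal-cut screen.
#'
#' @param n_patients,n_genes cohort and gene-set sizes.
#' @param baseline_rate events per day (default 3e-4).
#' @param admin_censor_time censoring horizon in days.
#' @param dropout_rate exponential dropout hazard.
#' @param seed RNG seed.
#' @return an `analysis_dataset` with all-null genes.
#' @export
simulate_null_screen <- function(n_patients, n_genes, baseline_rate = 3e-4,
                                 admin_censor_time = DAYS_5YR,
                                 dropout_rate = 0, seed = 1L) {
  cfg <- sim_config(
    n_patients = n_patients,
    effects = gene_effects(n_genes),
    baseline_rate = baseline_rate,
    covariate_log_hr = stats::setNames(rep(0, length(DEFAULT_COV_LOG_HR)),
                                       names(DEFAULT_COV_LOG_HR)),
    admin_censor_time = admin_censor_time,
    dropout_rate = dropout_rate,
    seed = seed
  )
  sim <- simulate_dataset(cfg)
  if (n_genes == 0L) {
    sim$dataset$expression <- sim$dataset$expression[integer(0), , drop = FALSE]
  }
  sim$dataset
}

#' Write a simulated cohort to disk in the pipeline's input dialects
#'
#' Emits `clinical.tsv` and `expression.tsv` exactly as [read_dataset()]
#' consumes them, plus `truth.json` with the planted effects.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  paths <- write_dataset(sim$dataset, dir)
  tr_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(effects = sim$truth$effects,
         censoring_fraction = sim$truth$censoring_fraction,
         tobacco_split = sim$truth$tobacco_split,
         seed = sim$truth$config$seed),
    tr_path, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(c(paths, tr_path))
}
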