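#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] and returns the curve evaluated at the
#' distinct observed event times only (censoring times do not change the
#' estimate, they only deplete the risk set).
#'
#' @param times follow-up times in days, non-negative.
#' @param events event indicators, 1 = death observed, 0 = censored.
#' @return An object of class `km_curve`: a list with `event_times`
#'   (ascending distinct times with at least one event), `survival`
#'   (the product-limit estimate S(t) at each), and `at_risk` (number at
#'   risk just before each event time). With no events the curve is the
#'   constant 1 and `event_times` is empty.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop("empty survival input")
  if (length(times) != length(events)) stop("times and events differ in length")
  if (any(times < 0)) stop("negative follow-up time")
  if (!all(events %in% c(0, 1))) stop("event indicator must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  keep <- fit$n.event > 0
  structure(
    list(
      event_times = fit$time[keep],
      survival    = fit$surv[keep],
      at_risk     = fit$n.risk[keep],
      n           = length(times),
      n_events    = sum(events)
    ),
    class = "km_curve"
  )
}

#' Read a survival probability off a Kaplan-Meier curve
#'
#' The estimator is a right-continuous step function: S(t) holds the value
#' established at the most recent event time at or before `t`, is 1 before
#' the first event, and extends flat beyond the last observed event.
#'
#' @param curve a `km_curve` from [km_estimate()].
#' @param t time (days) at which to evaluate, `t >= 0`; vectorized.
#' @return survival probabilities in `[0, 1]`.
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"), all(t >= 0))
  if (length(curve$event_times) == 0L) return(rep(1, length(t)))
  idx <- findInterval(t, curve$event_times)
  c(1, curve$survival)[idx + 1L]
}

# Shared log-rank kernel. Given follow-up sorted into an arbitrary patient
# order and a 0/1 group-membership matrix G (patients x cuts), returns the
# one-degree-of-freedom log-rank chi-square for every column of G: observed
# minus expected group-1 events accumulated over the pooled distinct event
# times, with the hypergeometric variance (ties handled by the usual
# (n-d)/(n-1) factor). Vectorizing over columns is what makes the serial-cut
# scan affordable genome-wide.
logrank_kernel <- function(times, events, G) {
  d_times <- sort(unique(times[events == 1]))
  J <- length(d_times)
  if (J == 0L) {
    return(list(chi = rep(NA_real_, ncol(G)), var = rep(0, ncol(G)),
                events_in = rep(0, ncol(G)), total_events = 0))
  }
  # risk-set and event incidence matrices over pooled event times (J x N)
  Y <- outer(d_times, times, `<=`)         # at risk just before t_j
  D <- outer(d_times, times, `==`) * rep(events, each = J)
  n_j <- rowSums(Y)
  d_j <- rowSums(D)
  nA <- Y %*% G                            # group at-risk per cut (J x K)
  dA <- D %*% G                            # group events per cut
  U <- colSums(dA - d_j * nA / n_j)
  frac <- nA / n_j
  tie_fac <- ifelse(n_j > 1, (n_j - d_j) / (n_j - 1), 0)
  V <- colSums(d_j * frac * (1 - frac) * tie_fac)
  chi <- ifelse(V > 0, U^2 / V, NA_real_)
  list(chi = as.numeric(chi), var = as.numeric(V),
       events_in = as.numeric(colSums(dA)), total_events = sum(events))
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank comparison of two survival
#' curves: observed minus expected events accumulated over the pooled
#' event times with hypergeometric variance. Identical in substance to
#' [survival::survdiff()]; implemented directly because the serial-cut
#' screen evaluates the same statistic at every candidate cutpoint and
#' this routine is its single-cut case.
#'
#' @param timesA,eventsA follow-up and 0/1 event indicator, group A.
#' @param timesB,eventsB follow-up and 0/1 event indicator, group B.
#' @return list with `chi_square`, `df` (always 1) and `p`
#'   (upper-tail chi-square probability).
#' @export
logrank <- function(timesA, eventsA, timesB, eventsB) {
  if (length(timesA) == 0L || length(timesB) == 0L) {
    stop("both groups must be non-empty")
  }
  if (sum(eventsA) + sum(eventsB) == 0) {
    stop_onegroup("no events in either group", "one-group-logrank")
  }
  times <- c(timesA, timesB)
  events <- c(eventsA, eventsB)
  G <- matrix(rep(c(1, 0), c(length(timesA), length(timesB))), ncol = 1)
  k <- logrank_kernel(times, events, G)
  if (!is.finite(k$chi[1])) {
    stop_onegroup("log-rank variance is zero (degenerate groups)",
                  "one-group-logrank")
  }
  list(chi_square = k$chi[1], df = 1L,
       p = stats::pchisq(k$chi[1], df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit with Wald inference
#'
#' Fits h(t) = h0(t) * exp(beta1 X1 + ... + betan Xn) by partial-likelihood
#' maximization via [survival::coxph()], Efron tie handling by default.
#' Returns per-covariate hazard ratios exp(beta), Wald 95\% confidence
#' intervals exp(beta +/- 1.96 se), and Wald p values, plus an explicit
#' convergence flag: monotone-likelihood/separation (infinite coefficient
#' drift) is reported, never silently returned as a finite estimate.
#'
#' @param covariates numeric matrix or data.frame of covariates (binary in
#'   this pipeline), one column per covariate, no constant column.
#' @param times,events follow-up (days) and 0/1 event indicators.
#' @param tie_method `"efron"` (default) or `"breslow"`.
#' @return object of class `cox_result`: data.frame `table` with columns
#'   `term`, `hr`, `ci_lo`, `ci_hi`, `p`, plus `converged`, `n`, `n_events`.
#' @export
cox_fit <- function(covariates, times, events,
                    tie_method = c("efron", "breslow")) {
  tie_method <- match.arg(tie_method)
  X <- as.matrix(covariates)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (sum(events) == 0) stop("no events in cohort; Cox model undefined")
  const <- apply(X, 2, function(col) length(unique(col[!is.na(col)])) < 2L)
  if (any(const)) {
    stop_onegroup(
      paste0("constant covariate(s): ", paste(colnames(X)[const], collapse = ", ")),
      "one-group-cox"
    )
  }
  dat <- data.frame(X, check.names = FALSE)
  dat$.time <- times
  dat$.event <- events
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", colnames(X)), collapse = " + ")
  ))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = tie_method,
                    control = survival::coxph.control(eps = 1e-9, iter.max = 50)),
    warning = function(w) {
      if (grepl("converge|infinite|Loglik converged", conditionMessage(w))) {
        converged <<- FALSE
      }
      invokeRestart("muffleWarning")
    }
  )
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(!is.finite(beta)) || any(!is.finite(se)) || any(abs(beta) > 15)) {
    converged <- FALSE
  }
  z <- beta / se
  structure(
    list(
      table = data.frame(
        term = colnames(X),
        hr = exp(beta),
        ci_lo = exp(beta - 1.96 * se),
        ci_hi = exp(beta + 1.96 * se),
        p = 2 * stats::pnorm(-abs(z)),
        row.names = NULL
      ),
      converged = converged,
      n = length(times),
      n_events = sum(events)
    ),
    class = "cox_result"
  )
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox PH fit: n=%d, events=%d, converged=%s\n",
              x$n, x$n_events, x$converged))
  tab <- x$table
  tab$hr <- signif(tab$hr, 4)
  tab$ci_lo <- signif(tab$ci_lo, 4)
  tab$ci_hi <- signif(tab$ci_hi, 4)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Univariate Cox table across clinical covariates and a gene indicator
#'
#' One single-covariate Cox fit per dichotomized clinical feature plus the
#' gene's low/high indicator, estimating each feature's unadjusted
#' contribution to overall survival. Per-feature failures (e.g. a level
#' absent from the cohort) are logged and the remaining rows returned.
#'
#' @param covariates data.frame of 0/1 clinical covariates (one column each).
#' @param gene_high 0/1 indicator of high expression, or NULL to omit.
#' @param times,events follow-up and event indicators.
#' @param tie_method passed to [cox_fit()].
#' @return list with `table` (one row per successfully fitted feature:
#'   term, hr, ci_lo, ci_hi, p, converged) and `failures` (term + message).
#' @export
univariate_table <- function(covariates, gene_high = NULL, times, events,
                             tie_method = "efron") {
  covs <- as.data.frame(covariates)
  if (!is.null(gene_high)) covs$gene_high <- gene_high
  rows <- list()
  fails <- list()
  for (nm in names(covs)) {
    res <- tryCatch(
      cox_fit(covs[, nm, drop = FALSE], times, events, tie_method),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      fails[[nm]] <- conditionMessage(res)
    } else {
      r <- res$table
      r$converged <- res$converged
      rows[[nm]] <- r
    }
  }
  list(
    table = if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
            else data.frame(),
    failures = if (length(fails))
      data.frame(term = names(fails), message = unlist(fails), row.names = NULL)
    else data.frame(term = character(), message = character())
  )
}

#' Multivariate Cox fit: all clinical covariates plus the gene indicator
#'
#' Pools the eight dichotomized clinical confounders and the gene's
#' low/high indicator in one hazard function, so the gene coefficient is
#' adjusted for the clinical covariates. Covariates with a near-empty
#' subgroup (fewer than `min_subgroup` patients on one side, e.g. distant
#' metastasis in a mostly M0 cohort) are flagged with a warning: their own
#' hazard ratios are unstable and should be ignored, though they remain in
#' the adjustment set.
#'
#' @inheritParams univariate_table
#' @param min_subgroup smallest subgroup size not flagged (default 5).
#' @return a `cox_result`; flagged terms in attribute `"flagged"`.
#' @export
multivariate_fit <- function(covariates, gene_high, times, events,
                             tie_method = "efron", min_subgroup = 5L) {
  covs <- as.data.frame(covariates)
  covs$gene_high <- gene_high
  sizes <- vapply(covs, function(z) min(table(factor(z, levels = 0:1))), 0)
  flagged <- names(covs)[sizes > 0 & sizes < min_subgroup]
  if (length(flagged)) {
    warning("near-empty subgroup for: ", paste(flagged, collapse = ", "),
            " - hazard ratio unstable, interpret with caution")
  }
  res <- cox_fit(covs, times, events, tie_method)
  attr(res, "flagged") <- flagged
  res
}
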