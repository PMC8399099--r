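#' Candidate cut positions inside a percentile band
#'
#' The serial cut is restricted to a central percentile band (default
#' 30th-70th) so that neither group becomes small enough to destabilize the
#' log-rank test. With N patients ranked ascending by expression, the
#' admissible cut ranks are floor(lo*N)+1 through ceil(hi*N) inclusive
#' (a cut at rank k puts ranks 1..k in the low group), clamped to 1..N-1 so
#' both groups are non-empty. For N = 414 and the default band this gives
#' ranks 125..290, 166 candidate cuts.
#'
#' @param n_patients cohort size, at least 10.
#' @param lo_frac,hi_frac band limits as fractions, 0 < lo < hi < 1.
#' @return object of class `cut_grid`: list with `n_patients`, `lo_frac`,
#'   `hi_frac` and the integer vector `positions`.
#' @export
candidate_positions <- function(n_patients, lo_frac = 0.30, hi_frac = 0.70) {
  if (n_patients < 10) stop("cohort too small for a cut grid (n < 10)")
  if (!(lo_frac > 0 && hi_frac < 1 && lo_frac < hi_frac)) {
    stop("need 0 < lo_frac < hi_frac < 1")
  }
  lo <- floor(lo_frac * n_patients) + 1L
  hi <- ceiling(hi_frac * n_patients)
  lo <- max(lo, 1L)
  hi <- min(hi, n_patients - 1L)
  if (lo > hi) stop("empty cut grid: band too narrow for this cohort size")
  structure(
    list(n_patients = as.integer(n_patients), lo_frac = lo_frac,
         hi_frac = hi_frac, positions = lo:hi),
    class = "cut_grid"
  )
}

#' Order patients by expression with deterministic tie-breaking
#'
#' Stable ascending sort by expression value; exact ties are broken by
#' patient id (lexicographic), so a scan is reproducible regardless of
#' input order.
#'
#' @param values numeric expression vector (no missing values; missingness
#'   is handled upstream by subsetting the cohort per gene).
#' @param ids patient identifiers, same length.
#' @return integer permutation such that `values[perm]` is ascending.
#' @export
rank_patients <- function(values, ids) {
  if (anyNA(values)) stop("missing expression values must be removed upstream")
  order(values, as.character(ids), method = "radix")
}

#' Serial-cut log-rank scan of one gene
#'
#' Patients are ranked by the gene's expression and, at every candidate cut
#' rank k in the grid, split into low (ranks 1..k) and high (k+1..N) groups;
#' a two-group log-rank test is evaluated at each admissible cut. Cuts that
#' would split tied expression values are skipped (`skipped_tie`), as are
#' cuts where either group carries zero events or the log-rank variance is
#' zero (`skipped_degenerate`). The whole profile is computed with one
#' vectorized pass over the pooled event times, which is what makes
#' genome-wide scanning affordable.
#'
#' @param values expression vector, one value per patient, no missing.
#' @param times,events follow-up (days) and 0/1 event indicators, aligned
#'   with `values`.
#' @param grid a `cut_grid` from [candidate_positions()] for this cohort
#'   size.
#' @param ids optional patient ids for tie-breaking (defaults to input
#'   position).
#' @param gene optional gene symbol carried through to outputs.
#' @return object of class `cutoff_scan`: list with `gene`, `order` (the
#'   ranking permutation), `profile` (data.frame: rank, n_low, n_high,
#'   status, p), `failed`, `failure_category`, and the rank-sorted
#'   `values`, `times`, `events` needed to re-evaluate any cut.
#' @export
scan_gene <- function(values, times, events, grid, ids = NULL, gene = NA_character_) {
  stopifnot(inherits(grid, "cut_grid"))
  N <- length(values)
  if (N != grid$n_patients) stop("grid was built for a different cohort size")
  if (length(times) != N || length(events) != N) {
    stop("survival data not aligned with expression values")
  }
  if (is.null(ids)) ids <- sprintf("P%06d", seq_len(N))
  ord <- rank_patients(values, ids)
  vs <- values[ord]; ts <- times[ord]; es <- events[ord]
  pos <- grid$positions
  K <- length(pos)

  tie <- vs[pos] == vs[pos + 1L]
  k <- serial_logrank(ts, es, pos)

  status <- rep("valid", K)
  deg <- k$events_in == 0 | (k$total_events - k$events_in) == 0 |
    !is.finite(k$chi) | k$var == 0
  status[deg] <- "skipped_degenerate"
  status[tie] <- "skipped_tie"
  p <- ifelse(status == "valid",
              stats::pchisq(k$chi, df = 1, lower.tail = FALSE), NA_real_)
  # guard against underflow: a valid log-rank p lies in (0, 1]
  p[status == "valid" & p == 0] <- .Machine$double.xmin

  failed <- !any(status == "valid")
  structure(
    list(
      gene = gene,
      order = ord,
      profile = data.frame(rank = pos, n_low = pos, n_high = N - pos,
                           status = status, p = p),
      failed = failed,
      failure_category = if (failed) "one-group-logrank" else NA_character_,
      values = vs, times = ts, events = es, ids = as.character(ids)[ord]
    ),
    class = "cutoff_scan"
  )
}

# Log-rank statistics at every serial cut of a rank-ordered cohort.
# Patients arrive sorted by expression rank (times/events in rank order);
# cut k puts ranks 1..pos[k] in the low group. Rather than materializing a
# risk-set matrix over patients, each patient contributes a single point
# mass at (last event time they are at risk for, first cut that contains
# them), and the low-group at-risk and event counts for every (event time,
# cut) pair fall out of two cumulative sums — O(J*K) per gene instead of
# O(J*N*K), which is what makes a genome-wide serial-cut screen cheap.
# Numerically identical to logrank_kernel() with an explicit membership
# matrix (a tested invariant).
serial_logrank <- function(times, events, pos) {
  N <- length(times)
  K <- length(pos)
  lo <- pos[1L]
  d_times <- sort(unique(times[events == 1]))
  J <- length(d_times)
  if (J == 0L) {
    return(list(chi = rep(NA_real_, K), var = rep(0, K),
                events_in = rep(0, K), total_events = 0))
  }
  jmax <- findInterval(times, d_times)     # last event time with t_j <= T_i
  r <- seq_len(N)
  kstart <- pmax(r - lo + 1L, 1L)          # first cut whose low group holds rank r
  in_any <- r <= pos[K]

  # low-group at-risk counts n_A[j,k] via 2D suffix/prefix cumulation
  selA <- in_any & jmax >= 1L
  massA <- matrix(tabulate((kstart[selA] - 1L) * J + jmax[selA], J * K),
                  nrow = J)
  # low-group event counts d_A[j,k]
  jev <- ifelse(events == 1, match(times, d_times), NA_integer_)
  selD <- events == 1 & in_any
  massD <- matrix(tabulate((kstart[selD] - 1L) * J + jev[selD], J * K),
                  nrow = J)
  cum_k <- upper.tri(matrix(0, K, K), diag = TRUE) * 1      # prefix over cuts
  cum_j <- upper.tri(matrix(0, J, J), diag = TRUE) * 1      # suffix over times
  n_A <- cum_j %*% (massA %*% cum_k)
  d_A <- massD %*% cum_k

  n_j <- rev(cumsum(rev(tabulate(jmax[jmax >= 1L], J))))    # pooled at-risk
  d_j <- tabulate(jev[events == 1], J)                      # pooled events
  w <- d_j / n_j
  a <- n_A / n_j                            # length-J vector recycles by row
  tie_fac <- ifelse(n_j > 1, (n_j - d_j) / (n_j - 1), 0)
  U <- colSums(d_A) - as.numeric(crossprod(w, n_A))
  V <- as.numeric(crossprod(d_j * tie_fac, a - a * a))
  chi <- ifelse(V > 0, U^2 / V, NA_real_)
  list(chi = chi, var = V, events_in = colSums(d_A), total_events = sum(d_j))
}

# log-rank p for a single rank cut on an already-sorted scan; NA when the
# cut splits a tie or a group carries no events
cut_p_at_rank <- function(scan, k) {
  N <- length(scan$values)
  if (k < 1L || k >= N) return(NA_real_)
  if (scan$values[k] == scan$values[k + 1L]) return(NA_real_)
  G <- matrix(rep(c(1, 0), c(k, N - k)), ncol = 1)
  kr <- logrank_kernel(scan$times, scan$events, G)
  if (kr$events_in[1] == 0 || (kr$total_events - kr$events_in[1]) == 0 ||
      !is.finite(kr$chi[1]) || kr$var[1] == 0) {
    return(NA_real_)
  }
  max(stats::pchisq(kr$chi[1], df = 1, lower.tail = FALSE), .Machine$double.xmin)
}

#' Select the optimal cutpoint from a scan profile
#'
#' The optimal cut is the valid position with the minimum log-rank p,
#' provided some valid p is below `sig_level`; p-value ties go to the
#' smallest rank for determinism. When no cut reaches `sig_level` the
#' gene falls back to its median expression cutpoint (rank floor(N/2)),
#' flagged via `used_fallback`, with the gene's p re-evaluated at that
#' rank. A gene whose scan failed and whose median cut is itself
#' degenerate (tied values or a zero-event group) is excluded with an
#' error carrying the failure category.
#'
#' @param scan a `cutoff_scan` from [scan_gene()].
#' @param sig_level raw significance level deciding whether the minimum-p
#'   cut is adopted (default 0.05).
#' @return object of class `optimal_cut`: list with `gene`, `rank_k`,
#'   `n_low`, `n_high`, `cutoff_value` (expression at rank k, the largest
#'   low-group value), `p_min`, `used_fallback`.
#' @export
select_optimal <- function(scan, sig_level = 0.05) {
  stopifnot(inherits(scan, "cutoff_scan"))
  N <- length(scan$values)
  prof <- scan$profile
  valid <- prof$status == "valid"
  if (any(valid) && min(prof$p[valid]) < sig_level) {
    pv <- prof$p
    pv[!valid] <- Inf
    k <- prof$rank[which.min(pv)]   # which.min takes the first = smallest rank
    p <- min(prof$p[valid])
    fallback <- FALSE
  } else {
    k <- as.integer(floor(N / 2))
    p <- cut_p_at_rank(scan, k)
    fallback <- TRUE
    if (is.na(p)) {
      stop_onegroup(
        sprintf("gene %s: no admissible cut and median fallback degenerate",
                scan$gene),
        "one-group-logrank"
      )
    }
  }
  structure(
    list(gene = scan$gene, rank_k = as.integer(k), n_low = as.integer(k),
         n_high = as.integer(N - k), cutoff_value = scan$values[k],
         p_min = p, used_fallback = fallback),
    class = "optimal_cut"
  )
}

# median-rank cut without scanning, used by the median-cutoff strategy
median_cut <- function(scan) {
  N <- length(scan$values)
  k <- as.integer(floor(N / 2))
  p <- cut_p_at_rank(scan, k)
  if (is.na(p)) {
    stop_onegroup(sprintf("gene %s: median cut degenerate", scan$gene),
                  "one-group-logrank")
  }
  structure(
    list(gene = scan$gene, rank_k = k, n_low = k, n_high = as.integer(N - k),
         cutoff_value = scan$values[k], p_min = p, used_fallback = FALSE),
    class = "optimal_cut"
  )
}

#' Scan every gene of a dataset and select its cutpoint
#'
#' Runs the serial-cut scan gene by gene, subsetting each gene to the
#' patients with observed (non-null) expression and rebuilding the cut
#' grid for that effective cohort size. A gene never halts the pipeline:
#' each yields either a selected cut or a categorized failure
#' (`one-group-logrank`, `one-group-cox`, `unknown`), and the proportions
#' of failure categories are reported, mirroring an error-log audit of a
#' genome-wide run.
#'
#' @param dataset an `analysis_dataset` (see [merge_cohort()] /
#'   [simulate_dataset()]).
#' @param lo_frac,hi_frac percentile band for the cut grid.
#' @param sig_level significance level for the median fallback rule.
#' @param mode `"optimal"` (serial-cut scan, default) or `"median"`
#'   (fixed median-rank cutpoint, the validation-cohort strategy).
#' @param keep_scans return the per-gene scan objects (memory-heavy;
#'   default FALSE).
#' @return object of class `screen_result`: list with `cuts` (data.frame:
#'   gene, n_used, rank_k, n_low, n_high, cutoff_value, p_min,
#'   used_fallback), `failures` (gene, category, message),
#'   `failure_proportions`, `mode`, and optionally `scans`.
#' @export
scan_all <- function(dataset, lo_frac = 0.30, hi_frac = 0.70,
                     sig_level = 0.05, mode = c("optimal", "median"),
                     keep_scans = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "analysis_dataset"))
  expr <- dataset$expression
  mask <- attr(expr, "null_mask")
  genes <- rownames(expr)
  times <- dataset$clinical$time
  events <- dataset$clinical$event
  ids <- dataset$clinical$patient_id

  rows <- vector("list", length(genes))
  fails <- list()
  scans <- if (keep_scans) vector("list", length(genes)) else NULL
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    obs <- !mask[gi, ]
    res <- tryCatch({
      if (sum(obs) < 10L) stop("fewer than 10 patients with observed expression")
      grid <- candidate_positions(sum(obs), lo_frac, hi_frac)
      sc <- scan_gene(expr[gi, obs], times[obs], events[obs], grid,
                      ids = ids[obs], gene = g)
      if (keep_scans) scans[[gi]] <- sc
      cut <- if (mode == "median") median_cut(sc) else select_optimal(sc, sig_level)
      data.frame(gene = g, n_used = sum(obs), rank_k = cut$rank_k,
                 n_low = cut$n_low, n_high = cut$n_high,
                 cutoff_value = cut$cutoff_value, p_min = cut$p_min,
                 used_fallback = cut$used_fallback)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      category <- if (inherits(res, "survscreen_one_group_error")) {
        res$category %||% "one-group-logrank"
      } else "unknown"
      fails[[g]] <- data.frame(gene = g, category = category,
                               message = conditionMessage(res))
    } else {
      rows[[gi]] <- res
    }
  }
  rows <- Filter(Negate(is.null), rows)
  cuts <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else NULL
  if (is.null(cuts)) {
    cuts <- data.frame(gene = character(), n_used = integer(),
                       rank_k = integer(), n_low = integer(),
                       n_high = integer(), cutoff_value = numeric(),
                       p_min = numeric(), used_fallback = logical())
  }
  failures <- if (length(fails)) do.call(rbind, c(fails, make.row.names = FALSE))
              else data.frame(gene = character(), category = character(),
                              message = character())
  props <- if (nrow(failures)) {
    prop.table(table(failures$category))
  } else table(character())
  structure(
    list(cuts = cuts, failures = failures,
         failure_proportions = props, mode = mode,
         lo_frac = lo_frac, hi_frac = hi_frac, sig_level = sig_level,
         scans = if (keep_scans) stats::setNames(scans, genes) else NULL),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("Gene screen (%s cutpoints): %d genes scanned, %d failed\n",
              x$mode, nrow(x$cuts) + nrow(x$failures), nrow(x$failures)))
  if (nrow(x$cuts)) {
    cat(sprintf("  raw p < %.3g at selected cut: %d genes; median fallback: %d\n",
                x$sig_level, sum(x$cuts$p_min < x$sig_level),
                sum(x$cuts$used_fallback)))
  }
  if (nrow(x$failures)) {
    cat("  failure categories:\n")
    print(round(x$failure_proportions, 4))
  }
  invisible(x)
}

#' Export a scan profile for cumulative-p plotting
#'
#' @param scan a `cutoff_scan`.
#' @return data.frame (gene, rank, n_low, n_high, status, p) ready to write
#'   as TSV; the p column of valid rows traces the cumulative p-value curve
#'   along the serial cut.
#' @export
scan_profile_table <- function(scan) {
  stopifnot(inherits(scan, "cutoff_scan"))
  cbind(gene = scan$gene, scan$profile)
}
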