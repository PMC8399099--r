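# Canonical clinical schema used throughout the pipeline. `time` is overall
# survival in days, `event` 1 = death observed / 0 = censored; the remaining
# columns are the raw clinicopathological features later dichotomized into
# the eight binary confounders.
CLINICAL_FIELDS <- c("patient_id", "time", "event", "gender", "age_years",
                     "clinical_t", "clinical_n", "clinical_m", "stage",
                     "margin", "tobacco_pack_years")

CLINICAL_LEVELS <- list(
  gender = c("female", "male"),
  clinical_t = c("T1", "T2", "T3", "T4"),
  clinical_n = c("N0", "N1", "N2", "N3"),
  clinical_m = c("M0", "M1"),
  stage = c("I", "II", "III", "IV"),
  margin = c("negative", "positive")
)

#' Read a clinical table
#'
#' Reads a delimited clinical file (TSV by default, comma accepted) into
#' the canonical schema: patient id, overall-survival time (days), event
#' indicator, gender, age, clinical T/N/M, stage, surgical-margin status
#' and tobacco pack-years. Column names in the file are translated through
#' `column_map`. Rows with an unparseable or negative time, or an event
#' flag outside \{0, 1\}, are reported in the attached `invalid` attribute
#' rather than silently dropped; rows with out-of-vocabulary categorical
#' values are kept but flagged incomplete (they drop out later if the
#' field is required).
#'
#' @param path file path.
#' @param column_map named character vector mapping canonical field names
#'   (see `survscreen:::CLINICAL_FIELDS`) to column names in the file;
#'   canonical names absent from the map are assumed to match verbatim.
#' @param sep field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return data.frame with the canonical columns plus logical `complete`;
#'   attribute `invalid` holds the rejected rows and reasons.
#' @export
read_clinical_table <- function(path, column_map = NULL, sep = NULL) {
  if (!file.exists(path)) stop_config("clinical file not found: ", path)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""), comment.char = "",
                           quote = "\"")
  map <- stats::setNames(CLINICAL_FIELDS, CLINICAL_FIELDS)
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  missing_cols <- map[!(map %in% names(raw))]
  if (length(missing_cols)) {
    stop_config("clinical file lacks required column(s): ",
                paste(sprintf("%s (for %s)", missing_cols, names(missing_cols)),
                      collapse = ", "))
  }
  dat <- stats::setNames(raw[, map, drop = FALSE], names(map))

  dat$time <- suppressWarnings(as.numeric(dat$time))
  dat$event <- suppressWarnings(as.numeric(dat$event))
  dat$age_years <- suppressWarnings(as.numeric(dat$age_years))
  dat$tobacco_pack_years <- suppressWarnings(as.numeric(dat$tobacco_pack_years))

  bad_time <- is.na(dat$time) | dat$time < 0
  bad_event <- is.na(dat$event) | !(dat$event %in% c(0, 1))
  bad_id <- is.na(dat$patient_id) | duplicated(dat$patient_id)
  invalid <- bad_time | bad_event | bad_id
  reasons <- character(sum(invalid))
  if (any(invalid)) {
    reasons <- apply(cbind(bad_time, bad_event, bad_id)[invalid, , drop = FALSE],
                     1, function(r) {
                       paste(c("invalid time", "invalid event",
                               "missing/duplicate id")[r], collapse = "; ")
                     })
  }
  rejected <- cbind(raw[invalid, , drop = FALSE], reason = reasons)
  dat <- dat[!invalid, , drop = FALSE]

  ok_level <- function(field) {
    v <- dat[[field]]
    !is.na(v) & v %in% CLINICAL_LEVELS[[field]]
  }
  complete <- !is.na(dat$age_years) & dat$age_years > 0
  for (f in names(CLINICAL_LEVELS)) complete <- complete & ok_level(f)
  # tobacco may be missing; completeness for it is tracked separately by
  # required_fields at merge time
  dat$complete <- complete
  rownames(dat) <- NULL
  attr(dat, "invalid") <- rejected
  dat
}

#' Read an expression matrix
#'
#' Delimited text, first column gene symbols, remaining columns patient
#' ids, values continuous log2-scale expression. Entries that are missing
#' or non-finite (a raw zero carried through the log transform) are
#' recorded in a not-expressed ("null") mask and set to `NA`, keeping the
#' log-scale values uncontaminated. Duplicated gene symbols or patient ids
#' are dropped after the first occurrence and reported.
#'
#' @param path file path.
#' @param sep separator; `NULL` auto-detects tab vs comma.
#' @return numeric matrix genes x patients with attributes `null_mask`
#'   (logical matrix, TRUE = not expressed/missing) and `dropped`
#'   (duplicate identifiers removed).
#' @export
read_expression_matrix <- function(path, sep = NULL) {
  if (!file.exists(path)) stop_config("expression file not found: ", path)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""), comment.char = "",
                           quote = "\"")
  genes <- as.character(raw[[1]])
  vals <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  dup_g <- duplicated(genes)
  dup_p <- duplicated(colnames(vals))
  vals <- vals[!dup_g, !dup_p, drop = FALSE]
  rownames(vals) <- genes[!dup_g]
  as_expression_matrix(
    vals,
    dropped = list(genes = genes[dup_g], patients = colnames(raw[, -1])[dup_p])
  )
}

# attach the not-expressed mask and normalize storage
as_expression_matrix <- function(vals, null_mask = NULL, dropped = NULL) {
  mask <- if (is.null(null_mask)) !is.finite(vals) else null_mask | !is.finite(vals)
  dimnames(mask) <- dimnames(vals)
  vals[mask] <- NA_real_
  attr(vals, "null_mask") <- mask
  attr(vals, "dropped") <- dropped
  vals
}

#' Merge clinical and expression data into an aligned analysis dataset
#'
#' Inner join on patient id; patients missing any required clinical field
#' are dropped and reported (samples without complete clinical information
#' are removed rather than imputed). The expression matrix is restricted
#' and column-reordered to exactly the retained patients, so clinical row i
#' and expression column i always describe the same patient.
#'
#' @param clinical data.frame from [read_clinical_table()] (or equivalent).
#' @param expr expression matrix from [read_expression_matrix()].
#' @param required_fields clinical fields that must be present and valid;
#'   defaults to all categorical fields plus age (tobacco optional, since
#'   smoking history is often incompletely recorded).
#' @return object of class `analysis_dataset`: list with `clinical`
#'   (canonical data.frame), `expression` (genes x patients with
#'   `null_mask`), and `dropped` (ids removed for incompleteness).
#' @export
merge_cohort <- function(clinical, expr,
                         required_fields = c("gender", "age_years",
                                             "clinical_t", "clinical_n",
                                             "clinical_m", "stage", "margin")) {
  if (nrow(clinical) == 0L || ncol(expr) == 0L) {
    stop("clinical table and expression matrix must both be non-empty")
  }
  common <- intersect(clinical$patient_id, colnames(expr))
  if (length(common) == 0L) {
    stop_config("no patient ids shared between clinical and expression data ",
                "- check the id scheme")
  }
  cl <- clinical[match(common, clinical$patient_id), , drop = FALSE]

  ok <- rep(TRUE, nrow(cl))
  for (f in required_fields) {
    v <- cl[[f]]
    good <- !is.na(v)
    if (f %in% names(CLINICAL_LEVELS)) good <- good & v %in% CLINICAL_LEVELS[[f]]
    if (f == "age_years") good <- good & v > 0
    ok <- ok & good
  }
  dropped <- cl$patient_id[!ok]
  cl <- cl[ok, , drop = FALSE]
  rownames(cl) <- NULL
  mask <- attr(expr, "null_mask")
  sel <- match(cl$patient_id, colnames(expr))
  ex <- expr[, sel, drop = FALSE]
  attr(ex, "null_mask") <- mask[, sel, drop = FALSE]
  structure(
    list(clinical = cl, expression = ex,
         dropped = dropped, required_fields = required_fields),
    class = "analysis_dataset"
  )
}

#' @export
print.analysis_dataset <- function(x, ...) {
  cat(sprintf("Analysis dataset: %d patients x %d genes (%d events, %d dropped at merge)\n",
              nrow(x$clinical), nrow(x$expression),
              sum(x$clinical$event), length(x$dropped)))
  invisible(x)
}

#' Remove genes with too many null (not-expressed) values
#'
#' A gene is excluded when its fraction of null entries — missing values
#' or raw zeros recorded in the not-expressed mask — strictly exceeds
#' `max_null_fraction`; "more than 30\%" null is the default rule, so a
#' gene at exactly the threshold is retained.
#'
#' @param expr expression matrix with a `null_mask` attribute.
#' @param max_null_fraction removal threshold in (0, 1), default 0.30.
#' @return filtered matrix; attribute `removed` reports the excluded genes
#'   and their null fractions.
#' @export
filter_null_genes <- function(expr, max_null_fraction = 0.30) {
  stopifnot(max_null_fraction > 0, max_null_fraction < 1)
  mask <- attr(expr, "null_mask")
  frac <- rowMeans(mask)
  drop <- frac > max_null_fraction
  out <- expr[!drop, , drop = FALSE]
  attr(out, "null_mask") <- mask[!drop, , drop = FALSE]
  attr(out, "removed") <- data.frame(gene = rownames(expr)[drop],
                                     null_fraction = frac[drop],
                                     row.names = NULL)
  out
}

#' Apply the null-gene filter within an analysis dataset
#'
#' @param dataset an `analysis_dataset`.
#' @inheritParams filter_null_genes
#' @return the dataset with its expression part filtered.
#' @export
filter_dataset_genes <- function(dataset, max_null_fraction = 0.30) {
  stopifnot(inherits(dataset, "analysis_dataset"))
  dataset$expression <- filter_null_genes(dataset$expression, max_null_fraction)
  dataset
}

#' Dichotomize clinical features into the eight binary confounders
#'
#' Deterministic translation of the raw clinicopathological profile into
#' the binary covariates of the Cox models: male gender, age > 65 years,
#' T3-T4 tumor size, node-positive (N != N0), distant metastasis (M1),
#' late stage (III-IV), positive surgical margin, and high tobacco
#' exposure (pack-years above `tobacco_split`). Reference levels (female,
#' age <= 65, T1-T2, N0, M0, stage I-II, negative margin, low tobacco)
#' map to 0.
#'
#' @param clinical canonical clinical data.frame (one or more rows).
#' @param tobacco_split pack-years split point for low/high tobacco
#'   exposure; the cohort median via [tobacco_median_split()] is the
#'   conventional choice when no external threshold exists.
#' @return data.frame of 0/1 columns `male`, `age_gt_65`, `t34`,
#'   `n_positive`, `m1`, `late_stage`, `margin_positive`, `tobacco_high`.
#' @export
dichotomize <- function(clinical, tobacco_split) {
  for (f in c("gender", "age_years", "clinical_t", "clinical_n",
              "clinical_m", "stage", "margin", "tobacco_pack_years")) {
    if (!f %in% names(clinical)) stop("clinical data lacks field: ", f)
    bad <- is.na(clinical[[f]])
    if (f %in% names(CLINICAL_LEVELS)) {
      bad <- bad | !(clinical[[f]] %in% CLINICAL_LEVELS[[f]])
    }
    if (any(bad)) {
      stop("incomplete profile: field '", f, "' missing or invalid for patient(s) ",
           paste(utils::head(clinical$patient_id[bad], 5), collapse = ", "))
    }
  }
  data.frame(
    male = as.integer(clinical$gender == "male"),
    age_gt_65 = as.integer(clinical$age_years > 65),
    t34 = as.integer(clinical$clinical_t %in% c("T3", "T4")),
    n_positive = as.integer(clinical$clinical_n != "N0"),
    m1 = as.integer(clinical$clinical_m == "M1"),
    late_stage = as.integer(clinical$stage %in% c("III", "IV")),
    margin_positive = as.integer(clinical$margin == "positive"),
    tobacco_high = as.integer(clinical$tobacco_pack_years > tobacco_split)
  )
}

#' Cohort-median tobacco split
#'
#' @param clinical canonical clinical data.frame.
#' @return median pack-years over patients with a recorded value.
#' @export
tobacco_median_split <- function(clinical) {
  stats::median(clinical$tobacco_pack_years, na.rm = TRUE)
}

#' Summarize a cohort's clinical composition
#'
#' Counts and percentages per level of each categorical (or dichotomized)
#' feature, percentages to one decimal with half-up rounding as clinical
#' tables conventionally print them (so 142 of 528 females reads 26.9).
#'
#' @param clinical canonical clinical data.frame, non-empty.
#' @param features which columns to tabulate (default: the categorical
#'   clinical fields plus the event indicator).
#' @return data.frame (feature, level, count, percent).
#' @export
summarize_cohort <- function(clinical,
                             features = c("gender", "clinical_t", "clinical_n",
                                          "clinical_m", "stage", "margin",
                                          "event")) {
  if (nrow(clinical) == 0L) stop("empty cohort")
  n <- nrow(clinical)
  out <- lapply(features, function(f) {
    tab <- table(clinical[[f]], useNA = "ifany")
    data.frame(feature = f, level = as.character(names(tab)),
               count = as.integer(tab),
               percent = round_half_up(100 * as.integer(tab) / n, 1))
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Write an analysis dataset as plain-text files
#'
#' Serializes the cleaned dataset the same way the readers consume it:
#' `clinical.tsv` (canonical columns), `expression.tsv` (gene column plus
#' one column per patient), and `cleaning_report.json` (dropped patients,
#' removed genes, null-mask counts).
#'
#' @param dataset an `analysis_dataset`.
#' @param dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "analysis_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cl_path <- file.path(dir, "clinical.tsv")
  ex_path <- file.path(dir, "expression.tsv")
  rp_path <- file.path(dir, "cleaning_report.json")
  cl <- dataset$clinical
  cl$complete <- NULL
  utils::write.table(cl, cl_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ex <- data.frame(gene = rownames(dataset$expression),
                   dataset$expression, check.names = FALSE)
  utils::write.table(ex, ex_path, sep = "\t", quote = FALSE, row.names = FALSE)
  removed <- attr(dataset$expression, "removed")
  jsonlite::write_json(
    list(
      n_patients = nrow(dataset$clinical),
      n_genes = nrow(dataset$expression),
      dropped_patients = dataset$dropped,
      removed_genes = if (is.null(removed)) character() else removed$gene,
      null_entries = sum(attr(dataset$expression, "null_mask"))
    ),
    rp_path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(c(cl_path, ex_path, rp_path))
}

#' Load an analysis dataset previously written by [write_dataset()]
#'
#' @param dir directory holding `clinical.tsv` and `expression.tsv`.
#' @param required_fields passed to [merge_cohort()].
#' @return an `analysis_dataset`.
#' @export
read_dataset <- function(dir, required_fields = c("gender", "age_years",
                                                  "clinical_t", "clinical_n",
                                                  "clinical_m", "stage",
                                                  "margin")) {
  clinical <- read_clinical_table(file.path(dir, "clinical.tsv"))
  expr <- read_expression_matrix(file.path(dir, "expression.tsv"))
  merge_cohort(clinical, expr, required_fields)
}
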