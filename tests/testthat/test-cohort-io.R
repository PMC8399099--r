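test_that("clinical reader returns one record per valid row and reports bad rows", {
  df <- make_clinical_df(3)
  expect_equal(nrow(read_clinical_table(write_clinical_tsv(df))), 3)

  # a negative follow-up time is reported, not silently dropped
  df2 <- make_clinical_df(3)
  df2$time[2] <- -5
  got <- read_clinical_table(write_clinical_tsv(df2))
  expect_equal(nrow(got), 2)
  bad <- attr(got, "invalid")
  expect_equal(nrow(bad), 1)
  expect_match(bad$reason, "invalid time")

  # comma-separated input is accepted too
  csv <- tempfile(fileext = ".csv")
  write.table(df, csv, sep = ",", quote = FALSE, row.names = FALSE)
  expect_equal(nrow(read_clinical_table(csv)), 3)
})

test_that("a missing required column is a configuration error naming it", {
  df <- make_clinical_df(3)
  df$event <- NULL
  err <- expect_error(read_clinical_table(write_clinical_tsv(df)),
                      class = "survscreen_config_error")
  expect_match(conditionMessage(err), "event")
})

test_that("column mapping translates nonstandard headers", {
  df <- make_clinical_df(4)
  names(df)[names(df) == "time"] <- "os_days"
  names(df)[names(df) == "event"] <- "dead"
  got <- read_clinical_table(write_clinical_tsv(df),
                             column_map = c(time = "os_days", event = "dead"))
  expect_equal(got$time, df$os_days)
  expect_equal(got$event, df$dead)
})

test_that("merge inner-joins on patient id and drops incomplete records with a report", {
  cl <- make_clinical_df(5)
  expr_mat <- matrix(rnorm(3 * 4), nrow = 3,
                     dimnames = list(paste0("G", 1:3), cl$patient_id[1:4]))
  expr <- survscreen:::as_expression_matrix(expr_mat)
  ds <- merge_cohort(cl, expr)
  expect_equal(nrow(ds$clinical), 4)
  expect_identical(ds$clinical$patient_id, colnames(ds$expression))

  cl2 <- cl
  cl2$margin[2] <- NA
  ds2 <- merge_cohort(cl2, expr)
  expect_equal(nrow(ds2$clinical), 3)
  expect_identical(ds2$dropped, cl$patient_id[2])

  cl3 <- cl
  cl3$patient_id <- paste0("X", cl3$patient_id)
  expect_error(merge_cohort(cl3, expr), class = "survscreen_config_error")
})

test_that("null-gene filter removes strictly above the threshold only", {
  m <- matrix(rnorm(30), nrow = 3,
              dimnames = list(c("over", "none", "at"), sprintf("P%02d", 1:10)))
  m["over", 1:4] <- NA   # 0.4 > 0.3 -> removed
  m["at", 1:3] <- NA     # 0.3, not > 0.3 -> retained
  expr <- survscreen:::as_expression_matrix(m)
  out <- filter_null_genes(expr, 0.30)
  expect_identical(rownames(out), c("none", "at"))
  expect_identical(attr(out, "removed")$gene, "over")
  expect_equal(attr(out, "removed")$null_fraction, 0.4)
})

test_that("null-gene filter never removes a gene at or below the threshold (exhaustive)", {
  # every possible null count for a 10-patient gene
  for (k in 0:10) {
    m <- matrix(1, nrow = 1, ncol = 10,
                dimnames = list("g", sprintf("P%02d", 1:10)))
    if (k > 0) m[1, seq_len(k)] <- NA
    out <- filter_null_genes(survscreen:::as_expression_matrix(m), 0.30)
    expect_equal(nrow(out) == 1L, k / 10 <= 0.30,
                 label = sprintf("null count %d", k))
  }
})

test_that("dichotomization follows the clinical category definitions", {
  prof <- data.frame(
    patient_id = "PT-001", gender = "female", age_years = 70,
    clinical_t = "T3", clinical_n = "N1", clinical_m = "M0",
    stage = "IV", margin = "positive", tobacco_pack_years = 10
  )
  b <- dichotomize(prof, tobacco_split = 20)
  expect_equal(unlist(b),
               c(male = 0, age_gt_65 = 1, t34 = 1, n_positive = 1, m1 = 0,
                 late_stage = 1, margin_positive = 1, tobacco_high = 0))

  # age exactly 65 sits in the reference (<=65) group
  prof$age_years <- 65
  expect_equal(dichotomize(prof, 20)$age_gt_65, 0L)

  ref <- data.frame(
    patient_id = "PT-002", gender = "female", age_years = 50,
    clinical_t = "T1", clinical_n = "N0", clinical_m = "M0",
    stage = "I", margin = "negative", tobacco_pack_years = 0
  )
  expect_true(all(unlist(dichotomize(ref, 20)) == 0))

  prof$stage <- NA
  expect_error(dichotomize(prof, 20), "stage")
})

test_that("cohort summary reproduces printed-percentage conventions", {
  cl <- data.frame(gender = rep(c("female", "male"), c(142, 386)),
                   event = 0)
  s <- summarize_cohort(cl, features = "gender")
  expect_equal(s$percent[s$level == "female"], 26.9)

  cl2 <- data.frame(gender = rep(c("female", "male"), c(49, 239)), event = 0)
  s2 <- summarize_cohort(cl2, features = "gender")
  expect_equal(s2$percent[s2$level == "female"], 17.0)

  cl3 <- data.frame(gender = rep("male", 20), event = 0)
  s3 <- summarize_cohort(cl3, features = "gender")
  expect_equal(s3$percent, 100.0)
  expect_error(summarize_cohort(cl3[0, , drop = FALSE]), "empty")
})

test_that("percentages over one binary feature sum to 100 within rounding", {
  for (seed in 1:10) {
    cl <- make_clinical_df(sample(30:500, 1), seed = seed)
    s <- summarize_cohort(cl, features = "margin")
    expect_lte(abs(sum(s$percent) - 100), 0.1)
  }
})

test_that("merge -> filter -> dichotomize is idempotent", {
  cl <- make_clinical_df(20)
  m <- matrix(rnorm(100), nrow = 5,
              dimnames = list(paste0("G", 1:5), cl$patient_id))
  m[1, 1:9] <- NA
  ds <- filter_dataset_genes(merge_cohort(cl, survscreen:::as_expression_matrix(m)))
  ds2 <- filter_dataset_genes(merge_cohort(ds$clinical, ds$expression))
  expect_identical(ds2$clinical[names(ds$clinical)], ds$clinical[names(ds$clinical)])
  expect_equal(unname(ds2$expression), unname(ds$expression), ignore_attr = TRUE)
  expect_identical(rownames(ds2$expression), rownames(ds$expression))
  split <- tobacco_median_split(ds$clinical)
  expect_identical(dichotomize(ds$clinical, split), dichotomize(ds2$clinical, split))
})

test_that("a dataset written to disk reads back identically", {
  sim <- simulate_dataset(sim_config(n_patients = 30, effects = gene_effects(8),
                                     null_value_fraction = 0.05, seed = 11))
  dir <- tempfile()
  write_dataset(sim$dataset, dir)
  back <- read_dataset(dir)
  expect_equal(back$clinical$time, sim$dataset$clinical$time)
  expect_equal(back$clinical$event, sim$dataset$clinical$event)
  expect_equal(unname(back$expression), unname(sim$dataset$expression),
               tolerance = 1e-12, ignore_attr = TRUE)
  m1 <- attr(back$expression, "null_mask")
  m2 <- attr(sim$dataset$expression, "null_mask")
  dimnames(m1) <- dimnames(m2) <- NULL
  expect_identical(m1, m2)
})
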