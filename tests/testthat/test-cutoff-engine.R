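test_that("cut grid follows the floor/ceil band convention", {
  g <- candidate_positions(414, 0.30, 0.70)
  expect_equal(g$positions[1], 125)
  expect_equal(g$positions[length(g$positions)], 290)
  expect_length(g$positions, 166)

  expect_equal(candidate_positions(10, 0.30, 0.70)$positions, 4:7)
  expect_error(candidate_positions(9), "too small")
  expect_error(candidate_positions(414, 0.7, 0.3), "lo_frac")
})

test_that("cut grid matches brute-force enumeration for all cohort sizes", {
  for (N in 10:600) {
    got <- candidate_positions(N, 0.30, 0.70)$positions
    want <- Filter(function(k) 0.30 * N < k && k <= ceiling(0.70 * N) && k < N,
                   seq_len(N))
    expect_equal(got, as.integer(want), label = sprintf("N=%d", N))
  }
  # near-degenerate band: falls back to a single position or errors,
  # matching direct enumeration
  N <- 414
  lo <- 0.5; hi <- 0.5 + 1e-9
  want <- Filter(function(k) lo * N < k && k <= ceiling(hi * N) && k < N,
                 seq_len(N))
  if (length(want)) {
    expect_equal(candidate_positions(N, lo, hi)$positions, as.integer(want))
  } else {
    expect_error(candidate_positions(N, lo, hi))
  }
})

test_that("patient ranking is a stable value-then-id sort", {
  v <- c(3, 1, 2)
  expect_equal(rank_patients(v, c("a", "b", "c")), c(2, 3, 1))
  # all equal: pure id order
  expect_equal(rank_patients(c(5, 5, 5), c("c", "a", "b")), c(2, 3, 1))
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:60, 1)
    v <- sample(round(rnorm(n), 1), n, replace = TRUE)  # force ties
    ids <- sample(sprintf("P%03d", 1:n))
    got <- rank_patients(v, ids)
    naive <- order(v, ids)   # naive sort oracle
    expect_equal(v[got], v[naive])
    expect_equal(ids[got], ids[naive])
  }
})

test_that("vectorized serial log-rank equals the membership-matrix kernel", {
  for (seed in 1:5) {
    set.seed(seed + 10)
    N <- 120
    times <- round(rexp(N, 0.01), 1)
    events <- rbinom(N, 1, 0.5)
    pos <- candidate_positions(N)$positions
    fast <- survscreen:::serial_logrank(times, events, pos)
    G <- outer(seq_len(N), pos, `<=`) * 1
    slow <- survscreen:::logrank_kernel(times, events, G)
    expect_equal(fast$chi, slow$chi, tolerance = 1e-10)
    expect_equal(fast$var, slow$var, tolerance = 1e-10)
    expect_equal(fast$events_in, as.numeric(slow$events_in))
  }
})

test_that("scan statuses cover the grid and stored p values are reproducible", {
  sim <- simulate_dataset(sim_config(150, gene_effects(1), seed = 3))
  d <- sim$dataset
  grid <- candidate_positions(150)
  sc <- scan_gene(d$expression[1, ], d$clinical$time, d$clinical$event,
                  grid, ids = d$clinical$patient_id, gene = "NULL0001")
  expect_equal(sc$profile$rank, grid$positions)
  expect_true(all(sc$profile$status %in%
                    c("valid", "skipped_tie", "skipped_degenerate")))
  valid <- sc$profile$status == "valid"
  expect_true(all(sc$profile$p[valid] > 0 & sc$profile$p[valid] <= 1))
  # each stored p is recovered by an independent two-group log-rank on the
  # reconstructed groups
  for (i in which(valid)[seq(1, sum(valid), by = 7)]) {
    k <- sc$profile$rank[i]
    lr <- logrank(sc$times[1:k], sc$events[1:k],
                  sc$times[(k + 1):150], sc$events[(k + 1):150])
    expect_equal(sc$profile$p[i], lr$p, tolerance = 1e-10)
  }
})

test_that("tie blocks shrink the evaluated range exactly as ranks demand", {
  # 414 patients whose lowest 144 expression values are one tied block:
  # every cut below rank 144 would split the block, so the valid range is
  # 144..290 - 147 evaluated p values
  set.seed(8)
  N <- 414
  vals <- c(rep(-10, 144), sort(rnorm(N - 144)))
  times <- round(rexp(N, 0.002), 1)
  events <- rbinom(N, 1, 0.5)
  sc <- scan_gene(vals, times, events, candidate_positions(N),
                  gene = "TIEBLOCK")
  valid_ranks <- sc$profile$rank[sc$profile$status == "valid"]
  expect_equal(valid_ranks, 144:290)
  expect_length(valid_ranks, 147)
  expect_equal(sum(sc$profile$status == "skipped_tie"), 144 - 125)
})

test_that("degenerate scans fail with a category instead of halting", {
  N <- 50
  times <- round(rexp(N, 0.01), 1)
  # all-tied expression: every cut splits the tie
  sc <- scan_gene(rep(1, N), times, rbinom(N, 1, 0.5),
                  candidate_positions(N), gene = "FLAT")
  expect_true(all(sc$profile$status == "skipped_tie"))
  expect_true(sc$failed)
  expect_equal(sc$failure_category, "one-group-logrank")
  # no deaths at all: every position is degenerate
  sc2 <- scan_gene(rnorm(N), times, rep(0, N), candidate_positions(N))
  expect_true(all(sc2$profile$status == "skipped_degenerate"))
  expect_true(sc2$failed)
})

test_that("optimal selection equals an exhaustive survdiff re-scan", {
  sim <- simulate_dataset(sim_config(
    400, gene_effects(0, data.frame(q = 0.4, hr = 3)), seed = 17
  ))
  d <- sim$dataset
  sc <- scan_gene(d$expression[1, ], d$clinical$time, d$clinical$event,
                  candidate_positions(400), ids = d$clinical$patient_id,
                  gene = "SIG01")
  oc <- select_optimal(sc)
  expect_equal(oc$n_low + oc$n_high, 400)
  expect_equal(oc$n_low, oc$rank_k)
  expect_false(oc$used_fallback)
  # recovered cut near the planted 40th percentile (rank 160)
  expect_lte(abs(oc$rank_k - 160), 20)
  orc <- rescan_oracle(d$expression[1, ], d$clinical$time, d$clinical$event,
                       d$clinical$patient_id)
  expect_equal(oc$rank_k, orc$positions[which.min(orc$p)])
  expect_equal(oc$p_min, min(orc$p, na.rm = TRUE), tolerance = 1e-10)
  expect_equal(oc$cutoff_value, sort(d$expression[1, ])[oc$rank_k])
})

test_that("selection falls back to the median rank when nothing is significant", {
  sim <- simulate_dataset(sim_config(101, gene_effects(1), seed = 9))
  d <- sim$dataset
  sc <- scan_gene(d$expression[1, ], d$clinical$time, d$clinical$event,
                  candidate_positions(101), ids = d$clinical$patient_id)
  oc <- select_optimal(sc, sig_level = 0)   # nothing can beat level 0
  expect_true(oc$used_fallback)
  expect_equal(oc$rank_k, 50)               # floor(101/2)
  expect_equal(oc$p_min, survscreen:::cut_p_at_rank(sc, 50))

  # failed scan whose median cut is also degenerate: excluded with category
  flat <- scan_gene(rep(2, 40), round(rexp(40, 0.01), 1), rbinom(40, 1, 0.5),
                    candidate_positions(40), gene = "FLAT")
  expect_error(select_optimal(flat), class = "survscreen_one_group_logrank")
})

test_that("whole-dataset scan isolates per-gene failures and is deterministic", {
  sim <- simulate_dataset(sim_config(80, gene_effects(50), seed = 13))
  d <- sim$dataset
  # plant 5 all-tied genes
  for (g in 1:5) {
    d$expression[g, ] <- 7
  }
  attr(d$expression, "null_mask")[1:5, ] <- FALSE
  scr <- scan_all(d)
  expect_equal(nrow(scr$cuts), 45)
  expect_equal(nrow(scr$failures), 5)
  expect_true(all(scr$failures$category == "one-group-logrank"))
  expect_equal(sum(scr$failure_proportions), 1)

  scr2 <- scan_all(d)
  expect_identical(scr, scr2)

  empty <- d
  empty$expression <- d$expression[integer(0), , drop = FALSE]
  attr(empty$expression, "null_mask") <-
    attr(d$expression, "null_mask")[integer(0), , drop = FALSE]
  expect_equal(nrow(scan_all(empty)$cuts), 0)
})

test_that("per-gene missingness shrinks the effective cohort, not the pipeline", {
  sim <- simulate_dataset(sim_config(60, gene_effects(4),
                                     null_value_fraction = 0.2, seed = 19))
  scr <- scan_all(sim$dataset)
  expect_true(all(scr$cuts$n_used <= 60))
  expect_true(all(scr$cuts$n_used >= 10))
  mask <- attr(sim$dataset$expression, "null_mask")
  for (i in seq_len(nrow(scr$cuts))) {
    g <- scr$cuts$gene[i]
    expect_equal(scr$cuts$n_used[i], sum(!mask[match(g, rownames(mask)), ]))
  }
})
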