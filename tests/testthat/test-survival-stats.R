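test_that("Kaplan-Meier estimate matches the product-limit formula", {
  # fully censored cohort: survival stays at 1
  cens <- km_estimate(c(3, 7, 9), c(0, 0, 0))
  expect_length(cens$event_times, 0)
  expect_equal(survival_at(cens, c(0, 5, 100)), c(1, 1, 1))

  # hand-computed: censor at 1, events at 2 and 3
  km <- km_estimate(c(1, 2, 3), c(0, 1, 1))
  expect_equal(km$event_times, c(2, 3))
  expect_equal(km$survival, c(0.5, 0))
  expect_equal(km$at_risk, c(2, 1))

  # random small datasets against the textbook formula
  for (seed in 1:50) {
    d <- random_surv(sample(5:30, 1), seed)
    km <- km_estimate(d$times, d$events)
    orc <- km_oracle(d$times, d$events)
    expect_equal(km$event_times, orc$time)
    expect_equal(km$survival, orc$surv, tolerance = 1e-12)
    expect_equal(km$at_risk, orc$at_risk)
  }
})

test_that("survival curves are valid step functions (property)", {
  for (seed in 1:25) {
    d <- random_surv(sample(5:40, 1), seed + 100)
    km <- km_estimate(d$times, d$events)
    s <- km$survival
    expect_true(all(s >= 0 & s <= 1))
    expect_true(all(diff(s) <= 0))
    if (length(km$at_risk) > 1) expect_true(all(diff(km$at_risk) < 0))
    # right-continuity and flat extension
    if (length(km$event_times)) {
      t1 <- km$event_times[1]
      expect_equal(survival_at(km, t1 - 1e-9), 1)
      expect_equal(survival_at(km, t1), s[1])
      expect_equal(survival_at(km, max(km$event_times) + 1000), s[length(s)])
    }
  }
})

test_that("log-rank matches hand evaluation, the direct-formula oracle, and survdiff", {
  # one event per group: O-E = 0.5 at the first event time, V = 0.25
  lr <- logrank(1, 1, 2, 1)
  expect_equal(lr$chi_square, 1.0)
  expect_equal(lr$p, pchisq(1, 1, lower.tail = FALSE), tolerance = 1e-12)

  # identical groups: no signal
  lr0 <- logrank(c(1, 5, 9), c(1, 0, 1), c(1, 5, 9), c(1, 0, 1))
  expect_equal(lr0$chi_square, 0)
  expect_equal(lr0$p, 1)

  for (seed in 1:50) {
    a <- random_surv(sample(5:25, 1), seed + 200)
    b <- random_surv(sample(5:25, 1), seed + 500)
    lr <- logrank(a$times, a$events, b$times, b$events)
    orc <- logrank_oracle(a$times, a$events, b$times, b$events)
    expect_equal(lr$chi_square, orc$chi_square, tolerance = 1e-10)
    sd <- survival::survdiff(
      survival::Surv(c(a$times, b$times), c(a$events, b$events)) ~
        rep(1:2, c(length(a$times), length(b$times)))
    )
    expect_equal(lr$chi_square, unname(sd$chisq), tolerance = 1e-10)
  }
})

test_that("log-rank is label-symmetric and invariant to time rescaling", {
  a <- random_surv(15, 1); b <- random_surv(12, 2)
  lr1 <- logrank(a$times, a$events, b$times, b$events)
  lr2 <- logrank(b$times, b$events, a$times, a$events)
  expect_equal(lr1$chi_square, lr2$chi_square, tolerance = 1e-12)
  lr3 <- logrank(a$times * 365.25, a$events, b$times * 365.25, b$events)
  expect_equal(lr1$p, lr3$p, tolerance = 1e-12)
})

test_that("log-rank degenerate inputs raise categorized errors", {
  expect_error(logrank(numeric(0), numeric(0), 1, 1), "non-empty")
  err <- expect_error(logrank(c(1, 2), c(0, 0), c(3, 4), c(0, 0)),
                      class = "survscreen_one_group_logrank")
  expect_equal(err$category, "one-group-logrank")
})

test_that("Cox fit agrees with an independent Newton/Efron maximizer", {
  # fixed 20-row, 2-covariate dataset with ties
  set.seed(33)
  X <- cbind(x1 = rbinom(20, 1, 0.5), x2 = rbinom(20, 1, 0.4))
  times <- sample(rep(c(2, 5, 8, 11, 15), each = 4))
  events <- rbinom(20, 1, 0.7)
  fit <- cox_fit(X, times, events)
  orc <- cox_oracle(X, times, events)
  expect_equal(log(fit$table$hr), unname(orc$beta), tolerance = 1e-6)
  expect_equal(log(fit$table$hr) - log(fit$table$ci_lo),
               1.96 * unname(orc$se), tolerance = 1e-6)

  # random replicates
  for (seed in 1:10) {
    set.seed(seed + 900)
    n <- 30
    X <- cbind(a = rbinom(n, 1, 0.5), b = rbinom(n, 1, 0.3))
    if (min(colSums(X)) %in% c(0, n)) next
    tm <- round(rexp(n, 0.1), 2)
    ev <- rbinom(n, 1, 0.8)
    fit <- cox_fit(X, tm, ev)
    orc <- cox_oracle(X, tm, ev)
    expect_equal(log(fit$table$hr), unname(orc$beta), tolerance = 1e-6)
  }
})

test_that("Cox hazard ratio is exactly 1 on label-symmetric data", {
  times <- rep(c(3, 6, 9, 12), 2)
  events <- rep(c(1, 0, 1, 1), 2)
  g <- rep(c(0, 1), each = 4)
  fit <- cox_fit(data.frame(g = g), times, events)
  expect_equal(fit$table$hr, 1, tolerance = 1e-8)
})

test_that("Cox fit recovers a planted hazard ratio at large n", {
  set.seed(77)
  n <- 2000
  g <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, rate = 0.001 * ifelse(g == 1, 2.0, 1.0))
  t_c <- rexp(n, rate = 0.00025)   # ~20% censoring
  times <- pmin(t_ev, t_c)
  events <- as.integer(t_ev <= t_c)
  fit <- cox_fit(data.frame(g = g), times, events)
  expect_true(fit$table$ci_lo <= 2.0 && fit$table$ci_hi >= 2.0)
  expect_true(fit$converged)
})

test_that("Cox estimator is consistent for the planted log hazard ratio", {
  est <- numeric(100)
  for (r in 1:100) {
    set.seed(r + 4000)
    n <- 1000
    g <- rbinom(n, 1, 0.5)
    t_ev <- rexp(n, 0.001 * ifelse(g == 1, 1.8, 1))
    t_c <- rexp(n, 0.0003)
    fit <- cox_fit(data.frame(g = g), pmin(t_ev, t_c),
                   as.integer(t_ev <= t_c))
    est[r] <- log(fit$table$hr)
  }
  expect_lt(abs(mean(est) - log(1.8)), 0.05)
})

test_that("Cox degenerate inputs are explicit errors", {
  err <- expect_error(cox_fit(data.frame(g = rep(1, 5)), 1:5, rep(1, 5)),
                      class = "survscreen_one_group_cox")
  expect_equal(err$category, "one-group-cox")
  expect_error(cox_fit(data.frame(g = c(0, 1, 0)), 1:3, c(0, 0, 0)), "events")
})

test_that("monotone likelihood is reported as non-convergence, not a finite estimate", {
  # perfect separation: the covariate-1 group all fails first
  times <- c(1, 2, 3, 10, 11, 12)
  events <- c(1, 1, 1, 1, 1, 1)
  g <- c(1, 1, 1, 0, 0, 0)
  fit <- cox_fit(data.frame(g = g), times, events)
  expect_false(fit$converged)
})

test_that("univariate table fits each feature separately and logs failures", {
  sim <- simulate_dataset(sim_config(300, gene_effects(2), seed = 5))
  d <- sim$dataset
  covs <- dichotomize(d$clinical, tobacco_median_split(d$clinical))
  gene_high <- as.integer(d$expression[1, ] > median(d$expression[1, ]))
  ut <- univariate_table(covs, gene_high, d$clinical$time, d$clinical$event)
  expect_equal(nrow(ut$table) + nrow(ut$failures), 9)
  expect_true(all(ut$table$hr > 0))
  expect_true(all(ut$table$ci_lo <= ut$table$hr & ut$table$hr <= ut$table$ci_hi))

  covs$all_same <- 1L
  ut2 <- univariate_table(covs, NULL, d$clinical$time, d$clinical$event)
  expect_true("all_same" %in% ut2$failures$term)
})

test_that("univariate fit recovers a doubled-hazard margin effect", {
  set.seed(21)
  n <- 800
  margin <- rbinom(n, 1, 0.4)
  t_ev <- rexp(n, 0.001 * ifelse(margin == 1, 2, 1))
  times <- pmin(t_ev, 2000)
  events <- as.integer(t_ev <= 2000)
  ut <- univariate_table(data.frame(margin_positive = margin), NULL, times, events)
  row <- ut$table[ut$table$term == "margin_positive", ]
  expect_true(row$ci_lo <= 2 && row$ci_hi >= 2)
})

test_that("multivariate fit adjusts the gene effect for confounders", {
  set.seed(99)
  n <- 1200
  conf <- rbinom(n, 1, 0.5)
  gene <- rbinom(n, 1, 0.4)
  t_ev <- rexp(n, 0.001 * exp(log(2) * gene + log(1.8) * conf))
  times <- pmin(t_ev, 2500)
  events <- as.integer(t_ev <= 2500)
  fit <- multivariate_fit(data.frame(conf = conf), gene, times, events)
  tab <- fit$table
  grow <- tab[tab$term == "gene_high", ]
  crow <- tab[tab$term == "conf", ]
  expect_true(grow$ci_lo <= 2 && grow$ci_hi >= 2)
  expect_true(crow$ci_lo <= 1.8 && crow$ci_hi >= 1.8)

  expect_error(multivariate_fit(data.frame(conf = conf), rep(1L, n),
                                times, events),
               class = "survscreen_one_group_cox")
})

test_that("a near-empty covariate subgroup triggers an instability warning", {
  set.seed(12)
  n <- 200
  m1 <- c(rep(1, 3), rep(0, n - 3))
  gene <- rbinom(n, 1, 0.5)
  times <- round(rexp(n, 0.001), 1)
  events <- rbinom(n, 1, 0.6)
  expect_warning(
    multivariate_fit(data.frame(m1 = m1), gene, times, events),
    "near-empty subgroup"
  )
})
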