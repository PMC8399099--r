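# Independent oracles used to cross-check the package's estimators. Each is
# a deliberately naive, direct-formula implementation sharing no code with
# the package internals.

# product-limit estimator straight from the definition
km_oracle <- function(times, events) {
  ts <- sort(unique(times[events == 1]))
  s <- 1
  out <- data.frame(time = ts, surv = NA_real_, at_risk = NA_integer_)
  for (i in seq_along(ts)) {
    n_risk <- sum(times >= ts[i])
    d <- sum(times == ts[i] & events == 1)
    s <- s * (1 - d / n_risk)
    out$surv[i] <- s
    out$at_risk[i] <- n_risk
  }
  out
}

# two-group log-rank chi-square by explicit loop over pooled event times
logrank_oracle <- function(tA, eA, tB, eB) {
  times <- c(tA, tB); events <- c(eA, eB)
  grp <- rep(c(1, 0), c(length(tA), length(tB)))
  U <- 0; V <- 0
  for (t in sort(unique(times[events == 1]))) {
    at <- times >= t
    n <- sum(at); nA <- sum(at & grp == 1)
    d <- sum(times == t & events == 1)
    dA <- sum(times == t & events == 1 & grp == 1)
    U <- U + dA - d * nA / n
    if (n > 1) V <- V + d * (nA / n) * (1 - nA / n) * (n - d) / (n - 1)
  }
  chi <- U^2 / V
  list(chi_square = chi, p = pchisq(chi, 1, lower.tail = FALSE))
}

# quadratic-time Benjamini-Hochberg step-up from the definition
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(ord == i)  # rank of p[i]
    adj[i] <- min(sapply(r:m, function(j) min(1, p[ord[j]] * m / j)))
  }
  adj
}

pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Newton-Raphson maximizer of the Cox partial likelihood with Efron tie
# handling, written from the score/information formulas
cox_oracle <- function(X, times, events, iter = 60, tol = 1e-12) {
  X <- as.matrix(X)
  p <- ncol(X)
  beta <- rep(0, p)
  d_times <- sort(unique(times[events == 1]))
  for (it in seq_len(iter)) {
    eta <- as.numeric(X %*% beta)
    w <- exp(eta)
    U <- rep(0, p); I <- matrix(0, p, p)
    for (t in d_times) {
      R <- which(times >= t)
      D <- which(times == t & events == 1)
      d <- length(D)
      s0R <- sum(w[R]);  s1R <- colSums(w[R] * X[R, , drop = FALSE])
      s2R <- t(X[R, , drop = FALSE]) %*% (w[R] * X[R, , drop = FALSE])
      s0D <- sum(w[D]);  s1D <- colSums(w[D] * X[D, , drop = FALSE])
      s2D <- t(X[D, , drop = FALSE]) %*% (w[D] * X[D, , drop = FALSE])
      U <- U + colSums(X[D, , drop = FALSE])
      for (l in seq_len(d) - 1) {
        s0 <- s0R - (l / d) * s0D
        s1 <- s1R - (l / d) * s1D
        s2 <- s2R - (l / d) * s2D
        U <- U - s1 / s0
        I <- I + s2 / s0 - tcrossprod(s1 / s0)
      }
    }
    step <- solve(I, U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(beta = beta, se = sqrt(diag(solve(I))))
}

# small random right-censored survival dataset
random_surv <- function(n, seed) {
  set.seed(seed)
  t_ev <- rexp(n, 0.1)
  t_c <- rexp(n, 0.05)
  times <- round(pmin(t_ev, t_c), 3)
  # perturb occasionally to create ties
  if (n > 4) times[sample(n, 2)] <- times[1]
  list(times = times, events = as.integer(t_ev <= t_c))
}

# exhaustive serial-cut re-scan using survival::survdiff, used as the
# independent route for checking optimal-cut selection
rescan_oracle <- function(values, times, events, ids, lo = 0.3, hi = 0.7) {
  N <- length(values)
  ord <- order(values, as.character(ids), method = "radix")
  vs <- values[ord]; ts <- times[ord]; es <- events[ord]
  pos <- (floor(lo * N) + 1L):min(ceiling(hi * N), N - 1L)
  ps <- rep(NA_real_, length(pos))
  for (i in seq_along(pos)) {
    k <- pos[i]
    if (vs[k] == vs[k + 1]) next
    g <- rep(c(0, 1), c(k, N - k))
    if (sum(es[g == 0]) == 0 || sum(es[g == 1]) == 0) next
    sd <- survival::survdiff(survival::Surv(ts, es) ~ g)
    ps[i] <- pchisq(sd$chisq, 1, lower.tail = FALSE)
  }
  list(positions = pos, p = ps)
}

# canonical small clinical table used by the io tests
make_clinical_df <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    patient_id = sprintf("PT-%03d", seq_len(n)),
    time = round(runif(n, 10, 2000), 1),
    event = rbinom(n, 1, 0.5),
    gender = sample(c("female", "male"), n, replace = TRUE),
    age_years = round(runif(n, 35, 85), 1),
    clinical_t = sample(c("T1", "T2", "T3", "T4"), n, replace = TRUE),
    clinical_n = sample(c("N0", "N1", "N2", "N3"), n, replace = TRUE),
    clinical_m = sample(c("M0", "M1"), n, replace = TRUE, prob = c(0.95, 0.05)),
    stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE),
    margin = sample(c("negative", "positive"), n, replace = TRUE),
    tobacco_pack_years = round(runif(n, 0, 80), 1),
    stringsAsFactors = FALSE
  )
}

write_clinical_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_expression_tsv <- function(mat, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
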