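# Independent brute-force oracles. Deliberately naive (double loops,
# enumeration, grid search) and kept free of the package code paths they
# cross-check.

# product-moment correlation by the textbook formula, double loop
oraclePearson <- function(x, y) {
  x <- unname(x); y <- unname(y)
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sxx <- syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# pair indicators by explicit double loop over pairs and samples
oraclePairMatrix <- function(m) {
  ids <- sort(rownames(m))
  out <- list()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i < j) {
      a <- numeric(ncol(m))
      for (s in seq_len(ncol(m)))
        a[s] <- if (m[ids[i], s] > m[ids[j], s]) 1 else 0
      out[[paste(ids[i], ids[j], sep = "|")]] <- a
    }
  }
  res <- do.call(rbind, out)
  colnames(res) <- colnames(m)
  res
}

# Breslow partial log-likelihood for arbitrary beta (matrix X: n x p)
oracleBreslowLoglik <- function(beta, time, event, X) {
  eta <- as.vector(X %*% beta)
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

# 1-D grid maximization of the Breslow partial likelihood
oracleGridCox1 <- function(time, event, x, lo = -5, hi = 5, step = 1e-3) {
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, function(b)
    oracleBreslowLoglik(b, time, event, cbind(x)), numeric(1))
  grid[which.max(ll)]
}

# 2-D grid maximization (coarse-to-fine to stay fast)
oracleGridCox2 <- function(time, event, X, lo = -5, hi = 5) {
  best <- c(0, 0)
  width <- hi - lo
  centre <- c(0, 0)
  for (pass in 1:4) {
    g1 <- seq(centre[1] - width / 2, centre[1] + width / 2, length.out = 41)
    g2 <- seq(centre[2] - width / 2, centre[2] + width / 2, length.out = 41)
    ll_best <- -Inf
    for (b1 in g1) for (b2 in g2) {
      ll <- oracleBreslowLoglik(c(b1, b2), time, event, X)
      if (ll > ll_best) { ll_best <- ll; best <- c(b1, b2) }
    }
    centre <- best
    width <- width / 10
  }
  best
}

# exhaustive AIC scan over ALL midpoint candidates (no group-size guard
# ordering tricks; same guard applied independently)
oracleAICScan <- function(score, time, event, min_frac = 0.10) {
  u <- sort(unique(score))
  cand <- (head(u, -1) + tail(u, -1)) / 2
  n <- length(score)
  best <- NULL; best_aic <- Inf
  for (c0 in cand) {
    nh <- sum(score > c0)
    if (nh < ceiling(min_frac * n) || (n - nh) < ceiling(min_frac * n)) next
    fit <- survival::coxph(survival::Surv(time, event) ~ I(score > c0),
                           ties = "breslow")
    aic <- -2 * fit$loglik[2] + 2
    if (aic < best_aic - 1e-12) { best_aic <- aic; best <- c0 }
  }
  list(cutoff = best, aic = best_aic)
}

# hand risk-set accounting for the two-group log-rank test
oracleLogrank <- function(time, event, group) {
  g <- as.integer(factor(group)) # 1/2
  ts <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t0 in ts) {
    at_risk <- time >= t0
    n1 <- sum(at_risk & g == 1); n2 <- sum(at_risk & g == 2)
    d1 <- sum(time == t0 & event == 1 & g == 1)
    d2 <- sum(time == t0 & event == 1 & g == 2)
    n <- n1 + n2; d <- d1 + d2
    if (n < 2) next
    O <- O + d1
    E <- E + d * n1 / n
    V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  list(O = O, E = E, V = V, chisq = (O - E)^2 / V)
}

# exact two-sided Wilcoxon rank-sum p by full enumeration of assignments
oracleExactWilcoxP <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- combn(n, nx)
  ws <- apply(combs, 2, function(i) sum(rank(pooled)[i]) - nx * (nx + 1) / 2)
  mu <- nx * (n - nx) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# BH step-up by the textbook recipe
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# empirical cumulative/dynamic AUC for uncensored data: concordance of
# (case by t, control after t) pairs with 0.5 credit for score ties
oracleUncensoredAUC <- function(score, time, t0) {
  cases <- which(time <= t0)
  controls <- which(time > t0)
  tot <- 0
  for (i in cases) for (j in controls)
    tot <- tot + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
  tot / (length(cases) * length(controls))
}

# small synthetic configs used across tests
smallConfig <- function(seed = 1, ...) {
  syntheticConfig(n_tumor = 120, n_normal = 30, n_aging_genes = 10,
                  n_lncRNA = 40, n_linked_lncRNA = 30, n_de_up = 16,
                  n_de_down = 4, n_signal_pairs = 2,
                  true_coefficients = c(1.5, -1.0), seed = seed, ...)
}
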