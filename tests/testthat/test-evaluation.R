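scoresDF <- function(x, samples = paste0("s", seq_along(x))) {
  data.frame(sample = samples, risk_score = x, stringsAsFactors = FALSE)
}

clinDF <- function(time, event, samples = paste0("s", seq_along(time))) {
  data.frame(sample = samples, time = time, event = event,
             stringsAsFactors = FALSE)
}

test_that("a perfect marker reaches AUC 1 and a null marker ~ 0.5", {
  set.seed(50)
  n <- 300
  tm <- rexp(n, 1e-3)
  ev <- rep(1, n)
  roc <- timeDependentROC(scoresDF(-tm), clinDF(tm, ev), 700)
  expect_equal(roc$auc, 1, tolerance = 1e-12)
  null_roc <- timeDependentROC(scoresDF(rnorm(n)), clinDF(tm, ev), 700)
  expect_lt(abs(null_roc$auc - 0.5), 0.1)
})

test_that("uncensored ROC equals the exhaustive concordance oracle", {
  set.seed(51)
  for (s in 1:10) {
    n <- 6
    tm <- sample(10:100, n)
    sc <- rnorm(n)
    t0 <- median(tm) + 1
    roc <- timeDependentROC(scoresDF(sc), clinDF(tm, rep(1, n)), t0)
    expect_equal(roc$auc, oracleUncensoredAUC(sc, tm, t0), tolerance = 1e-10)
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(52)
  n <- 80
  sc <- rnorm(n)
  tm <- rexp(n, 1e-3 * exp(0.7 * sc))
  ev <- rbinom(n, 1, 0.8)
  cl <- clinDF(tm, ev)
  a1 <- timeDependentROC(scoresDF(sc), cl, median(tm))$auc
  a2 <- timeDependentROC(scoresDF(exp(sc)), cl, median(tm))$auc
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("ROC contract errors fire", {
  tm <- c(10, 20, 30); ev <- c(0, 0, 1)
  expect_error(timeDependentROC(scoresDF(1:3), clinDF(tm, ev), 100),
               "exceeds the observed follow-up")
  expect_error(timeDependentROC(scoresDF(1:3), clinDF(tm, ev), 25),
               "no event before the horizon")
})

test_that("AIC cutoff equals the exhaustive scan and is shift-equivariant", {
  set.seed(53)
  for (s in 1:15) {
    n <- sample(20:50, 1)
    sc <- rnorm(n)
    tm <- rexp(n, 1e-3 * exp(sc))
    ev <- rbinom(n, 1, 0.9); ev[1] <- 1
    res <- aicOptimalCutoff(scoresDF(sc), clinDF(tm, ev))
    ora <- oracleAICScan(sc, tm, ev)
    expect_equal(res$cutoff, ora$cutoff, tolerance = 1e-10)
    expect_equal(min(res$aic_profile$aic), ora$aic, tolerance = 1e-10)
    # translation equivariance
    res_k <- aicOptimalCutoff(scoresDF(sc + 5), clinDF(tm, ev))
    expect_equal(res_k$cutoff, res$cutoff + 5, tolerance = 1e-10)
  }
})

test_that("well-separated score clusters are split between the clusters", {
  # the AIC-minimal dichotomy may legitimately shave one or two boundary
  # samples whose survival draw is atypical, so assert near-separation:
  # the cutoff lies between the cluster medians and the implied grouping
  # agrees with the cluster label for almost every sample
  set.seed(54)
  n <- 100
  cluster <- rep(c(0, 1), each = n / 2)
  sc <- c(rnorm(n / 2, 0, 0.2), rnorm(n / 2, 5, 0.2))
  tm <- rexp(n, 1e-3 * exp(2 * cluster))
  res <- aicOptimalCutoff(scoresDF(sc), clinDF(tm, rep(1, n)))
  expect_gt(res$cutoff, median(sc[cluster == 0]))
  expect_lt(res$cutoff, median(sc[cluster == 1]))
  expect_gte(mean((sc > res$cutoff) == (cluster == 1)), 0.95)
  expect_equal(res$n_high + res$n_low, n)
})

test_that("log-rank O/E/V match hand risk-set accounting", {
  # classic small two-group case with censoring
  tm <- c(6, 7, 10, 15, 19, 25, 23, 21)
  ev <- c(1, 0, 1, 1, 0, 1, 1, 0)
  gr <- rep(c("high", "low"), each = 4)
  sc <- scoresDF(c(2, 2, 2, 2, -1, -1, -1, -1))
  sc$group <- gr
  out <- kmLogrank(sc, clinDF(tm, ev))
  ora <- oracleLogrank(tm, ev, gr)
  expect_equal(out$chisq, ora$chisq, tolerance = 1e-8)
  expect_equal(unname(out$obs[1]), ora$O)
  expect_equal(unname(out$exp[1]), ora$E, tolerance = 1e-8)
  # label swap leaves the statistic unchanged
  sc2 <- sc; sc2$group <- rev(gr)
  out2 <- kmLogrank(sc2, clinDF(tm, ev))
  expect_equal(out2$chisq, out$chisq, tolerance = 1e-12)
})

test_that("identical groups give statistic 0 and KM equals empirical survival", {
  tm <- rep(c(5, 10, 15, 20), 2)
  ev <- rep(1, 8)
  sc <- scoresDF(rep(0, 8)); sc$group <- rep(c("high", "low"), each = 4)
  out <- kmLogrank(sc, clinDF(tm, ev))
  expect_lt(out$chisq, 1e-10)
  expect_equal(out$p, 1, tolerance = 1e-6)
  # with no censoring the product-limit estimate is the empirical survivor
  km_high <- out$km[out$km$group == "high", ]
  expect_equal(km_high$surv, c(3, 2, 1, 0) / 4, tolerance = 1e-12)
  # no events anywhere is an error
  sc0 <- sc
  expect_error(kmLogrank(sc0, clinDF(tm, rep(0, 8))), "no events")
})

test_that("chi-square association matches the hand 2x2 formula", {
  sc <- scoresDF(c(rnorm(10, 5), rnorm(10, -5)))
  sc$group <- rep(c("high", "low"), each = 10)
  cl <- clinDF(rexp(20, 0.01), rep(1, 20))
  cl$sex <- rep(c("male", "female"), each = 10)   # perfectly aligned
  out <- clinicalAssociations(sc, cl, variables = "sex")
  chi <- out[out$test == "chi-square", ]
  expect_equal(chi$statistic, 20, tolerance = 1e-10)  # (10,0 / 0,10) table
  # identical score distributions across levels: Wilcoxon p = 1
  sc2 <- scoresDF(rep(c(1, 2, 3, 4, 5), 4))
  sc2$group <- rep(c("high", "low"), 10)
  cl2 <- clinDF(rexp(20, 0.01), rep(1, 20))
  cl2$sex <- rep(c("male", "female"), 10)
  out2 <- clinicalAssociations(sc2, cl2, variables = "sex")
  expect_equal(out2$p[out2$test == "Wilcoxon"], 1, tolerance = 1e-9)
})

test_that("multi-level variables get Kruskal-Wallis plus pairwise contrasts", {
  set.seed(55)
  n <- 120
  sc <- scoresDF(rnorm(n)); sc$group <- sample(c("high", "low"), n, TRUE)
  cl <- clinDF(rexp(n, 0.01), rbinom(n, 1, 0.7))
  cl$stage <- sample(c("I", "II", "III", "IV"), n, TRUE)
  out <- clinicalAssociations(sc, cl, variables = "stage")
  expect_true("Kruskal-Wallis" %in% out$test)
  expect_equal(sum(out$test == "Wilcoxon"), choose(4, 2))
  expect_true(all(out$p >= 0 & out$p <= 1))
})

test_that("null chi-square p-values are uniform over replicates", {
  set.seed(56)
  ps <- replicate(200, {
    n <- 1000   # coarse p-value support at small n would bias the KS distance
    grp <- rep(c("high", "low"), each = n / 2)
    cov <- sample(rep(c("a", "b"), each = n / 2))
    suppressWarnings(chisq.test(table(grp, cov), correct = FALSE)$p.value)
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("independence Cox isolates a score-driven hazard", {
  set.seed(57)
  hits <- 0
  for (s in 1:20) {
    n <- 300
    score <- rnorm(n)
    tm <- rexp(n, 1e-3 * exp(score))
    ev <- rbinom(n, 1, 0.85)
    cl <- clinDF(tm, ev)
    cl$age <- round(rnorm(n, 65, 10))
    cl$sex <- sample(c("male", "female"), n, TRUE)
    cl$stage <- sample(c("I", "II", "III", "IV"), n, TRUE)
    out <- independenceCox(scoresDF(score), cl,
                           covariates = c("age", "sex", "stage"))
    multi <- out$multivariate
    ok <- multi$p[multi$term == "risk_score"] < 0.05 &&
      all(multi$p[multi$term != "risk_score"] > 0.05)
    hits <- hits + ok
  }
  expect_gte(hits, 14)   # covariate false positives at ~5% each
})

test_that("single-covariate multivariate fit equals the univariate fit", {
  set.seed(58)
  n <- 100
  score <- rnorm(n)
  cl <- clinDF(rexp(n, 1e-3 * exp(score)), rep(1, n))
  out <- independenceCox(scoresDF(score), cl, covariates = character(0))
  expect_equal(out$multivariate$coef, out$univariate$coef, tolerance = 1e-10)
})

test_that("duplicated covariates are dropped with a warning", {
  set.seed(59)
  n <- 80
  score <- rnorm(n)
  cl <- clinDF(rexp(n, 1e-3), rbinom(n, 1, 0.8))
  cl$age <- round(rnorm(n, 65, 8))
  cl$stage <- c("I", "II", "III", "IV")[pmin(4, pmax(1, round(cl$age / 20)))]
  cl$t_stage <- paste0("T", pmin(4, pmax(1, round(cl$age / 20))))  # duplicate
  expect_warning(
    out <- independenceCox(scoresDF(score), cl,
                           covariates = c("age", "stage", "t_stage")),
    "collinear|dropped")
  expect_false("t_stage" %in% out$multivariate$term)
})

test_that("ordinal clinical coding maps stages and handles unknowns", {
  cl <- data.frame(sample = paste0("s", 1:4),
                   time = 1:4, event = c(1, 0, 1, 0),
                   age = c(60, 70, 55, 80),
                   sex = c("male", "female", "M", "F"),
                   stage = c("I", "Stage II", "IV", "X"),
                   t_stage = c("T1", "T3", "TX", "T4"),
                   n_stage = c("N0", "N2", "N1", "NX"),
                   m_stage = c("M0", "M1", "M0", "MX"))
  enc <- encodeOrdinalClinical(cl)
  expect_equal(enc$sex, c(1, 0, 1, 0))
  expect_equal(enc$stage, c(1, 2, 4, NA))
  expect_equal(enc$t_stage, c(1, 3, NA, 4))
  expect_equal(enc$n_stage, c(0, 2, 1, NA))
  expect_equal(enc$m_stage, c(0, 1, 0, NA))
})
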