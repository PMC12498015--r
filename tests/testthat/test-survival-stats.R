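# Unit and property tests for the core statistics.

test_that("km_fit reproduces hand-computed product-limit estimates", {
  # no censoring: empirical survival
  c1 <- km_fit(c(10, 20, 30, 40), c(1, 1, 1, 1))
  expect_equal(c1$survival, c(0.75, 0.50, 0.25, 0.00))

  # mixed censoring, hand product: 4/5 * 3/4 * (censor skipped) * 1/2 * 0
  c2 <- km_fit(c(6, 44, 21, 14, 62), c(1, 1, 0, 1, 1))
  expect_equal(c2$event_times, c(6, 14, 44, 62))
  expect_equal(c2$survival, c(0.8, 0.6, 0.3, 0.0))

  # tied deaths and censorings at the same time: deaths processed first
  c3 <- km_fit(c(5, 5, 5, 10), c(1, 0, 1, 1))
  expect_equal(c3$at_risk, c(4, 1))
  expect_equal(c3$survival, c(0.5, 0.0))

  # single censored patient: curve identically 1, flagged
  expect_warning(c4 <- km_fit(3, 0), "zero events")
  expect_true(c4$no_events)
  expect_length(c4$survival, 0)
  expect_equal(survival_at(c4, 1000)$estimate, 1)

  expect_error(km_fit(numeric(0), integer(0)), "no patients")
  expect_error(km_fit(c(1, -2), c(1, 1)), "positive")
})

test_that("km_fit with no censoring equals the empirical survival function", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    t <- sample(1:40, n, replace = TRUE) # many ties
    km <- km_fit(t, rep(1, n))
    emp <- vapply(km$event_times, function(x) mean(t > x), numeric(1))
    expect_equal(km$survival, emp)
  }
})

test_that("survival_at is a right-continuous step function with carry-forward", {
  curve <- km_fit(c(10, 20, 30, 40), c(1, 1, 1, 1))
  expect_equal(survival_at(curve, 25)$estimate, 0.50)
  expect_equal(survival_at(curve, 20)$estimate, 0.50) # right-continuous at event
  expect_equal(survival_at(curve, 5)$estimate, 1.0)
  beyond <- survival_at(curve, 100)
  expect_equal(beyond$estimate, 0.0) # carried forward
  expect_false(beyond$defined)
  expect_true(survival_at(curve, 40)$defined)

  # non-increasing in the horizon
  curve2 <- km_fit(c(3, 8, 8, 15, 21, 30), c(1, 1, 0, 1, 0, 1))
  hs <- seq(1, 40, by = 1)
  vals <- vapply(hs, function(h) survival_at(curve2, h)$estimate, numeric(1))
  expect_true(all(diff(vals) <= 0))
})

test_that("logrank matches a brute-force per-event-time 2x2 oracle", {
  set.seed(21)
  for (i in 1:30) {
    n <- sample(10:50, 1)
    t <- round(rexp(n, 0.01), 2)
    s <- rbinom(n, 1, 0.7)
    g <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(g)) < 2 || sum(s) == 0) next
    bf <- logrank2_bruteforce(g, t, s)
    lr <- logrank(g, t, s)
    expect_equal(lr$statistic, bf$statistic, tolerance = 1e-10)
    expect_equal(lr$p_value, bf$p_value, tolerance = 1e-10)
    # O and E both sum to the total number of deaths
    expect_equal(sum(lr$observed), sum(s))
    expect_equal(sum(lr$expected), sum(s))
  }
})

test_that("logrank handles symmetry, degenerate and multi-group inputs", {
  t <- c(5, 9, 14, 20); s <- c(1, 1, 0, 1)
  dup <- logrank(rep(c("a", "b"), each = 4), c(t, t), c(s, s))
  expect_equal(dup$statistic, 0, tolerance = 1e-12)
  expect_equal(dup$p_value, 1, tolerance = 1e-12)

  zero <- logrank(c("a", "a", "b", "b"), c(1, 2, 3, 4), c(0, 0, 0, 0))
  expect_equal(zero$p_value, 1)
  expect_equal(zero$statistic, 0)

  expect_error(logrank(factor(c("a", "a"), levels = c("a", "b")),
                       c(1, 2), c(1, 1)), "empty group")

  # four groups: df = 3 and a valid chi-square
  set.seed(3)
  g <- sample(LETTERS[1:4], 80, replace = TRUE)
  lr <- logrank(g, rexp(80, 0.01), rbinom(80, 1, 0.8))
  expect_equal(lr$df, 3L)
  expect_gte(lr$statistic, 0)
})

test_that("hazard_ratio_oe satisfies its identities", {
  t <- c(5, 9, 14, 20); s <- c(1, 1, 0, 1)
  ident <- hazard_ratio_oe(rep(c("a", "b"), each = 4), c(t, t), c(s, s))
  expect_equal(ident$hr, 1, tolerance = 1e-12)

  set.seed(31)
  g <- sample(c("a", "b"), 60, replace = TRUE)
  tt <- rexp(60, 0.01); ss <- rbinom(60, 1, 0.8)
  ab <- hazard_ratio_oe(g, tt, ss, "a", "b")
  ba <- hazard_ratio_oe(g, tt, ss, "b", "a")
  expect_equal(ab$hr, 1 / ba$hr, tolerance = 1e-12) # label swap inverts exactly
  expect_equal(ab$log_hr_se, sqrt(1 / ab$e_a + 1 / ab$e_b))
})

test_that("quartile_bins uses the Q1-high convention and partitions patients", {
  qb <- quartile_bins(1:8)
  expect_equal(as.character(qb$bins),
               c("Q4", "Q4", "Q3", "Q3", "Q2", "Q2", "Q1", "Q1"))

  # heavy ties at a cutpoint: still a partition, ties to the lower bin
  v <- c(1, 2, 2, 2, 2, 2, 3, 4, 5, 6, 7, 8)
  qb2 <- quartile_bins(v)
  expect_equal(length(qb2$bins), length(v))
  expect_false(anyNA(qb2$bins))
  expect_true(all(v[qb2$bins == "Q1"] > v[qb2$bins == "Q4"]))

  expect_error(quartile_bins(rep(3, 10)), "constant")
  expect_error(quartile_bins(1:7), "at least 8")
})

test_that("quartile_bins is invariant under strictly monotone transforms", {
  set.seed(41)
  for (i in 1:20) {
    v <- rlnorm(sample(8:60, 1), 3, 1)
    base <- quartile_bins(v)$bins
    expect_equal(quartile_bins(log(v))$bins, base)
    expect_equal(quartile_bins(rank(v))$bins, base)
    expect_equal(quartile_bins(v^3)$bins, base)
  }
})

test_that("mann_whitney exact path matches brute-force enumeration", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$method, "exact")
  expect_equal(r$p_value, 0.1) # 2 * 1/20 by full enumeration

  # identical multisets: p = 1 (tie path)
  expect_equal(mann_whitney(c(2, 4, 6), c(2, 4, 6))$p_value, 1)

  # exact path agrees with wilcox.test's exact two-sided p
  set.seed(51)
  for (i in 1:15) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1))
    ref <- wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(mann_whitney(x, y)$p_value, ref$p.value, tolerance = 1e-12)
  }

  # asymptotic path with ties agrees with wilcox.test's corrected normal p
  set.seed(52)
  for (i in 1:10) {
    x <- sample(1:8, 30, replace = TRUE); y <- sample(2:9, 25, replace = TRUE)
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(mann_whitney(x, y)$p_value, ref$p.value, tolerance = 1e-10)
  }

  # power: a 2-SD shift at n = 100 is detected far below 0.001
  set.seed(53)
  expect_lt(mann_whitney(rnorm(100, 2), rnorm(100))$p_value, 1e-3)
})

test_that("pearson_r matches the direct covariance formula", {
  expect_equal(pearson_r(1:10, 1:10), 1)
  expect_equal(pearson_r(1:10, 10:1), -1)
  x <- c(1, 2, 3, 4); y <- c(2, 4, 5, 4)
  direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), direct, tolerance = 1e-12)
  expect_warning(r0 <- pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_true(is.na(r0))
})

test_that("bh_fdr performs the step-up adjustment", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # order preserved relative to input, q >= p elementwise
  set.seed(61)
  p <- runif(40)
  q <- bh_fdr(p)
  expect_equal(q, p.adjust(p, "BH"))
  expect_true(all(q >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("hypergeom_tail reproduces the worked enrichment example", {
  expect_equal(hypergeom_tail(4, K = 5, n = 5, N = 20), 76 / 15504,
               tolerance = 1e-12)
  expect_equal(hypergeom_tail(0, 5, 5, 20), 1)
})
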