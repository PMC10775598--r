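test_that("delta_abs computes |inter| - |intra| and drops missing pairs", {
  tab <- data.frame(parameter = c("a", "a", "b"),
                    inter_mm = c(8, 2, NA),
                    intra_mm = c(-3, 2, 1))
  d <- delta_abs(tab)
  expect_equal(d$delta_mm, c(5, 0))
  expect_equal(attr(d, "n_dropped"), 1L)
})

test_that("order-statistic percentiles follow the stated convention", {
  expect_equal(percentile_os(1:100, 0.95), 95)
  expect_equal(percentile_os(rep(7, 30), 0.5), 7)
  expect_equal(percentile_os(1:100, 1), 100)
  expect_error(percentile_os(1:10, 0), "q must")
  tab <- data.frame(parameter = rep(c("a", "b"), each = 100),
                    inter_mm = c(1:100, -(1:100)))
  ps <- percentile_summary(tab, 0.95, "inter_mm")
  expect_equal(unname(ps$per_parameter), c(95, 95))
  expect_equal(ps$median_across, 95)
  expect_warning(percentile_summary(tab[c(1:5, 101:105), ], 0.95, "inter_mm"),
                 "unstable")
})

test_that("signed-rank: all-positive n = 10 reproduces the enumeration p", {
  r <- signed_rank_test(1:10)
  expect_equal(r$method, "wilcoxon_signed_rank_exact")
  # 2 of 2^10 sign patterns are as extreme
  expect_lt(abs(r$p_value - 2 / 1024), 1e-6)
  expect_equal(r$statistic, 55)
})

test_that("signed-rank agrees with the reference implementation", {
  set.seed(31)
  for (i in 1:50) {
    d <- round(rnorm(sample(8:20, 1), mean = 0.3), 4)
    d <- d[d != 0]
    if (any(duplicated(abs(d)))) next
    mine <- signed_rank_test(d)
    ref <- wilcox.test(d, exact = TRUE)
    expect_lt(abs(mine$p_value - ref$p.value), 1e-6)
  }
})

test_that("signed-rank handles symmetry, zeros and degeneracy", {
  sym <- c(-6, -4, -2, 2, 4, 6)
  expect_gt(signed_rank_test(sym)$p_value, 0.5)
  withz <- c(0, 0, 1, 2, 3, -1, 4, 5, -2, 6, 7, 8)
  r <- signed_rank_test(withz)
  expect_equal(r$method, "wilcoxon_signed_rank_normal")
  expect_true(r$p_value > 0 && r$p_value < 1)
  deg <- signed_rank_test(rep(0, 5))
  expect_match(deg$note, "degenerate")
  # paired interface
  expect_equal(signed_rank_test(c(5, 6, 7), c(1, 2, 3))$statistic,
               signed_rank_test(c(4, 4, 4))$statistic)
})

test_that("rank-sum: {1,2} vs {3,4} reproduces the enumeration p", {
  r <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(r$method, "wilcoxon_rank_sum_exact")
  expect_lt(abs(r$p_value - 1 / 3), 1e-6)
  expect_equal(r$statistic, 0)
})

test_that("rank-sum agrees with the reference implementation", {
  set.seed(32)
  for (i in 1:50) {
    x <- round(runif(sample(4:10, 1)) * 100, 4)
    y <- round(runif(sample(4:12, 1)) * 100 + 10, 4)
    if (any(duplicated(c(x, y)))) next
    mine <- rank_sum_test(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_lt(abs(mine$p_value - ref$p.value), 1e-6)
  }
  # identical multisets put U at its midpoint
  x <- c(1, 3, 5, 7)
  r <- rank_sum_test(x, x)
  expect_equal(r$statistic, length(x)^2 / 2)
})

test_that("Ansari-Bradley exact matches hand enumeration on {1,9} vs {4,5,6}", {
  r <- scale_test(c(1, 9), c(4, 5, 6), "ansari_bradley")
  # after median-centering: {-4, 4} vs {-1, 0, 1}; pooled AB scores
  # (1,2,3,2,1); sample-one sum = 2, the unique minimum of the 10
  # assignments, so p = 2 * 1/10
  expect_equal(r$statistic, 2)
  expect_equal(r$method, "ansari_bradley_exact")
  expect_lt(abs(r$p_value - 0.2), 1e-9)
})

test_that("scale tests agree with the reference implementations", {
  set.seed(33)
  for (i in 1:20) {
    x <- rnorm(sample(6:9, 1))
    y <- rnorm(sample(6:9, 1)) * 2
    mine <- scale_test(x, y, "ansari_bradley", center = FALSE)
    ref <- ansari.test(x, y)
    expect_lt(abs(mine$p_value - ref$p.value), 1e-9)
    expect_equal(unname(mine$statistic), unname(ref$statistic))
  }
  for (i in 1:20) {
    x <- rnorm(25); y <- rnorm(25) * 1.5
    mine <- scale_test(x, y, "mood", center = FALSE)
    ref <- mood.test(x, y)
    expect_lt(abs(mine$p_value - ref$p.value), 1e-9)
  }
})

test_that("scale tests reject 3x spread with good power", {
  set.seed(34)
  rej <- 0L
  n_sim <- 200
  for (i in seq_len(n_sim)) {
    x <- rnorm(50); y <- rnorm(50, sd = 3)
    if (scale_test(x, y, "ansari_bradley")$p_value < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / n_sim, 0.8)
})

test_that("identical dispersion yields a calm scale test", {
  x <- c(1.1, 2.7, 3.2, 4.8, 5.9, 7.3)
  r <- scale_test(x, x + 100, "ansari_bradley")  # same spread, shifted
  expect_gt(r$p_value, 0.5)
  expect_warning(scale_test(rep(1:2, 10), rep(1:2, 10)), "tied")
})

test_that("correlations match the reference and hit the trivial poles", {
  x <- 1:20
  expect_equal(correlations(x, x, "pearson")$estimate, 1)
  expect_equal(correlations(x, -x + 3, "spearman")$estimate, -1)
  set.seed(35)
  for (i in 1:10) {
    a <- rnorm(30); b <- 0.5 * a + rnorm(30)
    mine <- correlations(a, b, "pearson")
    ref <- cor.test(a, b, method = "pearson")
    expect_lt(abs(mine$estimate - unname(ref$estimate)), 1e-9)
    expect_lt(abs(mine$p_value - ref$p.value), 1e-9)
    mine_s <- correlations(a, b, "spearman")
    ref_s <- cor.test(a, b, method = "spearman", exact = FALSE)
    expect_lt(abs(mine_s$estimate - unname(ref_s$estimate)), 1e-9)
  }
  r <- correlations(rnorm(40), rnorm(40), "pearson")
  expect_true(r$ci[1] < r$estimate && r$estimate < r$ci[2])
  expect_error(correlations(1:3, 1:3), "at least 5")
})

test_that("ECDF wrapper behaves as a right-continuous step function", {
  f <- step_ecdf(rep(4, 10))
  expect_equal(f(4), 1); expect_equal(f(3.999), 0)
  v <- rnorm(50)
  expect_equal(step_ecdf(v)(max(v)), 1)
  # Kolmogorov bound holds at its nominal rate
  set.seed(36)
  n <- 100; inside <- 0L; n_sim <- 200
  for (i in seq_len(n_sim)) {
    su <- sort(runif(n))
    d <- max(pmax((1:n) / n - su, su - (0:(n - 1)) / n))
    if (d < 1.36 / sqrt(n)) inside <- inside + 1L
  }
  expect_gt(inside / n_sim, 0.90)
})

test_that("percentile CI: conventions, degenerate cases, coverage", {
  r <- percentile_with_ci(1:100, q = 0.025)
  expect_equal(r$estimate, 3)  # ceiling(2.5) = 3rd order statistic
  expect_true(r$ci[1] <= r$estimate && r$estimate <= r$ci[2])
  cst <- percentile_with_ci(rep(5, 40), q = 0.25)
  expect_equal(unname(cst$ci), c(5, 5))
  expect_warning(percentile_with_ci(1:20, q = 0.01), "order statistic")
  # bootstrap path is seeded
  v <- rnorm(50)
  b1 <- percentile_with_ci(v, 0.25, method = "bootstrap", seed = 4)
  b2 <- percentile_with_ci(v, 0.25, method = "bootstrap", seed = 4)
  expect_identical(b1$ci, b2$ci)
  # binomial order-statistic inversion covers at its nominal rate
  set.seed(37)
  hits <- 0L; n_sim <- 300
  true_q <- qexp(0.25)
  for (i in seq_len(n_sim)) {
    v <- rexp(80)
    ci <- percentile_with_ci(v, 0.25)$ci
    if (ci[1] <= true_q && true_q <= ci[2]) hits <- hits + 1L
  }
  expect_gt(hits / n_sim, 0.90)
  expect_lt(hits / n_sim, 0.999)
})

test_that("rank adaptation fit matches the normal-equations oracle", {
  dev <- c(-4, -1, 0, 2, 5)
  rk <- c(0.9, 0.7, 0.5, 0.35, 0.1)
  fit <- rank_adaptation_fit(rk, dev)
  # closed-form OLS via the normal equations
  X <- cbind(1, dev)
  beta <- solve(t(X) %*% X, t(X) %*% rk)
  expect_equal(unname(fit$coefficients), as.numeric(beta), tolerance = 1e-12)
  res <- rk - X %*% beta
  r2 <- 1 - sum(res^2) / sum((rk - mean(rk))^2)
  expect_equal(fit$r_squared, r2, tolerance = 1e-12)
  # perfectly linear data
  perfect <- rank_adaptation_fit(seq(0, 1, length.out = 10),
                                 seq(-5, 5, length.out = 10))
  expect_equal(perfect$r_squared, 1, tolerance = 1e-9)
  # zero-slope data
  flat <- rank_adaptation_fit(rep(c(0.4, 0.6), 10), seq_len(20))
  expect_lt(flat$r_squared, 0.05)
  quad <- rank_adaptation_fit(rk, dev, quadratic = TRUE)
  expect_length(quad$coefficients, 3)
  expect_error(rank_adaptation_fit(c(0.5, 2), c(1, 2)), "scaled")
})
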