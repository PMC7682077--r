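test_that("spearman recovers perfect monotone and antitone relations", {
  up <- spearman(1:5, c(2, 4, 6, 8, 10))
  expect_equal(up$estimate, 1)
  expect_equal(up$p_value, 0)
  down <- spearman(1:5, c(10, 8, 6, 4, 2))
  expect_equal(down$estimate, -1)
})

test_that("spearman matches the sum-of-squared-rank-differences formula", {
  x <- 1:5
  y <- c(3, 1, 2, 5, 4)
  d2 <- sum((rank(x) - rank(y))^2)
  expect_equal(spearman(x, y)$estimate, 1 - 6 * d2 / (5 * (25 - 1)))
  expect_equal(spearman(x, y)$estimate, 0.6)
  # and the t-approximation p
  rs <- 0.6
  tt <- rs * sqrt(3 / (1 - rs^2))
  expect_equal(spearman(x, y)$p_value, 2 * pt(-abs(tt), df = 3))
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(15)
    y <- rnorm(15)
    base <- spearman(x, y)
    expect_equal(spearman(exp(x), y)$estimate, base$estimate)
    expect_equal(spearman(x, y^3 + 2 * y)$estimate, base$estimate)
    expect_equal(spearman(rank(x), y)$p_value, base$p_value)
  }
})

test_that("spearman flags degenerate inputs", {
  r <- spearman(c(1, 1, 1, 1), c(1, 2, 3, 4))
  expect_true(r$degenerate)
  expect_equal(r$p_value, 1)
  expect_error(spearman(1:3, 1:4), "equal length")
  expect_error(spearman(c(1, 2, NA), 1:3), "finite")
})

test_that("exact permutation p agrees with enumeration on tie-free data", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 5, 1, 4, 3)
  r <- spearman(x, y, exact = TRUE)
  # enumeration over all 120 permutations, done independently here
  perms <- expand.grid(rep(list(1:5), 5))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5), ]
  null_rs <- apply(perms, 1, function(p) cor(rank(x), rank(y)[unlist(p)]))
  expect_equal(r$p_value, mean(abs(null_rs) >= abs(r$estimate) - 1e-12))
})

test_that("bh_adjust implements the step-up definition", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("bh_adjust matches the brute-force step-up on random vectors", {
  set.seed(7)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_brute(p))
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
    # order-preserving: sorted inputs give sorted outputs
    expect_equal(order(q[order(p)]), seq_along(p))
  }
})

test_that("t_test matches the pooled-variance textbook formula", {
  a <- c(2.1, 1.9, 2.0, 2.2)
  b <- c(1.0, 1.2, 0.9, 1.1)
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  r <- t_test(a, b, paired = FALSE)
  expect_equal(r$statistic, t_hand)
  expect_equal(r$p_value, 2 * pt(-abs(t_hand), df = 6))
  expect_equal(r$estimate, mean(a) - mean(b))
})

test_that("t_test flags zero-variance cases", {
  a <- c(1, 2, 3)
  same <- t_test(a, a, paired = TRUE)
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)
  shifted <- t_test(a + 1, a, paired = TRUE)
  expect_true(shifted$degenerate)
  expect_equal(shifted$p_value, 0)
  expect_equal(shifted$estimate, 1)
})

test_that("two-group anova equals the squared unpaired t", {
  set.seed(3)
  for (i in 1:10) {
    a <- rnorm(8)
    b <- rnorm(6, mean = 0.5)
    f <- anova_oneway(list(a, b))
    t2 <- t_test(a, b, paired = FALSE)$statistic^2
    expect_equal(f$statistic, t2, tolerance = 1e-10)
  }
})

test_that("anova matches the sum-of-squares decomposition", {
  groups <- list(c(1, 2, 3), c(2, 4, 5, 6), c(7, 8, 6))
  vals <- unlist(groups)
  gm <- mean(vals)
  ss_between <- sum(vapply(groups, function(g) {
    length(g) * (mean(g) - gm)^2
  }, numeric(1)))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  f_hand <- (ss_between / 2) / (ss_within / 7)
  r <- anova_oneway(groups)
  expect_equal(r$statistic, f_hand)
  expect_equal(r$p_value, pf(f_hand, 2, 7, lower.tail = FALSE))
  ident <- anova_oneway(list(c(1, 1), c(1, 1)))
  expect_true(ident$degenerate)
  expect_equal(ident$p_value, 1)
})

test_that("chi-squared goodness-of-fit matches hand arithmetic", {
  flat <- chi_square_gof(c(10, 10))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  r <- chi_square_gof(c(378, 189))
  expect_equal(r$statistic, 2 * 94.5^2 / 283.5)  # = 63.0
  expect_equal(r$statistic, 63)
  skewed <- chi_square_gof(c(30, 10), expected_proportions = c(0.75, 0.25))
  expect_equal(skewed$statistic, 0)
  expect_error(chi_square_gof(c(0, 0)), "positive total")
  expect_error(chi_square_gof(c(5, 5), c(1, 0)), "positive")
})

test_that("logrank matches risk-set enumeration on a small cohort", {
  ta <- c(6, 13, 21, 30)
  ea <- c(1, 1, 0, 1)
  tb <- c(10, 19, 25)
  eb <- c(1, 0, 1)
  oracle <- logrank_brute(ta, ea, tb, eb)
  r <- logrank(ta, ea, tb, eb)
  expect_equal(r$statistic, oracle$chisq)
  expect_equal(r$estimate, oracle$o_minus_e)
  expect_equal(r$p_value, pchisq(oracle$chisq, 1, lower.tail = FALSE))
})

test_that("logrank handles identical groups, no events and empty groups", {
  t1 <- c(5, 10, 15)
  e1 <- c(1, 0, 1)
  same <- logrank(t1, e1, t1, e1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  censored <- logrank(t1, c(0, 0, 0), t1, c(0, 0, 0))
  expect_true(censored$degenerate)
  expect_equal(censored$p_value, 1)
  expect_error(logrank(numeric(0), numeric(0), t1, e1), "non-empty")
})

test_that("cox_ph maximizes the Breslow partial likelihood", {
  time <- c(4, 7, 9, 12, 15, 18, 22, 26)
  event <- c(1, 1, 0, 1, 1, 0, 1, 1)
  x <- c(1.2, 0.5, 2.0, -0.3, 0.8, -1.0, -0.9, -1.5)
  fit <- cox_ph(time, event, x)
  beta_hat <- attr(fit, "beta")
  opt <- optimize(function(b) breslow_loglik(b, time, event, x),
                  interval = c(-5, 5), maximum = TRUE)
  expect_equal(beta_hat, opt$maximum, tolerance = 1e-3)
  expect_equal(fit$estimate, exp(beta_hat))
})

test_that("cox_ph direction sanity and degenerate handling", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- rep(1, 6)
  # covariate largest for the earliest deaths -> hazard increases with x
  fit <- cox_ph(time, event, -rank(time))
  expect_gt(fit$estimate, 1)
  flat <- cox_ph(time, event, rep(2, 6))
  expect_true(flat$degenerate)
  expect_equal(flat$estimate, 1)
  expect_equal(flat$p_value, 1)
})
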