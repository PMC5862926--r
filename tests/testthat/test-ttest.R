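test_that("the JZS Bayes factor matches a dense Riemann-sum oracle", {
  st <- ttest_stats(2.0, 20, 20)
  bf <- bf10(jzs_ttest_bf(st, cauchy_prior()))
  oracle <- riemann_jzs_bf(2.0, 20, 20, sqrt(2) / 2)
  expect_lt(abs(bf / oracle - 1), 1e-4)
  # one-sample variant against the same construction
  st1 <- ttest_stats(1.8, 25)
  d <- seq(-15, 15, length.out = 40001)
  f <- suppressWarnings(dt(1.8, 24, ncp = d * sqrt(25))) * dcauchy(d, 0, sqrt(2) / 2)
  oracle1 <- sum(f) * (d[2] - d[1]) / dt(1.8, 24, 0)
  expect_lt(abs(bf10(jzs_ttest_bf(st1)) / oracle1 - 1), 1e-4)
})

test_that("two-sided BFs are symmetric in t and one-sided BFs mirror", {
  for (t in c(0.4, 1.7, 3.2)) {
    b_pos <- jzs_ttest_bf(ttest_stats(t, 15, 18))$log_bf10
    b_neg <- jzs_ttest_bf(ttest_stats(-t, 15, 18))$log_bf10
    expect_equal(b_pos, b_neg, tolerance = 1e-8)
    plus <- jzs_ttest_bf(ttest_stats(t, 15, 18), cauchy_prior(side = "positive"))
    minus <- jzs_ttest_bf(ttest_stats(-t, 15, 18), cauchy_prior(side = "negative"))
    expect_equal(plus$log_bf10, minus$log_bf10, tolerance = 1e-8)
  }
})

test_that("two-sided BF is the equal mixture of the one-sided BFs", {
  set.seed(42)
  for (i in 1:50) {
    t <- rnorm(1, 0, 2.5)
    n1 <- sample(5:80, 1); n2 <- sample(5:80, 1)
    r <- runif(1, 0.3, 1.5)
    st <- ttest_stats(t, n1, n2)
    b2 <- exp(jzs_ttest_bf(st, cauchy_prior(r))$log_bf10)
    bp <- exp(jzs_ttest_bf(st, cauchy_prior(r, "positive"))$log_bf10)
    bn <- exp(jzs_ttest_bf(st, cauchy_prior(r, "negative"))$log_bf10)
    expect_lt(abs(b2 - 0.5 * (bp + bn)) / b2, 1e-8)
  }
})

test_that("the two-sided BF increases strictly with |t| and tends to 1 as r -> 0", {
  ts <- seq(0, 4, by = 0.25)
  bfs <- vapply(ts, function(t) jzs_ttest_bf(ttest_stats(t, 25, 25))$log_bf10,
                numeric(1))
  expect_true(all(diff(bfs) > 0))
  tiny <- jzs_ttest_bf(ttest_stats(2.4, 30, 30), cauchy_prior(scale = 1e-6))
  expect_lt(abs(tiny$log_bf10), 1e-3)
})

test_that("the table interface reproduces the hand-computed t statistic", {
  tab <- generate_data(sim_spec("two_group", n = 50, delta = 0, seed = 17))
  fit <- jzs_ttest(tab, "y", "group", posterior = FALSE)
  y1 <- tab$y[tab$group == "g1"]; y2 <- tab$y[tab$group == "g2"]
  sp <- sqrt(((length(y1) - 1) * var(y1) + (length(y2) - 1) * var(y2)) /
               (length(y1) + length(y2) - 2))
  t_hand <- (mean(y1) - mean(y2)) / (sp * sqrt(1 / length(y1) + 1 / length(y2)))
  expect_equal(fit$t, t_hand, tolerance = 1e-12)
  expect_equal(fit$bf$log_bf10,
               jzs_ttest_bf(ttest_stats(t_hand, 50, 50))$log_bf10,
               tolerance = 1e-10)
  # hypothesis direction maps onto the folded prior for group 1
  f_pos <- jzs_ttest(tab, "y", "group", hypothesis = "group1_greater",
                     posterior = FALSE)
  expect_equal(f_pos$bf$log_bf10,
               jzs_ttest_bf(ttest_stats(t_hand, 50, 50),
                            cauchy_prior(side = "positive"))$log_bf10,
               tolerance = 1e-10)
})

test_that("a zero t statistic makes the two one-sided tests coincide", {
  df <- data.frame(y = c(c(-1, 0, 1, 2) + 5, c(-1, 0, 1, 2) + 5),
                   g = rep(c("a", "b"), each = 4), stringsAsFactors = FALSE)
  tab <- bf_table(df, levels = c(y = "continuous", g = "nominal"))
  bp <- jzs_ttest(tab, "y", "g", hypothesis = "group1_greater", posterior = FALSE)
  bn <- jzs_ttest(tab, "y", "g", hypothesis = "group2_greater", posterior = FALSE)
  expect_equal(bp$bf$log_bf10, bn$bf$log_bf10, tolerance = 1e-8)
})

test_that("degenerate table inputs raise errors", {
  tab <- bf_table(data.frame(y = rnorm(9), g = rep(c("a", "b", "c"), 3),
                             stringsAsFactors = FALSE),
                  levels = c(y = "continuous"))
  expect_error(jzs_ttest(tab, "y", "g"), "exactly 2")
  const <- bf_table(data.frame(y = rep(1, 8), g = rep(c("a", "b"), 4),
                               stringsAsFactors = FALSE),
                    levels = c(y = "continuous", g = "nominal"))
  expect_error(jzs_ttest(const, "y", "g"), "pooled variance")
  expect_error(ttest_stats(Inf, 10, 10), "finite")
  expect_error(ttest_stats(1, 1, 10), ">= 2")
})

test_that("posterior summaries invert the CDF correctly", {
  # symmetric case: t = 0 gives a median at zero
  ps0 <- posterior_delta(ttest_stats(0, 20, 20))
  expect_lt(abs(ps0$median), 1e-6)
  # against an independent fixed-grid quantile oracle
  st <- ttest_stats(1.5, 30, 30)
  ps <- posterior_delta(st)
  d <- seq(-4, 4, length.out = 200001)
  w <- suppressWarnings(dt(1.5, 58, ncp = d * sqrt(15))) * dcauchy(d, 0, sqrt(2) / 2)
  cdf <- cumsum(w) / sum(w)
  oracle_q <- approx(cdf, d, xout = c(0.025, 0.5, 0.975), ties = "ordered")$y
  expect_equal(ps$median, oracle_q[2], tolerance = 1e-3)
  expect_equal(ps$ci95[1], oracle_q[1], tolerance = 1e-3)
  expect_equal(ps$ci95[2], oracle_q[3], tolerance = 1e-3)
  expect_true(ps$ci95[1] <= ps$median && ps$median <= ps$ci95[2])
})

test_that("Savage-Dickey and integral Bayes factors agree", {
  for (case in list(c(2, 20, 20), c(0.5, 40, 35), c(-1.2, 12, 18))) {
    st <- ttest_stats(case[1], case[2], case[3])
    direct <- jzs_ttest_bf(st)$log_bf10
    sd_bf <- savage_dickey_bf(posterior_delta(st), cauchy_prior())$log_bf10
    expect_lt(abs(exp(direct - sd_bf) - 1), 1e-3)
  }
})

test_that("BF10 and BF01 are exact reciprocals", {
  b <- jzs_ttest_bf(ttest_stats(2.2, 24, 31))
  expect_equal(bf10(b) * bf01(b), 1, tolerance = 1e-15)
  expect_gte(b$error_pct, 0)
})
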