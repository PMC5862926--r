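test_that("sum-to-zero contrast blocks have the advertised shape", {
  tab <- read_bf_csv(hair_color_path())
  d <- build_design(tab, "pain_tolerance", model_spec("hair_color"))
  X <- d$blocks[["hair_color"]]
  expect_equal(ncol(X), 3)   # k - 1 columns for 4 levels
  # over a balanced replication of the levels every column sums to zero
  levs <- unique(tab$hair_color)
  bal <- bf_table(data.frame(pain_tolerance = rnorm(8),
                             hair_color = rep(levs, 2),
                             stringsAsFactors = FALSE),
                  levels = c(pain_tolerance = "continuous"))
  Xb <- build_design(bal, "pain_tolerance", model_spec("hair_color"))$blocks[[1]]
  expect_equal(colSums(Xb), rep(0, 3), tolerance = 1e-12)
  # a 2-level factor contributes one +-sqrt(2)/2 column
  two <- bf_table(data.frame(y = rnorm(6), g = rep(c("a", "b"), 3),
                             stringsAsFactors = FALSE),
                  levels = c(y = "continuous"))
  X2 <- build_design(two, "y", model_spec("g"))$blocks[[1]]
  expect_equal(sort(unique(round(abs(X2), 10))), round(sqrt(2) / 2, 10))
})

test_that("mains plus interaction span the full cell-means space", {
  tab <- generate_data(sim_spec("factorial", n = 4, levels = c(3, 2), seed = 2))
  d <- build_design(tab, "y", model_spec(c("F1", "F2", "F1:F2")))
  X <- cbind(1, do.call(cbind, d$blocks))
  cells <- interaction(tab$F1, tab$F2)
  indicator <- sapply(levels(cells), function(l) as.numeric(cells == l))
  expect_equal(qr(X)$rank, qr(indicator)$rank)  # both span the 6 cell means
})

test_that("design construction rejects degenerate factors and empty cells", {
  one <- bf_table(data.frame(y = rnorm(5), g = rep("only", 5),
                             stringsAsFactors = FALSE),
                  levels = c(y = "continuous"))
  expect_error(build_design(one, "y", model_spec("g")), "single level")
  df <- generate_data(sim_spec("factorial", n = 3, levels = c(2, 2), seed = 1))
  df2 <- as.data.frame(df)[!(df$F1 == "f1_2" & df$F2 == "f2_2"), ]
  tab2 <- bf_table(df2, levels = c(y = "continuous"))
  expect_error(build_design(tab2, "y", model_spec(c("F1", "F2", "F1:F2"))),
               "f1_2:f2_2")
})

test_that("the one-way g-prior BF reproduces the classic pain-threshold value", {
  tab <- read_bf_csv(hair_color_path())
  d <- build_design(tab, "pain_tolerance", model_spec("hair_color"))
  ml <- marginal_likelihood(d$y, d$blocks)
  expect_lt(abs(exp(ml$log_ml) / 11.97 - 1), 0.03)
  expect_lt(ml$mc_error_pct, 0.1)   # deterministic quadrature
})

test_that("a balanced two-group ANOVA equals the JZS t-test at matched scale", {
  tab <- generate_data(sim_spec("two_group", n = 20, delta = 0.5, seed = 7))
  d <- build_design(tab, "y", model_spec("group"))
  ml <- marginal_likelihood(d$y, d$blocks, g_prior_settings(r_fixed = 0.5))
  fit <- jzs_ttest(tab, "y", "group", prior = cauchy_prior(scale = sqrt(2) * 0.5),
                   posterior = FALSE)
  expect_lt(abs(exp(ml$log_ml - fit$bf$log_bf10) - 1), 1e-3)
})

test_that("importance sampling is seeded, reproducible and matches quadrature", {
  tab <- generate_data(sim_spec("oneway", n = 10, levels = 3,
                                effects = c(0.4, 0, -0.4), seed = 4))
  d <- build_design(tab, "y", model_spec("group"))
  s <- g_prior_settings(mc_samples = 5000, seed = 99)
  is1 <- marginal_likelihood(d$y, d$blocks, s, method = "importance")
  is2 <- marginal_likelihood(d$y, d$blocks, s, method = "importance")
  expect_identical(is1$log_ml, is2$log_ml)   # bit-reproducible
  qd <- marginal_likelihood(d$y, d$blocks, s, method = "quadrature")
  # agreement within 3 Monte Carlo standard errors (error is in percent)
  expect_lt(abs(exp(is1$log_ml - qd$log_ml) - 1), 3 * is1$mc_error_pct / 100)
  # the RNG state of the session is left untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); marginal_likelihood(d$y, d$blocks, s, method = "importance")
  expect_identical(rnorm(1), before)
})

test_that("Bayes factors are invariant to affine rescaling of the response", {
  tab <- generate_data(sim_spec("factorial", n = 8, levels = c(2, 3),
                                effects = list(F1 = c(0.5, -0.5)), seed = 11))
  spec <- model_spec(c("F1", "F2"))
  d <- build_design(tab, "y", spec)
  s <- g_prior_settings(mc_samples = 4000, seed = 3)
  ml1 <- marginal_likelihood(d$y, d$blocks, s)
  ml2 <- marginal_likelihood(7.3 * d$y - 2.1, d$blocks, s)
  expect_lt(abs(ml1$log_ml - ml2$log_ml), 1e-6)
})

test_that("a pure-noise factor is usually evidence for the null", {
  wins <- 0L
  for (s in 1:100) {
    tab <- generate_data(sim_spec("two_group", n = 50, delta = 0, seed = 1000 + s))
    d <- build_design(tab, "y", model_spec("group"))
    ml <- marginal_likelihood(d$y, d$blocks)
    if (ml$log_ml < 0) wins <- wins + 1L
  }
  expect_gte(wins, 90)
})

test_that("model_bf is log-additive and the self-comparison is exactly 1", {
  tab <- generate_data(sim_spec("factorial", n = 10, levels = c(2, 2),
                                effects = list(F1 = c(0.6, -0.6)), seed = 21))
  full <- model_spec(c("F1", "F2", "F1:F2"))
  mains <- model_spec(c("F1", "F2"))
  s <- g_prior_settings(mc_samples = 4000, seed = 5)
  bf <- model_bf(tab, "y", full, mains, s)
  ml_full <- marginal_likelihood(build_design(tab, "y", full)$y,
                                 build_design(tab, "y", full)$blocks, s)
  ml_mains <- marginal_likelihood(build_design(tab, "y", mains)$y,
                                  build_design(tab, "y", mains)$blocks, s)
  expect_equal(bf$log_bf10, ml_full$log_ml - ml_mains$log_ml, tolerance = 1e-12)
  same <- model_bf(tab, "y", mains, mains, s)
  expect_identical(same$log_bf10, 0)
  expect_identical(same$error_pct, 0)
  expect_error(model_bf(tab, "y", mains, full, s), "not nested")
})

test_that("the singers two-way ANOVA reproduces the published interaction test", {
  tab <- singers_table()
  nuis <- c("gender", "pitch")
  bf <- model_bf(tab, "height",
                 model_spec(c("gender", "pitch", "gender:pitch"), nuisance = nuis),
                 model_spec(c("gender", "pitch"), nuisance = nuis),
                 g_prior_settings(seed = 7))
  expect_lt(abs(bf10(bf) / 0.108 - 1), 0.05)
  fit <- anova_bf(tab, "height", fixed = c("gender", "pitch"),
                  settings = g_prior_settings(seed = 5))
  expect_equal(fit$comparison$model,
               c("Null model", "gender", "pitch", "gender + pitch",
                 "gender + pitch + gender:pitch"))
  gp <- fit$comparison$bf10[fit$comparison$model == "gender + pitch"]
  expect_lt(abs(gp / 8.192e39 - 1), 0.10)
  expect_equal(sum(fit$comparison$p_m_data), 1, tolerance = 1e-10)
})

test_that("a repeated-measures design with a random subject factor runs end to end", {
  wide <- generate_data(sim_spec("within", n = 30, levels = c(2, 2),
                                 effects = list(F1 = c(0.8, -0.8)),
                                 subject_sd = 1, seed = 31))
  long <- wide_to_cells(wide,
                        factors = list(F1 = paste0("f1_", 1:2),
                                       F2 = paste0("f2_", 1:2)),
                        cell_map = setNames(names(wide), names(wide)))
  fit <- anova_bf(long, "y", fixed = c("F1", "F2"), random = "subject",
                  settings = g_prior_settings(mc_samples = 2000, seed = 13))
  expect_equal(nrow(fit$comparison), 5)   # subject enters every model silently
  expect_equal(sum(fit$comparison$p_m_data), 1, tolerance = 1e-10)
  # the injected main effect should be detected
  eff <- fit$effects
  expect_gt(eff$p_incl_data[eff$term == "F1"], 0.9)
  expect_equal(eff$p_incl[match(c("F1", "F2", "F1:F2"), eff$term)],
               c(0.6, 0.6, 0.2), tolerance = 1e-12)
  # interaction appears in a single model: inclusion prob equals that model's
  inter <- fit$comparison$p_m_data[fit$comparison$model == "F1 + F2 + F1:F2"]
  expect_equal(eff$p_incl_data[eff$term == "F1:F2"], inter, tolerance = 1e-12)
})
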