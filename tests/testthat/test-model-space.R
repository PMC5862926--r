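test_that("model enumeration counts match the brute-force closure oracle", {
  for (k in 1:4) {
    n_enum <- length(enumerate_models(LETTERS[1:k]))
    expect_equal(n_enum, brute_force_model_count(k))
  }
  expect_equal(length(enumerate_models("A")), 2)
  expect_equal(length(enumerate_models(c("A", "B"))), 5)
  expect_equal(length(enumerate_models(c("A", "B", "C"))), 19)
  expect_equal(length(enumerate_models(c("A", "B", "C", "D"))), 167)
})

test_that("enumerated models respect marginality, nuisance and ordering", {
  specs <- enumerate_models(c("A", "B"), nuisance = "A")
  labels <- vapply(specs, model_label, character(1))
  expect_equal(labels[1], "Null model")
  for (s in specs) {
    labs <- vapply(s$terms, function(t) paste(t, collapse = ":"), character(1))
    expect_true("A" %in% labs)             # nuisance in every model
    if ("A:B" %in% labs) expect_true(all(c("A", "B") %in% labs))
  }
  # deterministic order: by size then lexicographic
  sizes <- vapply(specs, function(s) length(s$terms), integer(1))
  expect_true(all(diff(sizes) >= 0))
  expect_error(enumerate_models(c("A", "A")), "twice")
  expect_error(model_spec("A:B"), "marginality")
})

test_that("the comparison table normalizes like the published one-way table", {
  ct <- comparison_table(c(`Null model` = 1, `Hair Color` = 11.97))
  expect_equal(ct$p_m, c(0.5, 0.5))
  expect_equal(ct$p_m_data, c(0.077, 0.923), tolerance = 1e-3)
  expect_equal(ct$bf_m[2], 11.97, tolerance = 1e-12)  # equal prior odds
  expect_equal(sum(ct$p_m_data), 1, tolerance = 1e-12)
  single <- comparison_table(c(only = 3.2))
  expect_equal(single$p_m_data, 1)
})

test_that("posterior model probabilities match a direct normalization oracle", {
  set.seed(12)
  bfs <- setNames(exp(rnorm(5, 0, 40)), paste0("m", 1:5))  # huge spread
  ct <- comparison_table(bfs)
  direct <- bfs / sum(bfs)
  expect_equal(ct$p_m_data, unname(direct), tolerance = 1e-12)
  # invariance under rescaling all BFs by a common constant
  ct2 <- comparison_table(bfs * 1e17)
  expect_equal(ct$p_m_data, ct2$p_m_data, tolerance = 1e-12)
  # custom prior probabilities must sum to one
  expect_error(comparison_table(bfs, prior_probs = setNames(rep(0.3, 5),
                                                            names(bfs))),
               "sum to 1")
})

test_that("rebasing reproduces the published two-way ANOVA arithmetic", {
  bfs <- c(`Gender + Pitch` = 8.192e39, `Gender + Pitch + Gender:Pitch` = 8.864e38)
  rb <- rebase_bayes_factors(bfs, "Gender + Pitch")
  expect_equal(round(unname(1 / rb[2]), 2), 9.24)
  expect_equal(round(unname(rb[2]), 3), 0.108)
  # identity rebase and exact double-rebase round trip
  expect_equal(unname(rb["Gender + Pitch"]), 1)
  set.seed(3)
  big <- setNames(exp(rnorm(6, 0, 30)), letters[1:6])
  twice <- rebase_bayes_factors(rebase_bayes_factors(big, "c"), "a")
  expect_equal(log(twice), log(big / big[["a"]]), tolerance = 1e-12)
  expect_error(rebase_bayes_factors(big, "zz"), "not present")
  # repeated measures example: main effects vs interaction model
  arth <- c(`Disgust + Fright` = 3.240, `Disgust + Fright + Disgust:Fright` = 1.245)
  ratio <- rebase_bayes_factors(arth, "Disgust + Fright + Disgust:Fright")
  expect_equal(round(unname(ratio[1]), 1), 2.6)
})

test_that("effects tables aggregate inclusion probabilities over models", {
  # posterior model masses consistent with the published 2x2 repeated
  # measures table; the split of the remaining 0.014 over the null and
  # Fright-only models does not affect the Disgust inclusion sums
  post <- c(`Null model` = 1e-15, Disgust = 4.497e-9, Fright = 0.013999995503,
            `Disgust + Fright` = 0.712, `Disgust + Fright + Disgust:Fright` = 0.274)
  bfs <- post / post[["Null model"]]
  models <- list(`Null model` = character(),
                 Disgust = "Disgust", Fright = "Fright",
                 `Disgust + Fright` = c("Disgust", "Fright"),
                 `Disgust + Fright + Disgust:Fright` =
                   c("Disgust", "Fright", "Disgust:Fright"))
  ct <- comparison_table(bfs, models = models)
  eff <- effects_table(ct, c("Disgust", "Fright", "Disgust:Fright"))
  expect_equal(eff$p_incl[eff$term == "Disgust"], 0.6, tolerance = 1e-12)
  expect_equal(eff$p_incl_data[eff$term == "Disgust"],
               4.497e-9 + 0.712 + 0.274, tolerance = 1e-9)
  # a term present in a single model inherits that model's probability
  expect_equal(eff$p_incl_data[eff$term == "Disgust:Fright"],
               ct$p_m_data[5], tolerance = 1e-12)
  expect_true(all(eff$p_incl >= 0 & eff$p_incl <= 1))
  expect_true(all(eff$p_incl_data >= 0 & eff$p_incl_data <= 1))
  expect_error(effects_table(ct, "NotATerm"), "absent")
})

test_that("random tables match a brute-force inclusion-sum oracle", {
  set.seed(8)
  specs <- enumerate_models(c("A", "B"))
  labels <- vapply(specs, model_label, character(1))
  models <- lapply(specs, function(s) {
    vapply(s$terms, function(t) paste(t, collapse = ":"), character(1))
  })
  names(models) <- labels
  bfs <- setNames(exp(rnorm(5, 0, 3)), labels)
  bfs["Null model"] <- 1
  ct <- comparison_table(bfs, models = models)
  eff <- effects_table(ct, c("A", "B", "A:B"))
  post <- bfs / sum(bfs)
  for (tm in c("A", "B", "A:B")) {
    has <- vapply(models, function(m) tm %in% m, logical(1))
    expect_equal(eff$p_incl_data[eff$term == tm], unname(sum(post[has])),
                 tolerance = 1e-12)
    p <- sum(ct$p_m[has])
    q <- eff$p_incl_data[eff$term == tm]
    expect_equal(eff$bf_inclusion[eff$term == tm],
                 (q / (1 - q)) / (p / (1 - p)), tolerance = 1e-9)
  }
})
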