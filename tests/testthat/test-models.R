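test_that("split arithmetic and stratification match the stated design", {
  set.seed(1)
  y124 <- rbinom(124, 1, 0.54)
  sp <- split_cohort(y124, 0.7, seed = 3)
  expect_length(sp$train, 87L)
  expect_length(sp$test, 37L)
  expect_setequal(c(sp$train, sp$test), 1:124)
  # stratification: class fraction preserved within one patient
  expect_lt(abs(sum(y124[sp$train]) - 0.7 * sum(y124)), 1.5)

  y10 <- rep(c(0, 1), 5)
  sp10 <- split_cohort(y10, 0.7, seed = 1)
  expect_length(sp10$train, 7L)
  expect_length(sp10$test, 3L)

  expect_identical(split_cohort(y124, 0.7, seed = 9),
                   split_cohort(y124, 0.7, seed = 9))
  expect_error(split_cohort(c(0, 0, 0, 1), 0.7), "at least 2")
})

test_that("screening removes zero-variance and non-significant columns", {
  set.seed(2)
  n <- 200
  y <- rep(c(0L, 1L), each = n / 2)
  x <- cbind(matrix(rnorm(n * 10), n, 10),
             const = rep(3, n),
             strong = rnorm(n) + 2 * y)
  colnames(x)[1:10] <- sprintf("noise_%02d", 1:10)
  sc <- screen_features(x, y)
  expect_true("const" %in% sc$removed$feature)
  expect_equal(sc$removed$reason[sc$removed$feature == "const"],
               "zero_variance")
  expect_true("strong" %in% sc$kept)
  sc2 <- screen_features(x, y, rank_test = FALSE)
  expect_setequal(sc2$kept, setdiff(colnames(x), "const"))
})

test_that("informative features survive screening across seeds", {
  hits <- 0L
  for (s in 1:20) {
    co <- simulate_feature_cohort(cohort_spec(n_patients = 200,
                                              feature_effect = 2.0,
                                              n_features = 100,
                                              n_informative = 5, seed = s))
    sc <- screen_features(co$features, co$labels)
    if (all(co$informative %in% sc$kept)) hits <- hits + 1L
  }
  expect_gte(hits / 20, 0.95)
})

test_that("lasso model is reproducible, leak-free and score-correct", {
  co <- simulate_feature_cohort(cohort_spec(n_patients = 150,
                                            feature_effect = 1.5,
                                            n_features = 60,
                                            n_informative = 5, seed = 77))
  m1 <- fit_lasso_cv(co$features, co$labels, seed = 5)
  m2 <- fit_lasso_cv(co$features, co$labels, seed = 5)
  expect_identical(m1$selected, m2$selected)
  expect_equal(m1$coefficients, m2$coefficients)

  # radscore arithmetic: intercept + sum beta_j x_j on standardized columns
  s <- compute_radscore(m1, co$features)
  xs <- scale(co$features[, m1$selected, drop = FALSE],
              center = m1$center[m1$selected],
              scale = m1$scale[m1$selected])
  expect_equal(s, drop(m1$intercept + xs %*% m1$coefficients))
  # monotone in predicted probability
  expect_identical(order(s), order(stats::plogis(s)))
  expect_error(compute_radscore(m1, co$features[, 1:3, drop = FALSE]),
               "lacks selected")

  # no test-set leakage: the fitted model ignores rows outside training
  task <- run_radscore_task(co$features, co$labels, seed = 11)
  xmut <- co$features
  xmut[task$split$test, ] <- xmut[task$split$test,
                                  sample(ncol(xmut)), drop = FALSE]
  task2 <- run_radscore_task(xmut, co$labels, seed = 11)
  expect_identical(task$model$selected, task2$model$selected)
  expect_equal(task$model$coefficients, task2$model$coefficients)
  expect_equal(task$scores$train, task2$scores$train)
})

test_that("ROC summary matches exhaustive pair counting and Youden logic", {
  sc <- c(0.1, 0.4, 0.35, 0.8); y <- c(0, 0, 1, 1)
  r <- evaluate_roc(sc, y)
  expect_equal(r$auc, 0.75)
  expect_equal(r$auc, auc_oracle(sc, y))

  set.seed(3)
  for (i in 1:25) {
    n <- sample(10:40, 1)
    s <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # with ties
    yy <- rbinom(n, 1, 0.5)
    if (length(unique(yy)) < 2) next
    expect_equal(evaluate_roc(s, yy)$auc, auc_oracle(s, yy))
  }

  # perfect separation
  rp <- evaluate_roc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(rp$auc, 1)
  expect_equal(rp$sensitivity, 1)
  expect_equal(rp$specificity, 1)
  expect_equal(rp$accuracy, 1)

  # AUC invariant under strictly monotone transforms
  set.seed(4)
  s <- rnorm(60); yy <- rbinom(60, 1, 0.5)
  expect_equal(evaluate_roc(s, yy)$auc,
               evaluate_roc(exp(2 * s), yy)$auc)

  expect_error(evaluate_roc(s, rep(1, 60)), "both classes")
})

test_that("permuted labels give chance-level AUC", {
  set.seed(5)
  s <- rnorm(2000)
  y <- sample(rep(0:1, 1000))
  expect_lt(abs(evaluate_roc(s, y)$auc - 0.5), 0.03)
})

test_that("univariate ROC auto-orients and flags degenerate input", {
  set.seed(6)
  y <- rbinom(80, 1, 0.5)
  v <- y + rnorm(80, sd = 0.1)
  r <- univariate_roc(v, y)
  expect_gt(r$auc, 0.95)
  expect_false(r$flipped)
  rneg <- univariate_roc(-v, y)
  expect_equal(rneg$auc, r$auc)
  expect_true(rneg$flipped)
  rconst <- univariate_roc(rep(2.2, 80), y)
  expect_equal(rconst$auc, 0.5)
  expect_true(rconst$degenerate)
})

test_that("decision-curve identities hold", {
  set.seed(7)
  y <- rep(c(0, 1), each = 50)
  # perfect classifier: net benefit = prevalence everywhere
  p_perfect <- ifelse(y == 1, 0.99, 0.01)
  dca <- decision_curve(p_perfect, y, thresholds = seq(0.05, 0.95, 0.05))
  expect_equal(dca$net_benefit, rep(0.5, nrow(dca)))
  expect_equal(dca$treat_none, rep(0, nrow(dca)))
  # treat-all closed form, including 0 at p_t = prevalence = 0.5
  expect_equal(dca$treat_all,
               0.5 - 0.5 * dca$threshold / (1 - dca$threshold))
  expect_equal(dca$treat_all[dca$threshold == 0.5], 0)
  expect_error(decision_curve(p_perfect, y, thresholds = c(0.5, 1)),
               "inside")
})
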