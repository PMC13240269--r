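test_that("outer folds are a stratified, disjoint partition of subjects", {
  ids <- sprintf("S%02d", 1:10)
  labs <- rep(c("P", "HC"), 5)
  folds <- outer_folds(ids, labs, 5, seed = 3)
  test_sets <- lapply(folds, `[[`, "test")
  expect_true(all(lengths(test_sets) == 2))
  expect_equal(sort(unlist(test_sets)), sort(ids))        # union = all, disjoint
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_equal(sort(c(f$train, f$test)), sort(ids))
  }
  expect_identical(outer_folds(ids, labs, 5, seed = 3),
                   outer_folds(ids, labs, 5, seed = 3))
  expect_error(outer_folds(ids, labs, 11, seed = 1), "exceeds")
})

test_that("a 19 + 24 cohort split five ways keeps >= 3 of each class per fold", {
  ids <- sprintf("S%02d", 1:43)
  labs <- c(rep("P", 19), rep("HC", 24))
  for (s in 1:5) {
    folds <- outer_folds(ids, labs, 5, seed = s)
    for (f in folds) {
      tab <- table(labs[match(f$test, ids)])
      expect_gte(min(tab), 3)
    }
  }
})

test_that("inner-CV fitting learns separable data and is seed-deterministic", {
  tbl <- toy_table(n_per_class = 8, p_noise = 3, sep = 4)
  cfg <- cv_config(inner_folds = 3, stability = list(eps = 1e-9, k = 2, n_repeats = 5),
                   seed = 5)
  fit <- fit_with_inner_cv(tbl, cfg, fold_tag = 1)
  expect_true("signal" %in% fit$features)
  p <- predict_fit(fit, tbl)
  expect_equal(mean((p >= 0.5) == (tbl$label == "P")), 1)   # training accuracy 1
  fit2 <- fit_with_inner_cv(tbl, cfg, fold_tag = 1)
  expect_identical(fit$params, fit2$params)
  expect_identical(fit$features, fit2$features)

  one_class <- tbl[tbl$label == "P", ]
  expect_error(fit_with_inner_cv(one_class, cfg), "class")
})

test_that("label-permuted data gives chance-level inner selection scores", {
  tbl <- toy_table(n_per_class = 8, p_noise = 3, sep = 4)
  cfg <- cv_config(inner_folds = 3, svm_grid = list(C = 1, gamma = 0.1),
                   stability = list(eps = 1e-9, k = 2, n_repeats = 3), seed = 1)
  best <- vapply(1:20, function(s) {
    set.seed(s)
    null_tbl <- tbl
    null_tbl$label <- sample(tbl$label)
    if (min(table(null_tbl$label)) < 2) return(NA_real_)
    f <- fit_with_inner_cv(null_tbl, cv_config(inner_folds = 3,
                                               svm_grid = list(C = 1, gamma = 0.1),
                                               stability = list(eps = 1e-9, k = 2,
                                                                n_repeats = 3),
                                               seed = s), fold_tag = 1)
    max(f$inner_scores)
  }, numeric(1))
  # max over a 1-point grid of held-out AUC: near chance on average
  expect_gt(mean(best, na.rm = TRUE), 0.3)
  expect_lt(mean(best, na.rm = TRUE), 0.7)
})

test_that("subject aggregation is the arithmetic mean with variance 1/n", {
  expect_equal(aggregate_subject(c(0.2, 0.4, 0.6)), 0.4)
  expect_equal(aggregate_subject(rep(0.9, 5)), 0.9)
  expect_error(aggregate_subject(numeric(0)), "no epoch")
  set.seed(18)
  n <- 25
  agg <- replicate(2000, aggregate_subject(runif(n)))
  expect_equal(var(agg), (1 / 12) / n, tolerance = 0.15)
})

test_that("metrics match hand-enumerated confusion tables and a pROC oracle", {
  # TP=3 FN=1 TN=4 FP=0
  preds <- data.frame(label = c(rep("P", 4), rep("HC", 4)),
                      prob = c(0.9, 0.8, 0.7, 0.2, 0.4, 0.3, 0.2, 0.1))
  m <- compute_metrics(preds)
  expect_equal(m$recall, 0.75)
  expect_equal(m$specificity, 1.0)
  expect_equal(m$accuracy, 0.875)

  perfect <- data.frame(label = c("P", "P", "HC", "HC"), prob = c(.9, .8, .2, .1))
  mp <- compute_metrics(perfect)
  expect_equal(unlist(mp), c(accuracy = 1, recall = 1, specificity = 1, auc = 1))

  ties <- data.frame(label = c("P", "P", "HC", "HC"), prob = rep(0.5, 4))
  expect_equal(compute_metrics(ties)$auc, 0.5)

  expect_error(compute_metrics(data.frame(label = "P", prob = 0.5)), "single class")

  set.seed(19)
  for (i in 1:10) {
    d <- data.frame(label = sample(c("P", "HC"), 20, replace = TRUE),
                    prob = round(runif(20), 1))
    if (length(unique(d$label)) < 2) next
    oracle <- as.numeric(pROC::auc(pROC::roc(d$label == "P", d$prob,
                                             levels = c(FALSE, TRUE),
                                             direction = "<", quiet = TRUE)))
    expect_equal(compute_metrics(d)$auc, oracle, tolerance = 1e-12)
  }
})

test_that("bootstrap CIs are degenerate when perfect and bracket the estimate", {
  perfect <- data.frame(label = rep(c("P", "HC"), each = 5),
                        prob = rep(c(0.9, 0.1), each = 5))
  ci <- bootstrap_ci(perfect, B = 500, seed = 1, statistic = "accuracy")
  expect_equal(ci, c(1, 1))

  set.seed(20)
  mixed <- data.frame(label = rep(c("P", "HC"), each = 10),
                      prob = c(runif(10, .3, 1), runif(10, 0, .7)))
  for (stat in c("accuracy", "auc")) {
    ci <- bootstrap_ci(mixed, B = 500, seed = 2, statistic = stat)
    point <- if (stat == "accuracy") compute_metrics(mixed)$accuracy
             else compute_metrics(mixed)$auc
    expect_lte(ci[1], point)
    expect_gte(ci[2], point)
  }
  expect_warning(bootstrap_ci(mixed, B = 50, seed = 1), "unstable")
})

test_that("bootstrap accuracy CI coverage is near nominal", {
  set.seed(22)
  hits <- replicate(200, {
    correct <- rbinom(40, 1, 0.8)
    preds <- data.frame(label = rep(c("P", "HC"), 20),
                        prob = ifelse(correct == 1,
                                      ifelse(rep(c(TRUE, FALSE), 20), 0.9, 0.1),
                                      ifelse(rep(c(TRUE, FALSE), 20), 0.1, 0.9)))
    ci <- bootstrap_ci(preds, B = 2000, seed = sample.int(1e6, 1))
    ci[1] <= 0.8 && 0.8 <= ci[2]
  })
  expect_gte(mean(hits), 0.88)
  expect_lte(mean(hits), 0.99)
})

test_that("Welch test and Cohen's d reproduce summary-statistic arithmetic", {
  # valid-epoch summaries: (492.8, 38.7, 19) vs (513.8, 25.5, 24)
  res <- group_summary_test(492.8, 38.7, 19, 513.8, 25.5, 24)
  expect_equal(round(abs(res$cohen_d), 2), 0.66)
  expect_equal(res$t, -2.0405, tolerance = 1e-3)
  # from rounded summaries the t value differs in the last digit from the
  # raw-data value (-2.05); assert we reproduce the summary-based figure
  expect_equal(round(res$t, 2), -2.04)
  expect_lt(res$p, 0.06)

  eq <- group_summary_test(5, 1, 10, 5, 1, 10)
  expect_equal(eq$t, 0)
  expect_equal(eq$cohen_d, 0)
  expect_error(group_summary_test(1, 0, 5, 2, 0, 5), "zero variance")

  # cross-check t and df against stats::t.test on raw data with these moments
  set.seed(23)
  x <- rnorm(19); x <- (x - mean(x)) / sd(x) * 38.7 + 492.8
  y <- rnorm(24); y <- (y - mean(y)) / sd(y) * 25.5 + 513.8
  tt <- t.test(x, y)
  res2 <- group_summary_test(mean(x), sd(x), 19, mean(y), sd(y), 24)
  expect_equal(res2$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res2$df, unname(tt$parameter), tolerance = 1e-10)
})

test_that("nested CV predicts every subject exactly once, with no leakage", {
  tbl <- toy_table(n_per_class = 10, p_noise = 4, sep = 3)
  cfg <- cv_config(outer_folds = 5, inner_folds = 3,
                   svm_grid = list(C = c(1, 10), gamma = c(0.03, 0.3)),
                   stability = list(eps = 1e-9, k = 3, n_repeats = 3), seed = 7)
  res <- nested_cv(tbl, cfg)
  expect_setequal(res$predictions$subject_id, tbl$subject_id)
  expect_false(anyDuplicated(res$predictions$subject_id) > 0)
  for (d in res$fold_details) {
    expect_length(intersect(d$test_subjects,
                            setdiff(tbl$subject_id, d$test_subjects)), 0)
  }
  m <- compute_metrics(res$predictions)
  expect_gt(m$auc, 0.8)     # strongly separable toy problem
  expect_s3_class(res$ranking, "data.frame")
  expect_true("signal" %in% res$ranking$feature)
})

test_that("nested CV can attach exact Shapley attributions per fold", {
  tbl <- toy_table(n_per_class = 8, p_noise = 2, sep = 4)
  cfg <- cv_config(outer_folds = 4, inner_folds = 2,
                   svm_grid = list(C = 1, gamma = c(0.03, 0.3)),
                   stability = list(eps = 1e-9, k = 3, n_repeats = 3), seed = 13)
  res <- nested_cv(tbl, cfg, compute_shapley = TRUE)
  expect_length(res$shapley, 4)
  for (i in seq_along(res$shapley)) {
    sh <- res$shapley[[i]]
    expect_equal(ncol(sh$values), length(res$fold_details[[i]]$features))
    expect_equal(nrow(sh$values), length(res$fold_details[[i]]$test_subjects))
    # local accuracy: base + contributions equals the fold's predictions
    recon <- sort(sh$base + rowSums(sh$values))
    fold_preds <- sort(res$predictions$prob[res$predictions$fold == i])
    expect_equal(recon, fold_preds, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("random-forest models run through the same nested machinery", {
  tbl <- toy_table(n_per_class = 8, p_noise = 2, sep = 4)
  cfg <- cv_config(model = "random_forest", inner_folds = 2,
                   rf_grid = list(ntree = 50, max_depth = c(NA, 3)),
                   stability = list(eps = 1e-9, k = 2, n_repeats = 3), seed = 9)
  res <- nested_cv(tbl, cfg)
  m <- compute_metrics(res$predictions)
  expect_gt(m$auc, 0.8)
  res2 <- nested_cv(tbl, cfg)
  expect_identical(res$predictions, res2$predictions)     # RF seeded via RNG
})
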