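## records whose sample mean and SD are exactly (mu, sigma), over 5 folds
records_with_moments <- function(feature, mu, sigma) {
  base <- as.numeric(scale(1:5))            # mean 0, sd 1
  data.frame(feature = feature, fold = 1:5, value = mu + sigma * base)
}

test_that("the stability score reproduces reference mean/SD arithmetic", {
  recs <- rbind(records_with_moments("theta_plv_fp", 0.084, 0.012),
                records_with_moments("geff_theta", 0.072, 0.011),
                records_with_moments("clust_alpha", 0.065, 0.010))
  rk <- stability_score(recs, eps = 1e-9)
  expect_equal(rk$feature[1], "theta_plv_fp")   # largest score first
  by_feat <- setNames(rk$score, rk$feature)
  expect_equal(round(by_feat[["theta_plv_fp"]], 2), 7.00)
  expect_equal(by_feat[["geff_theta"]], 6.5454, tolerance = 1e-3)
  expect_equal(round(by_feat[["clust_alpha"]], 2), 6.50)
  expect_equal(rk$mu, c(0.084, 0.072, 0.065), tolerance = 1e-12)
  expect_equal(rk$sigma, c(0.012, 0.011, 0.010), tolerance = 1e-12)
})

test_that("epsilon keeps zero-dispersion features finite", {
  recs <- data.frame(feature = "f", fold = 1:3, value = 0.05)
  rk <- stability_score(recs, eps = 1e-9)
  expect_equal(rk$sigma, 0)
  expect_equal(rk$score, 0.05 / 1e-9)
  expect_true(is.finite(rk$score))
})

test_that("stability moments agree with a two-pass oracle and are fold-order invariant", {
  set.seed(14)
  recs <- expand.grid(feature = paste0("f", 1:12), fold = 1:5)
  recs$value <- rnorm(nrow(recs))
  rk <- stability_score(recs)
  for (f in unique(recs$feature)) {
    v <- recs$value[recs$feature == f]
    mu <- sum(v) / length(v)
    sg <- sqrt(sum((v - mu)^2) / (length(v) - 1))
    expect_equal(rk$mu[rk$feature == f], mu, tolerance = 1e-12)
    expect_equal(rk$sigma[rk$feature == f], sg, tolerance = 1e-12)
    expect_equal(rk$score[rk$feature == f], mu / (sg + 1e-9), tolerance = 1e-12)
  }
  shuffled <- recs[sample(nrow(recs)), ]
  shuffled$fold <- ave(seq_along(shuffled$fold), shuffled$feature, FUN = seq_along)
  rk2 <- stability_score(shuffled)
  expect_equal(rk2[order(rk2$feature), c("mu", "sigma")],
               rk[order(rk$feature), c("mu", "sigma")], ignore_attr = TRUE)
})

test_that("scaling fold importances leaves the score asymptotically invariant", {
  set.seed(15)
  recs <- data.frame(feature = "f", fold = 1:5, value = abs(rnorm(5)) + 0.1)
  for (c0 in c(0.5, 3, 100)) {
    r1 <- stability_score(recs, eps = 1e-9)
    r2 <- stability_score(transform(recs, value = value * c0), eps = 1e-9)
    expect_equal(r2$mu, c0 * r1$mu)
    expect_equal(r2$sigma, c0 * r1$sigma)
    expect_equal(r2$score, r1$score, tolerance = 1e-6)
  }
})

test_that("stability scoring rejects malformed records", {
  expect_error(stability_score(data.frame(feature = "f", fold = 1, value = 1)),
               "single fold")
  dup <- data.frame(feature = "f", fold = c(1, 1), value = c(1, 2))
  expect_error(stability_score(dup), "duplicate")
  mixed <- data.frame(feature = "f", fold = 1:2, value = 1:2,
                      estimator = c("permutation", "shapley"))
  expect_error(stability_score(mixed), "mix")
})

test_that("top-k retention follows score then mu then name", {
  rk <- data.frame(feature = c("b", "a", "c"), mu = c(3, 2, 2),
                   sigma = c(1, 1, 1), score = c(5, 5, 4))
  rk <- rk[order(-rk$score, -rk$mu, rk$feature), ]
  expect_equal(select_stable(rk, 3), c("b", "a", "c"))
  expect_equal(select_stable(rk, 1), "b")
  expect_error(select_stable(rk, 4), "k must be")
  expect_error(select_stable(rk, 0), "k must be")
})

test_that("permutation importance separates signal from noise columns", {
  tbl <- toy_table(n_per_class = 10, p_noise = 2, sep = 4)
  X <- scale(as.matrix(tbl[, c("signal", "noise1", "noise2")]))
  m <- netstab:::fit_classifier(X, tbl$label, "svm_rbf",
                                list(C = 1, gamma = 0.3), "P", 1)
  imp <- permutation_importance(m, X, tbl$label, n_repeats = 30, seed = 2,
                                score = "accuracy")
  # a perfectly separating column loses ~ (baseline - chance) when permuted
  expect_lt(abs(unname(imp["signal"]) - 0.5), 0.12)
  expect_lt(max(abs(imp[c("noise1", "noise2")])), 0.08)
})

test_that("duplicating a predictive column dilutes its importance", {
  tbl <- toy_table(n_per_class = 10, p_noise = 1, sep = 4)
  X1 <- scale(as.matrix(tbl[, c("signal", "noise1")]))
  m1 <- netstab:::fit_classifier(X1, tbl$label, "svm_rbf",
                                 list(C = 1, gamma = 0.3), "P", 1)
  imp1 <- permutation_importance(m1, X1, tbl$label, n_repeats = 30, seed = 3,
                                 score = "brier")
  X2 <- cbind(X1, signal_copy = X1[, "signal"])
  m2 <- netstab:::fit_classifier(X2, tbl$label, "svm_rbf",
                                 list(C = 1, gamma = 0.3), "P", 1)
  imp2 <- permutation_importance(m2, X2, tbl$label, n_repeats = 30, seed = 3,
                                 score = "brier")
  expect_lt(imp2[["signal"]], imp1[["signal"]])
  expect_lt(imp2[["signal_copy"]], imp1[["signal"]])
})

test_that("exact Shapley values match brute-force coalition enumeration", {
  tbl <- toy_table(n_per_class = 8, p_noise = 1, sep = 2, seed = 9)
  X <- scale(as.matrix(tbl[, c("signal", "noise1")]))
  m <- netstab:::fit_classifier(X, tbl$label, "svm_rbf",
                                list(C = 1, gamma = 0.5), "P", 1)
  bg <- X[1:8, ]
  sh <- shapley_attribution(m, X[9:12, , drop = FALSE], background = bg)

  # independent oracle: enumerate the 4 coalitions of a 2-feature game
  v <- function(x, on) {
    rows <- bg
    if (length(on)) rows[, on] <- matrix(x[on], nrow(bg), length(on), byrow = TRUE)
    mean(predict_prob(m, rows))
  }
  for (i in 1:4) {
    x <- X[8 + i, ]
    phi1 <- 0.5 * (v(x, 1) - v(x, integer(0))) + 0.5 * (v(x, 1:2) - v(x, 2))
    phi2 <- 0.5 * (v(x, 2) - v(x, integer(0))) + 0.5 * (v(x, 1:2) - v(x, 1))
    expect_equal(unname(sh$values[i, ]), c(phi1, phi2), tolerance = 1e-10)
    # local accuracy: base + contributions = prediction
    expect_equal(sh$base + sum(sh$values[i, ]),
                 predict_prob(m, X[8 + i, , drop = FALSE]), tolerance = 1e-2)
  }
})

test_that("a constant model gets zero attributions", {
  const_model <- structure(list(value = 0.37), class = "const_model")
  registerS3method("predict_prob", "const_model",
                   function(model, X) rep(model$value, nrow(as.matrix(X))),
                   envir = asNamespace("netstab"))
  X <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, paste0("f", 1:4)))
  sh <- shapley_attribution(const_model, X)
  expect_equal(sh$base, 0.37)
  expect_equal(max(abs(sh$values)), 0)
})

test_that("sampled Shapley attributions stay additive within tolerance", {
  tbl <- toy_table(n_per_class = 8, p_noise = 13, sep = 2, seed = 10)
  feats <- setdiff(names(tbl), c("row_id", "subject_id", "label"))
  X <- scale(as.matrix(tbl[, feats]))
  m <- netstab:::fit_classifier(X, tbl$label, "svm_rbf",
                                list(C = 1, gamma = 0.1), "P", 1)
  sh <- shapley_attribution(m, X[1:2, , drop = FALSE], background = X,
                            exact_limit = 4, nsim = 400, seed = 5)
  pred <- predict_prob(m, X[1:2, , drop = FALSE])
  expect_lt(max(abs(sh$base + rowSums(sh$values) - pred)), 0.05)
})
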