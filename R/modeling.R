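#' Cross-validation configuration
#'
#' Nested subject-wise CV: a stratified outer loop over subjects and an inner
#' grouped loop for stability-driven feature selection and hyperparameter
#' tuning. All randomness fans out deterministically from `seed`.
#'
#' @param outer_folds outer fold count (default 5).
#' @param inner_folds inner fold count (default 3).
#' @param model `"svm_rbf"` or `"random_forest"`.
#' @param svm_grid list with `C` and `gamma` candidate vectors.
#' @param rf_grid list with `ntree` and `max_depth` (NA = unlimited) vectors.
#' @param stability list: `eps`, `k` (features retained), `n_repeats`
#'   (permutation-importance shuffles), `score` (importance scoring rule,
#'   see [permutation_importance()]).
#' @param aggregation epoch-to-subject rule (only `"mean_prob"`).
#' @param decision_threshold probability cutoff for the positive class.
#' @param positive positive class label (sensitivity/recall refer to it).
#' @param seed integer pipeline seed.
#' @export
cv_config <- function(outer_folds = 5, inner_folds = 3,
                      model = c("svm_rbf", "random_forest"),
                      svm_grid = list(C = c(0.1, 1, 10, 100),
                                      gamma = c(1e-3, 1e-2, 1e-1, 1)),
                      rf_grid = list(ntree = c(100, 300), max_depth = c(NA, 5, 10)),
                      stability = list(eps = 1e-9, k = 10, n_repeats = 10,
                                       score = "brier"),
                      aggregation = "mean_prob", decision_threshold = 0.5,
                      positive = "P", seed = 1) {
  model <- match.arg(model)
  stopifnot(is_count(outer_folds), outer_folds >= 2, is_count(inner_folds),
            inner_folds >= 2, aggregation == "mean_prob")
  if (!length(svm_grid$C) || !length(svm_grid$gamma)) stopf("svm_grid must be non-empty")
  if (!length(rf_grid$ntree) || !length(rf_grid$max_depth)) stopf("rf_grid must be non-empty")
  structure(list(outer_folds = outer_folds, inner_folds = inner_folds,
                 model = model, svm_grid = svm_grid, rf_grid = rf_grid,
                 stability = stability, aggregation = aggregation,
                 decision_threshold = decision_threshold, positive = positive,
                 seed = seed), class = "cv_config")
}

#' Stratified subject-wise folds
#'
#' Partitions subjects into `k` disjoint test sets, stratified by label:
#' subjects are shuffled within class (seeded) and dealt round-robin, so fold
#' class counts differ by at most one.
#'
#' @param subject_ids unique subject identifiers.
#' @param labels one label per subject.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return list of `k` lists with `train` and `test` subject-id vectors.
#' @export
outer_folds <- function(subject_ids, labels, k, seed = 1) {
  stopifnot(length(subject_ids) == length(labels), !anyDuplicated(subject_ids))
  if (k > length(subject_ids)) stopf("k (%d) exceeds number of subjects (%d)", k, length(subject_ids))
  if (k > min(table(labels))) {
    warning("k exceeds the smallest class count; some folds will lack that class")
  }
  fold_of <- with_seed(seed, {
    f <- integer(length(subject_ids))
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      f[idx[sample(length(idx))]] <- rep(seq_len(k), length.out = length(idx))
    }
    f
  })
  lapply(seq_len(k), function(i) list(train = subject_ids[fold_of != i],
                                      test = subject_ids[fold_of == i]))
}

positive_class <- function(model) model$positive

## Rank-statistic AUC with tie correction (mid-ranks).
auc_rank <- function(truth, prob) {
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) stopf("AUC undefined: a single class is present")
  r <- rank(prob)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## Fit one classifier on a (pre-standardized) feature matrix.
## SVM probabilities come from a deterministic Platt-style calibration:
## a logistic fit of the training labels on the SVM decision values.
fit_classifier <- function(X, y, model, params, positive, seed) {
  X <- as.matrix(X)
  ybin <- factor(ifelse(y == positive, positive, "neg"), levels = c(positive, "neg"))
  if (length(unique(y)) < 2) stopf("degenerate single-class training set")
  fit <- with_seed(seed, {
    if (model == "svm_rbf") {
      e1071::svm(X, ybin, kernel = "radial", cost = params$C, gamma = params$gamma,
                 scale = FALSE)
    } else {
      maxnodes <- if (is.na(params$max_depth)) NULL
                  else max(2L, min(2^params$max_depth, nrow(X)))
      randomForest::randomForest(X, ybin, ntree = params$ntree, maxnodes = maxnodes)
    }
  })
  platt <- NULL
  if (model == "svm_rbf") {
    dec <- as.numeric(attr(stats::predict(fit, X, decision.values = TRUE),
                           "decision.values"))
    platt <- suppressWarnings(stats::coef(stats::glm((y == positive) ~ dec,
                                                     family = stats::binomial())))
    if (any(!is.finite(platt))) platt <- c(0, if (mean(dec[y == positive]) >= 0) 1 else -1)
  }
  structure(list(kind = model, fit = fit, positive = positive, platt = platt,
                 features = colnames(X)), class = "netstab_model")
}

#' Predicted positive-class probability
#'
#' @param model a fitted `netstab_model`.
#' @param X feature matrix on the model's (standardized) feature scale.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predict_prob <- function(model, X) UseMethod("predict_prob")

#' @export
predict_prob.netstab_model <- function(model, X) {
  X <- as.matrix(X)[, model$features, drop = FALSE]
  if (model$kind == "svm_rbf") {
    dec <- as.numeric(attr(stats::predict(model$fit, X, decision.values = TRUE),
                           "decision.values"))
    as.numeric(1 / (1 + exp(-(model$platt[1] + model$platt[2] * dec))))
  } else {
    as.numeric(stats::predict(model$fit, X, type = "prob")[, model$positive])
  }
}

grid_combos <- function(cfg) {
  if (cfg$model == "svm_rbf") {
    g <- expand.grid(C = cfg$svm_grid$C, gamma = cfg$svm_grid$gamma,
                     KEEP.OUT.ATTRS = FALSE)
  } else {
    g <- expand.grid(ntree = cfg$rf_grid$ntree, max_depth = cfg$rf_grid$max_depth,
                     KEEP.OUT.ATTRS = FALSE)
  }
  lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
}

standardizer <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl,
       apply = function(M) sweep(sweep(as.matrix(M), 2, ctr), 2, scl, "/"))
}

#' Fit a model on one training fold with inner-CV selection and tuning
#'
#' Standardization (z-score) is fitted on the training rows only. The inner
#' grouped folds drive four steps: hyperparameters are tuned on the full
#' feature set (pooled subject-level AUC; ties resolved by grid order);
#' fold-wise permutation importances are estimated with the tuned settings
#' (fit on inner-train, importance on inner-validation); the stability score
#' `mu / (sigma + eps)` retains the top-`k` features; and the grid is re-tuned
#' on the retained features. The winning model is refit on the full training
#' fold.
#'
#' @param train_table feature table rows for the training subjects.
#' @param cfg a [cv_config()].
#' @param fold_tag tag mixed into derived seeds (use the outer fold index).
#' @return `netstab_fit`: model, scaler, selected features, chosen
#'   hyperparameters, inner importance records and stability ranking.
#' @export
fit_with_inner_cv <- function(train_table, cfg, fold_tag = "0") {
  feats <- feature_columns(train_table)
  subj <- unique(train_table$subject_id)
  lab_of <- tapply(train_table$label, train_table$subject_id, `[`, 1)[subj]
  if (min(table(lab_of)) < 2) stopf("need >= 2 subjects per class in training data")
  Xall <- as.matrix(train_table[, feats, drop = FALSE])
  sc <- standardizer(Xall)
  Xs <- sc$apply(Xall)

  inner <- outer_folds(subj, as.character(lab_of), cfg$inner_folds,
                       seed = derive_seed(cfg$seed, "inner", fold_tag))

  ## pooled subject-level AUC of one hyperparameter combo over the inner folds
  grid_score <- function(combo, cols, tag) {
    preds <- do.call(rbind, lapply(seq_along(inner), function(i) {
      tr <- train_table$subject_id %in% inner[[i]]$train
      m <- fit_classifier(Xs[tr, cols, drop = FALSE], train_table$label[tr],
                          cfg$model, combo, cfg$positive,
                          derive_seed(cfg$seed, tag, fold_tag, i))
      data.frame(subject_id = train_table$subject_id[!tr],
                 label = train_table$label[!tr],
                 prob = predict_prob(m, Xs[!tr, cols, drop = FALSE]))
    }))
    agg <- stats::aggregate(prob ~ subject_id + label, preds, mean)
    auc_rank(agg$label == cfg$positive, agg$prob)
  }
  combos <- grid_combos(cfg)
  tune <- function(cols, tag) {
    scores <- vapply(seq_along(combos), function(ci)
      grid_score(combos[[ci]], cols, paste0(tag, ci)), numeric(1))
    list(best = combos[[which.max(scores)]], scores = scores)
  }

  ## 1) tune on all features, 2) fold-wise permutation importances with the
  ## tuned model, 3) stability selection, 4) retune on the retained features
  pre <- tune(feats, "pregrid")
  records <- do.call(rbind, lapply(seq_along(inner), function(i) {
    tr <- train_table$subject_id %in% inner[[i]]$train
    m <- fit_classifier(Xs[tr, , drop = FALSE], train_table$label[tr],
                        cfg$model, pre$best, cfg$positive,
                        derive_seed(cfg$seed, "selfit", fold_tag, i))
    imp <- permutation_importance(m, Xs[!tr, , drop = FALSE],
                                  train_table$label[!tr],
                                  n_repeats = cfg$stability$n_repeats,
                                  seed = derive_seed(cfg$seed, "perm", fold_tag, i),
                                  score = if (is.null(cfg$stability$score)) "brier"
                                          else cfg$stability$score)
    data.frame(feature = names(imp), fold = i, estimator = "permutation",
               value = as.numeric(imp), stringsAsFactors = FALSE)
  }))
  ranking <- stability_score(records, eps = cfg$stability$eps)
  selected <- select_stable(ranking, min(cfg$stability$k, nrow(ranking)))
  post <- tune(selected, "grid")
  best <- post$best

  model <- fit_classifier(Xs[, selected, drop = FALSE], train_table$label,
                          cfg$model, best, cfg$positive,
                          derive_seed(cfg$seed, "refit", fold_tag))
  structure(list(model = model, center = sc$center, scale = sc$scale,
                 features = selected, all_features = feats, params = best,
                 inner_scores = post$scores, records = records, ranking = ranking),
            class = "netstab_fit")
}

#' Predict positive-class probabilities from a fitted fold
#' @param fit a `netstab_fit` from [fit_with_inner_cv()].
#' @param table feature table rows to score.
#' @export
predict_fit <- function(fit, table) {
  X <- as.matrix(table[, fit$all_features, drop = FALSE])
  Xs <- sweep(sweep(X, 2, fit$center), 2, fit$scale, "/")
  predict_prob(fit$model, Xs[, fit$features, drop = FALSE])
}

#' Average epoch-level probabilities to one subject-level probability
#' @param epoch_probs probabilities in \[0, 1\] for one subject's epochs.
#' @return their arithmetic mean.
#' @export
aggregate_subject <- function(epoch_probs) {
  if (!length(epoch_probs)) stopf("no epoch probabilities to aggregate")
  stopifnot(is.numeric(epoch_probs), all(is.finite(epoch_probs)),
            all(epoch_probs >= 0 & epoch_probs <= 1))
  mean(epoch_probs)
}

#' Nested subject-wise cross-validation
#'
#' Runs the full evaluation: stratified outer folds over subjects, per-fold
#' [fit_with_inner_cv()] (standardization, stability selection, grid search),
#' out-of-fold prediction with epoch-to-subject probability averaging, and a
#' cross-fold global stability ranking (one importance record per feature per
#' outer fold = the mean of that fold's inner-fold importances). Subject-level
#' train/test disjointness is asserted on every fold.
#'
#' @param tbl feature table ([build_feature_table()]); one or more rows per
#'   subject.
#' @param cfg a [cv_config()].
#' @param compute_shapley also compute Shapley attributions of each fold's
#'   model on its test rows (reporting only; adds runtime).
#' @return list: `predictions` (subject_id, label, prob, fold), `ranking`
#'   (global stability ranking), `fold_details`, `shapley` (or NULL).
#' @export
nested_cv <- function(tbl, cfg, compute_shapley = FALSE) {
  subj <- unique(tbl$subject_id)
  lab_of <- tapply(tbl$label, tbl$subject_id, `[`, 1)[subj]
  folds <- outer_folds(subj, as.character(lab_of), cfg$outer_folds,
                       seed = derive_seed(cfg$seed, "outer"))
  preds <- list(); details <- list(); outer_records <- list(); shap <- list()
  for (i in seq_along(folds)) {
    tr_subj <- folds[[i]]$train; te_subj <- folds[[i]]$test
    stopifnot(length(intersect(tr_subj, te_subj)) == 0)   # leakage guard
    tr <- tbl[tbl$subject_id %in% tr_subj, , drop = FALSE]
    te <- tbl[tbl$subject_id %in% te_subj, , drop = FALSE]
    fit <- fit_with_inner_cv(tr, cfg, fold_tag = i)
    p <- predict_fit(fit, te)
    agg <- tapply(p, te$subject_id, aggregate_subject)
    preds[[i]] <- data.frame(subject_id = names(agg),
                             label = as.character(lab_of[names(agg)]),
                             prob = as.numeric(agg), fold = i,
                             stringsAsFactors = FALSE)
    fold_imp <- stats::aggregate(value ~ feature, fit$records, mean)
    outer_records[[i]] <- data.frame(feature = fold_imp$feature, fold = i,
                                     estimator = "permutation",
                                     value = fold_imp$value,
                                     stringsAsFactors = FALSE)
    if (compute_shapley) {
      Xs <- sweep(sweep(as.matrix(te[, fit$all_features, drop = FALSE]), 2,
                        fit$center), 2, fit$scale, "/")[, fit$features, drop = FALSE]
      shap[[i]] <- shapley_attribution(fit$model, Xs,
                                       seed = derive_seed(cfg$seed, "shap", i))
    }
    details[[i]] <- list(fold = i, params = fit$params, features = fit$features,
                         test_subjects = te_subj)
  }
  predictions <- do.call(rbind, preds)
  if (anyDuplicated(predictions$subject_id)) stopf("a subject was predicted in more than one fold")
  if (!setequal(predictions$subject_id, subj)) stopf("out-of-fold predictions do not cover all subjects")
  list(predictions = predictions,
       ranking = stability_score(do.call(rbind, outer_records), eps = cfg$stability$eps),
       fold_details = details,
       shapley = if (compute_shapley) shap else NULL)
}

#' Classification metrics from subject-level predictions
#'
#' Accuracy, recall (sensitivity for the positive class), specificity, and
#' AUC via the rank statistic with mid-rank tie correction.
#'
#' @param preds data.frame with `label` and `prob` columns (one row per subject).
#' @param threshold probability cutoff for a positive call.
#' @param positive positive class label.
#' @return list with `accuracy`, `recall`, `specificity`, `auc`.
#' @export
compute_metrics <- function(preds, threshold = 0.5, positive = "P") {
  truth <- preds$label == positive
  if (all(truth) || !any(truth)) stopf("metrics undefined: a single class is present")
  call_pos <- preds$prob >= threshold
  tp <- sum(truth & call_pos); fn <- sum(truth & !call_pos)
  tn <- sum(!truth & !call_pos); fp <- sum(!truth & call_pos)
  list(accuracy = (tp + tn) / length(truth),
       recall = tp / (tp + fn),
       specificity = tn / (tn + fp),
       auc = auc_rank(truth, preds$prob))
}

#' Percentile bootstrap confidence interval over subjects
#'
#' Resamples subjects with replacement `B` times; resamples lacking a class
#' are redrawn. Bounds are the 2.5/97.5 percentiles.
#'
#' @param preds subject-level predictions (`label`, `prob`).
#' @param B bootstrap iterations (the reference analysis uses 10000).
#' @param seed RNG seed.
#' @param statistic `"accuracy"` or `"auc"`.
#' @param threshold,positive passed to the statistic.
#' @return numeric `c(lower, upper)`.
#' @export
bootstrap_ci <- function(preds, B = 10000, seed = 1,
                         statistic = c("accuracy", "auc"),
                         threshold = 0.5, positive = "P") {
  statistic <- match.arg(statistic)
  if (B < 100) warning("B < 100 gives unstable percentile bounds")
  truth <- preds$label == positive
  if (sum(truth) < 2 || sum(!truth) < 2) stopf("need >= 2 subjects per class")
  stat <- function(t, p) {
    if (statistic == "accuracy") mean((p >= threshold) == t) else auc_rank(t, p)
  }
  stat(truth, preds$prob)   # errors here mean the statistic is undefined
  n <- length(truth)
  vals <- with_seed(seed, vapply(seq_len(B), function(b) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (any(truth[idx]) && any(!truth[idx])) break
    }
    stat(truth[idx], preds$prob[idx])
  }, numeric(1)))
  as.numeric(stats::quantile(vals, c(0.025, 0.975)))
}

#' Full metrics report with fold variability and bootstrap CIs
#'
#' Pooled subject-level metrics, per-fold metrics with across-fold SDs, and
#' percentile bootstrap CIs (accuracy and AUC) on the pooled out-of-fold
#' subject predictions.
#'
#' @param predictions `nested_cv()$predictions`.
#' @param B bootstrap iterations.
#' @param seed RNG seed.
#' @param threshold,positive passed to [compute_metrics()].
#' @export
metrics_report <- function(predictions, B = 10000, seed = 1,
                           threshold = 0.5, positive = "P") {
  pooled <- compute_metrics(predictions, threshold, positive)
  per_fold <- lapply(split(predictions, predictions$fold), function(d) {
    m <- try(compute_metrics(d, threshold, positive), silent = TRUE)
    if (inherits(m, "try-error")) NULL else m
  })
  per_fold <- Filter(Negate(is.null), per_fold)
  fold_mat <- do.call(rbind, lapply(per_fold, function(m) unlist(m)))
  list(pooled = pooled,
       per_fold = per_fold,
       fold_sd = if (length(per_fold) > 1) apply(fold_mat, 2, stats::sd) else NULL,
       ci = list(accuracy = bootstrap_ci(predictions, B, derive_seed(seed, "ci_acc"),
                                         "accuracy", threshold, positive),
                 auc = bootstrap_ci(predictions, B, derive_seed(seed, "ci_auc"),
                                    "auc", threshold, positive)),
       bootstrap_B = B)
}

#' Welch test and Cohen's d from summary statistics
#'
#' Group comparison from printed means, SDs and sizes: Welch's t with the
#' Welch–Satterthwaite degrees of freedom, and Cohen's d using the pooled SD.
#' Note that recomputing t from rounded summary statistics can differ in the
#' last digit from a value computed on raw data.
#'
#' @param m1,s1,n1 mean, SD, size of group 1.
#' @param m2,s2,n2 mean, SD, size of group 2.
#' @return list: `t`, `df`, `p` (two-sided), `cohen_d` (signed, group1 - group2).
#' @export
group_summary_test <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  if (s1 == 0 && s2 == 0) stopf("zero variance in both groups")
  se2 <- s1^2 / n1 + s2^2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), cohen_d = (m1 - m2) / sp)
}
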