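#' Permutation importance
#'
#' Performance drop when one feature column is randomly shuffled: the mean
#' over `n_repeats` of (baseline score - score with the column permuted).
#' Label-independent columns score ~0; duplicated predictive columns share
#' (and therefore dilute) their importance.
#'
#' @param model fitted classifier supporting [predict_prob()].
#' @param X named feature matrix / data.frame.
#' @param y true labels (factor or character), positive class = first level of
#'   the model's training factor.
#' @param n_repeats shuffles per feature.
#' @param seed RNG seed (deterministic output).
#' @param score scoring rule whose drop defines importance: `"brier"`
#'   (negative Brier score; continuous, so small effects register even on few
#'   validation samples), `"auc"` (rank statistic), or `"accuracy"` at
#'   threshold 0.5.
#' @return named numeric vector of importances, one per column of `X`.
#' @export
permutation_importance <- function(model, X, y, n_repeats = 10, seed = 1,
                                   score = c("brier", "auc", "accuracy")) {
  score <- match.arg(score)
  X <- as.matrix(X)
  truth <- y == positive_class(model)
  score_fun <- function(p) {
    switch(score,
      brier = -mean((p - truth)^2),
      auc = auc_rank(truth, p),
      accuracy = mean((p >= 0.5) == truth))
  }
  baseline <- score_fun(predict_prob(model, X))
  with_seed(seed, {
    imp <- vapply(colnames(X), function(f) {
      drops <- vapply(seq_len(n_repeats), function(r) {
        Xp <- X
        Xp[, f] <- sample(Xp[, f])
        baseline - score_fun(predict_prob(model, Xp))
      }, numeric(1))
      mean(drops)
    }, numeric(1))
    imp
  })
}

shapley_weights <- function(p) {
  s <- 0:(p - 1)
  factorial(s) * factorial(p - s - 1) / factorial(p)
}

#' Shapley attribution of model predictions
#'
#' Additive per-sample decomposition of the predicted positive-class
#' probability over features, against a background dataset: the value of a
#' coalition S is the mean prediction with features in S taken from the sample
#' and the rest from the background rows. With `p <= exact_limit` features all
#' `2^p` coalitions are enumerated (exact Shapley values; local accuracy
#' `base + sum(values) == prediction` holds to machine precision). Larger
#' feature sets use permutation sampling with `nsim` draws.
#'
#' @param model fitted classifier supporting [predict_prob()].
#' @param X samples to explain (matrix/data.frame with named columns).
#' @param background reference rows (defaults to `X`); subsampled to
#'   `max_background` rows for tractability.
#' @param exact_limit largest feature count for exhaustive enumeration.
#' @param nsim sampled permutations per sample in approximate mode.
#' @param max_background background row cap.
#' @param seed RNG seed for subsampling / permutation draws.
#' @return list: `base` (mean background prediction), `values` (samples x
#'   features matrix), `global` (mean |value| per feature).
#' @export
shapley_attribution <- function(model, X, background = X, exact_limit = 12,
                                nsim = 200, max_background = 20, seed = 1) {
  X <- as.matrix(X); background <- as.matrix(background)
  p <- ncol(X)
  probe <- try(predict_prob(model, X[1, , drop = FALSE]), silent = TRUE)
  if (inherits(probe, "try-error") || !is.numeric(probe)) {
    stopf("model must provide probability predictions via predict_prob()")
  }
  if (nrow(background) > max_background) {
    background <- with_seed(derive_seed(seed, "bg"),
      background[sample(nrow(background), max_background), , drop = FALSE])
  }
  base <- mean(predict_prob(model, background))
  vals <- matrix(0, nrow(X), p, dimnames = list(rownames(X), colnames(X)))

  if (p <= exact_limit) {
    # coalition s (0-based) contains feature f iff bit f-1 of s is set
    codes <- 0:(2^p - 1)
    subsets <- vapply(seq_len(p), function(f) bitwAnd(codes, 2^(f - 1)) > 0,
                      logical(length(codes)))
    sizes <- rowSums(subsets)
    wgt <- shapley_weights(p)
    nb <- nrow(background)
    for (i in seq_len(nrow(X))) {
      big <- background[rep(seq_len(nb), times = length(codes)), , drop = FALSE]
      for (s in seq_along(codes)) {
        on <- which(subsets[s, ])
        if (length(on)) {
          rows <- ((s - 1) * nb + 1):(s * nb)
          big[rows, on] <- matrix(X[i, on], nb, length(on), byrow = TRUE)
        }
      }
      v <- colMeans(matrix(predict_prob(model, big), nb))
      for (f in seq_len(p)) {
        without <- which(!subsets[, f])               # 1-based rows lacking f
        with_f <- without + 2^(f - 1)
        vals[i, f] <- sum(wgt[sizes[without] + 1] * (v[with_f] - v[without]))
      }
    }
  } else {
    with_seed(derive_seed(seed, "perm"), {
      for (i in seq_len(nrow(X))) {
        contrib <- matrix(0, nsim, p)
        for (s in seq_len(nsim)) {
          ord <- sample(p)
          b <- background[sample(nrow(background), 1), ]
          walk <- matrix(b, p + 1, p, byrow = TRUE)
          for (j in seq_len(p)) {
            walk[(j + 1):(p + 1), ord[j]] <- X[i, ord[j]]
          }
          colnames(walk) <- colnames(X)
          pred <- predict_prob(model, walk)
          contrib[s, ord] <- diff(pred)
        }
        vals[i, ] <- colMeans(contrib)
      }
    })
  }
  list(base = base, values = vals, global = colMeans(abs(vals)))
}

#' Fold-wise stability score
#'
#' For each feature, the mean importance `mu` and sample standard deviation
#' `sigma` across folds are combined into `score = mu / (sigma + eps)`:
#' features must be both important (large `mu`) and consistently so across
#' folds (small `sigma`) to score highly. `eps` only guards against division
#' by zero and is numerically negligible at realistic `sigma`.
#'
#' @param records data.frame with columns `feature`, `fold`, `value` (one
#'   importance estimator's records; an `estimator` column, if present, must
#'   be constant).
#' @param eps small positive constant.
#' @return data.frame `feature`, `mu`, `sigma`, `score`, ordered by
#'   descending score (ties: larger `mu`, then feature name).
#' @export
stability_score <- function(records, eps = 1e-9) {
  stopifnot(is.data.frame(records), all(c("feature", "fold", "value") %in% names(records)))
  if (!is_number(eps) || eps <= 0) stopf("eps must be a positive number")
  if (!is.null(records$estimator) && length(unique(records$estimator)) > 1) {
    stopf("records mix importance estimators; score one estimator at a time")
  }
  if (anyDuplicated(records[c("feature", "fold")])) stopf("duplicate (feature, fold) records")
  counts <- table(records$feature)
  if (any(counts < 2)) {
    stopf("feature(s) with a single fold: sigma undefined (%s)",
          paste(names(counts)[counts < 2], collapse = ", "))
  }
  mu <- tapply(records$value, records$feature, mean)
  sigma <- tapply(records$value, records$feature, stats::sd)
  out <- data.frame(feature = names(mu), mu = as.numeric(mu),
                    sigma = as.numeric(sigma),
                    score = as.numeric(mu) / (as.numeric(sigma) + eps),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, -out$mu, out$feature), ]
  rownames(out) <- NULL
  out
}

#' Retain the most stable features
#'
#' Top-`k` features by stability score; ties broken by larger mean importance,
#' then lexicographic feature name (the ordering [stability_score()] returns).
#'
#' @param ranking output of [stability_score()].
#' @param k number of features to retain, `1 <= k <= nrow(ranking)`.
#' @return character vector of `k` feature names.
#' @export
select_stable <- function(ranking, k) {
  if (!is_count(k) || k > nrow(ranking)) {
    stopf("k must be an integer in [1, %d]", nrow(ranking))
  }
  ranking$feature[seq_len(k)]
}

#' Write a stability ranking as TSV
#' @param ranking output of [stability_score()].
#' @param path file path.
#' @export
write_stability_tsv <- function(ranking, path) {
  out <- data.frame(feature = ranking$feature,
                    mean_importance = signif(ranking$mu, 6),
                    sd = signif(ranking$sigma, 6),
                    stability_score = signif(ranking$score, 6))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
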