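## Shared miniature fixtures, built in code at test time.

tiny_synth <- function(seed = 7, n_sub = c(P = 3, HC = 3), n_ep = 8,
                       kappa = c(P = 1, HC = 6)) {
  synth_config(n_subjects_per_group = n_sub, n_epochs_per_subject = n_ep,
               kappa_group = kappa, seed = seed)
}

## a 10 Hz test tone recording
tone_recording <- function(freqs = 10, fs = 250, dur = 10, amp = 1) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  dat <- do.call(rbind, lapply(seq_along(freqs), function(i) amp * cos(2 * pi * freqs[i] * t)))
  recording("tone", "HC", fs, paste0("C", seq_along(freqs)), dat)
}

## small separable feature table: one informative column, several noise columns
toy_table <- function(n_per_class = 6, p_noise = 3, sep = 3, seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_class
  lab <- rep(c("P", "HC"), each = n_per_class)
  X <- matrix(rnorm(n * (p_noise + 1)), n)
  X[, 1] <- X[, 1] + ifelse(lab == "P", sep, 0)
  colnames(X) <- c("signal", paste0("noise", seq_len(p_noise)))
  data.frame(row_id = sprintf("S%02d", 1:n), subject_id = sprintf("S%02d", 1:n),
             label = lab, X, stringsAsFactors = FALSE)
}

## Floyd–Warshall shortest paths, the brute-force oracle for graph metrics
fw_distances <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[w > 0] <- 1 / w[w > 0]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

random_graph <- function(n, density = 0.6, seed = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  up <- upper.tri(w)
  vals <- runif(sum(up))
  vals[runif(sum(up)) > density] <- 0
  w[up] <- vals
  w <- w + t(w)
  w
}
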