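#' Analytic-signal instantaneous phase
#'
#' Hilbert-transform phase of each channel: the FFT of each row is multiplied
#' by the analytic-signal step function and inverse-transformed; the phase is
#' the argument of the result, wrapped to (-pi, pi]. Input should be
#' band-limited (e.g. a [band_decompose()] output) for the phase to be
#' physically meaningful.
#'
#' @param x channels-by-samples numeric matrix.
#' @return matrix of phases in radians, same shape as `x`.
#' @export
instantaneous_phase <- function(x) {
  x <- rbind(x)
  n <- ncol(x)
  if (any(apply(x, 1, function(r) all(r == 0)))) {
    warning("all-zero channel: instantaneous phase undefined, returned as 0")
  }
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  X <- t(stats::mvfft(t(x))) * rep(h, each = nrow(x))
  analytic <- t(stats::mvfft(t(X), inverse = TRUE)) / n
  ph <- Arg(analytic)
  dimnames(ph) <- dimnames(x)
  ph
}

#' Construct a ConnectivityMatrix
#'
#' @param subject_id subject label.
#' @param band band name.
#' @param measure `"plv"` or `"coh"`.
#' @param values symmetric channels-by-channels matrix in \[0, 1\], unit diagonal.
#' @export
connectivity_matrix <- function(subject_id, band, measure, values) {
  values <- as.matrix(values)
  if (!isSymmetric(unname(values), tol = 1e-8)) stopf("connectivity matrix must be symmetric")
  if (any(values < -1e-9 | values > 1 + 1e-9)) stopf("connectivity values must lie in [0, 1]")
  values <- (values + t(values)) / 2
  diag(values) <- 1
  values[values < 0] <- 0; values[values > 1] <- 1
  structure(list(subject_id = subject_id, band = band, measure = measure,
                 values = values), class = "connectivity_matrix")
}

#' Phase-locking value matrix
#'
#' `PLV_ij = | mean_t exp(i (phi_i(t) - phi_j(t))) |`: the resultant length of
#' the pairwise instantaneous phase difference. 1 means rigid phase locking,
#' values near `sqrt(pi) / (2 sqrt(T))` are the independence floor for T
#' samples.
#'
#' @param phases channels-by-samples matrix of phases in radians
#'   (see [instantaneous_phase()]).
#' @param min_samples smallest sample count considered estimable.
#' @return symmetric matrix with unit diagonal, entries in \[0, 1\].
#' @export
plv_matrix <- function(phases, min_samples = 8) {
  phases <- rbind(phases)
  ts <- ncol(phases)
  if (ts < min_samples) stopf("need >= %d samples for a PLV estimate, got %d", min_samples, ts)
  z <- exp(1i * phases)
  plv <- Mod(z %*% Conj(t(z))) / ts
  plv <- (plv + t(plv)) / 2
  diag(plv) <- 1
  plv[plv > 1] <- 1
  dimnames(plv) <- list(rownames(phases), rownames(phases))
  plv
}

## Welch auto-/cross-spectra: Hann-windowed segments with 50% overlap.
## Returns frequencies and the channels x channels x nfreq cross-spectral array.
welch_cross_spectra <- function(x, fs, seg_len, overlap = 0.5) {
  n <- ncol(x); n_ch <- nrow(x)
  step <- max(1L, as.integer(round(seg_len * (1 - overlap))))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  if (length(starts) < 2) stopf("epoch too short for >= 2 spectral segments")
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))   # Hann
  nf <- seg_len %/% 2 + 1L
  S <- array(0 + 0i, c(n_ch, n_ch, nf))
  for (s in starts) {
    seg <- x[, s:(s + seg_len - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    Fh <- t(stats::mvfft(t(seg * rep(win, each = n_ch))))[, seq_len(nf), drop = FALSE]
    for (f in seq_len(nf)) S[, , f] <- S[, , f] + Fh[, f] %*% Conj(t(Fh[, f]))
  }
  list(freq = (seq_len(nf) - 1L) * fs / seg_len, S = S / length(starts))
}

#' Magnitude-squared coherence matrix, band-averaged
#'
#' Welch estimate (`seg_len_s`-second Hann segments, 50% overlap) of
#' `|S_xy(f)|^2 / (S_xx(f) S_yy(f))`, averaged over the frequency bins inside
#' the band. Note the estimator's positive bias under independence, which
#' shrinks with the number of segments.
#'
#' @param x channels-by-samples signal matrix (one epoch).
#' @param band a [band_spec()].
#' @param fs sampling rate in Hz.
#' @param seg_len_s Welch segment length in seconds.
#' @return symmetric matrix with unit diagonal, entries in \[0, 1\].
#' @export
coherence_matrix <- function(x, band, fs, seg_len_s = 1) {
  x <- rbind(x)
  w <- welch_cross_spectra(x, fs, as.integer(round(seg_len_s * fs)))
  sel <- which(w$freq >= band$lo & w$freq <= band$hi)
  if (!length(sel)) stopf("band %s (%g-%g Hz) has no resolvable frequency bins", band$name, band$lo, band$hi)
  n_ch <- nrow(x)
  acc <- matrix(0, n_ch, n_ch)
  for (f in sel) {
    Sf <- w$S[, , f]
    p <- Re(diag(Sf))
    acc <- acc + Mod(Sf)^2 / outer(p, p)
  }
  coh <- acc / length(sel)
  coh <- (coh + t(coh)) / 2
  diag(coh) <- 1
  coh[coh > 1] <- 1
  dimnames(coh) <- list(rownames(x), rownames(x))
  coh
}

#' Average per-epoch connectivity matrices
#'
#' Element-wise (unweighted) mean across epochs; epochs are equal-duration so
#' no weighting question arises. Symmetry and range are inherited.
#'
#' @param per_epoch list of equal-shaped matrices.
#' @return single matrix, element-wise mean.
#' @export
average_connectivity <- function(per_epoch) {
  if (!length(per_epoch)) stopf("need at least one epoch matrix")
  dims <- unique(lapply(per_epoch, dim))
  if (length(dims) != 1) stopf("epoch matrices have inconsistent shapes")
  Reduce(`+`, per_epoch) / length(per_epoch)
}

#' Per-subject connectivity for one band and measure
#'
#' Computes the per-epoch connectivity matrix (PLV on Hilbert phases with
#' `edge_trim` of samples discarded at each epoch edge to suppress filter and
#' Hilbert transients, or Welch coherence on the raw band-filtered epoch) and
#' averages across epochs.
#'
#' @param ea an `epoch_array` from [band_decompose()], already band-limited.
#' @param band the matching [band_spec()].
#' @param measure `"plv"` or `"coh"`.
#' @param edge_trim fraction of samples discarded at each epoch edge for PLV.
#' @param per_epoch if `TRUE`, also return the list of epoch-level matrices.
#' @return a [connectivity_matrix()]; with `per_epoch = TRUE`, a list
#'   `(subject = connectivity_matrix, epochs = list of matrices)`.
#' @export
subject_connectivity <- function(ea, band, measure = c("plv", "coh"),
                                 edge_trim = 0.1, per_epoch = FALSE) {
  measure <- match.arg(measure)
  n_ep <- dim(ea$epochs)[1]
  spe <- dim(ea$epochs)[3]
  keep <- (floor(spe * edge_trim) + 1):(spe - floor(spe * edge_trim))
  mats <- vector("list", n_ep)
  for (e in seq_len(n_ep)) {
    seg <- ea$epochs[e, , , drop = TRUE]
    if (is.null(dim(seg))) seg <- rbind(seg)
    rownames(seg) <- ea$channel_labels
    mats[[e]] <- if (measure == "plv") {
      plv_matrix(instantaneous_phase(seg)[, keep, drop = FALSE])
    } else {
      coherence_matrix(seg, band, ea$fs)
    }
  }
  cm <- connectivity_matrix(ea$subject_id, band$name, measure, average_connectivity(mats))
  if (per_epoch) list(subject = cm, epochs = mats) else cm
}

#' Write a connectivity matrix as labelled TSV
#' @param cm a [connectivity_matrix()].
#' @param path output file.
#' @export
write_connectivity_tsv <- function(cm, path) {
  utils::write.table(cbind(channel = rownames(cm$values),
                           as.data.frame(signif(cm$values, 8))),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
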