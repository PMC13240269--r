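#' Expected phase-locking value of a von Mises phase difference
#'
#' For a phase difference distributed von Mises with concentration `kappa`,
#' the population PLV (mean resultant length) is the Bessel-function ratio
#' \eqn{I_1(\kappa)/I_0(\kappa)}. This is the analytic target the synthetic
#' generator plants, used throughout the tests as a closed-form oracle.
#'
#' @param kappa non-negative concentration parameter (vectorised).
#' @return PLV in \[0, 1\], monotone increasing in `kappa`.
#' @examples
#' expected_plv_von_mises(0)   # uniform phase: 0
#' expected_plv_von_mises(2)   # ~0.698
#' @export
expected_plv_von_mises <- function(kappa) {
  if (!is.numeric(kappa) || any(!is.finite(kappa)) || any(kappa < 0)) {
    stopf("kappa must be finite and >= 0")
  }
  out <- numeric(length(kappa))
  small <- kappa <= 100
  # besselI loses precision / overflows for large order arguments; beyond the
  # switch point the asymptotic expansion agrees to < 1e-6.
  out[small] <- besselI(kappa[small], 1, expon.scaled = TRUE) /
    besselI(kappa[small], 0, expon.scaled = TRUE)
  k <- kappa[!small]
  out[!small] <- 1 - 1 / (2 * k) - 1 / (8 * k^2)
  out
}

#' Draw von Mises-distributed angles
#'
#' Best–Fisher rejection sampler; `kappa = 0` reduces to the uniform
#' distribution on (-pi, pi].
#'
#' @param n number of draws.
#' @param kappa concentration (>= 0).
#' @param mu mean direction in radians.
#' @return numeric vector of angles in (-pi, pi].
#' @export
rvonmises <- function(n, kappa, mu = 0) {
  stopifnot(is_count(n) || n == 0, is_number(kappa), kappa >= 0)
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- max(n - got, 16L)
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    keep <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    acc <- f[keep]
    sgn <- sign(u3[keep] - 0.5)
    take <- min(length(acc), n - got)
    if (take > 0) {
      out[(got + 1):(got + take)] <- sgn[seq_len(take)] * acos(acc[seq_len(take)])
      got <- got + take
    }
  }
  ang <- (out + mu + pi) %% (2 * pi) - pi
  ang[ang <= -pi] <- pi
  ang
}

#' Default 16-channel montage
#'
#' A small 10-20-style stand-in layout with prefix-derived region tags.
#' @return named character vector mapping channel label to region.
#' @export
default_channel_roles <- function() {
  ch <- c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4",
          "O1", "O2", "F7", "F8", "T7", "T8", "Pz", "Fz")
  stats::setNames(vapply(ch, region_from_label, character(1)), ch)
}

#' Infer a scalp region from a 10-20 channel label
#'
#' Prefix rules: `Fp*`/`F*` frontal, `C*` central, `P*` parietal,
#' `O*` occipital, `T*` temporal; midline (`z`) channels follow their letter.
#' @param label channel label string.
#' @return one of `"frontal"`, `"central"`, `"parietal"`, `"occipital"`, `"temporal"`.
#' @export
region_from_label <- function(label) {
  first <- toupper(substr(label, 1, 1))
  switch(first,
    "F" = "frontal", "C" = "central", "P" = "parietal",
    "O" = "occipital", "T" = "temporal",
    stopf("cannot infer region for channel '%s'", label))
}

#' Configuration for the synthetic EEG generator
#'
#' Describes a two-group study in which designated channel pairs share a
#' band-limited carrier whose phase difference is von Mises-distributed with a
#' group-specific concentration `kappa`; all other channels carry independent
#' band-limited oscillations, and every channel receives additive broadband
#' Gaussian noise. Lower `kappa` means noisier phase coupling and therefore
#' lower phase-locking value (population PLV = I1(k)/I0(k)).
#'
#' @param n_subjects_per_group named integer vector, subjects per group
#'   (defaults `c(P = 19, HC = 24)`).
#' @param n_epochs_per_subject epochs of `epoch_len_s` seconds each.
#' @param channel_roles named character vector channel -> region.
#' @param fs sampling rate in Hz.
#' @param epoch_len_s epoch length in seconds.
#' @param coupled_pairs list of length-2 character vectors naming coupled
#'   channel pairs (the planted effect).
#' @param kappa_group named numeric vector, von Mises concentration per group.
#' @param carrier_band length-2 numeric, Hz band of the planted oscillation.
#' @param carrier_band_name band label used in planted feature names.
#' @param osc_amp amplitude of the oscillatory components.
#' @param noise_sd standard deviation of the broadband noise.
#' @param noise_exponent spectral exponent a of 1/f^a noise (0 = white).
#' @param phase_walk_sd per-sample sd of the carrier's phase random walk.
#' @param jitter_block_s duration (s) over which the von Mises phase jitter is
#'   held constant; blockwise-constant jitter keeps the marginal distribution
#'   von Mises while remaining visible to band-limited phase estimators.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return a `synth_config` list, validated.
#' @export
synth_config <- function(n_subjects_per_group = c(P = 19, HC = 24),
                         n_epochs_per_subject = 500,
                         channel_roles = default_channel_roles(),
                         fs = 128,
                         epoch_len_s = 2,
                         coupled_pairs = list(c("F3", "P3"), c("F4", "P4")),
                         kappa_group = c(P = 1, HC = 6),
                         carrier_band = c(4, 8),
                         carrier_band_name = "theta",
                         osc_amp = 1,
                         noise_sd = 1,
                         noise_exponent = 0,
                         phase_walk_sd = 0.05,
                         jitter_block_s = 0.5,
                         seed = 1) {
  # coerce YAML-style lists into the vectors the generator works with
  n_subjects_per_group <- unlist(n_subjects_per_group)
  kappa_group <- unlist(kappa_group)
  channel_roles <- unlist(channel_roles)
  carrier_band <- as.numeric(unlist(carrier_band))
  coupled_pairs <- lapply(coupled_pairs, function(p) as.character(unlist(p)))
  cfg <- list(n_subjects_per_group = n_subjects_per_group,
              n_epochs_per_subject = n_epochs_per_subject,
              channel_roles = channel_roles, fs = fs, epoch_len_s = epoch_len_s,
              coupled_pairs = coupled_pairs, kappa_group = kappa_group,
              carrier_band = carrier_band, carrier_band_name = carrier_band_name,
              osc_amp = osc_amp, noise_sd = noise_sd,
              noise_exponent = noise_exponent, phase_walk_sd = phase_walk_sd,
              jitter_block_s = jitter_block_s, seed = seed)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  groups <- names(cfg$n_subjects_per_group)
  if (is.null(groups) || length(groups) != 2 || anyDuplicated(groups)) {
    stopf("n_subjects_per_group must name exactly two groups")
  }
  if (!all(vapply(cfg$n_subjects_per_group, is_count, logical(1)))) {
    stopf("subject counts must be positive integers")
  }
  if (!is_count(cfg$n_epochs_per_subject)) stopf("n_epochs_per_subject must be a positive integer")
  ch <- names(cfg$channel_roles)
  if (length(ch) < 2 || anyDuplicated(ch)) stopf("need >= 2 uniquely named channels")
  if (!is_number(cfg$fs) || cfg$fs <= 0) stopf("fs must be positive")
  spe <- cfg$epoch_len_s * cfg$fs
  if (abs(spe - round(spe)) > 1e-9 || spe < 8) {
    stopf("epoch_len_s * fs must be an integer >= 8")
  }
  if (!setequal(names(cfg$kappa_group), groups)) {
    stopf("kappa_group must name the same groups as n_subjects_per_group")
  }
  if (any(!is.finite(cfg$kappa_group)) || any(cfg$kappa_group < 0)) {
    stopf("kappa must be finite and >= 0 for every group")
  }
  for (p in cfg$coupled_pairs) {
    if (length(p) != 2 || !all(p %in% ch)) stopf("coupled pair (%s) references unknown channels", paste(p, collapse = ","))
    if (p[1] == p[2]) stopf("self-pairs are not allowed in coupled_pairs")
  }
  if (cfg$carrier_band[1] <= 0 || cfg$carrier_band[2] <= cfg$carrier_band[1] ||
      cfg$carrier_band[2] >= cfg$fs / 2) {
    stopf("carrier_band must satisfy 0 < lo < hi < fs/2")
  }
  if (!is_number(cfg$noise_sd) || cfg$noise_sd < 0) stopf("noise_sd must be >= 0")
  invisible(cfg)
}

## Band-limited Gaussian oscillation, unit-free amplitude 'amp' (matched to the
## RMS of an amplitude-'amp' cosine).
bandlimited_noise <- function(n, band, fs, amp) {
  flt <- signal::butter(2, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(flt, stats::rnorm(n))
  x * (amp / sqrt(2)) / stats::sd(x)
}

## Broadband noise with optional 1/f^a spectral shaping.
broadband_noise <- function(n, sd, exponent) {
  x <- stats::rnorm(n, sd = sd)
  if (exponent <= 0) return(x)
  X <- stats::fft(x)
  f <- c(1, seq_len(n - 1))                      # avoid dividing DC by zero
  f <- pmin(f, n - f + 1)                        # mirror for negative freqs
  X <- X / f^(exponent / 2)
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y * sd / stats::sd(y)
}

#' Generate a two-group synthetic EEG dataset
#'
#' Each subject receives `n_epochs_per_subject * epoch_len_s` seconds of
#' continuous multichannel signal. Channels named in `coupled_pairs` share a
#' carrier-band oscillation: the second member's instantaneous phase lags the
#' first by an i.i.d. von Mises draw with the subject's group concentration, so
#' the raw pairwise phase difference has population PLV `expected_plv_von_mises(kappa)`.
#' Remaining channels carry independent band-limited Gaussian oscillations;
#' every channel gains additive broadband noise.
#'
#' @param cfg a [synth_config()].
#' @return list with `recordings` (list of [recording()] objects) and `truth`
#'   (character vector of planted feature names, empty when the groups share
#'   the same `kappa`).
#' @export
generate_dataset <- function(cfg) {
  validate_synth_config(cfg)
  groups <- names(cfg$n_subjects_per_group)
  ch <- names(cfg$channel_roles)
  n_ch <- length(ch)
  n <- as.integer(round(cfg$n_epochs_per_subject * cfg$epoch_len_s * cfg$fs))
  block <- max(1L, as.integer(round(cfg$jitter_block_s * cfg$fs)))
  np <- length(cfg$coupled_pairs)
  pair_freqs <- cfg$carrier_band[1] +
    (seq_len(max(np, 1)) - 0.5) * diff(cfg$carrier_band) / max(np, 1)
  coupled_members <- unique(unlist(cfg$coupled_pairs))

  recordings <- with_seed(cfg$seed, {
    out <- list()
    sid <- 0L
    for (g in groups) {
      kap <- cfg$kappa_group[[g]]
      for (s in seq_len(cfg$n_subjects_per_group[[g]])) {
        sid <- sid + 1L
        dat <- matrix(0, n_ch, n, dimnames = list(ch, NULL))
        for (j in seq_along(cfg$coupled_pairs)) {
          p <- cfg$coupled_pairs[[j]]
          # Distinct pairs get evenly spaced carrier frequencies inside the
          # band, so cross-pair phase differences sweep full cycles within an
          # epoch and only the within-pair relation is locked.
          phi <- 2 * pi * pair_freqs[j] * seq_len(n) / cfg$fs +
            cumsum(stats::rnorm(n, sd = cfg$phase_walk_sd)) +
            stats::runif(1, -pi, pi)
          # Jitter is constant over blocks of jitter_block_s seconds: the
          # marginal phase difference stays exactly von Mises (PLV target
          # I1(k)/I0(k)), but the jitter survives the smoothing implicit in
          # band-limited phase estimation, which would average out white
          # per-sample jitter and wash away the planted contrast.
          delta <- rep(rvonmises(ceiling(n / block), kap), each = block)[seq_len(n)]
          dat[p[1], ] <- dat[p[1], ] + cfg$osc_amp * cos(phi)
          dat[p[2], ] <- dat[p[2], ] + cfg$osc_amp * cos(phi + delta)
        }
        for (c0 in setdiff(ch, coupled_members)) {
          dat[c0, ] <- bandlimited_noise(n, cfg$carrier_band, cfg$fs, cfg$osc_amp)
        }
        for (c0 in ch) {
          dat[c0, ] <- dat[c0, ] + broadband_noise(n, cfg$noise_sd, cfg$noise_exponent)
        }
        out[[sprintf("S%03d", sid)]] <-
          recording(sprintf("S%03d", sid), g, cfg$fs, ch, dat)
      }
    }
    out
  })

  truth <- character(0)
  if (length(unique(cfg$kappa_group)) > 1) {
    pair_names <- unique(vapply(cfg$coupled_pairs, function(p) {
      r <- sort(c(cfg$channel_roles[[p[1]]], cfg$channel_roles[[p[2]]]))
      paste(r, collapse = "_")
    }, character(1)))
    truth <- as.vector(outer(c("plv", "coh"),
                             paste0(cfg$carrier_band_name, "_", pair_names),
                             paste, sep = "_"))
  }
  list(recordings = unname(recordings), truth = truth)
}

#' Write a dataset to a plain-text fixture directory
#'
#' One TSV per subject: `#`-prefixed header lines (subject, group, fs,
#' channel labels) followed by the channels-by-samples matrix, one channel per
#' row. Round-trips through [read_dataset()].
#'
#' @param dataset output of [generate_dataset()] (or any list with a
#'   `recordings` element).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in dataset$recordings) {
    path <- file.path(dir, paste0("sub-", rec$subject_id, ".tsv"))
    con <- file(path, "w")
    writeLines(c(
      paste0("# subject: ", rec$subject_id),
      paste0("# group: ", rec$group),
      paste0("# fs: ", format(rec$fs, digits = 15)),
      paste0("# channels: ", paste(rec$channel_labels, collapse = "\t"))
    ), con)
    utils::write.table(format(rec$data, digits = 8, trim = TRUE, scientific = FALSE),
                       con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    close(con)
  }
  invisible(dir)
}

#' Read a fixture directory written by [write_dataset()]
#' @param dir directory of `sub-*.tsv` files.
#' @return list with `recordings` (and `truth = NULL`; truth is not persisted).
#' @export
read_dataset <- function(dir) {
  files <- sort(list.files(dir, pattern = "^sub-.*\\.tsv$", full.names = TRUE))
  if (!length(files)) stopf("no sub-*.tsv files found in %s", dir)
  recs <- lapply(files, function(path) {
    hdr <- readLines(path, n = 4L)
    field <- function(i, key) sub(paste0("^# ", key, ": "), "", hdr[i])
    labels <- strsplit(field(4, "channels"), "\t", fixed = TRUE)[[1]]
    dat <- as.matrix(utils::read.table(path, sep = "\t", skip = 4L))
    dimnames(dat) <- list(labels, NULL)
    recording(field(1, "subject"), field(2, "group"),
              as.numeric(field(3, "fs")), labels, dat)
  })
  list(recordings = recs, truth = NULL)
}
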