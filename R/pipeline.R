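#' Pipeline configuration
#'
#' Assembles and validates every stage option of the end-to-end run:
#' input source, preprocessing, bands, connectivity measures, graph options,
#' stability selection, nested CV, and reporting. Unknown keys are rejected.
#'
#' @param input list: `mode` (`"simulate"` or `"fixture"`), `synth` (a
#'   [synth_config()], simulate mode), `dir` (fixture mode), and for fixture
#'   mode an optional `region_map` (defaults to prefix inference).
#' @param preprocess list: `bp_lo`, `bp_hi` (band-pass edges), `notch` (Hz or
#'   NULL), `epoch_len_s`.
#' @param bands character vector of canonical band names or list of [band_spec()]s.
#' @param measures subset of `c("plv", "coh")`.
#' @param graph list: `threshold_p` (NULL = fully weighted).
#' @param features_per `"subject"` (features from epoch-averaged connectivity,
#'   one row per subject) or `"epoch"` (one row per epoch; predictions are
#'   averaged per subject).
#' @param edge_trim per-edge sample fraction discarded before PLV.
#' @param cv list of [cv_config()] overrides (model, folds, grids, stability, ...).
#' @param permute_labels permute subject labels before CV (null-calibration runs).
#' @param bootstrap_B bootstrap iterations for the report CIs.
#' @param shapley compute per-fold Shapley attributions.
#' @param seed master seed; every stochastic stage derives from it.
#' @export
pipeline_config <- function(input = list(mode = "simulate", synth = synth_config()),
                            preprocess = list(bp_lo = 1, bp_hi = 40, notch = 50,
                                              epoch_len_s = 2),
                            bands = c("delta", "theta", "alpha", "beta"),
                            measures = c("plv", "coh"),
                            graph = list(threshold_p = NULL),
                            features_per = "subject",
                            edge_trim = 0.1,
                            cv = list(),
                            permute_labels = FALSE,
                            bootstrap_B = 10000,
                            shapley = TRUE,
                            seed = 1, ...) {
  extra <- names(list(...))
  if (length(extra)) stopf("unknown config key(s): %s", paste(extra, collapse = ", "))
  cfg <- list(input = input, preprocess = preprocess, bands = bands,
              measures = measures, graph = graph, features_per = features_per,
              edge_trim = edge_trim, cv = cv, permute_labels = permute_labels,
              bootstrap_B = bootstrap_B, shapley = shapley, seed = seed)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

resolve_bands <- function(bands) {
  if (is.character(bands)) default_bands(bands)
  else { b <- bands; names(b) <- vapply(b, `[[`, character(1), "name"); b }
}

validate_pipeline_config <- function(cfg) {
  known <- c("input", "preprocess", "bands", "measures", "graph", "features_per",
             "edge_trim", "cv", "permute_labels", "bootstrap_B", "shapley", "seed")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) stopf("unknown config key(s): %s", paste(extra, collapse = ", "))
  if (!cfg$input$mode %in% c("simulate", "fixture")) {
    stopf("input$mode must be 'simulate' or 'fixture'")
  }
  if (cfg$input$mode == "simulate") {
    if (is.null(cfg$input$synth)) stopf("simulate mode requires input$synth")
    validate_synth_config(cfg$input$synth)
  } else if (is.null(cfg$input$dir)) stopf("fixture mode requires input$dir")
  bands <- resolve_bands(cfg$bands)
  if (!length(bands)) stopf("bands must be non-empty")
  ord <- order(vapply(bands, `[[`, numeric(1), "lo"))
  bands <- bands[ord]
  if (length(bands) > 1) {
    for (i in seq_len(length(bands) - 1)) {
      if (bands[[i]]$hi > bands[[i + 1]]$lo + 1e-9) {
        stopf("bands '%s' and '%s' overlap", bands[[i]]$name, bands[[i + 1]]$name)
      }
    }
  }
  if (!all(cfg$measures %in% c("plv", "coh")) || !length(cfg$measures)) {
    stopf("measures must be a non-empty subset of plv, coh")
  }
  if (!cfg$features_per %in% c("subject", "epoch")) {
    stopf("features_per must be 'subject' or 'epoch'")
  }
  pp <- cfg$preprocess
  if (pp$bp_lo <= 0 || pp$bp_hi <= pp$bp_lo) stopf("band-pass edges must satisfy 0 < lo < hi")
  if (!is.null(cfg$graph$threshold_p) &&
      (cfg$graph$threshold_p <= 0 || cfg$graph$threshold_p > 1)) {
    stopf("graph$threshold_p must be in (0, 1]")
  }
  if (!is_count(cfg$bootstrap_B)) stopf("bootstrap_B must be a positive integer")
  invisible(cfg)
}

#' Standard preprocessing of one recording
#'
#' Zero-phase band-pass, optional notch, optional artifact hook, then common
#' average re-referencing — in that order, on the continuous signal.
#'
#' @param rec a [recording()].
#' @param bp_lo,bp_hi band-pass edges (Hz).
#' @param notch line-noise frequency in Hz, or NULL to skip (it is skipped
#'   automatically when at/above Nyquist).
#' @param hook optional artifact-removal function (see [artifact_hook()]).
#' @export
preprocess_recording <- function(rec, bp_lo = 1, bp_hi = 40, notch = 50, hook = NULL) {
  out <- bandpass_filter(rec, bp_lo, bp_hi)
  if (!is.null(notch) && notch < rec$fs / 2) out <- notch_filter(out, notch)
  out <- artifact_hook(out, hook)
  rereference_average(out)
}

#' Connectivity and feature extraction for a set of recordings
#'
#' Preprocesses each recording, band-decomposes it, computes per-epoch
#' connectivity for every requested band and measure, averages to
#' subject-level matrices, and builds the feature table (per subject, or per
#' epoch when `features_per = "epoch"`).
#'
#' @param recordings list of [recording()]s.
#' @param config a [pipeline_config()].
#' @param region_map named channel -> region vector; inferred by prefix when NULL.
#' @return list: `connectivity` (subject -> measure -> band
#'   [connectivity_matrix()]), `table` (feature table).
#' @export
extract_features <- function(recordings, config = pipeline_config(), region_map = NULL) {
  bands <- resolve_bands(config$bands)
  if (is.null(region_map)) {
    ch <- recordings[[1]]$channel_labels
    region_map <- stats::setNames(vapply(ch, region_from_label, character(1)), ch)
  }
  per_epoch <- config$features_per == "epoch"
  pp <- config$preprocess
  subj_conn <- list(); epoch_conn <- list(); epoch_meta <- list()
  for (rec in recordings) {
    pre <- preprocess_recording(rec, pp$bp_lo, pp$bp_hi, pp$notch)
    by_band <- band_decompose(pre, bands, pp$epoch_len_s)
    conn_m <- list()
    for (m in config$measures) {
      conn_m[[m]] <- lapply(stats::setNames(nm = names(by_band)), function(bn)
        subject_connectivity(by_band[[bn]], bands[[bn]], m,
                             edge_trim = config$edge_trim, per_epoch = per_epoch))
    }
    subj_conn[[rec$subject_id]] <- conn_m
    if (per_epoch) {
      n_ep <- dim(by_band[[1]]$epochs)[1]
      for (e in seq_len(n_ep)) {
        epoch_conn[[length(epoch_conn) + 1]] <-
          lapply(subj_conn[[rec$subject_id]], function(mm)
            lapply(mm, function(bb) bb$epochs[[e]]))
        epoch_meta[[length(epoch_meta) + 1]] <-
          data.frame(row_id = paste0(rec$subject_id, "_e", e),
                     subject_id = rec$subject_id, label = rec$group)
      }
      subj_conn[[rec$subject_id]] <-
        lapply(subj_conn[[rec$subject_id]], function(mm) lapply(mm, `[[`, "subject"))
    }
  }
  meta <- data.frame(
    subject_id = vapply(recordings, `[[`, character(1), "subject_id"),
    label = vapply(recordings, `[[`, character(1), "group"),
    stringsAsFactors = FALSE)
  tbl <- if (per_epoch) {
    build_feature_table(epoch_conn, region_map, do.call(rbind, epoch_meta))
  } else {
    build_feature_table(subj_conn, region_map, meta)
  }
  list(connectivity = subj_conn, table = tbl)
}

#' Run the full pipeline and write a run directory
#'
#' Simulates or loads recordings, extracts connectivity and network features,
#' runs nested subject-wise cross-validation with stability-driven selection,
#' and writes: the resolved config snapshot (`config.yaml`), per-subject
#' connectivity TSVs (`connectivity/`), the feature table
#' (`feature_table.tsv`), the cross-fold stability ranking
#' (`stability_ranking.tsv`), metrics (`metrics.json`, `report.txt`), and a
#' log (`run.log`). Outputs are staged in a temporary sibling directory and
#' renamed into place only on success, so a failed run leaves no partial run
#' directory. Identical config + seed reruns produce byte-identical tables.
#'
#' @param config a [pipeline_config()].
#' @param out output run directory (must not already contain a run).
#' @param seed optional override of `config$seed`.
#' @return invisibly, a list with `out`, `results` (nested_cv output),
#'   `report`, `table`, and `truth`.
#' @export
run_pipeline <- function(config, out, seed = NULL) {
  validate_pipeline_config(config)
  if (!is.null(seed)) {
    config$seed <- seed
    if (config$input$mode == "simulate") config$input$synth$seed <- derive_seed(seed, "synth")
  }
  if (dir.exists(out) && length(list.files(out))) stopf("output directory %s is not empty", out)
  staging <- paste0(out, ".staging")
  unlink(staging, recursive = TRUE)
  dir.create(staging, recursive = TRUE)
  dir.create(file.path(staging, "connectivity"))
  logfile <- file.path(staging, "run.log")
  logln <- function(...) cat(sprintf(...), "\n", sep = "", file = logfile, append = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(staging, recursive = TRUE), add = TRUE)

  logln("netstab run, seed=%d", config$seed)
  dataset <- if (config$input$mode == "simulate") {
    logln("simulating %s subjects x %d epochs",
          paste(config$input$synth$n_subjects_per_group, collapse = "+"),
          config$input$synth$n_epochs_per_subject)
    generate_dataset(config$input$synth)
  } else {
    logln("reading fixture directory %s", config$input$dir)
    read_dataset(config$input$dir)
  }

  ext <- extract_features(dataset$recordings, config,
                          region_map = config$input$region_map)
  logln("feature table: %d rows x %d features", nrow(ext$table),
        length(feature_columns(ext$table)))
  for (sid in names(ext$connectivity)) {
    for (m in names(ext$connectivity[[sid]])) {
      for (b in names(ext$connectivity[[sid]][[m]])) {
        write_connectivity_tsv(ext$connectivity[[sid]][[m]][[b]],
          file.path(staging, "connectivity", sprintf("%s_%s_%s.tsv", sid, m, b)))
      }
    }
  }
  tbl <- ext$table
  if (isTRUE(config$permute_labels)) {
    subj <- unique(tbl$subject_id)
    lab <- tapply(tbl$label, tbl$subject_id, `[`, 1)[subj]
    perm <- with_seed(derive_seed(config$seed, "labelperm"),
                      stats::setNames(sample(as.character(lab)), subj))
    tbl$label <- perm[tbl$subject_id]
    logln("labels permuted for null calibration")
  }
  write_feature_table(tbl, file.path(staging, "feature_table.tsv"))

  cv <- do.call(cv_config, c(config$cv, list(seed = config$seed)))
  res <- nested_cv(tbl, cv, compute_shapley = isTRUE(config$shapley))
  for (d in res$fold_details) {
    logln("fold %d: params {%s}; features: %s", d$fold,
          paste(names(d$params), unlist(d$params), sep = "=", collapse = ", "),
          paste(d$features, collapse = ", "))
  }
  write_stability_tsv(res$ranking, file.path(staging, "stability_ranking.tsv"))
  report <- metrics_report(res$predictions, B = config$bootstrap_B,
                           seed = derive_seed(config$seed, "boot"),
                           threshold = cv$decision_threshold, positive = cv$positive)
  jsonlite::write_json(report, file.path(staging, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(format_report(report, cv$model), file.path(staging, "report.txt"))
  snap <- config_snapshot(config)
  yaml::write_yaml(snap, file.path(staging, "config.yaml"))
  logln("pooled accuracy=%.3f auc=%.3f", report$pooled$accuracy, report$pooled$auc)

  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  unlink(out, recursive = TRUE)
  if (!file.rename(staging, out)) stopf("could not move staged run into %s", out)
  ok <- TRUE
  invisible(list(out = out, results = res, report = report, table = tbl,
                 truth = dataset$truth))
}

config_snapshot <- function(config) {
  snap <- unclass(config)
  if (!is.null(snap$input$synth)) snap$input$synth <- unclass(snap$input$synth)
  snap
}

#' Human-readable metrics table
#'
#' Aligned text mirroring the Model / Accuracy / Recall / Specificity / AUC
#' layout, with across-fold SDs and bootstrap CIs.
#' @param report output of [metrics_report()].
#' @param model model label for the row.
#' @export
format_report <- function(report, model = "svm_rbf") {
  p <- report$pooled; s <- report$fold_sd
  pct <- function(x) sprintf("%.1f", 100 * x)
  sd_of <- function(name) if (is.null(s)) "-" else sprintf("%.1f", 100 * s[[name]])
  c(sprintf("%-22s %-14s %-14s %-14s %-16s", "Model", "Accuracy (%)",
            "Recall (%)", "Specificity (%)", "AUC"),
    sprintf("%-22s %s ± %s %6s ± %s %7s ± %s %10.3f ± %.3f",
            model, pct(p$accuracy), sd_of("accuracy"), pct(p$recall), sd_of("recall"),
            pct(p$specificity), sd_of("specificity"), p$auc,
            if (is.null(s)) NA_real_ else s[["auc"]]),
    sprintf("95%% CI (bootstrap, B=%d): accuracy [%.3f, %.3f], AUC [%.3f, %.3f]",
            report$bootstrap_B, report$ci$accuracy[1], report$ci$accuracy[2],
            report$ci$auc[1], report$ci$auc[2]))
}

#' Load a pipeline config from YAML
#'
#' Reads a YAML file of overrides and merges it into [pipeline_config()]
#' defaults; unknown keys are rejected. The `input$synth` block, if present,
#' is passed to [synth_config()].
#'
#' @param path YAML file.
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$input$synth)) {
    raw$input$synth <- do.call(synth_config, raw$input$synth)
  }
  defaults <- formals(pipeline_config)
  extra <- setdiff(names(raw), names(defaults))
  if (length(extra)) stopf("unknown config key(s): %s", paste(extra, collapse = ", "))
  do.call(pipeline_config, raw)
}
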