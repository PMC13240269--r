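#' Convert a connectivity matrix to a weighted graph
#'
#' Off-diagonal connectivity values become edge weights; the diagonal is
#' zeroed. By default the graph is kept fully weighted (no threshold).
#' Optional proportional thresholding retains the strongest fraction `p` of
#' edges; ties at the cutoff are resolved deterministically by edge order
#' (ascending row index, then column index).
#'
#' @param cm a [connectivity_matrix()] or symmetric numeric matrix in \[0,1\].
#' @param threshold_p `NULL` (keep all edges) or the edge fraction to retain.
#' @return a `weighted_graph`: list with `nodes` and symmetric `weights`
#'   matrix (zero diagonal).
#' @export
to_graph <- function(cm, threshold_p = NULL) {
  w <- if (inherits(cm, "connectivity_matrix")) cm$values else as.matrix(cm)
  if (!isSymmetric(unname(w), tol = 1e-8)) stopf("connectivity input must be symmetric")
  w <- (w + t(w)) / 2
  diag(w) <- 0
  if (any(w < 0)) stopf("edge weights must be non-negative")
  if (!is.null(threshold_p)) {
    stopifnot(is_number(threshold_p), threshold_p > 0, threshold_p <= 1)
    idx <- which(upper.tri(w), arr.ind = TRUE)
    ord <- order(-w[idx], idx[, 1], idx[, 2])
    keep_n <- floor(nrow(idx) * threshold_p)
    drop <- idx[ord[-seq_len(keep_n)], , drop = FALSE]
    w[drop] <- 0
    w[drop[, c(2, 1), drop = FALSE]] <- 0
  }
  nodes <- rownames(w)
  if (is.null(nodes)) nodes <- paste0("n", seq_len(nrow(w)))
  dimnames(w) <- list(nodes, nodes)
  structure(list(nodes = nodes, weights = w), class = "weighted_graph")
}

as_weights <- function(g) if (inherits(g, "weighted_graph")) g$weights else to_graph(g)$weights

#' Node strength (weighted degree centrality)
#'
#' Sum of each node's edge weights.
#' @param g a [to_graph()] result or symmetric weight matrix.
#' @return named numeric vector, one value per node.
#' @export
strength_centrality <- function(g) {
  rowSums(as_weights(g))
}

#' Weighted clustering coefficient (Onnela)
#'
#' `C_i = (1 / (k_i (k_i - 1))) * sum_{j,h} (w'_ij w'_ih w'_jh)^(1/3)` with
#' weights normalised by the network maximum and `k_i` the number of nonzero
#' edges at node i. Nodes with fewer than two neighbours get 0. On binary
#' graphs this reduces to the fraction of closed triangles.
#'
#' @param g a [to_graph()] result or symmetric weight matrix.
#' @return named numeric vector in \[0, 1\].
#' @export
clustering_coefficient <- function(g) {
  w <- as_weights(g)
  mx <- max(w)
  if (mx == 0) return(stats::setNames(numeric(nrow(w)), rownames(w)))
  a <- (w / mx)^(1 / 3)
  num <- diag(a %*% a %*% a)
  k <- rowSums(w > 0)
  c_i <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  stats::setNames(c_i, rownames(w))
}

## Pairwise shortest-path distances with edge length 1/weight.
graph_distances <- function(w) {
  el <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  ig <- igraph::graph_from_edgelist(el, directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0, nrow(w) - igraph::vcount(ig)))
  igraph::distances(ig, weights = 1 / w[el], algorithm = "dijkstra")
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over all ordered node pairs, with edge
#' length `1/weight`; disconnected pairs contribute 0. For weights in
#' \[0, 1\] the result lies in \[0, 1\] (1 for a complete unit-weight graph).
#'
#' @param g a [to_graph()] result or symmetric weight matrix.
#' @export
global_efficiency <- function(g) {
  w <- as_weights(g)
  n <- nrow(w)
  if (n < 2) stopf("global efficiency needs >= 2 nodes")
  d <- graph_distances(w)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Characteristic path length
#'
#' Mean shortest-path length over all ordered node pairs (edge length
#' `1/weight`). A disconnected graph has no finite value: by default this is
#' an error; with `largest_component = TRUE` the mean within the largest
#' connected component is returned, flagged via the `"component"` attribute.
#'
#' @param g a [to_graph()] result or symmetric weight matrix.
#' @param largest_component fall back to the largest component when disconnected.
#' @export
characteristic_path_length <- function(g, largest_component = FALSE) {
  w <- as_weights(g)
  if (nrow(w) < 2) stopf("characteristic path length needs >= 2 nodes")
  d <- graph_distances(w)
  off <- d[row(d) != col(d)]
  if (all(is.finite(off))) return(mean(off))
  if (!largest_component) {
    stopf(paste("graph is disconnected: characteristic path length undefined;",
                "rerun with largest_component = TRUE to report the",
                "largest-component value (flagged in the result)"))
  }
  reach <- rowSums(is.finite(d))           # component sizes, incl. self
  comp <- which(reach == max(reach))
  comp <- comp[is.finite(d[comp[1], comp])]
  if (length(comp) < 2) stopf("largest component has < 2 nodes")
  dc <- d[comp, comp]
  structure(mean(dc[row(dc) != col(dc)]), component = length(comp))
}

region_pairs <- function(regions) {
  u <- sort(unique(regions))
  pairs <- list()
  for (i in seq_along(u)) for (j in i:length(u)) pairs[[length(pairs) + 1]] <- c(u[i], u[j])
  pairs
}

## Mean connectivity over all distinct channel pairs spanning two regions
## (within-region: unordered distinct pairs). NA when a region pair spans a
## single channel only.
region_pair_mean <- function(values, regions, r1, r2) {
  i <- which(regions == r1); j <- which(regions == r2)
  if (r1 == r2) {
    if (length(i) < 2) return(NA_real_)
    m <- values[i, i]
    mean(m[upper.tri(m)])
  } else {
    mean(values[i, j])
  }
}

#' Build the per-subject (or per-epoch) feature table
#'
#' For every measure and band, emits (a) mean connectivity for each unordered
#' region pair (including within-region pairs), (b) global efficiency and
#' characteristic path length, and (c) network-mean clustering coefficient and
#' network-mean strength. Column names follow
#' `<measure>_<band>_<descriptor>`, e.g. `plv_theta_frontal_parietal`,
#' `plv_theta_geff`, `coh_alpha_clust_mean`. Column order is deterministic
#' (measures, then bands, in input order; region pairs alphabetically;
#' then geff, cpl, clust_mean, strength_mean).
#'
#' @param connectivity nested list `subject -> measure -> band` of
#'   [connectivity_matrix()] objects (or plain matrices). For epoch-level rows,
#'   pass one "subject" entry per epoch with `row_id`/`subject_id` metadata in
#'   `meta`.
#' @param region_map named character vector channel -> region.
#' @param meta data.frame with one row per entry of `connectivity`, carrying
#'   at least `subject_id` and `label` columns.
#' @return data.frame: `row_id`, `subject_id`, `label`, then feature columns;
#'   no missing values.
#' @export
build_feature_table <- function(connectivity, region_map, meta) {
  stopifnot(length(connectivity) == nrow(meta))
  first <- connectivity[[1]]
  measures <- names(first)
  bands <- names(first[[1]])
  ch <- rownames(if (inherits(first[[1]][[1]], "connectivity_matrix"))
    first[[1]][[1]]$values else first[[1]][[1]])
  if (!all(ch %in% names(region_map))) stopf("region_map missing channels: %s",
    paste(setdiff(ch, names(region_map)), collapse = ", "))
  regions <- unname(region_map[ch])
  if (any(!table(factor(regions, levels = unique(regions))))) stopf("region with zero channels")
  rp <- region_pairs(regions)

  feat_one <- function(values, prefix) {
    g <- to_graph(values)
    rp_vals <- vapply(rp, function(p) region_pair_mean(values, regions, p[1], p[2]), numeric(1))
    names(rp_vals) <- paste0(prefix, "_", vapply(rp, paste, character(1), collapse = "_"))
    cpl <- characteristic_path_length(g, largest_component = TRUE)
    c(rp_vals,
      stats::setNames(c(global_efficiency(g), as.numeric(cpl),
                        mean(clustering_coefficient(g)), mean(strength_centrality(g))),
                      paste0(prefix, "_", c("geff", "cpl", "clust_mean", "strength_mean"))))
  }

  rows <- lapply(connectivity, function(subj) {
    unlist(lapply(measures, function(m) lapply(bands, function(b) {
      cm <- subj[[m]][[b]]
      values <- if (inherits(cm, "connectivity_matrix")) cm$values else cm
      feat_one(values, paste0(m, "_", b))
    })), use.names = TRUE)
  })
  feat <- do.call(rbind, rows)
  keep <- !apply(is.na(feat), 2, any)
  dropped <- colnames(feat)[!keep]
  if (length(dropped)) {
    message("dropping single-channel region-pair feature(s): ", paste(dropped, collapse = ", "))
    feat <- feat[, keep, drop = FALSE]
  }
  if (anyDuplicated(colnames(feat))) stopf("duplicate feature names")
  out <- data.frame(row_id = if (!is.null(meta$row_id)) meta$row_id else meta$subject_id,
                    subject_id = meta$subject_id, label = meta$label,
                    feat, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

feature_columns <- function(tbl) setdiff(colnames(tbl), c("row_id", "subject_id", "label"))

#' Write / read a feature table as TSV
#' @param tbl feature table from [build_feature_table()].
#' @param path file path.
#' @export
write_feature_table <- function(tbl, path) {
  num <- vapply(tbl, is.numeric, logical(1))
  tbl[num] <- lapply(tbl[num], function(x) signif(x, 10))
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
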