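# Cell-event tables are tibbles (sample_id, cell_id, one column per marker)
# carrying a `transformed` attribute so the arcsinh step cannot be applied
# twice, plus the cofactor used.

new_cell_events <- function(tbl, transformed, cofactor = NA_real_) {
  attr(tbl, "transformed") <- transformed
  attr(tbl, "cofactor") <- cofactor
  tbl
}

marker_cols <- function(events) {
  setdiff(names(events), c("sample_id", "cell_id"))
}

events_matrix <- function(events, markers = NULL) {
  markers <- markers %||% marker_cols(events)
  as.matrix(events[, markers, drop = FALSE])
}

#' Arcsinh-transform raw cytometry intensities
#'
#' Standard mass-cytometry preprocessing: each raw intensity `x` is mapped to
#' `asinh(x / cofactor)`. The default cofactor of 5 is the mass-cytometry
#' convention. The result is flagged so a second application errors.
#'
#' @param events A cell-event tibble (`sample_id`, `cell_id`, marker columns).
#' @param cofactor Positive scaling constant, default 5.
#' @return The transformed cell-event tibble.
#' @examples
#' ev <- tibble::tibble(sample_id = "s1", cell_id = "c1", CD3 = 5)
#' arcsinh_transform(ev)$CD3  # asinh(1)
#' @export
arcsinh_transform <- function(events, cofactor = 5) {
  if (cofactor <= 0) abort("`cofactor` must be positive")
  if (isTRUE(attr(events, "transformed")))
    abort("events are already arcsinh-transformed; refusing to transform twice")
  mk <- marker_cols(events)
  out <- events
  out[mk] <- lapply(out[mk], function(x) asinh(x / cofactor))
  new_cell_events(out, transformed = TRUE, cofactor = cofactor)
}

#' Density-dependent downsampling of cell events, per sample
#'
#' Estimates each cell's local density within its own sample as the inverse
#' median distance to its `k` nearest neighbours, then keeps each cell with
#' probability `min(1, target / density)`, where `target` is the
#' `target_fraction` quantile of that sample's densities. Dense regions are
#' thinned toward the target local density while rare cells are retained;
#' cells below the `outlier_quantile` density are dropped as outliers.
#' Sampling is seeded per sample from the sample identifier, so each sample's
#' kept set is independent of the others and of row order.
#'
#' @param events Transformed cell-event tibble.
#' @param target_fraction Quantile of local density used as the target;
#'   1 keeps everything.
#' @param outlier_quantile Density quantile below which cells are discarded.
#' @param k Neighbours for the density estimate.
#' @param seed Integer seed for the keep/drop draws.
#' @return The downsampled cell-event tibble.
#' @export
density_downsample <- function(events, target_fraction = 0.1,
                               outlier_quantile = 0.01, k = 15, seed = 1) {
  stopifnot(target_fraction > 0, target_fraction <= 1)
  mk <- marker_cols(events)
  keep <- unlist(lapply(split(seq_len(nrow(events)), events$sample_id),
                        function(idx) {
    if (length(idx) <= k) {
      warn("fewer cells than `k` in a sample; keeping all its cells")
      return(idx)
    }
    x <- as.matrix(events[idx, mk, drop = FALSE])
    d <- as.matrix(stats::dist(x))
    diag(d) <- Inf
    knn_med <- apply(d, 1, function(r) stats::median(sort(r)[seq_len(k)]))
    dens <- 1 / pmax(knn_med, 1e-12)
    target <- stats::quantile(dens, target_fraction, names = FALSE)
    floor_d <- stats::quantile(dens, outlier_quantile, names = FALSE)
    p_keep <- pmin(1, target / dens)
    p_keep[dens < floor_d] <- 0
    sid <- events$sample_id[idx[1]]
    sub_seed <- (seed + floor(string_hash_unit(sid) * 1e8)) %% .Machine$integer.max
    # draw the keep/drop uniforms in cell-id order so the kept set is
    # invariant to row order
    ord <- order(events$cell_id[idx])
    u <- numeric(length(idx))
    u[ord] <- with_seed(sub_seed, stats::runif(length(idx)))
    idx[u < p_keep]
  }), use.names = FALSE)
  out <- events[sort(keep), , drop = FALSE]
  new_cell_events(out, transformed = attr(events, "transformed"),
                  cofactor = attr(events, "cofactor"))
}

#' Cluster pooled cell events into scaffold nodes
#'
#' Partitions pooled (typically downsampled) cells into at most `k` clusters
#' by seeded k-means on the clustering marker subset (lineage markers by
#' default, per SPADE practice), then maps every cell of `full_events` to its
#' nearest cluster centroid. Node medians are computed over all markers and
#' per-sample cell fractions over all mapped cells, so the fractions of each
#' sample sum to 1. The realized number of non-empty nodes is reported; it can
#' be below `k`.
#'
#' @param events Transformed, pooled cell-event tibble used for clustering.
#' @param k Number of clusters, default 500.
#' @param full_events Cell-event tibble mapped onto the centroids; defaults to
#'   `events`.
#' @param markers Clustering markers; default = the panel's lineage markers
#'   intersected with the event columns.
#' @param seed Integer seed for k-means initialization.
#' @return A list of class `"scaffold_nodes"`: `nodes` (node_id, n_cells, one
#'   median column per marker), `fractions` (sample_id, node_id, fraction),
#'   `assignment` (sample_id, cell_id, node_id), `markers` (clustering subset),
#'   and `k_requested`.
#' @export
cluster_events <- function(events, k = 500, full_events = NULL,
                           markers = NULL, seed = 1) {
  if (k < 1) abort("`k` must be >= 1")
  full_events <- full_events %||% events
  default_markers <- intersect(
    time_panel()$marker[time_panel()$role == "lineage"], marker_cols(events))
  markers <- markers %||%
    (if (length(default_markers)) default_markers else marker_cols(events))
  x <- events_matrix(events, markers)
  if (k > nrow(x)) abort("`k` exceeds the number of pooled cells")
  centers <- if (k == 1) {
    matrix(colMeans(x), 1, ncol(x), dimnames = list(NULL, markers))
  } else {
    with_seed(seed,
      stats::kmeans(x, centers = k, iter.max = 100, nstart = 1)$centers)
  }
  xf <- events_matrix(full_events, markers)
  # nearest-centroid mapping of every original cell
  cross <- xf %*% t(centers)
  d2 <- outer(rowSums(xf^2), rowSums(centers^2), "+") - 2 * cross
  node_idx <- max.col(-d2, ties.method = "first")
  used <- sort(unique(node_idx))
  node_id <- sprintf("N%04d", match(node_idx, used))
  all_mk <- marker_cols(full_events)
  assignment <- tibble(sample_id = full_events$sample_id,
                       cell_id = full_events$cell_id, node_id = node_id)
  med <- as_tibble(do.call(rbind, lapply(split(seq_along(node_idx), node_id),
    function(idx) apply(as.matrix(full_events[idx, all_mk]), 2, stats::median))))
  nodes <- bind_cols(
    tibble(node_id = sort(unique(node_id)),
           n_cells = as.integer(table(node_id))),
    med
  )
  fractions <- assignment |>
    dplyr::count(.data$sample_id, .data$node_id) |>
    group_by(.data$sample_id) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup() |>
    tidyr::complete(sample_id = unique(assignment$sample_id),
                    node_id = nodes$node_id,
                    fill = list(n = 0L, fraction = 0)) |>
    select("sample_id", "node_id", "fraction")
  structure(list(nodes = nodes, fractions = fractions,
                 assignment = assignment, markers = markers,
                 k_requested = k),
            class = "scaffold_nodes")
}

#' @export
print.scaffold_nodes <- function(x, ...) {
  cat("<scaffold_nodes> ", nrow(x$nodes), " non-empty nodes (k requested: ",
      x$k_requested, "), ", length(unique(x$fractions$sample_id)),
      " samples\n", sep = "")
  invisible(x)
}

# Per-marker hi/lo cutpoint across nodes: midpoint of the node-median range.
marker_cutpoints <- function(node_medians) {
  apply(node_medians, 2, function(v) (min(v) + max(v)) / 2)
}

#' Assign a phenotype label to every scaffold node
#'
#' For each gating definition, the representative (landmark) node is the node
#' best matching the gate: every `+` marker above and every `-` marker below
#' the across-node midpoint cutpoint, maximizing the standardized gate margin.
#' All nodes are then grouped by average-linkage hierarchical clustering of
#' their lineage-marker medians, cut into as many groups as phenotypes; nodes
#' sharing a cluster with a representative inherit its phenotype (nearest
#' representative within the cluster if several), and clusters without a
#' representative take the phenotype of the overall nearest representative.
#'
#' Gate markers that do not vary across nodes carry no information and are
#' treated as satisfied. A gate no node fully satisfies errors naming the
#' phenotype when `strict = TRUE` (the default); with `strict = FALSE` the
#' best-scoring node is taken as representative with a warning.
#'
#' @param scaffold A `"scaffold_nodes"` object from [cluster_events()].
#' @param definitions Phenotype gates, default [time_phenotypes()].
#' @param strict Error (rather than warn) on unsatisfiable gates.
#' @return The `scaffold_nodes` object with `phenotype` and `landmark` columns
#'   added to `$nodes`.
#' @export
assign_phenotypes <- function(scaffold, definitions = time_phenotypes(),
                              strict = TRUE) {
  nodes <- scaffold$nodes
  mk <- intersect(unique(definitions$marker), names(nodes))
  missing_mk <- setdiff(unique(definitions$marker), names(nodes))
  if (length(missing_mk))
    abort(paste0("gate markers absent from nodes: ",
                 paste(missing_mk, collapse = ", ")))
  med <- as.matrix(nodes[, mk, drop = FALSE])
  cut <- marker_cutpoints(med)
  sds <- pmax(apply(med, 2, stats::sd), 1e-9)
  rng <- apply(med, 2, function(v) diff(range(v)))
  phenos <- unique(definitions$phenotype)
  rep_of <- character(length(phenos))
  names(rep_of) <- phenos
  for (ph in phenos) {
    gate <- definitions[definitions$phenotype == ph, ]
    margin <- sapply(seq_len(nrow(gate)), function(i) {
      m <- gate$marker[i]
      gate$sign[i] * (med[, m] - cut[m]) / sds[m]
    })
    margin <- matrix(margin, nrow = nrow(med))
    informative <- rng[gate$marker] > 1e-8
    ok <- rowSums(margin > 0 | rep(!informative, each = nrow(med))) ==
      ncol(margin)
    if (!any(ok)) {
      msg <- paste0("gate unsatisfiable on all nodes for phenotype: ", ph)
      if (strict) abort(msg)
      warn(paste0(msg, "; using the best-scoring node"))
      ok <- rep(TRUE, nrow(med))
    }
    score <- rowMeans(margin)
    score[!ok] <- -Inf
    rep_of[ph] <- nodes$node_id[which.max(score)]
  }

  lineage <- intersect(scaffold$markers, names(nodes))
  lm <- as.matrix(nodes[, lineage, drop = FALSE])
  rownames(lm) <- nodes$node_id
  cl <- if (nrow(lm) > length(phenos)) {
    stats::cutree(stats::hclust(stats::dist(lm), method = "average"),
                  k = length(phenos))
  } else {
    stats::setNames(seq_len(nrow(lm)), nodes$node_id)
  }
  rep_idx <- match(rep_of, nodes$node_id)
  dist_to_reps <- as.matrix(stats::dist(lm))[, rep_idx, drop = FALSE]
  colnames(dist_to_reps) <- phenos
  label <- character(nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    reps_here <- phenos[cl[rep_idx] == cl[i]]
    cand <- if (length(reps_here)) reps_here else phenos
    label[i] <- cand[which.min(dist_to_reps[i, cand])]
  }
  label[rep_idx] <- phenos
  out <- scaffold
  out$nodes$phenotype <- label
  out$nodes$landmark <- nodes$node_id %in% rep_of
  out
}

#' Build the landmark-anchored similarity graph over scaffold nodes
#'
#' Connects every pair of nodes with an edge weighted by the cosine similarity
#' of their lineage-marker median vectors. Landmark (representative) nodes are
#' flagged so their identity stays fixed across maps. Edges below the
#' `retention_quantile` of the weight distribution are marked unretained for
#' sparse export but kept in the table.
#'
#' @param scaffold A `"scaffold_nodes"` object, ideally phenotype-annotated.
#' @param retention_quantile Quantile of edge weights below which edges are
#'   flagged `retained = FALSE`; default 0.9.
#' @return A list of class `"scaffold_graph"`: `nodes`, `edges`
#'   (`from`, `to`, `weight`, `retained`).
#' @export
build_scaffold_graph <- function(scaffold, retention_quantile = 0.9) {
  nodes <- scaffold$nodes
  mk <- intersect(scaffold$markers, names(nodes))
  m <- as.matrix(nodes[, mk, drop = FALSE])
  n <- nrow(m)
  if (n < 2) abort("need at least two nodes to build a graph")
  pairs <- utils::combn(n, 2)
  weight <- vapply(seq_len(ncol(pairs)), function(j)
    cosine_similarity(m[pairs[1, j], ], m[pairs[2, j], ]), numeric(1))
  edges <- tibble(from = nodes$node_id[pairs[1, ]],
                  to = nodes$node_id[pairs[2, ]],
                  weight = weight)
  thr <- stats::quantile(edges$weight, retention_quantile, names = FALSE)
  edges$retained <- edges$weight >= thr
  structure(list(nodes = nodes, edges = edges), class = "scaffold_graph")
}

#' Discover the two immunologic subtypes from node composition
#'
#' Average-linkage hierarchical clustering of samples on one minus the Pearson
#' correlation of their node-fraction profiles, cut into two clusters. The
#' cluster with the higher mean total fraction of partially exhausted
#' (PD-1+CTLA-4+) CD8 T-cell nodes is labeled subtype `"I"` (the good-TiME
#' orientation); this requires node phenotype labels. Without them, cluster
#' labels are assigned by the alphabetically first sample with a warning, and
#' only the partition (not the I/II semantics) is meaningful.
#'
#' @param fractions Tidy tibble `sample_id`, `node_id`, `fraction`.
#' @param node_phenotypes Optional tibble `node_id`, `phenotype`.
#' @param exhausted_phenotype Phenotype name used for orientation.
#' @return A tibble `sample_id`, `subtype` (`"I"`/`"II"`).
#' @export
subtype_samples <- function(fractions, node_phenotypes = NULL,
                            exhausted_phenotype = "exhausted_CD8_T") {
  wide <- tidyr::pivot_wider(fractions, id_cols = "sample_id",
                             names_from = "node_id",
                             values_from = "fraction", values_fill = 0)
  x <- as.matrix(wide[, -1, drop = FALSE])
  rownames(x) <- wide$sample_id
  if (nrow(x) < 4) abort("need at least 4 samples to define subtypes")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) abort("degenerate correlation: constant fraction profile")
  d <- stats::as.dist(1 - stats::cor(t(x)))
  grp <- stats::cutree(stats::hclust(d, method = "average"), k = 2)
  if (!is.null(node_phenotypes)) {
    exh_nodes <- node_phenotypes$node_id[
      node_phenotypes$phenotype == exhausted_phenotype]
    exh_frac <- rowSums(x[, intersect(colnames(x), exh_nodes), drop = FALSE])
    means <- tapply(exh_frac, grp, mean)
    good_cluster <- as.integer(names(means)[which.max(means)])
  } else {
    warn("no node phenotypes given; subtype I/II orientation is arbitrary")
    good_cluster <- grp[order(rownames(x))][1]
  }
  tibble(sample_id = rownames(x),
         subtype = ifelse(grp == good_cluster, "I", "II")) |>
    arrange(.data$sample_id)
}

#' Compare node fractions between two maps, paired by node
#'
#' For each phenotype, runs a two-tailed paired t test across the fractions of
#' corresponding nodes in the two group-pooled maps. Phenotypes with fewer
#' than two node pairs are returned with `NA` statistics and flagged.
#'
#' @param fractions_a,fractions_b Tibbles `node_id`, `fraction` (one pooled
#'   map per group), sharing the node-identifier set.
#' @param node_phenotypes Tibble `node_id`, `phenotype`.
#' @return A tibble `phenotype`, `n_nodes`, `mean_diff`, `statistic`,
#'   `p_value`, `insufficient_pairs`.
#' @export
compare_nodes <- function(fractions_a, fractions_b, node_phenotypes) {
  if (!setequal(fractions_a$node_id, fractions_b$node_id))
    abort("the two maps must share the same node identifiers")
  paired <- inner_join(fractions_a, fractions_b, by = "node_id",
                       suffix = c("_a", "_b")) |>
    inner_join(node_phenotypes, by = "node_id")
  paired_t <- function(a, b) {
    d <- a - b
    if (length(d) < 2) return(c(NA_real_, NA_real_))
    if (stats::sd(d) == 0) {
      # identical profiles: no evidence of difference
      if (all(d == 0)) return(c(0, 1))
      return(c(NA_real_, NA_real_))
    }
    tt <- stats::t.test(a, b, paired = TRUE)
    c(unname(tt$statistic), tt$p.value)
  }
  paired |>
    group_by(.data$phenotype) |>
    summarise(
      n_nodes = n(),
      mean_diff = mean(.data$fraction_a - .data$fraction_b),
      statistic = paired_t(.data$fraction_a, .data$fraction_b)[1],
      p_value = paired_t(.data$fraction_a, .data$fraction_b)[2],
      .groups = "drop"
    ) |>
    mutate(insufficient_pairs = .data$n_nodes < 2)
}

#' Z-ratio differential activation statistic
#'
#' Each feature is z-scored across all samples in the comparison; the Z ratio
#' of feature i is the difference between the group means of its z-scores,
#' divided by the standard deviation of all such differences in the
#' comparison. `|Z ratio| >= 1.96` is flagged significant (two-sided P < 0.05
#' under a standard-normal reference).
#'
#' @param data Tibble with `sample_id` plus one numeric column per feature.
#' @param samples_a,samples_b Sample identifiers of the two groups.
#' @param cutoff Significance cutoff on `|z_ratio|`, default 1.96.
#' @return A tibble `feature`, `delta_z`, `z_ratio`, `significant`.
#' @examples
#' d <- tibble::tibble(sample_id = paste0("s", 1:6),
#'                     m1 = c(5, 6, 7, 1, 2, 3), m2 = c(1, 2, 3, 5, 6, 7))
#' z_ratio(d, paste0("s", 1:3), paste0("s", 4:6))
#' @export
z_ratio <- function(data, samples_a, samples_b, cutoff = 1.96) {
  feats <- setdiff(names(data), "sample_id")
  if (length(feats) < 2) abort("need at least 2 features for a Z ratio")
  if (!all(c(samples_a, samples_b) %in% data$sample_id))
    abort("group samples missing from `data`")
  x <- as.matrix(data[, feats, drop = FALSE])
  rownames(x) <- data$sample_id
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warn("dropping constant features from the Z-ratio comparison")
    x <- x[, sds > 0, drop = FALSE]
    feats <- colnames(x)
    if (length(feats) < 2) abort("degenerate comparison: too few varying features")
  }
  z <- scale(x)
  d <- colMeans(z[samples_a, , drop = FALSE]) -
    colMeans(z[samples_b, , drop = FALSE])
  s <- stats::sd(d)
  if (s == 0) abort("degenerate comparison: zero SD of z-score differences")
  zr <- d / s
  tibble(feature = feats, delta_z = unname(d), z_ratio = unname(zr),
         significant = abs(zr) >= cutoff)
}
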