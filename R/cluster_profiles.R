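# Differential-expression clustering: hierarchical agglomeration with
# 1 - Pearson correlation as the distance and Ward's criterion, per-cluster
# mean Z-score profiles offset to a reference cell, and hypergeometric
# gene-set enrichment per cluster.

#' Ward clustering on 1 - Pearson distances
#'
#' Agglomerative clustering of the rows of a matrix (or its columns with
#' `axis = "samples"`) using `d = 1 - r` (Pearson) and Ward's
#' minimum-variance criterion in its squared-distance (Ward.D2) form, cut
#' into `k` clusters. A constant row has no defined correlation and is
#' rejected with an error naming it. The merge order, heights and leaf
#' order come from [stats::hclust()] and are a deterministic function of the
#' input order.
#'
#' @param X numeric matrix (features x samples), or a [time_course()].
#' @param k number of clusters (`<=` rows on the clustered axis).
#' @param axis cluster `"features"` (rows) or `"samples"` (columns).
#' @return object of class `ward_clustering`: `assignments` (named vector),
#'   `hclust` (the dendrogram), `order` (leaf order), `k`, `axis`.
#' @export
ward_cluster <- function(X, k, axis = c("features", "samples")) {
  axis <- match.arg(axis)
  if (inherits(X, "time_course")) X <- X$values
  M <- if (axis == "features") X else t(X)
  if (k > nrow(M)) stop("k = ", k, " exceeds the ", nrow(M), " rows to cluster")
  sds <- apply(M, 1, stats::sd)
  if (any(sds == 0))
    stop("constant row(s) have no defined correlation distance: ",
         paste(utils::head(rownames(M)[sds == 0], 5), collapse = ", "))
  d <- stats::as.dist(1 - stats::cor(t(M)))
  hc <- stats::hclust(d, method = "ward.D2")
  assignments <- stats::cutree(hc, k = k)
  structure(list(assignments = assignments, hclust = hc, order = hc$order,
                 k = k, axis = axis, linkage = "ward.D2",
                 distance = "1 - Pearson"),
            class = "ward_clustering")
}

#' @export
print.ward_clustering <- function(x, ...) {
  cat("Ward clustering (", x$distance, ", ", x$linkage, "): ",
      length(x$assignments), " ", x$axis, " in ", x$k, " clusters\n", sep = "")
  print(table(x$assignments))
  invisible(x)
}

#' Per-cluster mean Z-score profiles with confidence intervals
#'
#' Each feature is Z-scored across all samples, replicate means are taken
#' per (group, ZT) cell, cluster profiles are the mean over the cluster's
#' features, and every cluster's profile is offset so that the reference
#' cell (by default the first group at the earliest ZT) equals zero. The
#' 95 percent confidence half-width is the t-quantile times the standard
#' error over the cluster's features; it is `NA` for singleton clusters.
#'
#' @param tcm a [time_course()].
#' @param assignments named cluster vector covering all features of `tcm`.
#' @param reference length-2 vector `c(group, zt)` naming the zero cell.
#' @return data.frame of class `cluster_profiles`: `cluster`, `group`,
#'   `zt`, `mean`, `ci95`, `n_features`.
#' @export
cluster_profile_summary <- function(tcm, assignments, reference = NULL) {
  stopifnot(inherits(tcm, "time_course"))
  miss <- setdiff(rownames(tcm$values), names(assignments))
  if (length(miss))
    stop("assignments missing for: ", paste(utils::head(miss, 5), collapse = ", "))
  X <- tcm$values
  Z <- t(scale(t(X)))          # per-feature mean 0, sd 1 across all samples
  Z[is.nan(Z)] <- 0            # constant features carry a flat profile
  cell <- interaction(tcm$samples$group, tcm$samples$zt, drop = TRUE, sep = "\r")
  counts <- table(cell)
  Ind <- stats::model.matrix(~ 0 + cell)
  Zc <- Z %*% Ind %*% diag(1 / as.numeric(counts), nlevels(cell))
  cell_info <- do.call(rbind, strsplit(levels(cell), "\r", fixed = TRUE))
  groups <- cell_info[, 1]; zts <- as.numeric(cell_info[, 2])
  if (is.null(reference)) {
    g0 <- unique(tcm$samples$group)[1]
    reference <- c(g0, min(tcm$samples$zt[tcm$samples$group == g0]))
  }
  ref_col <- which(groups == reference[1] & zts == as.numeric(reference[2]))
  if (length(ref_col) != 1) stop("reference cell not found in the design")

  asg <- assignments[rownames(X)]
  out <- list()
  for (cl in sort(unique(asg))) {
    rows <- which(asg == cl)
    m <- colMeans(Zc[rows, , drop = FALSE])
    nf <- length(rows)
    ci <- if (nf > 1) {
      se <- apply(Zc[rows, , drop = FALSE], 2, stats::sd) / sqrt(nf)
      stats::qt(0.975, nf - 1) * se
    } else rep(NA_real_, ncol(Zc))
    out[[length(out) + 1L]] <-
      data.frame(cluster = cl, group = groups, zt = zts,
                 mean = m - m[ref_col], ci95 = ci, n_features = nf,
                 stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  attr(res, "reference") <- reference
  class(res) <- c("cluster_profiles", "data.frame")
  res
}

#' Z-score matrix in dendrogram order
#'
#' The heatmap companion of [ward_cluster()]: per-feature Z-scores with
#' rows in the feature dendrogram's leaf order and columns in the sample
#' dendrogram's leaf order (or sheet order when no sample clustering is
#' given). Orders are a deterministic function of the dendrograms.
#'
#' @param tcm a [time_course()].
#' @param feature_clust `ward_clustering` of the features.
#' @param sample_clust optional `ward_clustering` of the samples.
#' @return numeric matrix of Z-scores in display order.
#' @export
heatmap_matrix <- function(tcm, feature_clust, sample_clust = NULL) {
  stopifnot(inherits(tcm, "time_course"), inherits(feature_clust, "ward_clustering"))
  Z <- t(scale(t(tcm$values)))
  Z[is.nan(Z)] <- 0
  rows <- feature_clust$hclust$labels[feature_clust$order]
  cols <- if (is.null(sample_clust)) colnames(Z)
          else sample_clust$hclust$labels[sample_clust$order]
  Z[rows, cols, drop = FALSE]
}

#' Gene-set enrichment per cluster
#'
#' One hypergeometric over-representation test per (cluster, set), with the
#' universe defaulting to all clustered features and BH adjustment within
#' each cluster's family of sets. Sets with no member in the universe are
#' skipped with a message.
#'
#' @param assignments named cluster vector.
#' @param gene_sets a [gene_sets()] collection.
#' @param universe feature universe; default `names(assignments)`.
#' @return data.frame: `cluster`, `set`, `set_size`, `overlap`, `expected`,
#'   `p`, `q`.
#' @export
enrich_clusters <- function(assignments, gene_sets, universe = NULL) {
  stopifnot(inherits(gene_sets, "gene_sets"))
  if (is.null(universe)) universe <- names(assignments)
  universe <- unique(universe)
  sets <- lapply(gene_sets$sets, intersect, universe)
  empty <- lengths(sets) == 0
  if (any(empty)) {
    message("skipping ", sum(empty), " set(s) with no member in the universe")
    sets <- sets[!empty]
  }
  if (!length(sets)) return(data.frame())
  out <- list()
  for (cl in sort(unique(assignments))) {
    hits <- intersect(names(assignments)[assignments == cl], universe)
    p <- vapply(sets, function(s) hypergeom_enrich(hits, s, universe)$p, numeric(1))
    ov <- vapply(sets, function(s) length(intersect(hits, s)), numeric(1))
    out[[length(out) + 1L]] <-
      data.frame(cluster = cl, set = names(sets), set_size = lengths(sets),
                 overlap = ov, expected = length(hits) * lengths(sets) / length(universe),
                 p = p, q = bh_adjust(p), stringsAsFactors = FALSE,
                 row.names = NULL)
  }
  do.call(rbind, out)
}
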