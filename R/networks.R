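# Seed-gene correlation networks: top-k partners by absolute Pearson
# correlation, all pairwise edges among the k+1 nodes tested via the t
# transform with Bonferroni adjustment over the displayed pairs, network
# density, and cross-condition retention of the seed's significant partners.

# two-sided p for a Pearson correlation via the t transform (n - 2 df)
.cor_p <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t <- abs(r) * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(t, n - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  p
}

#' Seed-gene correlation network
#'
#' Correlates a seed feature with every other feature over one condition's
#' samples, keeps the `k` partners with the highest absolute correlation
#' (ties broken by feature id), and tests all `choose(k+1, 2)` pairwise
#' correlations among the `k + 1` nodes via the t transform. Edges are kept
#' when the Bonferroni-adjusted p (family = displayed pairs) is below
#' `alpha`; with `partner_rule = "raw"` the seed-partner significance flags
#' use unadjusted p instead. Constant features have no defined correlation
#' and are excluded with a message.
#'
#' @param tcm a [time_course()].
#' @param group condition to correlate over (needs >= 4 samples).
#' @param seed_feature feature id of the seed.
#' @param k number of partners (reduced with a warning when fewer features
#'   are available).
#' @param alpha significance level for edges.
#' @param partner_rule `"bonferroni"` (same rule as edges) or `"raw"` for
#'   the seed-partner significance flags.
#' @return object of class `seed_network`: `seed`, `partners` (data.frame
#'   `feature`, `r`, `p`, `p_adjusted`, `significant`), `edges` (all tested
#'   pairs), `density` (significant edges / tested pairs), `degree` (named,
#'   over significant edges), `n`, `k`, `alpha`, `group`.
#' @export
seed_network <- function(tcm, group, seed_feature, k = 50, alpha = 0.05,
                         partner_rule = c("bonferroni", "raw")) {
  stopifnot(inherits(tcm, "time_course"))
  partner_rule <- match.arg(partner_rule)
  sub <- subset_group(tcm, group)
  X <- sub$values
  n <- ncol(X)
  if (n < 4) stop("group '", group, "' has fewer than 4 samples")
  if (!seed_feature %in% rownames(X)) stop("seed feature '", seed_feature, "' not found")
  sds <- apply(X, 1, stats::sd)
  if (sds[seed_feature] == 0) stop("seed feature is constant in this group")
  if (any(sds == 0)) {
    message("excluding ", sum(sds == 0), " constant feature(s)")
    X <- X[sds > 0, , drop = FALSE]
  }
  others <- setdiff(rownames(X), seed_feature)
  if (length(others) < k) {
    warning("only ", length(others), " candidate partners; k reduced")
    k <- length(others)
  }
  r_seed <- as.numeric(stats::cor(X[seed_feature, ], t(X[others, , drop = FALSE])))
  names(r_seed) <- others
  ord <- order(-abs(r_seed), others)
  partners <- others[ord[seq_len(k)]]

  nodes <- c(seed_feature, partners)
  C <- stats::cor(t(X[nodes, , drop = FALSE]))
  m <- choose(k + 1, 2)
  ij <- which(upper.tri(C), arr.ind = TRUE)
  edges <- data.frame(node_a = nodes[ij[, 1]], node_b = nodes[ij[, 2]],
                      r = C[ij], stringsAsFactors = FALSE)
  edges$p <- .cor_p(edges$r, n)
  edges$p_adjusted <- pmin(1, edges$p * m)
  edges$significant <- edges$p_adjusted < alpha

  seed_edge <- edges$node_a == seed_feature | edges$node_b == seed_feature
  pr <- data.frame(feature = partners, r = r_seed[partners],
                   stringsAsFactors = FALSE, row.names = NULL)
  idx <- match(partners, ifelse(edges$node_a[seed_edge] == seed_feature,
                                edges$node_b[seed_edge], edges$node_a[seed_edge]))
  pr$p <- edges$p[seed_edge][idx]
  pr$p_adjusted <- edges$p_adjusted[seed_edge][idx]
  pr$significant <- if (partner_rule == "bonferroni") pr$p_adjusted < alpha
                    else pr$p < alpha

  deg <- stats::setNames(numeric(length(nodes)), nodes)
  sig <- edges[edges$significant, , drop = FALSE]
  for (nd in nodes)
    deg[nd] <- sum(sig$node_a == nd) + sum(sig$node_b == nd)

  structure(list(seed = seed_feature, partners = pr, edges = edges,
                 density = sum(edges$significant) / m, degree = deg,
                 n = n, k = k, alpha = alpha, group = group,
                 partner_rule = partner_rule),
            class = "seed_network")
}

#' @export
print.seed_network <- function(x, ...) {
  cat("Seed network of '", x$seed, "' (", x$group, ", n = ", x$n, "): ",
      x$k, " partners, ", sum(x$edges$significant), "/", nrow(x$edges),
      " significant edges (density ", signif(x$density, 3), ")\n", sep = "")
  invisible(x)
}

#' Cross-condition retention of a seed network
#'
#' Re-evaluates the seed-partner correlations of an existing network on the
#' samples of a second condition, with the same partner list, Bonferroni
#' family and significance rule, and reports which of the originally
#' significant partners remain significant, plus the density of the fully
#' re-evaluated network.
#'
#' @param net a [seed_network()] built on condition A.
#' @param tcm the [time_course()] holding condition B's samples.
#' @param group_b condition label to re-evaluate on.
#' @param alpha significance level; default the network's.
#' @return list of class `network_retention`: `n_initial` (significant
#'   partners in A), `n_retained`, `retained` (ids), `density_b`, `table`
#'   (per-partner r/p in both conditions).
#' @export
network_retention <- function(net, tcm, group_b, alpha = net$alpha) {
  stopifnot(inherits(net, "seed_network"), inherits(tcm, "time_course"))
  sub <- subset_group(tcm, group_b)
  X <- sub$values
  nodes <- c(net$seed, net$partners$feature)
  miss <- setdiff(nodes, rownames(X))
  if (length(miss))
    stop("network node(s) absent from the matrix: ", paste(utils::head(miss, 5), collapse = ", "))
  n_b <- ncol(X)
  m <- choose(net$k + 1, 2)

  r_b <- as.numeric(stats::cor(X[net$seed, ],
                               t(X[net$partners$feature, , drop = FALSE])))
  p_b <- .cor_p(r_b, n_b)
  p_b_adj <- pmin(1, p_b * m)
  sig_b <- if (net$partner_rule == "bonferroni") p_b_adj < alpha else p_b < alpha

  tab <- data.frame(feature = net$partners$feature,
                    r_a = net$partners$r, sig_a = net$partners$significant,
                    r_b = r_b, p_b = p_b, p_b_adjusted = p_b_adj,
                    sig_b = sig_b, retained = net$partners$significant & sig_b,
                    stringsAsFactors = FALSE)
  C <- stats::cor(t(X[nodes, , drop = FALSE]))
  pe <- .cor_p(C[upper.tri(C)], n_b)
  density_b <- sum(pmin(1, pe * m) < alpha) / m

  structure(list(n_initial = sum(tab$sig_a), n_retained = sum(tab$retained),
                 retained = tab$feature[tab$retained], density_b = density_b,
                 group_b = group_b, table = tab),
            class = "network_retention")
}

#' @export
print.network_retention <- function(x, ...) {
  cat("Retention in ", x$group_b, ": ", x$n_retained, " of ", x$n_initial,
      " initially significant partners remain significant",
      " (re-evaluated density ", signif(x$density_b, 3), ")\n", sep = "")
  invisible(x)
}

#' Pairwise correlation table with significance masking
#'
#' Symmetric Pearson correlation matrix over one condition's samples for a
#' chosen feature list, with per-cell two-sided p from the t transform and
#' a mask flag for cells with `p >= alpha`. The diagonal is `r = 1`,
#' unmasked. Constant features yield `NA` rows/columns, flagged undefined.
#'
#' @param tcm a [time_course()].
#' @param group condition label.
#' @param features_list character vector of >= 2 feature ids.
#' @param alpha masking threshold.
#' @return list of class `cor_table`: `r`, `p`, `masked` (logical matrix),
#'   `undefined` (ids of constant features), `n`, `alpha`.
#' @export
pairwise_correlation_table <- function(tcm, group, features_list, alpha = 0.05) {
  stopifnot(inherits(tcm, "time_course"), length(features_list) >= 2)
  sub <- subset_group(tcm, group)
  miss <- setdiff(features_list, rownames(sub$values))
  if (length(miss)) stop("feature(s) not found: ", paste(miss, collapse = ", "))
  X <- sub$values[features_list, , drop = FALSE]
  n <- ncol(X)
  sds <- apply(X, 1, stats::sd)
  undefined <- features_list[sds == 0]
  R <- suppressWarnings(stats::cor(t(X)))
  P <- .cor_p(R, n)
  diag(R) <- 1
  diag(P) <- 0
  masked <- P >= alpha
  diag(masked) <- FALSE
  masked[is.na(R)] <- TRUE
  structure(list(r = R, p = P, masked = masked, undefined = undefined,
                 n = n, alpha = alpha, group = group),
            class = "cor_table")
}

#' @export
print.cor_table <- function(x, ...) {
  cat("Pairwise correlation table (", x$group, ", n = ", x$n, "): ",
      nrow(x$r), " features, ", sum(x$masked[upper.tri(x$masked)]),
      " of ", sum(upper.tri(x$masked)), " cells masked at p >= ", x$alpha,
      "\n", sep = "")
  invisible(x)
}
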