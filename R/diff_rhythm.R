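# Six-class differential-rhythmicity classification from two per-condition
# rhythm scans:
#   1 rhythmic in both, identical period and acrophase
#   2 rhythmic in both, acrophase shifted in condition B
#   3 rhythmic in both, period changed in condition B
#   4 rhythmic in A only
#   5 rhythmic in B only
#   6 rhythmic in neither

.circular_lag_diff <- function(a, b, tau) {
  d <- abs(a - b) %% tau
  pmin(d, tau - d)
}

#' Classify features by differential rhythmicity across two conditions
#'
#' Each feature's two [jtk_scan()] rows are combined into one of six classes
#' from (i) per-condition significance at `q < alpha` (each condition's scan
#' is its own BH family) and (ii) equality of the estimated period and
#' acrophase. Acrophases are compared circularly modulo the shared period.
#' Default tolerances are half the scan's grid steps, so grid-identical
#' estimates compare equal and neighbouring grid points differ.
#'
#' @param res_a,res_b `jtk_result` tables for the two conditions, same
#'   features and same grid.
#' @param alpha per-condition rhythmicity FDR threshold.
#' @param period_tol period equality tolerance in hours; default half the
#'   smallest gap between grid periods.
#' @param lag_tol acrophase equality tolerance in hours; default half the
#'   phase step.
#' @return data.frame of class `rhythm_classes`: `feature`, `class`,
#'   `sig_a`, `sig_b`, `period_equal`, `lag_equal`, and the per-condition
#'   `q`, `period`, `lag` columns.
#' @export
classify_rhythms <- function(res_a, res_b, alpha = 0.05,
                             period_tol = NULL, lag_tol = NULL) {
  if (!identical(res_a$feature, res_b$feature))
    stop("the two rhythm tables must cover the same features in the same order")
  grid <- attr(res_a, "grid")
  if (is.null(period_tol)) {
    pers <- sort(unique(grid$period))
    period_tol <- if (length(pers) > 1) min(diff(pers)) / 2 else Inf
  }
  if (is.null(lag_tol)) lag_tol <- attr(res_a, "phase_step") / 2

  sig_a <- res_a$q < alpha
  sig_b <- res_b$q < alpha
  period_equal <- abs(res_a$period - res_b$period) <= period_tol
  lag_equal <- period_equal &
    .circular_lag_diff(res_a$lag, res_b$lag, pmax(res_a$period, 1e-9)) <= lag_tol

  cls <- integer(nrow(res_a))
  both <- sig_a & sig_b
  cls[both & period_equal & lag_equal] <- 1L
  cls[both & period_equal & !lag_equal] <- 2L
  cls[both & !period_equal] <- 3L
  cls[sig_a & !sig_b] <- 4L
  cls[!sig_a & sig_b] <- 5L
  cls[!sig_a & !sig_b] <- 6L

  out <- data.frame(feature = res_a$feature, class = cls,
                    sig_a = sig_a, sig_b = sig_b,
                    period_equal = period_equal, lag_equal = lag_equal,
                    q_a = res_a$q, q_b = res_b$q,
                    period_a = res_a$period, period_b = res_b$period,
                    lag_a = res_a$lag, lag_b = res_b$lag,
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "period_tol") <- period_tol
  attr(out, "lag_tol") <- lag_tol
  class(out) <- c("rhythm_classes", "data.frame")
  out
}

#' @export
print.rhythm_classes <- function(x, ...) {
  cat("Differential-rhythmicity classes (alpha =", attr(x, "alpha"), "):\n")
  print(table(factor(x$class, levels = 1:6)))
  invisible(x)
}

#' Classify a single feature
#'
#' @param res_a,res_b one-row rhythm results for the same feature.
#' @inheritParams classify_rhythms
#' @return integer class in 1..6.
#' @export
classify_feature <- function(res_a, res_b, alpha = 0.05,
                             period_tol = NULL, lag_tol = NULL) {
  classify_rhythms(res_a, res_b, alpha, period_tol, lag_tol)$class[1]
}

#' Per-cluster distribution of rhythm classes
#'
#' @param classes a `rhythm_classes` table (or any data.frame with
#'   `feature` and `class`).
#' @param clusters named integer/character vector mapping every classified
#'   feature to a cluster label.
#' @return data.frame: one row per cluster with `n` and the fraction of
#'   each class 1..6 (fractions sum to 1; an empty cluster level yields a
#'   zero row with `n = 0`).
#' @export
class_distribution <- function(classes, clusters) {
  miss <- setdiff(classes$feature, names(clusters))
  if (length(miss))
    stop("feature(s) without a cluster label: ", paste(utils::head(miss, 5), collapse = ", "))
  cl <- clusters[classes$feature]
  levs <- if (is.factor(clusters)) levels(clusters) else sort(unique(clusters))
  tab <- table(factor(cl, levels = levs), factor(classes$class, levels = 1:6))
  n <- rowSums(tab)
  prop <- sweep(tab, 1, pmax(n, 1), "/")
  out <- data.frame(cluster = rownames(tab), n = as.integer(n),
                    as.data.frame.matrix(prop), check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[-(1:2)] <- paste0("class_", 1:6)
  out
}
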