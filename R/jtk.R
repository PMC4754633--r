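# Nonparametric rhythm detection: each feature's values are compared against
# cosine reference waveforms on a period/phase grid via Kendall's S, and the
# minimum p-value is taken from the exact permutation null of S under the
# design's tie structure (the JTK_Cycle scheme).

.null_cache <- new.env(parent = emptyenv())

#' Kendall's S between two vectors
#'
#' Concordant-minus-discordant pair count; pairs tied in either vector
#' contribute zero.
#'
#' @param x,r numeric vectors of equal length.
#' @return integer S.
#' @export
kendall_s <- function(x, r) {
  n <- length(x)
  stopifnot(length(r) == n)
  if (n < 2) return(0L)
  ij <- which(upper.tri(diag(n)), arr.ind = TRUE)
  as.integer(sum(sign(x[ij[, 2]] - x[ij[, 1]]) * sign(r[ij[, 2]] - r[ij[, 1]])))
}

# Tie-group sizes in increasing order of the underlying value. The order
# matters: when both the data and the reference are tied, the exact null of S
# depends on which block sizes sit at which end of the value scale (and can be
# asymmetric), so blocks are always passed in value order.
.tie_sizes <- function(v, digits = 9) {
  v <- round(as.numeric(v), digits)
  as.integer(table(factor(v, levels = sort(unique(v)))))
}

# Enumerate compositions of t into G parts bounded by caps (rows of a matrix).
.compositions <- function(t, caps) {
  G <- length(caps)
  if (G == 1) {
    if (t <= caps[1]) return(matrix(t, 1, 1)) else return(matrix(0L, 0, 1))
  }
  out <- list()
  for (first in 0:min(t, caps[1])) {
    rest <- .compositions(t - first, caps[-1])
    if (nrow(rest)) out[[length(out) + 1L]] <- cbind(first, rest)
  }
  if (!length(out)) return(matrix(0L, 0, G))
  res <- do.call(rbind, out)
  dimnames(res) <- NULL
  res
}

#' Exact permutation null distribution of Kendall's S under ties
#'
#' Computes, by dynamic programming over tie groups, the exact distribution
#' of Kendall's S between a data vector with tie-group sizes
#' `data_tie_groups` and a fixed reference ordering with tie-group sizes
#' `ref_tie_groups`, when the data labels are assigned uniformly at random
#' over their distinct permutations. This is the Harding-style convolution
#' recursion generalised to ties in both rankings: data tie blocks are placed
#' into reference groups in increasing data order; placing `t_b` block
#' members into reference group `b` when `m_a` earlier members already
#' occupy group `a` adds `sum_b t_b * (sum_{a<b} m_a - sum_{a>b} m_a)` to S,
#' with multiplicity `prod_b choose(cap_b - m_b, t_b)`.
#'
#' The result equals exhaustive enumeration over all distinct permutations.
#' Tie-group sizes are taken in increasing order of the underlying value;
#' this order is part of the design: when both rankings are tied the
#' distribution can differ between orderings (and need not be symmetric),
#' although `P(|S| >= a)` is unchanged by reversing either ranking, which is
#' what the two-sided test uses. Distributions are cached by the ordered
#' pair of tie sequences.
#'
#' @param data_tie_groups integer sizes of the data value tie groups, in
#'   increasing data-value order.
#' @param ref_tie_groups integer sizes of the reference tie groups, in
#'   increasing reference-value order; totals must agree.
#' @return object of class `s_null`: list with `s` (support, `-M..M`),
#'   `prob`, and `tail`, where `tail[a + 1] = P(|S| >= a)`.
#' @export
exact_null_distribution <- function(data_tie_groups, ref_tie_groups) {
  data_tie_groups <- as.integer(data_tie_groups)
  ref_tie_groups <- as.integer(ref_tie_groups)
  if (any(data_tie_groups < 1) || any(ref_tie_groups < 1))
    stop("tie-group sizes must be positive integers")
  n <- sum(data_tie_groups)
  if (n == 0) stop("empty design: no observations")
  if (sum(ref_tie_groups) != n)
    stop("data and reference tie groups must cover the same number of observations")
  key <- paste0("d", paste(data_tie_groups, collapse = ","),
                "|r", paste(ref_tie_groups, collapse = ","))
  if (!is.null(.null_cache[[key]])) return(.null_cache[[key]])

  caps <- ref_tie_groups
  G <- length(caps)
  M <- (n^2 - sum(ref_tie_groups^2)) / 2   # pairs comparable in the reference
  L <- as.integer(2 * M + 1)
  off <- as.integer(M + 1)                 # S = 0 maps to index off

  mult <- cumprod(c(1L, caps[-G] + 1L))
  nstate <- prod(caps + 1L)
  # decode table: state index -> occupancy vector
  occ <- as.matrix(expand.grid(lapply(caps, function(cp) 0:cp),
                               KEEP.OUT.ATTRS = FALSE))
  dimnames(occ) <- NULL
  below <- t(apply(occ, 1, function(m) cumsum(c(0, m[-G]))))
  if (G == 1) below <- matrix(below, ncol = 1)
  totals <- rowSums(occ)

  dp <- vector("list", nstate)
  dp[[1]] <- { v <- numeric(L); v[off] <- 1; v }
  for (t_block in data_tie_groups) {
    newdp <- vector("list", nstate)
    for (i in which(!vapply(dp, is.null, logical(1)))) {
      m <- occ[i, ]
      comps <- .compositions(t_block, caps - m)
      if (!nrow(comps)) next
      tot <- totals[i]
      for (ci in seq_len(nrow(comps))) {
        tg <- comps[ci, ]
        ways <- prod(choose(caps - m, tg))
        # S increment: earlier (smaller-data) members below vs above each group
        dS <- sum(tg * (below[i, ] - (tot - below[i, ] - m)))
        j <- i + as.integer(sum(tg * mult))
        src <- dp[[i]]
        idx <- which(src != 0)
        if (is.null(newdp[[j]])) newdp[[j]] <- numeric(L)
        newdp[[j]][idx + dS] <- newdp[[j]][idx + dS] + src[idx] * ways
      }
    }
    dp <- newdp
  }
  counts <- dp[[nstate]]
  prob <- counts / sum(counts)
  support <- seq.int(-M, M)
  # tail[a+1] = P(|S| >= a)
  abs_s <- abs(support)
  tail <- vapply(0:as.integer(M), function(a) sum(prob[abs_s >= a]), numeric(1))
  out <- structure(list(s = support, prob = prob, tail = tail,
                        data_ties = data_tie_groups, ref_ties = ref_tie_groups),
                   class = "s_null")
  .null_cache[[key]] <- out
  out
}

#' @export
print.s_null <- function(x, ...) {
  cat("Exact Kendall-S null: n =", sum(x$data_ties),
      "| data ties:", paste(x$data_ties, collapse = ","),
      "| ref ties:", paste(x$ref_ties, collapse = ","),
      "| support -", max(x$s), "..", max(x$s), "\n")
  invisible(x)
}

# two-sided exact p: P(|S| >= |s|)
.p_two_sided <- function(null, s) {
  a <- abs(as.integer(s))
  if (a > max(null$s)) return(0)
  null$tail[a + 1L]
}

#' Cosine reference grid for the rhythm scan
#'
#' Builds the non-redundant (period, lag) hypotheses: lags step through
#' `[0, period)` at `phase_step`, and a lag and its antiphase partner
#' (`lag + period/2`) induce negated orderings, so only lags below
#' `period/2` are kept; the scan recovers antiphase acrophases from the sign
#' of S.
#'
#' @param periods candidate periods, hours.
#' @param phase_step lag grid step, hours.
#' @return data.frame with columns `period`, `lag`.
#' @export
reference_grid <- function(periods = c(12, 24), phase_step = 6) {
  stopifnot(all(periods > 0), phase_step > 0)
  do.call(rbind, lapply(periods, function(tau) {
    lags <- seq(0, tau - phase_step / 2, by = phase_step)
    lags <- lags[lags < tau / 2]
    data.frame(period = tau, lag = lags)
  }))
}

# Internal scan over a value matrix (features x samples) at times t_h.
.jtk_core <- function(X, t_h, periods, phase_step, bonferroni = TRUE) {
  grid <- reference_grid(periods, phase_step)
  m_hyp <- nrow(grid)
  n <- length(t_h)
  if (length(unique(t_h)) < 2) stop("need >= 2 distinct ZT values")
  ij <- which(upper.tri(diag(n)), arr.ind = TRUE)
  ii <- ij[, 1]; jj <- ij[, 2]

  refs <- lapply(seq_len(m_hyp), function(k)
    cos(2 * pi * (t_h - grid$lag[k]) / grid$period[k]))
  W <- vapply(refs, function(r) sign(round(r[jj] - r[ii], 9)), numeric(length(ii)))
  W <- matrix(W, ncol = m_hyp)
  ref_ties <- lapply(refs, .tie_sizes)
  ref_pairs <- vapply(ref_ties, function(ts) (n^2 - sum(ts^2)) / 2, numeric(1))

  S <- sign(round(X[, jj, drop = FALSE] - X[, ii, drop = FALSE], 9)) %*% W

  data_keys <- apply(X, 1, function(x) paste(.tie_sizes(x), collapse = ","))
  data_ties <- lapply(strsplit(data_keys, ","), as.integer)
  data_pairs <- vapply(data_ties, function(ts) (n^2 - sum(ts^2)) / 2, numeric(1))
  constant <- data_pairs == 0

  P <- matrix(1, nrow(X), m_hyp)
  for (key in unique(data_keys[!constant])) {
    rows <- which(data_keys == key & !constant)
    dt <- data_ties[[rows[1]]]
    for (k in seq_len(m_hyp)) {
      null <- exact_null_distribution(dt, ref_ties[[k]])
      a <- pmin(abs(S[rows, k]), max(null$s))
      P[rows, k] <- null$tail[as.integer(a) + 1L]
    }
  }

  # best hypothesis: smallest p, then largest |S|, then grid order
  best <- integer(nrow(X))
  for (f in seq_len(nrow(X)))
    best[f] <- order(P[f, ], -abs(S[f, ]))[1]
  bi <- cbind(seq_len(nrow(X)), best)
  period <- grid$period[best]
  lag0 <- grid$lag[best]
  s_best <- S[bi]
  lag <- ifelse(s_best >= 0, lag0, (lag0 + period / 2) %% period)
  tau <- ifelse(data_pairs > 0 & ref_pairs[best] > 0,
                s_best / sqrt(data_pairs * ref_pairs[best]), 0)
  p <- P[bi]
  adj_p <- if (bonferroni) pmin(1, p * m_hyp) else p

  res <- data.frame(feature = rownames(X), period = period, lag = lag,
                    S = s_best, tau = tau, p = p, adj_p = adj_p,
                    stringsAsFactors = FALSE)
  res$period[constant] <- 0
  res$lag[constant] <- 0
  res$S[constant] <- 0L
  res$tau[constant] <- 0
  res$p[constant] <- 1
  res$adj_p[constant] <- 1
  attr(res, "grid") <- grid
  attr(res, "phase_step") <- phase_step
  attr(res, "n_hypotheses") <- m_hyp
  res
}

#' Rhythm test for a single series
#'
#' Scans one series against the cosine reference grid and reports the
#' best-fitting period and acrophase with the exact two-sided p-value and a
#' within-feature Bonferroni-adjusted p over the non-redundant hypotheses.
#' A constant series carries no ordering information and is reported with
#' `period = 0`, `p = 1` (not an error).
#'
#' @param y numeric series.
#' @param zt Zeitgeber times (hours) of the observations.
#' @param periods candidate periods, hours.
#' @param phase_step lag grid step, hours.
#' @param bonferroni apply the within-feature multiplicity factor
#'   (number of non-redundant hypotheses after antiphase collapsing).
#' @return one-row data.frame: `feature`, `period`, `lag` (acrophase), `S`,
#'   `tau` (normalised Kendall correlation), `p`, `adj_p`.
#' @export
jtk_test <- function(y, zt, periods = c(12, 24), phase_step = 6,
                     bonferroni = TRUE) {
  X <- matrix(as.numeric(y), 1, dimnames = list("series", NULL))
  .jtk_core(X, as.numeric(zt), periods, phase_step, bonferroni)
}

#' Rhythm scan of one condition of a time course
#'
#' Runs [jtk_test()] for every feature on the samples of one condition and
#' adds Benjamini-Hochberg q-values across features; features with
#' `q < alpha` are flagged significantly rhythmic. Exact null distributions
#' are computed once per (data tie structure, reference tie structure) pair
#' and cached, so matrix scans reuse the same null.
#'
#' @param tcm a [time_course()].
#' @param group condition label to scan.
#' @param periods,phase_step,bonferroni see [jtk_test()].
#' @param alpha FDR threshold for the significance flag.
#' @return data.frame of class `jtk_result` with columns `feature`,
#'   `period`, `lag`, `S`, `tau`, `p`, `adj_p`, `q`, `significant`.
#' @export
jtk_scan <- function(tcm, group, periods = c(12, 24), phase_step = 6,
                     alpha = 0.05, bonferroni = TRUE) {
  stopifnot(inherits(tcm, "time_course"))
  sub <- subset_group(tcm, group)
  res <- .jtk_core(sub$values, sub$samples$zt, periods, phase_step, bonferroni)
  res$q <- stats::p.adjust(res$adj_p, method = "BH")
  res$significant <- res$q < alpha
  attr(res, "group") <- group
  attr(res, "alpha") <- alpha
  class(res) <- c("jtk_result", "data.frame")
  res
}

#' @export
print.jtk_result <- function(x, ...) {
  cat("Rhythm scan (", attr(x, "group"), "): ", nrow(x), " features, ",
      sum(x$significant), " rhythmic at q < ", attr(x, "alpha"), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more rows)\n", sep = "")
  invisible(x)
}
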