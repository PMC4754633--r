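# Shared statistical kernels used across the pipeline: BH FDR, the
# Student/Welch two-group test with a variance-equality gate, Kruskal-Wallis
# (chi-square or exact), hypergeometric set enrichment, and the per-feature
# cell-means F test with optional empirical-Bayes variance moderation.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, `q(i) = min_{j >= i} m * p(j) / j` on the sorted
#' p-values mapped back to input order. Empty input yields empty output.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Two-group test with a variance-equality gate
#'
#' An F test of variance equality at `var_alpha` selects the branch: equal
#' variances use the pooled-variance Student t test, unequal variances the
#' Welch t test with Satterthwaite degrees of freedom; p is two-sided. Two
#' degenerate cases are handled without error: both groups constant with
#' equal means gives `t = 0, p = 1`; both constant with unequal means gives
#' `p = 0` with a warning flag in the result.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param var_alpha level of the variance-equality F test.
#' @return list of class `group_test`: `statistic`, `df`, `p`, `method`
#'   (`"student"` or `"welch"`), `var_p`, `degenerate`.
#' @export
two_group_test <- function(a, b, var_alpha = 0.05) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      res <- list(statistic = 0, df = length(a) + length(b) - 2, p = 1,
                  method = "student", var_p = 1, degenerate = FALSE)
    } else {
      res <- list(statistic = sign(mean(a) - mean(b)) * Inf,
                  df = length(a) + length(b) - 2, p = 0,
                  method = "student", var_p = 1, degenerate = TRUE)
    }
    class(res) <- "group_test"
    return(res)
  }
  var_p <- if (va == 0 || vb == 0) 0 else stats::var.test(a, b)$p.value
  equal <- var_p >= var_alpha
  tt <- stats::t.test(a, b, var.equal = equal)
  res <- list(statistic = unname(tt$statistic), df = unname(tt$parameter),
              p = tt$p.value, method = if (equal) "student" else "welch",
              var_p = var_p, degenerate = FALSE)
  class(res) <- "group_test"
  res
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("%s t = %.4g, df = %.4g, p = %.4g (variance-gate p = %.3g)\n",
              x$method, x$statistic, x$df, x$p, x$var_p))
  invisible(x)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with the chi-square approximation
#' (df = k - 1), or an exact permutation p-value obtained by enumerating all
#' assignments of the pooled values to groups (practical for total n up to
#' about 10). All values identical gives `H = 0, p = 1`.
#'
#' @param groups list of numeric vectors (>= 2 groups, total n >= 3).
#' @param exact compute the exact permutation p instead of chi-square.
#' @return list: `statistic` (H), `df`, `p`, `method`.
#' @export
kruskal_wallis <- function(groups, exact = FALSE) {
  stopifnot(is.list(groups), length(groups) >= 2)
  sizes <- lengths(groups)
  if (any(sizes < 1) || sum(sizes) < 3) stop("need n >= 1 per group, total >= 3")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  if (length(unique(x)) == 1)
    return(list(statistic = 0, df = length(groups) - 1, p = 1,
                method = if (exact) "kw_exact" else "kw"))
  kt <- stats::kruskal.test(x, g)
  H <- unname(kt$statistic)
  if (!exact)
    return(list(statistic = H, df = unname(kt$parameter), p = kt$p.value,
                method = "kw"))
  n <- length(x)
  if (n > 10) stop("exact enumeration limited to total n <= 10")
  pm <- .permutation_matrix(n)
  r <- rank(x)
  tie <- table(r)
  correction <- 1 - sum(tie^3 - tie) / (n^3 - n)
  Rv <- matrix(r[pm], nrow(pm), n)
  starts <- c(0, cumsum(sizes))
  ss <- 0
  for (k in seq_along(sizes)) {
    cols <- (starts[k] + 1):starts[k + 1]
    ss <- ss + rowSums(Rv[, cols, drop = FALSE])^2 / sizes[k]
  }
  Hp <- (12 / (n * (n + 1)) * ss - 3 * (n + 1)) / correction
  p <- mean(Hp >= H - 1e-9)
  list(statistic = H, df = length(groups) - 1, p = p, method = "kw_exact")
}

# all permutations of 1..n as an n! x n matrix
.permutation_matrix <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutation_matrix(n - 1L)
  out <- matrix(0L, factorial(n), n)
  blk <- nrow(sub)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * blk + 1L):(i * blk)
    rest <- sub
    rest[rest >= i] <- rest[rest >= i] + 1L
    out[rows, ] <- cbind(rep.int(i, blk), rest)
  }
  out
}

#' Hypergeometric over-representation test
#'
#' One-sided upper-tail p for the overlap between a hit set and a category
#' within a universe: the probability of observing at least the seen overlap
#' when drawing `|hits|` features without replacement.
#'
#' @param hit_set,category character vectors of feature ids, both subsets of
#'   `universe`.
#' @param universe character vector, non-empty.
#' @return list: `overlap`, `expected`, `p`, `method`.
#' @export
hypergeom_enrich <- function(hit_set, category, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  hit_set <- unique(as.character(hit_set))
  category <- unique(as.character(category))
  if (length(setdiff(hit_set, universe)) || length(setdiff(category, universe)))
    stop("hit set and category must be subsets of the universe")
  N <- length(universe); K <- length(category); nh <- length(hit_set)
  k <- length(intersect(hit_set, category))
  p <- stats::phyper(k - 1, K, N - K, nh, lower.tail = FALSE)
  list(overlap = k, expected = nh * K / N, p = p, method = "hypergeom")
}

# Newton inversion of trigamma, as used for the moment fit of the variance prior
.trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:64) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2)
      y <- y + dif
      if (abs(dif) < 1e-10 * y) break
    }
    y
  }, numeric(1))
}

#' Per-feature one-way F test across design cells with optional moderation
#'
#' Tests each feature for any difference among the (group x ZT) cell means
#' of the design (the differential-expression criterion of the emulated
#' study), with optional empirical-Bayes variance moderation: residual
#' variances are shrunk toward a prior fitted by moments on the
#' log-variances (inverting digamma/trigamma identities of the scaled
#' chi-square), the F denominator becomes the posterior variance and its
#' degrees of freedom gain the prior df. With prior df 0 the moderated F
#' equals the ordinary F. BH q-values are computed across features and
#' features with `q <= alpha` are flagged.
#'
#' @param tcm a [time_course()].
#' @param moderate apply empirical-Bayes variance moderation.
#' @param alpha FDR flag threshold (the study used 1 percent).
#' @return data.frame of class `de_result`: `feature`, `F`, `df1`, `df2`,
#'   `s2`, `s2_post`, `p`, `q`, `significant`; attributes `d0` (prior df)
#'   and `s0_2` (prior variance).
#' @export
moderated_f_test <- function(tcm, moderate = TRUE, alpha = 0.01) {
  stopifnot(inherits(tcm, "time_course"))
  X <- tcm$values
  cell <- interaction(tcm$samples$group, tcm$samples$zt, drop = TRUE)
  counts <- table(cell)
  if (any(counts < 2)) stop("every (group, ZT) cell needs >= 2 replicates")
  k <- nlevels(cell); n <- ncol(X); d <- n - k
  Ind <- stats::model.matrix(~ 0 + cell)
  M <- X %*% Ind %*% diag(1 / as.numeric(counts), k)  # cell means
  grand <- rowMeans(X)
  ssb <- as.numeric((M - grand)^2 %*% as.numeric(counts))
  ssw <- rowSums(X^2) - as.numeric(M^2 %*% as.numeric(counts))
  ssw <- pmax(ssw, 0)
  s2 <- ssw / d
  msb <- ssb / (k - 1)

  if (moderate) {
    pos <- s2 > 0
    if (!any(pos)) stop("all residual variances are zero; nothing to moderate")
    z <- log(s2[pos])
    e <- z - digamma(d / 2) + log(d / 2)
    ev <- stats::var(e) - trigamma(d / 2)
    if (is.na(ev) || ev <= 0) {
      d0 <- Inf
      s0_2 <- exp(mean(e))
    } else {
      d0 <- 2 * .trigamma_inverse(ev)
      s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    }
    s2_post <- if (is.infinite(d0)) rep(s0_2, length(s2))
               else (d0 * s0_2 + d * s2) / (d0 + d)
    df2 <- d + d0
    Fs <- msb / s2_post
    p <- stats::pf(Fs, k - 1, df2, lower.tail = FALSE)
  } else {
    d0 <- 0; s0_2 <- NA_real_
    s2_post <- s2
    df2 <- d
    Fs <- msb / s2
    zero <- s2 == 0
    if (any(zero)) {
      Fs[zero] <- ifelse(msb[zero] > 0, Inf, 0)
      if (any(msb[zero] > 0))
        warning("zero residual variance with unequal means for ",
                sum(msb[zero] > 0), " feature(s); p set to 0")
    }
    p <- stats::pf(Fs, k - 1, df2, lower.tail = FALSE)
    p[zero & msb == 0] <- 1
  }
  q <- bh_adjust(p)
  res <- data.frame(feature = rownames(X), F = Fs, df1 = k - 1, df2 = df2,
                    s2 = s2, s2_post = s2_post, p = p, q = q,
                    significant = q <= alpha, stringsAsFactors = FALSE)
  attr(res, "d0") <- d0
  attr(res, "s0_2") <- s0_2
  attr(res, "alpha") <- alpha
  attr(res, "moderated") <- moderate
  class(res) <- c("de_result", "data.frame")
  res
}

#' @export
print.de_result <- function(x, ...) {
  cat("Cell-means F test: ", nrow(x), " features, ", sum(x$significant),
      " at q <= ", attr(x, "alpha"),
      if (isTRUE(attr(x, "moderated")))
        sprintf(" (moderated, prior df = %.3g)", attr(x, "d0")), "\n", sep = "")
  invisible(x)
}

#' Per-time-point two-group comparisons
#'
#' Runs [two_group_test()] for every feature at every shared ZT between two
#' conditions, then adjusts all (feature x ZT) p-values of the batch as one
#' BH family (the `family = "per_feature"` option adjusts within each
#' feature instead). Significance stars follow the convention
#' `***` q < 0.005, `**` q < 0.01, `*` q < 0.05.
#'
#' @param tcm a [time_course()].
#' @param groups two condition labels; default the first two in the sheet.
#' @param var_alpha level of the variance-equality gate.
#' @param family `"batch"` or `"per_feature"` BH family.
#' @return data.frame: `feature`, `zt`, `statistic`, `df`, `method`, `p`,
#'   `q`, `stars`.
#' @export
compare_groups_by_zt <- function(tcm, groups = NULL, var_alpha = 0.05,
                                 family = c("batch", "per_feature")) {
  stopifnot(inherits(tcm, "time_course"))
  family <- match.arg(family)
  if (is.null(groups)) groups <- unique(tcm$samples$group)[1:2]
  stopifnot(length(groups) == 2)
  zts <- sort(intersect(tcm$samples$zt[tcm$samples$group == groups[1]],
                        tcm$samples$zt[tcm$samples$group == groups[2]]))
  rows <- list()
  for (zt in zts) {
    ca <- tcm$samples$group == groups[1] & tcm$samples$zt == zt
    cb <- tcm$samples$group == groups[2] & tcm$samples$zt == zt
    for (f in rownames(tcm$values)) {
      tt <- two_group_test(tcm$values[f, ca], tcm$values[f, cb], var_alpha)
      rows[[length(rows) + 1L]] <-
        data.frame(feature = f, zt = zt, statistic = tt$statistic,
                   df = tt$df, method = tt$method, p = tt$p,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (family == "batch") {
    out$q <- bh_adjust(out$p)
  } else {
    out$q <- stats::ave(out$p, out$feature, FUN = bh_adjust)
  }
  out$stars <- ifelse(out$q < 0.005, "***",
               ifelse(out$q < 0.01, "**",
               ifelse(out$q < 0.05, "*", "")))
  out
}
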