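# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately brute-force and kept separate from the
# package's own algorithms.

# all permutations of 1..n (n! x n matrix)
perm_matrix <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perm_matrix(n - 1L)
  out <- matrix(0L, factorial(n), n)
  blk <- nrow(sub)
  for (i in seq_len(n)) {
    rest <- sub
    rest[rest >= i] <- rest[rest >= i] + 1L
    out[((i - 1L) * blk + 1L):(i * blk), ] <- cbind(rep.int(i, blk), rest)
  }
  out
}

# Kendall S by definition (pair loop), independent of the package
s_by_definition <- function(x, r) {
  n <- length(x)
  s <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    s <- s + sign(x[j] - x[i]) * sign(r[j] - r[i])
  as.integer(s)
}

# exact null of S by exhaustive enumeration of all n! label permutations
# (duplicate permutations of tied data count multiply, which leaves the
# distribution unchanged); pm may be passed in to reuse across designs
enum_s_null <- function(y, r, pm = perm_matrix(length(y))) {
  n <- length(y)
  Yv <- matrix(y[pm], nrow(pm), n)
  S <- numeric(nrow(pm))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    w <- sign(r[j] - r[i])
    if (w != 0) S <- S + w * sign(Yv[, j] - Yv[, i])
  }
  tab <- table(S)
  list(s = as.numeric(names(tab)), prob = as.numeric(tab) / nrow(pm))
}

# vector with tie-block sizes in increasing value order
blocks_to_values <- function(sizes) rep(seq_along(sizes), sizes)

# ascending integer partitions of n
partitions_of <- function(n, max_part = n) {
  if (n == 0) return(list(integer(0)))
  out <- list()
  for (k in seq_len(min(n, max_part))) {
    for (rest in partitions_of(n - k, k))
      out[[length(out) + 1L]] <- c(rest, k)
  }
  out
}

# all compositions (ordered partitions) of n
compositions_of <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (first in seq_len(n)) {
    if (first == n) { out[[length(out) + 1L]] <- n; next }
    for (rest in compositions_of(n - first))
      out[[length(out) + 1L]] <- c(first, rest)
  }
  out
}

# BH step-up by its definition
bh_by_definition <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# Kruskal-Wallis H by the rank-sum formula with tie correction
kw_h_by_formula <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  r <- rank(x)
  sizes <- lengths(groups)
  starts <- c(0, cumsum(sizes))
  ss <- 0
  for (k in seq_along(groups))
    ss <- ss + sum(r[(starts[k] + 1):starts[k + 1]])^2 / sizes[k]
  h <- 12 / (n * (n + 1)) * ss - 3 * (n + 1)
  tie <- table(r)
  h / (1 - sum(tie^3 - tie) / (n^3 - n))
}

# small two-condition fixture around the standard 4 x 5 design
toy_tcm <- function(values, groups = "SPF", zts = c(0, 6, 12, 18), n_reps = 1) {
  d <- expand.grid(replicate = seq_len(n_reps), zt = zts, group = groups,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d <- d[, c("group", "zt", "replicate")]
  d$sample_id <- sprintf("%s_ZT%02d_r%d", d$group, as.integer(d$zt), d$replicate)
  values <- as.matrix(values)
  colnames(values) <- d$sample_id
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%03d", seq_len(nrow(values)))
  time_course(values, d[, c("sample_id", "group", "zt", "replicate")])
}

# adjusted Rand index (contingency-table formula), independent of mclust
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_ <- si * sj / n2
  (sij - exp_) / ((si + sj) / 2 - exp_)
}
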