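sep_data <- function(n_per = 6, p = 12, k = 2, seed = 1) {
  # noiseless linearly separable classes
  with_seed(seed, {
    y <- factor(rep(seq_len(k), each = n_per))
    centers <- matrix(rnorm(k * p, sd = 3), k, p)
    X <- centers[as.integer(y), ]
    dimnames(X) <- list(paste0("s", seq_len(k * n_per)), paste0("v", 1:p))
    list(X = X, y = y)
  })
}

test_that("Pareto scaling divides centered columns by the root of the sd", {
  set.seed(2)
  X <- cbind(a = rnorm(30), b = 4 * scale(rnorm(30))[, 1], c = rep(5, 30))
  # column b has sd exactly 4
  sc <- pareto_scale(X)
  expect_equal(sc$values[, "b"], (X[, "b"] - mean(X[, "b"])) / 2)
  expect_equal(sc$values[, "c"], rep(0, 30))
  expect_true(sc$constant["c"])
  expect_false(any(sc$constant[c("a", "b")]))
  # monotone transform: rank order preserved
  expect_equal(order(sc$values[, "a"]), order(X[, "a"]))
})

test_that("OSC with zero components is the identity and removed scores are class-orthogonal", {
  bs <- sim_buckets(n_buckets = 40, confounder_scale = 2, seed = 3)
  X <- t(bs$tcm$values)
  cls <- factor(bs$tcm$samples$zt)
  expect_equal(osc_filter(X, cls, n_osc = 0)$values, X)
  for (k in 1:2) {
    osc <- osc_filter(X, cls, n_osc = k)
    Y <- model.matrix(~ 0 + cls)
    rel <- abs(crossprod(osc$scores, Y)) /
      outer(sqrt(colSums(osc$scores^2)), sqrt(colSums(Y^2)))
    expect_lt(max(rel), 1e-8)
    expect_equal(ncol(osc$scores), k)
  }
})

test_that("OSC improves cross-validated Q2 under a strong structured confounder", {
  bs <- sim_buckets(n_buckets = 120, n_discriminant = 15, effect = 2,
                    confounder_scale = 1.5, seed = 7)
  X <- t(bs$tcm$values)
  cls <- factor(bs$tcm$samples$zt)
  q_raw <- q2_crossval(pareto_scale(X)$values, cls, A_max = 3, seed = 2)
  q_osc <- q2_crossval(pareto_scale(osc_filter(X, cls, 1)$values)$values,
                       cls, A_max = 3, seed = 2)
  expect_gt(max(q_osc$q2), max(q_raw$q2))
})

test_that("the first PLS component is proportional to X'y for two classes", {
  set.seed(5)
  X <- matrix(rnorm(20 * 15), 20, 15)
  y <- factor(rep(c("a", "b"), each = 10))
  fit <- plsda_fit(X, y, A = 1)
  yc <- scale(as.numeric(y == "b"), scale = FALSE)
  w_ref <- crossprod(scale(X, scale = FALSE), yc)
  w_ref <- w_ref / sqrt(sum(w_ref^2))
  cossim <- abs(sum(fit$W[, 1] * w_ref))
  expect_gte(cossim, 1 - 1e-8)
})

test_that("NIPALS reaches an exact fit on noiseless data and keeps scores orthogonal", {
  d <- sep_data(k = 4, seed = 6)
  fit <- plsda_fit(d$X, d$y, A = 3)    # rank k-1 suffices for k classes
  expect_equal(fit$r2y[3], 1, tolerance = 1e-8)
  expect_true(all(diff(fit$r2y) >= -1e-12))

  set.seed(7)
  Xr <- matrix(rnorm(18 * 25), 18, 25)
  yr <- factor(rep(1:3, each = 6))
  fr <- plsda_fit(Xr, yr, A = 4)
  G <- crossprod(fr$T)
  offdiag <- abs(G[upper.tri(G)]) / sqrt(diag(G)[row(G)[upper.tri(G)]] *
                                           diag(G)[col(G)[upper.tri(G)]])
  expect_lt(max(offdiag), 1e-8)
  expect_equal(unname(sqrt(colSums(fr$W^2))), rep(1, 4))
  # deflation conserves the total X energy
  Xc <- scale(Xr, scale = FALSE)
  recon <- sum((fr$T %*% t(fr$P))^2) + sum((Xc - fr$T %*% t(fr$P))^2)
  expect_equal(recon / sum(Xc^2), 1, tolerance = 1e-6)
})

test_that("adding a constant to a bucket does not change the fit", {
  set.seed(8)
  X <- matrix(rnorm(16 * 10), 16, 10)
  y <- factor(rep(1:2, each = 8))
  X2 <- X; X2[, 3] <- X2[, 3] + 100
  f1 <- plsda_fit(X, y, A = 2)
  f2 <- plsda_fit(X2, y, A = 2)
  expect_equal(f1$T, f2$T, tolerance = 1e-9)
  expect_equal(f1$r2y, f2$r2y, tolerance = 1e-9)
})

test_that("VIP satisfies its algebraic identities and ranks informative buckets first", {
  set.seed(9)
  X <- matrix(rnorm(24 * 30), 24, 30)
  y <- factor(rep(1:3, each = 8))
  fit <- plsda_fit(X, y, A = 3)
  v <- vip_scores(fit)
  expect_equal(sum(v^2), 30, tolerance = 1e-8)
  f1 <- plsda_fit(X, y, A = 1)
  expect_equal(vip_scores(f1), sqrt(30) * abs(f1$W[, 1]), tolerance = 1e-10,
               ignore_attr = TRUE)

  # one informative bucket among 99 noise buckets
  with_seed(10, {
    y2 <- factor(rep(1:2, each = 10))
    Xn <- matrix(rnorm(20 * 100), 20, 100)
    Xn[, 1] <- Xn[, 1] + 3 * (as.integer(y2) - 1.5)
    colnames(Xn) <- paste0("b", 1:100)
  })
  vin <- vip_scores(plsda_fit(Xn, y2, A = 1))
  expect_equal(names(which.max(vin)), "b1")
  expect_gt(vin["b1"], 1.5)
})

test_that("Q2 is near 1 for separable classes and low for permuted labels", {
  d <- sep_data(n_per = 7, k = 2, seed = 11)
  cv <- q2_crossval(d$X, d$y, A_max = 1, n_folds = 7, seed = 1)
  expect_gte(cv$q2[1], 0.95)
  expect_true(cv$valid)

  set.seed(12)
  bad <- 0
  for (i in 1:30) {
    yp <- sample(d$y)
    q <- q2_crossval(matrix(rnorm(14 * 12), 14, 12), yp, A_max = 2,
                     n_folds = 7, seed = i)
    if (max(q$q2) > 0.2) bad <- bad + 1
  }
  expect_lte(bad, 3)
  expect_lte(cv$q2[cv$A], 1)
  expect_lte(cv$q2[cv$A], cv$r2y + 1e-9)   # Q2 <= R2Y
})

test_that("permutation validation yields the minimal p on structured data", {
  d <- sep_data(n_per = 7, k = 2, seed = 13)
  X <- d$X + matrix(rnorm(length(d$X), sd = 0.05), nrow(d$X))
  pv <- permutation_validation(X, d$y, A = 1, n_perm = 30, seed = 2)
  expect_equal(pv$p_q2, 1 / 31)
  expect_gt(pv$q2_observed, 0.9)
})

test_that("bucket selection requires strict VIP > 1.5 and Kruskal-Wallis confirmation", {
  set.seed(14)
  X <- matrix(rnorm(20 * 5), 20, 5, dimnames = list(NULL, paste0("b", 1:5)))
  y <- factor(rep(1:4, each = 5))
  vips <- c(b1 = 2, b2 = 1.5, b3 = 1.6, b4 = 0.3, b5 = 1.51)
  X[, "b1"] <- X[, "b1"] + 2 * as.integer(y)   # discriminant
  X[, "b3"] <- X[, "b3"] + 2 * as.integer(y)
  sel <- select_discriminant(vips, X, y)
  expect_true(all(c("b1", "b3") %in% sel$bucket[sel$selected]))
  expect_false("b2" %in% sel$bucket[sel$selected])   # VIP exactly at the cut
  expect_false("b4" %in% sel$bucket[sel$selected])
  # b5 clears the VIP cut but not the rank test (pure noise)
  expect_false(sel$selected[sel$bucket == "b5"])
})

test_that("the Hotelling ellipse has positive axes from the score variances", {
  d <- sep_data(n_per = 8, k = 3, seed = 15)
  X <- d$X + matrix(rnorm(length(d$X), sd = 0.3), nrow(d$X))
  fit <- plsda_fit(X, d$y, A = 2)
  ell <- hotelling_ellipse(fit)
  n <- nrow(X)
  lim <- 2 * (n - 1) / (n - 2) * qf(0.95, 2, n - 2)
  expect_equal(ell$semi_axes,
               sqrt(apply(fit$T, 2, var) * lim))
  expect_true(all(ell$semi_axes > 0))
})
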