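test_that("noiseless class-1 feature follows the cosine formula exactly", {
  sim <- sim_rhythmic(n_features = 1, class_mix = c(1, 0, 0, 0, 0, 0),
                      amp_range = c(1, 1), sigma = 0, seed = 1)
  tr <- sim$truth
  v <- sim$tcm$values[1, ]
  expected <- tr$mesor + cos(2 * pi * (sim$tcm$samples$zt - tr$phase_A) / 24)
  expect_equal(unname(v), expected)
  # at phase 6 the four ZT means are m, m+1, m, m-1
  if (tr$phase_A == 6) {
    zt_means <- tapply(v[sim$tcm$samples$group == "SPF"],
                       sim$tcm$samples$zt[sim$tcm$samples$group == "SPF"], mean)
    expect_equal(unname(zt_means), c(10, 11, 10, 9))
  }
})

test_that("generators are deterministic given the seed", {
  a <- sim_rhythmic(n_features = 30, seed = 7)
  b <- sim_rhythmic(n_features = 30, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a$tcm$values,
                         sim_rhythmic(n_features = 30, seed = 8)$tcm$values))
  expect_identical(sim_network(seed = 3)$tcm$values,
                   sim_network(seed = 3)$tcm$values)
  expect_identical(sim_buckets(seed = 4)$tcm$values,
                   sim_buckets(seed = 4)$tcm$values)
})

test_that("planted class counts follow the mix and the truth is consistent", {
  mix <- c(0.3, 0.1, 0.1, 0.2, 0.1, 0.2)
  sim <- sim_rhythmic(n_features = 100, class_mix = mix, seed = 2)
  expect_equal(tabulate(sim$truth$class, 6), as.integer(mix * 100))
  tr <- sim$truth
  expect_true(all(tr$amp_A[tr$class == 4] > 0 & tr$amp_B[tr$class == 4] == 0))
  expect_true(all(tr$amp_A[tr$class == 5] == 0 & tr$amp_B[tr$class == 5] > 0))
  expect_true(all(tr$amp_A[tr$class == 6] == 0 & tr$amp_B[tr$class == 6] == 0))
  expect_true(all(tr$period_B[tr$class == 3] == 12))
  d <- abs(tr$phase_B - tr$phase_A)[tr$class == 2]
  expect_true(all(pmin(d %% 24, 24 - d %% 24) == 6))
  expect_error(sim_rhythmic(class_mix = c(0, 0, 1, 0, 0, 0), alt_period = 24),
               "class 3")
})

test_that("pure-noise features match the specified moments", {
  sim <- sim_rhythmic(n_features = 600, class_mix = c(0, 0, 0, 0, 0, 1),
                      sigma = 0.5, seed = 6)
  x <- as.numeric(sim$tcm$values) - 10
  n <- length(x)                       # 600 x 40 = 24000 draws
  expect_gt(n, 1e4)
  expect_lt(abs(mean(x)), 3 * 0.5 / sqrt(n))
  expect_lt(abs(sd(x) - 0.5), 3 * 0.5 / sqrt(2 * n))
})

test_that("network generator hits its limiting cases", {
  strong <- sim_network(n_background = 5, n_partners = 4, beta = 1,
                        sigma = 1e-4, seed = 1)
  Xa <- strong$tcm$values[, strong$tcm$samples$group == "SPF"]
  r <- cor(Xa["seed_gene", ], Xa["partner_001", ])
  expect_gt(r, 0.999)

  # beta = 0: seed-"partner" correlations behave like the null of r at n = 20
  rs <- unlist(lapply(1:40, function(s) {
    nullsim <- sim_network(n_background = 0, n_partners = 5, beta = 0,
                           sigma = 1, seed = s)
    Xa <- nullsim$tcm$values[, nullsim$tcm$samples$group == "SPF"]
    cor(Xa["seed_gene", ], t(Xa[-1, , drop = FALSE]))
  }))
  n <- 20
  # null sd of r is ~ 1/sqrt(n-1); with 200 draws the empirical sd is close
  expect_lt(abs(sd(rs) - 1 / sqrt(n - 1)), 0.06)
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("bucket generator plants discriminant buckets and a class-orthogonal confounder", {
  # with no confounder and a large effect, planted buckets lead the KW ranking
  bs <- sim_buckets(n_buckets = 60, n_discriminant = 8, effect = 4,
                    confounder_scale = 0, seed = 3)
  X <- t(bs$tcm$values)
  cls <- factor(bs$tcm$samples$zt)
  h <- vapply(seq_len(ncol(X)), function(j)
    kruskal_wallis(split(X[, j], cls))$statistic, numeric(1))
  top <- colnames(X)[order(-h)][1:8]
  expect_setequal(top, bs$discriminant)

  # effect = 0: no bucket discriminates beyond chance
  null <- sim_buckets(n_buckets = 200, n_discriminant = 0, effect = 0,
                      confounder_scale = 0, seed = 4)
  p <- vapply(seq_len(200), function(j)
    kruskal_wallis(split(t(null$tcm$values)[, j], cls))$p, numeric(1))
  expect_lt(mean(p < 0.05), 0.1)

  # the confounder component is exactly class-orthogonal: ZT cell means are
  # identical with and without it at the same seed
  conf_on <- sim_buckets(n_buckets = 30, n_discriminant = 0, effect = 0,
                         confounder_scale = 5, seed = 5)
  conf_off <- sim_buckets(n_buckets = 30, n_discriminant = 0, effect = 0,
                          confounder_scale = 0, seed = 5)
  cm_on <- apply(t(conf_on$tcm$values), 2, function(col) tapply(col, cls, mean))
  cm_off <- apply(t(conf_off$tcm$values), 2, function(col) tapply(col, cls, mean))
  expect_equal(cm_on, cm_off, tolerance = 1e-10)
  expect_false(identical(conf_on$tcm$values, conf_off$tcm$values))
})
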