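make_shape_matrix <- function(n_per = 10, sd = 1e-3, seed = 4) {
  set.seed(seed)
  s <- seq(0, 2 * pi, length.out = 8)
  shapes <- rbind(sin(s), cos(s), sin(2 * s))
  X <- shapes[rep(1:3, each = n_per), ] +
    matrix(rnorm(3 * n_per * 8, sd = sd), 3 * n_per, 8)
  dimnames(X) <- list(sprintf("f%02d", seq_len(3 * n_per)), paste0("s", 1:8))
  X
}

test_that("identical rows are merged first at distance zero", {
  X <- make_shape_matrix()
  X["f02", ] <- X["f01", ]
  wc <- ward_cluster(X, 3)
  first <- wc$hclust$merge[1, ]
  expect_equal(sort(wc$hclust$labels[-first]), c("f01", "f02"))
  expect_equal(wc$hclust$height[1], 0, tolerance = 1e-12)
})

test_that("planted correlation blocks are recovered exactly", {
  X <- make_shape_matrix()
  wc <- ward_cluster(X, 3)
  expect_equal(ari(wc$assignments, rep(1:3, each = 10)), 1)
})

test_that("nine noiseless archetypes are recovered at k = 9", {
  set.seed(9)
  s <- seq(0, 2 * pi, length.out = 12)
  arch <- rbind(sin(s), cos(s), sin(2 * s), cos(2 * s), sin(3 * s),
                cos(3 * s), s / max(s), (s / max(s))^2, abs(sin(s)))
  X <- arch[rep(1:9, each = 6), ] + matrix(rnorm(54 * 12, sd = 1e-4), 54, 12)
  dimnames(X) <- list(sprintf("f%02d", 1:54), paste0("s", 1:12))
  wc <- ward_cluster(X, 9)
  expect_equal(wc$k, 9)
  expect_equal(length(unique(wc$assignments)), 9)
  expect_equal(ari(wc$assignments, rep(1:9, each = 6)), 1)
})

test_that("clustering is invariant to per-feature affine rescaling", {
  X <- make_shape_matrix(sd = 0.05)
  set.seed(10)
  a <- runif(nrow(X), 0.5, 4)
  b <- rnorm(nrow(X), 0, 10)
  Y <- X * a + b
  expect_equal(ward_cluster(X, 3)$assignments, ward_cluster(Y, 3)$assignments)
  expect_equal(ward_cluster(X, 3)$order, ward_cluster(Y, 3)$order)
})

test_that("constant rows and oversized k are rejected by name", {
  X <- make_shape_matrix()
  X["f05", ] <- 2
  expect_error(ward_cluster(X, 3), "f05")
  expect_error(ward_cluster(make_shape_matrix(), 99), "exceeds")
})

test_that("Z-scores are exact and profiles offset to the reference cell", {
  sim <- sim_rhythmic(n_features = 40, class_mix = c(1, 0, 0, 0, 0, 0),
                      sigma = 0, seed = 51)
  tcm <- sim$tcm
  Z <- t(scale(t(tcm$values)))
  expect_equal(unname(rowMeans(Z)), rep(0, 40), tolerance = 1e-10)
  expect_equal(unname(apply(Z, 1, sd)), rep(1, 40), tolerance = 1e-10)

  # single planted-phase cluster: the profile is the offset cosine shape
  feats <- sim$truth$feature[sim$truth$phase_A == 6]
  skip_if(length(feats) < 3)
  sub <- time_course(tcm$values[feats, ], tcm$samples)
  asg <- setNames(rep(1L, length(feats)), feats)
  prof <- cluster_profile_summary(sub, asg)
  spf <- prof[prof$group == "SPF", ]
  shape <- cos(2 * pi * (spf$zt - 6) / 24)
  shape <- shape - shape[spf$zt == 0]
  # all features share mesor/period/phase, so the profile is proportional
  expect_equal(cor(spf$mean, shape), 1, tolerance = 1e-9)
  expect_equal(spf$mean[spf$zt == 0], 0)
})

test_that("constant-profile clusters are flat and singletons lack a CI", {
  vals <- rbind(matrix(rep(c(1, 2, 3, 4), each = 5), 3, 20, byrow = TRUE),
                matrix(7, 1, 20))
  rownames(vals) <- paste0("f", 1:4)
  tc <- toy_tcm(vals, zts = c(0, 6, 12, 18), n_reps = 5)
  asg <- setNames(c(1L, 1L, 1L, 2L), paste0("f", 1:4))
  prof <- cluster_profile_summary(tc, asg)
  flat <- prof[prof$cluster == 2, ]
  expect_equal(flat$mean, rep(0, 4))
  expect_true(all(is.na(flat$ci95)))
})

test_that("heatmap ordering is a deterministic function of the dendrograms", {
  X <- make_shape_matrix(sd = 0.05)
  tc <- toy_tcm(X, zts = c(0, 3, 6, 9, 12, 15, 18, 21))
  fc <- ward_cluster(tc$values, 3)
  sc <- ward_cluster(tc$values, 2, axis = "samples")
  h1 <- heatmap_matrix(tc, fc, sc)
  h2 <- heatmap_matrix(tc, ward_cluster(tc$values, 3),
                       ward_cluster(tc$values, 2, axis = "samples"))
  expect_identical(h1, h2)
  expect_equal(rownames(h1), fc$hclust$labels[fc$order])
  expect_equal(colnames(h1), sc$hclust$labels[sc$order])
})

test_that("cluster enrichment finds exact-membership sets and ignores shuffles", {
  asg <- setNames(rep(1:3, each = 20), sprintf("g%02d", 1:60))
  gs <- gene_sets(list(
    exact2 = names(asg)[asg == 2],
    everything = names(asg),
    absent = c("zz1", "zz2")
  ), universe = c(names(asg), "zz1", "zz2"))
  expect_message(enr <- enrich_clusters(asg, gs), "skipping 1")
  e2 <- enr[enr$cluster == 2 & enr$set == "exact2", ]
  expect_equal(e2$overlap, 20)
  expect_equal(e2$p, 1 / choose(60, 20))   # smallest achievable p
  expect_equal(enr$p[enr$set == "everything"], rep(1, 3))

  # shuffled labels rarely reach q < 0.05
  set.seed(12)
  gs_rand <- gene_sets(lapply(setNames(1:8, paste0("S", 1:8)),
                              function(i) sample(names(asg), 15)))
  hits <- replicate(60, {
    shuffled <- setNames(sample(asg), names(asg))
    min(enrich_clusters(shuffled, gs_rand)$q)
  })
  expect_gte(mean(hits > 0.05), 0.9)
})
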