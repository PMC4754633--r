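test_that("BH adjustment matches the step-up definition and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_length(bh_adjust(numeric(0)), 0)
  set.seed(11)
  for (i in 1:10) {
    p <- runif(sample(3:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_by_definition(p))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))   # monotone in p
    expect_true(all(q <= 1))
  }
})

test_that("two-group test matches the pooled-t closed form and gates on variance", {
  a <- 1:5; b <- 2:6
  res <- two_group_test(a, b)
  expect_equal(res$method, "student")
  sp2 <- (4 * var(a) + 4 * var(b)) / 8
  t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  expect_equal(res$statistic, t_manual)
  expect_equal(res$df, 8)
  expect_equal(res$p, 2 * pt(-abs(t_manual), 8))

  # strongly unequal variances select the Welch branch
  set.seed(2)
  a2 <- rnorm(5, sd = 0.1); b2 <- rnorm(5, sd = 10)
  res2 <- two_group_test(a2, b2)
  expect_lt(res2$var_p, 0.05)
  expect_equal(res2$method, "welch")
  expect_lt(res2$df, 8)   # Satterthwaite df below pooled df

  # identical groups, and the degenerate constant cases
  expect_equal(two_group_test(c(1, 2, 3), c(1, 2, 3))$p, 1)
  cc <- two_group_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(c(cc$statistic, cc$p), c(0, 1))
  dd <- two_group_test(c(2, 2, 2), c(5, 5, 5))
  expect_equal(dd$p, 0)
  expect_true(dd$degenerate)
})

test_that("two-group test is symmetric under swapping the groups", {
  set.seed(3)
  a <- rnorm(6); b <- rnorm(7, 1)
  r1 <- two_group_test(a, b); r2 <- two_group_test(b, a)
  expect_equal(r1$statistic, -r2$statistic)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$method, r2$method)
})

test_that("Kruskal-Wallis H matches the rank-sum formula and the exact null", {
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  res <- kruskal_wallis(g)
  expect_equal(res$statistic, kw_h_by_formula(g))

  # exact p by the package vs brute-force enumeration over permutations
  ex <- kruskal_wallis(g, exact = TRUE)
  pm <- perm_matrix(6)
  x <- unlist(g)
  hs <- apply(pm, 1, function(idx)
    kw_h_by_formula(list(x[idx[1:2]], x[idx[3:4]], x[idx[5:6]])))
  expect_equal(ex$p, mean(hs >= res$statistic - 1e-9))

  # tied data: tie-corrected H still matches the enumeration
  gt <- list(c(1, 1), c(2, 3), c(3, 3))
  ext <- kruskal_wallis(gt, exact = TRUE)
  xt <- unlist(gt)
  hst <- apply(pm, 1, function(idx)
    kw_h_by_formula(list(xt[idx[1:2]], xt[idx[3:4]], xt[idx[5:6]])))
  expect_equal(ext$p, mean(hst >= ext$statistic - 1e-9))

  expect_equal(kruskal_wallis(list(c(1, 1), c(1, 1)))$p, 1)
})

test_that("Kruskal-Wallis is invariant to strictly monotone transforms", {
  set.seed(5)
  g <- list(rnorm(4), rnorm(5, 1), rnorm(3, 2))
  r1 <- kruskal_wallis(g)
  r2 <- kruskal_wallis(lapply(g, function(v) exp(3 * v)))
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p, r2$p)
})

test_that("hypergeometric enrichment equals brute-force tail sums", {
  u <- sprintf("g%02d", 1:20)
  cat10 <- u[1:10]
  hits <- u[1:5]
  res <- hypergeom_enrich(hits, cat10, u)
  expect_equal(res$overlap, 5)
  expect_equal(res$p, choose(10, 5) / choose(20, 5))   # single tail term

  # generic instance vs explicit pmf summation
  hits2 <- u[c(1:3, 11, 12)]
  res2 <- hypergeom_enrich(hits2, cat10, u)
  tail_sum <- sum(vapply(3:5, function(k)
    choose(10, k) * choose(10, 5 - k) / choose(20, 5), numeric(1)))
  expect_equal(res2$p, tail_sum)

  expect_equal(hypergeom_enrich(hits, u, u)$p, 1)      # category = universe
  expect_equal(hypergeom_enrich(u[11:15], u[1:10], u)$overlap, 0)
  expect_equal(hypergeom_enrich(u[11:15], u[1:10], u)$p, 1)
  expect_error(hypergeom_enrich(hits, cat10, character(0)), "universe")
})

test_that("moderated F matches limma's variance shrinkage and the unmoderated limit", {
  skip_if_not_installed("limma")
  sim <- sim_rhythmic(n_features = 300, sigma = 0.3, seed = 17)
  de <- moderated_f_test(sim$tcm)
  d <- ncol(sim$tcm$values) - 8
  sq <- limma::squeezeVar(de$s2, df = d)
  expect_equal(attr(de, "d0"), sq$df.prior, tolerance = 1e-6)
  expect_equal(de$s2_post, sq$var.post, tolerance = 1e-8)

  # moderation off reduces to the ordinary one-way F
  plain <- moderated_f_test(sim$tcm, moderate = FALSE)
  f_manual <- vapply(rownames(sim$tcm$values)[1:5], function(f) {
    fit <- aov(sim$tcm$values[f, ] ~ interaction(sim$tcm$samples$group,
                                                 sim$tcm$samples$zt))
    summary(fit)[[1]]$`F value`[1]
  }, numeric(1))
  expect_equal(unname(plain$F[1:5]), unname(f_manual), tolerance = 1e-10)
})

test_that("features with large planted condition effects are all flagged", {
  sim <- sim_rhythmic(n_features = 100, class_mix = c(0, 0, 0, 0, 0, 1),
                      sigma = 0.2, seed = 23)
  vals <- sim$tcm$values
  shifted <- sim$tcm$samples$group == "GF"
  vals[1:20, shifted] <- vals[1:20, shifted] + 5 * 0.2   # 5 sigma shift
  tc <- time_course(vals, sim$tcm$samples)
  de <- moderated_f_test(tc)
  expect_true(all(de$significant[1:20]))
})

test_that("per-ZT comparisons report both branches with one BH family", {
  sim <- sim_rhythmic(n_features = 10, sigma = 0.3, seed = 29)
  cmp <- compare_groups_by_zt(sim$tcm)
  expect_equal(nrow(cmp), 40)               # 10 features x 4 ZT
  expect_equal(cmp$q, bh_by_definition(cmp$p))
  expect_true(all(cmp$stars %in% c("", "*", "**", "***")))
  pf <- compare_groups_by_zt(sim$tcm, family = "per_feature")
  one <- pf[pf$feature == "f0001", ]
  expect_equal(one$q, bh_by_definition(one$p))
})
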