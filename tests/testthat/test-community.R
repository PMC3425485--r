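test_that("Bray-Curtis follows its defining formula and bounds", {
  expect_equal(bray_curtis(c(1, 2, 3), c(2, 2, 1)), 3 / 11)
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0, 2), c(0, 5, 0)), 1)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  set.seed(2)
  for (rep in 1:50) {
    x <- rpois(6, 3); y <- rpois(6, 3)
    if (sum(x + y) == 0) next
    d <- bray_curtis(x, y)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, bray_curtis(y, x))
    if (d == 0) expect_equal(x, y)
  }
})

test_that("Bray-Curtis agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(8)
  M <- matrix(rpois(30, 4), 5, 6)
  D <- as.matrix(vegan::vegdist(M, "bray"))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(bray_curtis(M[i, ], M[j, ]), D[i, j], tolerance = 1e-12)
  }
})

test_that("row normalization yields unit row sums and is idempotent", {
  M <- rbind(c(2, 2, 0), c(1, 3, 4))
  N <- row_normalize(M)
  expect_equal(N[1, ], c(0.5, 0.5, 0))
  expect_equal(unname(rowSums(N)), c(1, 1))
  expect_equal(row_normalize(N), N)
  expect_warning(row_normalize(rbind(M, 0)), "all-zero")
  set.seed(3)
  R <- matrix(runif(40), 8, 5)
  expect_equal(unname(rowSums(row_normalize(R))), rep(1, 8))
})

test_that("the rare-species filter drops under-sampled columns", {
  M <- matrix(1, 40, 3, dimnames = list(NULL, c("A", "B", "C")))
  M[, 2] <- 0; M[3, 2] <- 1  # present at 1/40 = 2.5% of sites
  expect_equal(colnames(filter_rare(M, 0.05)), c("A", "C"))
  expect_equal(filter_rare(M, 0), M)
  expect_true("A" %in% colnames(filter_rare(M, 0.99)))
  expect_error(filter_rare(matrix(0, 40, 3), 0.05), "every species")
  # boundary: occurrence exactly at the threshold is kept under strict <
  M20 <- matrix(1, 20, 2, dimnames = list(NULL, c("A", "B")))
  M20[, 2] <- 0; M20[1, 2] <- 1  # 1/20 = 5%
  expect_equal(ncol(filter_rare(M20, 0.05)), 2)
  expect_equal(ncol(filter_rare(M20, 0.05, inclusive = TRUE)), 1)
})

test_that("MRPP permutation p matches exhaustive enumeration on 6 sites", {
  set.seed(10)
  M <- matrix(rpois(24, 5) + 1, 6, 4)
  groups <- rep(c("m", "x"), each = 3)
  res <- mrpp(M, groups, n_perm = 4999, seed = 123)
  expect_equal(res$delta_observed, oracle_delta(M, groups),
               tolerance = 1e-12)
  p_exact <- oracle_mrpp_exact_p(M, groups)
  # Monte-Carlo error of a proportion at n_perm = 4999
  expect_lt(abs(res$p_value - p_exact),
            3 * sqrt(p_exact * (1 - p_exact) / 4999) + 1 / 4999)
  expect_equal(res$A, 1 - res$delta_observed / res$delta_expected,
               tolerance = 1e-12)
})

test_that("MRPP behaves at the null and under perfect separation", {
  set.seed(12)
  M <- matrix(rpois(20 * 6, 4) + 1, 20, 6)
  res <- mrpp(M, sample(rep(c("m", "x"), 10)), n_perm = 499, seed = 9)
  expect_lt(abs(res$A), 0.2)

  # identical-within clusters: zero observed delta; only relabelings that
  # reproduce the partition (2 of the 20) tie it, so p sits at the
  # exhaustive-enumeration value 2/20
  M2 <- rbind(matrix(rep(c(5, 0, 1), 3), 3, byrow = TRUE),
              matrix(rep(c(0, 5, 4), 3), 3, byrow = TRUE))
  res2 <- mrpp(M2, rep(c("a", "b"), each = 3), n_perm = 999, seed = 2)
  expect_equal(res2$delta_observed, 0)
  expect_gte(res2$p_value, 1 / 1000)
  expect_lt(abs(res2$p_value - 2 / 20), 0.04)
})

test_that("MRPP errors on undersized groups and is seed-reproducible", {
  M <- matrix(rpois(15, 4) + 1, 5, 3)
  expect_error(mrpp(M, c("a", "a", "a", "a", "b"), 99, 1), "size 1")
  expect_error(mrpp(M, rep("a", 5), 99, 1), "2 groups")
  r1 <- mrpp(M, c("a", "a", "a", "b", "b"), 199, seed = 42)
  r2 <- mrpp(M, c("a", "a", "a", "b", "b"), 199, seed = 42)
  expect_identical(r1, r2)
})

test_that("MRPP agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(14)
  M <- matrix(rpois(48, 6) + 1, 8, 6)
  groups <- rep(c("m", "x"), each = 4)
  ours <- mrpp(M, groups, n_perm = 1999, seed = 5)
  vg <- vegan::mrpp(vegan::vegdist(M, "bray"), groups,
                    permutations = 1999, weight.type = 1)
  expect_equal(ours$delta_observed, vg$delta, tolerance = 1e-10)
  expect_equal(ours$A, vg$A, tolerance = 0.02)
  expect_lt(abs(ours$p_value - vg$Pvalue), 0.05)
})

test_that("Pielou evenness is 1 at equality and near 0 when dominated", {
  expect_equal(evenness(c(4, 4, 4, 4)), 1)
  expect_lt(evenness(c(99, 1)), 0.1)
  # direct H'/ln(2) evaluation
  p <- c(0.99, 0.01)
  expect_equal(evenness(c(99, 1)), -sum(p * log(p)) / log(2),
               tolerance = 1e-12)
  expect_equal(evenness(c(3, 7, 1)), evenness(c(7, 1, 3)))
  expect_warning(J <- evenness(c(5, 0, 0)), "fewer than 2")
  expect_true(is.na(J))
})

test_that("GUD ANOVA matches sums-of-squares and t-test oracles", {
  set.seed(16)
  y <- c(rnorm(8, 3), rnorm(9, 9))
  g <- rep(c("mesic", "xeric"), c(8, 9))
  a <- gud_anova(y, g)
  expect_equal(a$F, oracle_anova_F(y, g), tolerance = 1e-10)
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a$p_value, tt$p.value, tolerance = 1e-10)
  expect_equal(a$df1, 1); expect_equal(a$df2, 15)
  expect_equal(a$group_stats$mean,
               c(mean(y[g == "mesic"]), mean(y[g == "xeric"])))

  # identical group means: F ~ 0
  y0 <- c(1, 2, 3, 1, 2, 3)
  a0 <- gud_anova(y0, rep(c("a", "b"), each = 3))
  expect_equal(a0$F, 0, tolerance = 1e-12)

  # three-group toy set against the explicit oracle
  y3 <- c(1, 2, 4, 5, 9, 8)
  g3 <- rep(c("a", "b", "c"), each = 2)
  expect_equal(gud_anova(y3, g3)$F, oracle_anova_F(y3, g3),
               tolerance = 1e-10)
})

test_that("ANCOVA recovers a generated interaction and flags degeneracy", {
  set.seed(18)
  n <- 120
  g <- rep(c("mesic", "xeric"), each = n / 2)
  d <- runif(n, 1, 14)
  delta <- -0.4
  y <- 10 - 0.5 * d + (g == "xeric") * (2 + delta * d) + rnorm(n, 0, 0.5)
  res <- gud_ancova(y, g, d)
  expect_equal(res$interaction_estimate, delta, tolerance = 0.1)
  expect_lt(res$interaction_p, 0.001)
  expect_error(gud_ancova(y[g == "mesic"], g[g == "mesic"],
                          d[g == "mesic"]), "2 groups")
})

test_that("the paired microhabitat test matches its closed form", {
  pairs <- data.frame(yard_id = rep(c("Y1", "Y2", "Y3"), each = 2),
                      species = "HOSP",
                      microhabitat = rep(c("bush", "open"), 3),
                      gud = c(6, 5, 8, 6, 10, 7))  # diffs 1, 2, 3
  r <- paired_microhabitat_test(pairs)
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(r$df, 2)
  expect_equal(r$mean_diff, 2)

  # all-zero differences: t = 0, p = 1
  pairs0 <- pairs; pairs0$gud <- rep(c(4, 4), 3)
  r0 <- paired_microhabitat_test(pairs0)
  expect_equal(r0$t, 0)
  expect_equal(r0$p_value, 1)

  # unvisited side imputed at G0 adds a pair
  pairs_miss <- rbind(pairs, data.frame(
    yard_id = "Y4", species = "HOSP", microhabitat = "bush", gud = 12))
  expect_equal(paired_microhabitat_test(pairs_miss)$n_pairs, 3)
  r_imp <- paired_microhabitat_test(pairs_miss, include_unvisited = TRUE,
                                    G0 = 20)
  expect_equal(r_imp$n_pairs, 4)
  expect_error(paired_microhabitat_test(pairs[1:2, ]), "fewer than 2")
})

test_that("rank statistics match exact enumeration and the KW identity", {
  # complete separation of 4 vs 4: the rank sum is maximal
  x <- c(10, 11, 12, 13); y <- c(1, 2, 3, 4)
  wz <- wilcoxon_z(x, y)
  expect_equal(wz$W, sum(5:8))
  expect_equal(oracle_ranksum_exact_p(x, y), 2 / choose(8, 4),
               tolerance = 1e-12)
  expect_gt(wz$Z, 2)

  # normal-approximation p agrees with wilcox.test without correction
  set.seed(20)
  for (rep in 1:20) {
    a <- rnorm(6); b <- rnorm(7, 0.5)
    wz <- wilcoxon_z(a, b)
    wt <- suppressWarnings(stats::wilcox.test(a, b, correct = FALSE,
                                              exact = FALSE))
    expect_equal(wz$p_value, wt$p.value, tolerance = 1e-10)
    # two untied groups: KW chi-square equals Z squared
    kw <- stats::kruskal.test(c(a, b), factor(rep(1:2, c(6, 7))))
    expect_equal(unname(kw$statistic), wz$Z^2, tolerance = 1e-10)
  }

  # identical distributions: Z near 0 (exact on mirrored data)
  expect_equal(wilcoxon_z(c(1, 3, 5, 7), c(2, 4, 6, 8))$Z,
               wilcoxon_z(c(2, 4, 6, 8), c(1, 3, 5, 7))$Z * -1)
  expect_true(wilcoxon_z(rep(1, 4), rep(1, 5))$degenerate)
})

test_that("rank tests on small samples agree with exact enumeration", {
  set.seed(22)
  for (rep in 1:10) {
    x <- round(rnorm(4), 2); y <- round(rnorm(4, 1), 2)
    p_exact <- oracle_ranksum_exact_p(x, y)
    p_norm <- wilcoxon_z(x, y)$p_value
    expect_lt(abs(p_norm - p_exact), 0.15)  # normal approx at n = 8
  }
})
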