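test_that("Bray-Curtis and Spearman distances match direct computation", {
  t3 <- rbind(a = c(0.2, 0.3, 0.1, 0.4),
              b = c(0.5, 0.1, 0.2, 0.2),
              c = c(0.0, 0.6, 0.4, 0.0))
  colnames(t3) <- paste0("sp", 1:4)
  d <- bray_curtis(t3)
  # direct formula oracle
  for (i in 1:3) for (j in 1:3)
    expect_equal(d[i, j], sum(abs(t3[i, ] - t3[j, ])) / sum(t3[i, ] + t3[j, ]))
  # identical samples at distance 0, disjoint supports at 1
  tt <- rbind(x = c(0.5, 0.5, 0, 0), y = c(0.5, 0.5, 0, 0), z = c(0, 0, 0.4, 0.6))
  colnames(tt) <- paste0("sp", 1:4)
  expect_equal(bray_curtis(tt)["x", "y"], 0)
  expect_equal(bray_curtis(tt)["x", "z"], 1)
  expect_equal(spearman_distance(tt)["x", "y"], 0)
  # all-zero sample rejected
  bad <- rbind(x = c(0.5, 0.5), y = c(0, 0)); colnames(bad) <- c("sp1", "sp2")
  expect_error(bray_curtis(bad), "all-zero")
})

test_that("PCoA has the two-sample closed form and preserves Euclidean geometry", {
  D2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  co <- pcoa(D2, k = 1)
  expect_equal(unname(abs(co$coordinates[, 1])), c(1.5, 1.5))
  # planar points: recovered inter-point distances match within 1e-8
  set.seed(4)
  pts <- matrix(rnorm(20), 10, 2)
  D <- as.matrix(dist(pts)); dimnames(D) <- list(paste0("s", 1:10), paste0("s", 1:10))
  co2 <- pcoa(D, k = 2)
  expect_equal(as.matrix(dist(co2$coordinates)), D, ignore_attr = TRUE,
               tolerance = 1e-8)
  # degenerate all-zero distances
  D0 <- matrix(0, 3, 3, dimnames = list(1:3, 1:3))
  expect_error(pcoa(D0, k = 1), "degenerate")
  # k beyond positive eigenvalues truncates with a warning
  expect_warning(pcoa(D2, k = 2), "truncated")
})

test_that("PERMANOVA matches vegan::adonis2 on sequential terms", {
  skip_if_not_installed("vegan")
  g <- small_cohort()
  idx <- seq(1, nrow(g$table), by = 4)
  d <- bray_curtis(g$table[idx, ])
  md <- g$metadata[idx, ]
  terms <- c("country", "condition", "age_group", "condition:age_group")
  pv <- permanova(d, md, terms, n_perm = 99, seed = 1)
  av <- vegan::adonis2(stats::as.dist(d) ~ country + condition + age_group +
                         condition:age_group,
                       data = md, permutations = 99, by = "terms")
  expect_equal(pv$SumOfSqs, av$SumOfSqs, tolerance = 1e-10)
  expect_equal(pv$F[1:4], av$F[1:4], tolerance = 1e-10)
  expect_equal(pv$R2, av$R2, tolerance = 1e-10)
  expect_equal(pv$Df, av$Df)
})

test_that("exhaustive PERMANOVA equals the brute-force single-factor oracle", {
  set.seed(11)
  t6 <- matrix(abs(rnorm(6 * 5)), 6, 5,
               dimnames = list(paste0("s", 1:6), paste0("sp", 1:5)))
  t6 <- t6 / rowSums(t6)
  d <- bray_curtis(t6)
  f <- c("x", "x", "x", "y", "y", "y")
  md <- data.frame(sample_id = rownames(t6), grp = f)
  pv <- permanova(d, md, "grp", permutations = "exhaustive")
  oracle <- permanova_oracle(as.matrix(d), f)
  expect_equal(pv["grp", "F"], oracle$F, tolerance = 1e-8)
  expect_equal(pv["grp", "R2"], oracle$R2, tolerance = 1e-8)
  expect_equal(pv["grp", "Pr(>F)"], oracle$p, tolerance = 1e-8)
})

test_that("PERMANOVA permutation p is reproducible, nonzero, and order-invariant", {
  g <- small_cohort()
  idx <- seq(1, nrow(g$table), by = 9)
  d <- bray_curtis(g$table[idx, ])
  md <- g$metadata[idx, ]
  p1 <- permanova(d, md, "age_group", n_perm = 99, seed = 5)
  p2 <- permanova(d, md, "age_group", n_perm = 99, seed = 5)
  expect_identical(p1[["Pr(>F)"]], p2[["Pr(>F)"]])
  expect_gt(min(p1[["Pr(>F)"]], na.rm = TRUE), 0)
  # shuffling sample order leaves the decomposition unchanged
  ord <- sample(idx)
  p3 <- permanova(bray_curtis(g$table[ord, ]), g$metadata[ord, ],
                  "age_group", n_perm = 99, seed = 5)
  expect_equal(p3$R2, p1$R2, tolerance = 1e-10)
  expect_equal(sum(p1$SumOfSqs[1:2]), p1$SumOfSqs[3], tolerance = 1e-8)
})

test_that("PERMANOVA flags rank deficiency and drops incomplete samples", {
  g <- small_cohort()
  idx <- seq(1, nrow(g$table), by = 12)
  d <- bray_curtis(g$table[idx, ])
  md <- g$metadata[idx, ]
  md$dup <- md$age_group
  expect_error(permanova(d, md, c("age_group", "dup"), n_perm = 99), "dup")
  md2 <- md
  md2$age_group[1:2] <- NA
  expect_warning(pv <- permanova(d, md2, "age_group", n_perm = 99, seed = 1),
                 "dropped")
  expect_equal(pv["Total", "Df"], length(idx) - 3)
  expect_error(permanova(d, md[, "sample_id", drop = FALSE], "missing_cov"),
               "missing_cov")
})

test_that("bootstrapped factor screening separates a planted batch from its null", {
  cfg <- generator_config(
    n_species = 40,
    cohorts = list(
      cohort_spec("S1", "C1", "K1", "kitA", "D1",
                  n_control = c(Young = 40, Middle = 0, Elderly = 0),
                  n_case = c(Young = 0, Middle = 0, Elderly = 0)),
      cohort_spec("S2", "C1", "K1", "kitB", "D1",
                  n_control = c(Young = 40, Middle = 0, Elderly = 0),
                  n_case = c(Young = 0, Middle = 0, Elderly = 0))),
    diseases = "D1", sigma_batch = 1.2,
    marker_spec = list(D1 = list(fraction = 0)), seed = 21)
  g <- generate_cohort(cfg)
  res <- bootstrap_factor_effect(g$table, g$metadata, "dna_extraction",
                                 subsample_size = 40, n_iter = 10, seed = 3)
  # observed R2 stochastically above the permuted-label null
  expect_gt(median(res$observed$R2), median(res$null$R2))
  expect_true(mean(res$observed$R2 > max(res$null$R2) * 0.5) >= 0.8)
  expect_lt(median(res$observed$p), 0.05)
  expect_error(bootstrap_factor_effect(g$table, g$metadata, "dna_extraction",
                                       subsample_size = 1000), "exceeds")
})

test_that("intra-group variability detects a higher-dispersion group", {
  set.seed(9)
  profile <- exp(seq(0, 3, length.out = 20))
  base <- t(replicate(50, profile * exp(rnorm(20, 0, 0.15))))
  noisy <- t(replicate(50, profile * exp(rnorm(20, 0, 0.9))))
  tab <- rbind(base, noisy)
  rownames(tab) <- paste0("s", 1:100); colnames(tab) <- paste0("sp", 1:20)
  tab <- tab / rowSums(tab)
  d <- spearman_distance(tab)
  res <- intra_group_variability(d, rep(c("tight", "wide"), each = 50))
  expect_gt(median(res$distances$wide), median(res$distances$tight))
  expect_lt(res$tests$p[1], 0.05)
  # identical samples give all-zero within distances; tiny groups are excluded
  t2 <- tab[c(1, 1, 1, 2, 3, 4), ]
  rownames(t2) <- paste0("r", 1:6)
  d2 <- bray_curtis(t2 + 1e-9)
  expect_warning(res2 <- intra_group_variability(d2, c("a", "a", "a", "b", "b", "c")),
                 "excluded")
  expect_true(all(res2$distances$a < 1e-6))
})
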