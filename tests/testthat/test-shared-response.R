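mk_dir <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(disease = r[[1]], taxon = r[[2]], age_group = r[[3]],
               direction = as.numeric(r[[4]]))))
}

test_that("shared-group rules reproduce the G1-L3 definitions", {
  d <- mk_dir(
    # tx1: gained in 2 diseases in all age groups -> G1
    list("d1", "tx1", "Young", 1), list("d1", "tx1", "Elderly", 1),
    list("d2", "tx1", "Middle", 1), list("d2", "tx1", "Elderly", 1),
    # tx2: gained in 2 diseases only in the elderly -> G2
    list("d1", "tx2", "Elderly", 1), list("d2", "tx2", "Elderly", 1),
    list("d1", "tx2", "Young", 0), list("d2", "tx2", "Middle", 0),
    # tx3: gained young/middle only -> G3
    list("d1", "tx3", "Young", 1), list("d2", "tx3", "Middle", 1),
    # tx4: lost everywhere -> L1
    list("d1", "tx4", "Young", -1), list("d1", "tx4", "Elderly", -1),
    list("d2", "tx4", "Middle", -1), list("d2", "tx4", "Elderly", -1),
    # tx5: one disease only -> none
    list("d1", "tx5", "Young", 1), list("d1", "tx5", "Elderly", 1),
    # tx6: conflicting directions within a band -> none
    list("d1", "tx6", "Young", 1), list("d1", "tx6", "Middle", -1),
    list("d2", "tx6", "Young", 1), list("d2", "tx6", "Middle", 1),
    list("d1", "tx6", "Elderly", 1), list("d2", "tx6", "Elderly", 1),
    # tx7: lost only in the elderly -> L2
    list("d1", "tx7", "Elderly", -1), list("d2", "tx7", "Elderly", -1),
    # tx8: gained in one band, lost in the other -> none (mixed)
    list("d1", "tx8", "Young", 1), list("d2", "tx8", "Young", 1),
    list("d1", "tx8", "Elderly", -1), list("d2", "tx8", "Elderly", -1))
  out <- assign_shared_groups(d)
  got <- setNames(out$group, out$taxon)
  expect_equal(got[c("tx1", "tx2", "tx3", "tx4", "tx5", "tx7", "tx8")],
               c(tx1 = "G1", tx2 = "G2", tx3 = "G3", tx4 = "L1", tx5 = "none",
                 tx7 = "L2", tx8 = "none"))
  # tx6's young/middle conflict removes d1's vote; d2 alone still qualifies
  # the elderly band via both diseases -> G2
  expect_equal(unname(got["tx6"]), "G2")
  # order invariance and one label per taxon
  out2 <- assign_shared_groups(d[sample(nrow(d)), ])
  expect_equal(out2, out)
  expect_equal(anyDuplicated(out$taxon), 0)
})

test_that("Fisher's method matches its closed form", {
  expect_equal(fisher_method(c(1, 1))$p, 1)
  fm <- fisher_method(c(0.05, 0.05))
  expect_equal(fm$chisq, -4 * log(0.05), tolerance = 1e-10)
  expect_equal(fm$chisq, 11.98, tolerance = 1e-3)
  expect_equal(fm$df, 4)
  expect_equal(fm$p, pchisq(-4 * log(0.05), 4, lower.tail = FALSE), tolerance = 1e-10)
  expect_lt(abs(fm$p - 0.0175), 5e-4)
  expect_error(fisher_method(c(0, 0.5)), "in \\(0, 1\\]")
})

test_that("Cohen's D follows its definition", {
  set.seed(3)
  x <- rnorm(4000, 1, 1); y <- rnorm(4000, 0, 1)
  expect_lt(abs(cohens_d(x, y) - 1), 0.06)
  expect_lt(abs(cohens_d(y[1:100], y[101:200])), 0.3)
  expect_true(is.na(cohens_d(rep(1, 5), rep(1, 5))))
})

test_that("feature-rank stability spans self-similarity to anti-correlation", {
  set.seed(8)
  profile <- c(10, 8, 6, 4, 2, 1)
  mk <- function(noise) {
    m <- t(replicate(10, profile + rnorm(6, 0, noise)))
    colnames(m) <- paste0("t", 1:6)
    m
  }
  # two cohorts sharing the same planted signal: low distances
  expect_lt(median(feature_rank_stability(mk(0.3), mk(0.3))), 0.2)
  # independent random importances: distances near 1
  indep <- matrix(rexp(10 * 6), 10, 6, dimnames = list(NULL, paste0("t", 1:6)))
  expect_gt(median(feature_rank_stability(mk(0.3), indep)), 0.5)
  # exact reversal attains the distance bound of 2
  v <- matrix(rep(1:6, 2), 2, 6, byrow = TRUE, dimnames = list(NULL, paste0("t", 1:6)))
  w <- matrix(rep(6:1, 2), 2, 6, byrow = TRUE, dimnames = list(NULL, paste0("t", 1:6)))
  expect_equal(unname(feature_rank_stability(v, w)), rep(2, 4))
  expect_error(feature_rank_stability(v[1, , drop = FALSE], w), ">= 2 iterations")
})

test_that("prevalence shift computes per-cohort ratios and combined p-values", {
  tab1 <- rbind(matrix(c(1, 0), 10, 2, byrow = TRUE),
                matrix(c(1, 1), 10, 2, byrow = TRUE)) * 0.5
  rownames(tab1) <- paste0("a", 1:20); colnames(tab1) <- c("tx1", "tx2")
  md1 <- data.frame(sample_id = rownames(tab1), condition = "control",
                    age_group = rep(c("Young", "Elderly"), each = 10))
  co <- list(c1 = list(table = tab1, metadata = md1),
             c2 = list(table = tab1, metadata = md1))
  ps <- prevalence_shift(co, c("tx1", "tx2"))
  # tx1 prevalent everywhere: ratio 0, Fisher p 1, combined p 1
  expect_equal(ps$per_cohort$log2_ratio[ps$per_cohort$taxon == "tx1"], c(0, 0))
  expect_equal(ps$combined$p[ps$combined$taxon == "tx1"], 1)
  # tx2 detected only in elderly: strong positive ratio
  tx2 <- ps$per_cohort[ps$per_cohort$taxon == "tx2", ]
  expect_true(all(tx2$prev_elderly == 1 & tx2$prev_ym == 0))
  expect_lt(ps$combined$p[ps$combined$taxon == "tx2"], 0.001)
})

test_that("effect-size iterations flag masked elderly signatures", {
  cfg <- study_config("masking", seed = 77)
  g <- generate_cohort(cfg)
  gain <- names(which(apply(g$truth$delta > 0, 1, any)))[1:5]
  es <- effect_size_iterations(g$table, g$metadata, gain, n_per_arm = 20,
                               n_iter = 25, seed = 4)
  med <- aggregate(d ~ band, data = es, median)
  # carrier acquisition in elderly controls shrinks the case-control effect
  expect_lt(med$d[med$band == "elderly"], med$d[med$band == "ym"])
  # identical arms give near-zero effect sizes
  null_es <- effect_size_iterations(
    g$table, transform(g$metadata,
                       condition = sample(g$metadata$condition)),
    gain[1], n_per_arm = 20, n_iter = 25, seed = 5)
  expect_lt(abs(median(null_es$d)), 0.4)
})

test_that("generic classifiers are perfect under perfect planted separation", {
  set.seed(10)
  n <- 80
  tab <- matrix(abs(rnorm(n * 10, 1, 0.1)), n, 10)
  case <- rep(c(TRUE, FALSE), each = n / 2)
  tab[case, 1] <- tab[case, 1] + 10
  tab <- tab / rowSums(tab)
  rownames(tab) <- paste0("s", 1:n); colnames(tab) <- paste0("sp", 1:10)
  md <- data.frame(sample_id = rownames(tab),
                   condition = ifelse(case, "disease", "control"),
                   disease = ifelse(case, "dX", "none"),
                   age_group = rep(c("Young", "Elderly"), n / 2))
  ev <- generic_classifier_evaluation(tab, md, per_disease_n = 10,
                                      n_repeats = 3, num_trees = 100, seed = 2)
  expect_true(all(ev$results$auc == 1))
  expect_true(all(ev$results$sensitivity == 1))
  expect_true(all(ev$results$specificity == 1))
  expect_error(generic_classifier_evaluation(tab, md, per_disease_n = 100),
               "no disease qualifies")
})
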