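mk_scores <- function(mats) compute_marker_scores(mats)

test_that("marker scores rank a fixed importance toy as expected", {
  m <- rbind(c(0, 5, 1, 3), c(0, 4, 2, 3), c(0, 6, 0, 3))
  colnames(m) <- paste0("t", 1:4)
  sc <- mk_scores(list(Young = m))
  df <- sc$Young
  expect_equal(df$mean_importance, c(0, 5, 1, 3), ignore_attr = TRUE)
  expect_equal(order(df$percentile), order(c(0, 5, 1, 3)))
  expect_equal(df$percentile[2], 100)
  expect_equal(df$inclusion, c(0, 1, 2 / 3, 1), ignore_attr = TRUE)
  # the never-used taxon sits in the lowest percentile band
  expect_equal(which.min(df$percentile), 1)
  # taxa mismatch across runs is refused
  m2 <- m; colnames(m2) <- paste0("u", 1:4)
  expect_error(mk_scores(list(Young = m, Middle = m2)), "mismatch")
})

test_that("stability threshold follows the inclusion staircase", {
  # construct importances giving a clean staircase: top-ranked taxa always
  # included, lower ones included in half the iterations
  stable <- matrix(rep(c(10, 8, 6), each = 20), 20, 3,
                   dimnames = list(NULL, paste0("s", 1:3)))
  flaky <- matrix(rbinom(20 * 5, 1, 0.5) * 2, 20, 5)
  m <- cbind(stable, flaky)
  colnames(m) <- paste0("t", 1:8)
  sc <- mk_scores(list(Young = m))
  th <- stability_threshold(sc, min_inclusion = 0.95)
  staircase <- sc$Young
  failing_max <- max(staircase$percentile[staircase$inclusion < 0.95])
  expect_equal(unname(th["Young"]),
               min(staircase$percentile[staircase$percentile > failing_max]))
  # all-stable taxa give threshold 0
  sc_all <- mk_scores(list(Young = stable + 1))
  expect_equal(unname(stability_threshold(sc_all)["Young"]), 0)
  # the 85th-percentile operating point selects the top 15 percent of taxa
  mk <- select_markers(sc, percentile = 85)
  expect_true(all(mk$Young %in% c("t1", "t2")))
})

test_that("warning and 100 returned when even the top taxon is unstable", {
  m <- matrix(rbinom(40, 1, 0.5), 20, 2); colnames(m) <- c("a", "b")
  sc <- mk_scores(list(Young = m))
  expect_warning(th <- stability_threshold(sc), "100")
  expect_equal(unname(th["Young"]), 100)
})

test_that("Dunn's pairwise z statistics match the rank-sum formula", {
  # 6 untied values in 3 groups: mean ranks 1.5 / 3.5 / 5.5,
  # se = sqrt(N(N+1)/12 * (1/2 + 1/2)) = sqrt(3.5)
  res <- agemark:::dunn_test(c(1, 2, 3, 4, 5, 6), c("a", "a", "b", "b", "c", "c"))
  expect_equal(res$z[res$group1 == "a" & res$group2 == "b"], -2 / sqrt(3.5))
  expect_equal(res$z[res$group1 == "a" & res$group2 == "c"], -4 / sqrt(3.5))
  expect_equal(res$p, 2 * pnorm(-abs(res$z)))
})

test_that("cross-group comparison flags single-group importance and stays calibrated", {
  set.seed(14)
  null_m <- function() matrix(rexp(30 * 20), 30, 20,
                              dimnames = list(NULL, paste0("t", 1:20)))
  mats <- list(Young = null_m(), Middle = null_m(), Elderly = null_m())
  mats$Young[, "t1"] <- mats$Young[, "t1"] + 10  # planted group difference
  out <- compare_importance_across_groups(mk_scores(mats), fdr = 0.01)
  expect_true(out$significant[out$taxon == "t1"])
  # identical distributions elsewhere: no other rejection expected at FDR 0.01
  expect_lte(sum(out$significant), 2)
  expect_true(all(diff(out$p_adj[order(out$p)]) >= -1e-12))  # BH monotone
  # two-group path uses Mann-Whitney with full separation -> minimal p
  two <- list(Young = null_m()[, 1:3], Elderly = null_m()[, 1:3] + 100)
  out2 <- compare_importance_across_groups(mk_scores(two), fdr = 0.01)
  expect_true(all(out2$significant))
})

test_that("LLR deconvolution detects planted interactions and stays nested", {
  g <- generate_cohort(study_config("mixed", seed = 44))
  llr <- llr_deconvolution(g$table, g$metadata)
  truth <- g$truth$age_specific$D1
  expect_true(all(llr$llr[llr$testable] >= -1e-8))  # nested models
  expect_true(all(llr$df[llr$testable] == 2))
  hits <- llr$taxon[llr$p < 0.05 & llr$testable]
  expect_gte(length(intersect(hits, truth)) / length(truth), 0.7)
  # interaction beats the main-effects model on AIC for planted taxa
  planted <- llr[llr$taxon %in% truth, ]
  expect_gt(mean(planted$aic2 < planted$aic1), 0.7)
})

test_that("LLR flags a disease observed in one age group only as not testable", {
  g <- small_cohort()
  md <- g$metadata
  keep <- md$condition == "control" | md$age_group == "Young"
  res <- llr_deconvolution(g$table[keep, , drop = FALSE], md[keep, , drop = FALSE],
                           taxa = colnames(g$table)[1:3])
  expect_true(all(!res$testable))
})

test_that("directionality recovers planted signs and respects thresholds", {
  g <- generate_cohort(study_config("shared", seed = 55))
  bin <- build_disease_bins(g$metadata, "D1", "country")
  keep <- g$metadata$sample_id %in% bin$sample_ids
  dt <- directionality(g$table[keep, ], g$metadata[keep, ],
                       g$truth$markers$D1, level = "continent", fdr = 0.1)
  truth_dir <- g$truth$directions
  called <- dt[dt$direction != 0, ]
  agree <- mapply(function(tx, gr) truth_dir[tx, gr, "D1"],
                  called$taxon, called$age_group) == called$direction
  expect_gte(mean(agree), 0.9)
  # a taxon absent in both arms gets direction 0 and p 1
  tab0 <- cbind(g$table[keep, ], zero_tx = 0)
  dt0 <- directionality(tab0, g$metadata[keep, ], "zero_tx")
  expect_true(all(dt0$direction == 0))
  expect_true(all(dt0$p == 1))
})
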