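test_that("generation is deterministic and compositionally closed", {
  cfg <- generator_config(n_species = 40, seed = 7)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$table, g2$table)
  expect_identical(g1$metadata, g2$metadata)
  expect_true(all(abs(rowSums(g1$table) - 1) < 1e-9))
  expect_true(all(g1$metadata$age_group == assign_age_group(g1$metadata$age)))
})

test_that("null model without planted effects is symmetric across groups", {
  cfg <- generator_config(
    n_species = 30,
    cohorts = list(cohort_spec("S1", "C1", "K1", "kitA", "D1",
                               n_control = c(Young = 150, Middle = 150, Elderly = 150),
                               n_case = c(Young = 0, Middle = 0, Elderly = 0))),
    diseases = "D1",
    sigma_country = 0, sigma_batch = 0, sigma_age = 0,
    marker_spec = list(D1 = list(fraction = 0)),
    prevalence = list(tau = -Inf, s = 1), seed = 8)
  g <- generate_cohort(cfg)
  expect_true(all(g$table > 0))  # no zeros when tau = -Inf
  m_young <- colMeans(g$table[g$metadata$age_group == "Young", ])
  m_eld <- colMeans(g$table[g$metadata$age_group == "Elderly", ])
  # same generative distribution in every group: means agree within MC error
  expect_lt(max(abs(m_young - m_eld)) / max(m_young), 0.25)
})

test_that("planted age-specific effect magnitude is recovered", {
  cfg <- generator_config(
    n_species = 200,
    cohorts = list(cohort_spec("S1", "C1", "K1", "kitA", "D1",
                               n_control = c(Young = 200, Middle = 5, Elderly = 200),
                               n_case = c(Young = 200, Middle = 5, Elderly = 200))),
    diseases = "D1",
    marker_spec = list(D1 = list(species = "sp001",
                                 effect = c(Young = 2, Middle = 0, Elderly = 0))),
    prevalence = list(tau = -Inf, s = 1), seed = 9)
  g <- generate_cohort(cfg)
  md <- g$metadata
  gap <- function(grp) {
    d <- log(g$table[md$age_group == grp & md$condition == "disease", "sp001"])
    c <- log(g$table[md$age_group == grp & md$condition == "control", "sp001"])
    mean(d) - mean(c)
  }
  expect_lt(abs(gap("Young") - 2), 0.2)
  expect_lt(abs(gap("Elderly") - 0), 0.2)
})

test_that("zero samples or empty detection fail loudly", {
  cfg <- generator_config(cohorts = list(
    cohort_spec("S1", "C1", "K1", "kitA", "D1",
                n_control = c(Young = 0, Middle = 0, Elderly = 0),
                n_case = c(Young = 0, Middle = 0, Elderly = 0))))
  expect_error(generate_cohort(cfg), "zero samples")
  cfg2 <- generator_config(
    n_species = 5,
    cohorts = list(cohort_spec("S1", "C1", "K1", "kitA", "D1",
                               n_control = c(Young = 3, Middle = 0, Elderly = 0),
                               n_case = c(Young = 0, Middle = 0, Elderly = 0))),
    prevalence = list(tau = 50, s = 0), seed = 1)
  expect_error(generate_cohort(cfg2), "detected no species")
})

test_that("metabolite map density, extremes and duplicate labels behave", {
  expect_equal(mean(generate_metabolite_map(50, "a_production", density = 0)$matrix), 0)
  expect_equal(mean(generate_metabolite_map(50, "a_production", density = 1)$matrix), 1)
  m <- generate_metabolite_map(1000, sprintf("p%02d_consumption", 1:50),
                               density = 0.3, seed = 5)
  expect_lt(abs(mean(m$matrix) - 0.3), 0.02)
  expect_true(all(m$profiles$direction == "consumption"))
  expect_error(generate_metabolite_map(10, c("x_production", "x_production")),
               "duplicate")
  f <- generate_metabolite_map(10, "y_production", density = 0, seed = 1,
                               forced = list(y_production = c("sp001", "sp003")))
  expect_equal(sum(f$matrix), 2)
})

test_that("frailty scores follow the weighted log-abundance model", {
  g <- small_cohort()
  w0 <- stats::setNames(rep(0, 60), colnames(g$table))
  cfg0 <- generator_config(n_species = 60, seed = 101,
                           frailty = list(base = 77, weights = w0, noise_sd = 0))
  s0 <- generate_frailty_scores(g$table, NULL, cfg0)
  expect_true(all(s0$score == 77))

  w <- stats::setNames(rep(0, 60), colnames(g$table)); w["sp010"] <- 1
  cfg1 <- generator_config(n_species = 60, seed = 101,
                           frailty = list(base = 70, weights = w, noise_sd = 0))
  s1 <- generate_frailty_scores(g$table, NULL, cfg1)
  ord <- order(g$table[, "sp010"])
  expect_true(all(diff(s1$score[ord]) <= 0))  # monotone decreasing in abundance

  cfg5 <- generator_config(n_species = 60, seed = 101,
                           frailty = list(n_taxa = 5, weight = 3, noise_sd = 0.2))
  s5 <- generate_frailty_scores(g$table, g$truth, cfg5)
  w5 <- g$truth$frailty_weights
  target <- -as.numeric(log(g$table + 1e-6) %*%
                          stats::setNames(rep(3, 5), names(which(w5 > 0)))[colnames(g$table)])
  # regenerate the weighted sum independently and compare ranks
  w_vec <- stats::setNames(rep(0, 60), colnames(g$table))
  w_vec[names(which(w5 > 0))] <- 3
  target <- -as.numeric(log(g$table + 1e-6) %*% w_vec)
  expect_gt(cor(s5$score, target, method = "spearman"), 0.95)
})

test_that("truth sidecar round-trips the planted structure", {
  g <- small_cohort()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth(g$truth, path)
  back <- read.delim(path)
  expect_equal(nrow(back), 60 * 3 * 2)
  expect_equal(sort(unique(back$species[back$delta != 0 & back$disease == "D1"])),
               sort(g$truth$markers$D1))
})
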