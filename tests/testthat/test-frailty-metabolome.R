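test_that("metabolite profiles are the abundance-map inner product", {
  tab <- toy_table()
  m <- matrix(c(1, 0, 1,  0, 0, 0,  1, 1, 1), 3, 3,
              dimnames = list(paste0("sp", 1:3), c("pA", "pB", "pC")))
  map <- structure(list(matrix = m,
                        profiles = data.frame(profile_id = c("pA", "pB", "pC"),
                                              direction = "production")),
                   class = "metabolite_map")
  prof <- metabolite_profiles(tab, map)
  expect_equal(prof["s1", "pA"], 0.7)  # 0.5 + 0.2 by hand
  expect_equal(unname(prof[, "pB"]), rep(0, 3))
  expect_equal(unname(prof[, "pC"]), unname(rowSums(tab)))
  # linearity: disjoint maps add
  mA <- map; mA$matrix[, c("pB", "pC")] <- 0
  mB <- map; mB$matrix[, c("pA", "pC")] <- 0
  expect_equal(metabolite_profiles(tab, mA)[, "pA"] +
                 metabolite_profiles(tab, mB)[, "pB"],
               prof[, "pA"] + prof[, "pB"])
  # zero species overlap is an error
  tab2 <- tab; colnames(tab2) <- paste0("zz", 1:3)
  expect_error(metabolite_profiles(tab2, map), "no species shared")
})

test_that("metabolite map TSV dialect round-trips with directions", {
  map <- generate_metabolite_map(12, c("a_production", "b_consumption",
                                       "c_degradation"),
                                 density = 0.4, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metabolite_map(map, path)
  back <- read_metabolite_map(path)
  expect_equal(back$matrix, map$matrix)
  expect_equal(back$profiles$direction,
               c("production", "consumption", "degradation"))
})

test_that("frailty regression finds signal when present and not when absent", {
  cfg <- study_config("frailty", seed = 91)
  g <- generate_cohort(cfg)
  sc <- generate_frailty_scores(g$table, g$truth, cfg)
  m <- frailty_regression(g$table, sc, cv_folds = 5, num_trees = 200, seed = 6)
  expect_gt(m$r, 0.5)
  expect_true(all(sort(m$importance_rank) == seq_len(ncol(g$table))))
  planted <- names(which(g$truth$frailty_weights > 0))
  expect_lte(max(m$importance_rank[planted]), 25)
  # shuffled scores carry no signal
  m0 <- frailty_regression(g$table, sample(sc$score), train_frac = 0.2,
                           num_trees = 200, seed = 7)
  expect_lt(abs(m0$r), 0.25)
  expect_error(frailty_regression(g$table, rep(1, nrow(g$table))), "constant")
})

test_that("group mean ranks reward predictive groups and handle edge cases", {
  model <- structure(list(importance_rank = c(a = 1, b = 2, c = 3, d = 4)),
                     class = "frailty_model")
  groups <- data.frame(taxon = c("a", "b", "c", "d"),
                       group = c("G1", "G1", "L1", "none"))
  gmr <- group_mean_ranks(model, groups)
  expect_equal(gmr, c(G1 = 1.5, L1 = 3))
  expect_false("none" %in% names(gmr))
  # single-taxon group holding rank 1
  g2 <- data.frame(taxon = "a", group = "G2")
  expect_equal(group_mean_ranks(model, g2), c(G2 = 1))
  # rank invariance under monotone importance transforms
  m1 <- structure(list(importance_rank = rank(-c(9, 4, 2, 1),
                                              ties.method = "first")), class = "frailty_model")
  m2 <- structure(list(importance_rank = rank(-log(c(9, 4, 2, 1)),
                                              ties.method = "first")), class = "frailty_model")
  names(m1$importance_rank) <- names(m2$importance_rank) <- letters[1:4]
  expect_equal(group_mean_ranks(m1, groups), group_mean_ranks(m2, groups))
})

test_that("minimal marker set recovers a single informative taxon at small k", {
  set.seed(12)
  n <- 120
  tab <- matrix(abs(rnorm(n * 20, 1, 0.3)), n, 20)
  rownames(tab) <- paste0("s", 1:n); colnames(tab) <- paste0("sp", 1:20)
  tab <- tab / rowSums(tab)
  y <- 100 - 600 * tab[, "sp7"] + rnorm(n, 0, 0.5)
  mm <- minimal_marker_set(tab, y, k_grid = c(1, 2, 5, 10, 20),
                           cv_folds = 4, num_trees = 150, seed = 9)
  expect_lte(mm$k_opt, 5)
  expect_true("sp7" %in% mm$taxa)
  expect_equal(mm$ranking[1], "sp7")
  # all-noise features give a flat error curve (no deep minimum)
  y0 <- rnorm(n)
  mm0 <- minimal_marker_set(tab, y0, k_grid = c(1, 5, 20), cv_folds = 4,
                            num_trees = 100, seed = 10)
  expect_lt(diff(range(mm0$curve$mean_error)) / median(mm0$curve$mean_error), 0.5)
})

test_that("profile-frailty association and marker enrichment behave at the extremes", {
  set.seed(13)
  prof <- matrix(rnorm(60 * 4), 60, 4,
                 dimnames = list(paste0("s", 1:60), paste0("p", 1:4)))
  y <- prof[, "p1"] * 2 + rnorm(60, 0, 0.1)
  prof[, "p4"] <- 7  # constant profile is skipped
  res <- metabolite_frailty_association(prof, y, fdr = 0.25)
  expect_false("p4" %in% res$profile)
  expect_true(res$significant[res$profile == "p1"])
  expect_gt(res$rho[res$profile == "p1"], 0.9)
  # profile identical to the score ranks correlates perfectly
  prof2 <- cbind(prof, exact = rank(y))
  res2 <- metabolite_frailty_association(prof2, y)
  expect_equal(res2$rho[res2$profile == "exact"], 1)

  # enrichment: capability in all markers, absent elsewhere -> minimal p
  m <- matrix(0, 20, 2, dimnames = list(paste0("sp", 1:20), c("hit", "flat")))
  m[1:5, "hit"] <- 1
  m[, "flat"] <- rep(c(0, 1), 10)
  map <- structure(list(matrix = m,
                        profiles = data.frame(profile_id = c("hit", "flat"),
                                              direction = "production")),
                   class = "metabolite_map")
  markers <- paste0("sp", 1:5)
  enr <- marker_metabolite_enrichment(map, markers)
  expect_equal(enr$p[enr$profile == "hit"],
               fisher.test(matrix(c(5, 0, 0, 15), 2))$p.value)
  expect_true(enr$enriched[enr$profile == "hit"])
  expect_false(enr$enriched[enr$profile == "flat"])
  expect_error(marker_metabolite_enrichment(map, "spX"), "missing")
})

test_that("frail split is a median split with ties assigned NonFrail", {
  lab <- frail_split(setNames(1:10, paste0("s", 1:10)))
  expect_equal(sum(lab == "Frail"), 5)
  expect_true(all(lab[1:5] == "Frail"))
  # tie at the median goes to NonFrail
  lab2 <- frail_split(c(1, 2, 3, 3, 9))
  expect_equal(as.character(lab2[3]), "NonFrail")
  expect_error(frail_split(rep(5, 6)), "degenerate")
  # subgroup median drives all labels
  sc <- c(rep(10, 4), 1, 2, 3, 4)
  lab3 <- frail_split(sc, subgroup = 5:8)
  expect_true(all(lab3[1:4] == "NonFrail"))
  expect_equal(sum(lab3 == "Frail"), 2)
  # planted frailty taxa are higher in the frail half at strong effect
  cfg <- study_config("frailty", seed = 92)
  g <- generate_cohort(cfg)
  scf <- generate_frailty_scores(g$table, g$truth, cfg)
  labf <- frail_split(scf)
  tx <- names(which(g$truth$frailty_weights > 0))[1]
  expect_lt(wilcox.test(g$table[labf == "Frail", tx],
                        g$table[labf == "NonFrail", tx],
                        alternative = "greater")$p.value, 0.05)
})
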