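#' Random-forest frailty regression from taxonomic profiles
#'
#' Regresses a per-sample frailty score (e.g. a functional-independence
#' measure, higher = less frail) on the species relative abundances.
#' The default protocol trains on `train_frac` of the samples and tests on
#' the remainder, reporting the Pearson correlation between predicted and
#' actual scores on the test split; a k-fold cross-validation mode is also
#' provided (`cv_folds`), in which predictions are pooled over held-out
#' folds. Feature importance ranks (rank 1 = most important) come from the
#' impurity (Gini) importances.
#'
#' @param table samples x species abundances.
#' @param scores data.frame with `sample_id` and `score`, or a numeric
#'   vector aligned with the rows of `table`.
#' @param train_frac training fraction for the split protocol, default 0.2.
#' @param cv_folds if non-NULL, use k-fold cross-validation instead of the
#'   single split.
#' @param num_trees forest size.
#' @param seed integer seed.
#' @return object of class `frailty_model`: list with `r` (test-set Pearson
#'   correlation), `predictions` (data.frame `sample_id`, `actual`,
#'   `predicted`), `importance`, `importance_rank` (named, a permutation of
#'   1..n_taxa), `mode` and `config`.
#' @export
frailty_regression <- function(table, scores, train_frac = 0.2, cv_folds = NULL,
                               num_trees = 500, seed = NULL) {
  check_abundance(table)
  y <- if (is.data.frame(scores)) scores$score[match(rownames(table), scores$sample_id)]
       else as.numeric(scores)
  if (anyNA(y) || any(!is.finite(y))) stop("scores must be finite for all samples", call. = FALSE)
  if (nrow(table) < 10) stop("need >= 10 samples", call. = FALSE)
  if (stats::var(y) == 0) stop("constant frailty scores", call. = FALSE)
  n <- nrow(table)

  fit_one <- function(tr_idx, rf_seed) {
    df <- data.frame(.y = y[tr_idx], table[tr_idx, , drop = FALSE], check.names = FALSE)
    fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                          importance = "impurity", num.trees = num_trees,
                          seed = rf_seed, num.threads = 1)
    te_idx <- setdiff(seq_len(n), tr_idx)
    pred <- ranger::predictions(predict(fit, data.frame(table[te_idx, , drop = FALSE],
                                                        check.names = FALSE),
                                        num.threads = 1))
    list(te_idx = te_idx, pred = pred, importance = fit$variable.importance)
  }

  res <- with_seed(seed, {
    if (is.null(cv_folds)) {
      tr <- sample.int(n, max(2, round(train_frac * n)))
      one <- fit_one(tr, sample.int(.Machine$integer.max, 1))
      list(pred = data.frame(sample_id = rownames(table)[one$te_idx],
                             actual = y[one$te_idx], predicted = one$pred),
           importance = one$importance, mode = "split")
    } else {
      fold <- sample(rep(seq_len(cv_folds), length.out = n))
      preds <- vector("list", cv_folds)
      imps <- matrix(0, cv_folds, ncol(table), dimnames = list(NULL, colnames(table)))
      for (k in seq_len(cv_folds)) {
        one <- fit_one(which(fold != k), sample.int(.Machine$integer.max, 1))
        preds[[k]] <- data.frame(sample_id = rownames(table)[one$te_idx],
                                 actual = y[one$te_idx], predicted = one$pred)
        imps[k, ] <- one$importance[colnames(table)]
      }
      list(pred = do.call(rbind, preds), importance = colMeans(imps), mode = "cv")
    }
  })
  rank_imp <- rank(-res$importance, ties.method = "first")
  structure(list(r = stats::cor(res$pred$actual, res$pred$predicted),
                 predictions = res$pred,
                 importance = res$importance,
                 importance_rank = rank_imp,
                 mode = res$mode,
                 config = list(train_frac = train_frac, cv_folds = cv_folds,
                               num_trees = num_trees, seed = seed)),
            class = "frailty_model")
}

#' @export
print.frailty_model <- function(x, ...) {
  cat("Frailty regression (", x$mode, " protocol): test Pearson R = ",
      sprintf("%.3f", x$r), "\n", sep = "")
  top <- names(sort(x$importance_rank))[seq_len(min(5, length(x$importance_rank)))]
  cat("Top features:", paste(top, collapse = ", "), "\n")
  invisible(x)
}

#' Mean importance rank per shared-response group
#'
#' Arithmetic mean of the frailty-model importance ranks within each
#' shared-response group (G1--L3); a lower mean rank means the group is
#' more predictive of frailty. Invariant to monotone transforms of the
#' importances.
#'
#' @param model a `frailty_model`.
#' @param groups a `shared_groups` data.frame (or named character vector
#'   `taxon -> group`).
#' @return named numeric vector of mean ranks (groups absent from the
#'   model's taxa are `NA`); the `"none"` label is excluded.
#' @export
group_mean_ranks <- function(model, groups) {
  g <- if (is.data.frame(groups)) stats::setNames(groups$group, groups$taxon) else groups
  g <- g[names(g) %in% names(model$importance_rank)]
  labs <- setdiff(sort(unique(g)), "none")
  vapply(stats::setNames(labs, labs), function(lb) {
    taxa <- names(g)[g == lb]
    if (length(taxa) == 0) return(NA_real_)
    mean(model$importance_rank[taxa])
  }, numeric(1))
}

#' Minimal marker set for frailty prediction
#'
#' Ranks features by a full-model importance (averaged over repeated
#' train/test splits), then retrains on the top-k features over a grid of
#' k, recording the mean squared test error per k; the optimal set is the
#' k minimising the mean error (smallest k on ties).
#'
#' @inheritParams frailty_regression
#' @param k_grid candidate set sizes; default a log-spaced grid from 1 to
#'   the number of taxa.
#' @param n_rep train/test splits averaged per k, default 5 (ignored in CV
#'   mode, where the `cv_folds` held-out folds play that role).
#' @return list with `k_opt`, `taxa` (the selected minimal set), `curve`
#'   (data.frame `k`, `mean_error`) and `ranking`.
#' @export
minimal_marker_set <- function(table, scores, k_grid = NULL, train_frac = 0.2,
                               cv_folds = NULL, n_rep = 5, num_trees = 500,
                               seed = NULL) {
  check_abundance(table)
  p <- ncol(table)
  if (is.null(k_grid)) {
    k_grid <- sort(unique(pmin(p, c(1:10, 15, 20, 30, 50, 75, 100, 150, 200, p))))
  }
  y <- if (is.data.frame(scores)) scores$score[match(rownames(table), scores$sample_id)]
       else as.numeric(scores)
  if (!is.null(cv_folds)) n_rep <- 1L
  with_seed(seed, {
    base_seeds <- sample.int(.Machine$integer.max / 2, n_rep)
    imp <- matrix(0, n_rep, p, dimnames = list(NULL, colnames(table)))
    for (r in seq_len(n_rep)) {
      m <- frailty_regression(table, y, train_frac = train_frac, cv_folds = cv_folds,
                              num_trees = num_trees, seed = base_seeds[r])
      imp[r, ] <- m$importance[colnames(table)]
    }
    ranking <- names(sort(rank(-colMeans(imp), ties.method = "first")))
    rep_seeds <- sample.int(.Machine$integer.max / 2, n_rep)
    curve <- do.call(rbind, lapply(k_grid, function(k) {
      feats <- ranking[seq_len(k)]
      errs <- vapply(seq_len(n_rep), function(r) {
        m <- frailty_regression(table[, feats, drop = FALSE], y,
                                train_frac = train_frac, cv_folds = cv_folds,
                                num_trees = num_trees, seed = rep_seeds[r])
        mean((m$predictions$actual - m$predictions$predicted)^2)
      }, numeric(1))
      data.frame(k = k, mean_error = mean(errs))
    }))
    k_opt <- curve$k[which.min(curve$mean_error)]
    list(k_opt = k_opt, taxa = ranking[seq_len(k_opt)], curve = curve, ranking = ranking)
  })
}

#' Sample-level metabolite capability profiles
#'
#' Matrix inner product of the species abundance profiles with the binary
#' species-to-metabolite capability map: `score(sample, profile) =
#' sum_j abundance_j * map_jp`, i.e. the cumulated abundance of the taxa
#' carrying the capability.
#'
#' @param table samples x species abundances.
#' @param map a `metabolite_map` (see [generate_metabolite_map()] /
#'   [read_metabolite_map()]).
#' @return samples x profiles numeric matrix; the species universes are
#'   intersected (with a message when they differ; error on zero overlap).
#' @export
metabolite_profiles <- function(table, map) {
  check_abundance(table)
  m <- map$matrix
  common <- intersect(colnames(table), rownames(m))
  if (length(common) == 0) stop("no species shared between table and map", call. = FALSE)
  if (length(common) < ncol(table) || length(common) < nrow(m))
    message("species universes differ; using the ", length(common), " shared species")
  table[, common, drop = FALSE] %*% m[common, , drop = FALSE]
}

#' Association of metabolite profiles with frailty scores
#'
#' Spearman correlation of each profile score with the frailty score,
#' Benjamini-Hochberg corrected across profiles; the significant set uses
#' FDR < 0.25 by default. Constant profiles are skipped.
#'
#' @param profiles samples x profiles matrix from [metabolite_profiles()].
#' @param scores data.frame (`sample_id`, `score`) or aligned numeric vector.
#' @param fdr FDR threshold, default 0.25.
#' @return data.frame `profile`, `rho`, `p`, `p_adj`, `significant`.
#' @export
metabolite_frailty_association <- function(profiles, scores, fdr = 0.25) {
  y <- if (is.data.frame(scores)) scores$score[match(rownames(profiles), scores$sample_id)]
       else as.numeric(scores)
  if (nrow(profiles) < 10) stop("need >= 10 samples", call. = FALSE)
  keep <- apply(profiles, 2, function(v) stats::var(v) > 0)
  res <- do.call(rbind, lapply(colnames(profiles)[keep], function(pr) {
    ct <- suppressWarnings(stats::cor.test(profiles[, pr], y, method = "spearman"))
    data.frame(profile = pr, rho = as.numeric(ct$estimate), p = ct$p.value)
  }))
  res$p_adj <- stats::p.adjust(res$p, "BH")
  res$significant <- res$p_adj < fdr
  rownames(res) <- NULL
  res
}

#' Metabolite-capability enrichment in marker taxa
#'
#' Per profile, a 2x2 Fisher exact test of capability presence in marker
#' versus non-marker taxa, Benjamini-Hochberg corrected across the tested
#' profiles (FDR < 0.25 by default). Profiles absent from every species are
#' skipped.
#'
#' @param map a `metabolite_map`.
#' @param marker_taxa character vector of marker species (must be part of
#'   the map's species).
#' @param profiles profiles to test; default all (typically the
#'   FDR-significant set from [metabolite_frailty_association()]).
#' @param fdr FDR threshold, default 0.25.
#' @return data.frame `profile`, `odds_ratio`, `p`, `p_adj`, `enriched`.
#' @export
marker_metabolite_enrichment <- function(map, marker_taxa, profiles = NULL, fdr = 0.25) {
  m <- map$matrix
  if (!all(marker_taxa %in% rownames(m)))
    stop("marker taxa missing from the map", call. = FALSE)
  profiles <- profiles %||% colnames(m)
  is_marker <- rownames(m) %in% marker_taxa
  res <- do.call(rbind, lapply(profiles, function(pr) {
    v <- m[, pr]
    if (all(v == 0)) return(NULL)
    tab <- matrix(c(sum(v[is_marker] == 1), sum(v[is_marker] == 0),
                    sum(v[!is_marker] == 1), sum(v[!is_marker] == 0)), 2)
    ft <- stats::fisher.test(tab)
    data.frame(profile = pr, odds_ratio = as.numeric(ft$estimate), p = ft$p.value)
  }))
  if (is.null(res)) stop("no testable profiles", call. = FALSE)
  res$p_adj <- stats::p.adjust(res$p, "BH")
  res$enriched <- res$p_adj < fdr
  rownames(res) <- NULL
  res
}

#' Median split into Frail and Non-Frail
#'
#' Labels samples below the (subgroup) median score `Frail` and the rest
#' `NonFrail`; samples exactly at the median are assigned `NonFrail`
#' (scores are "below versus above" the median, and ties side with the
#' less-frail label). Downstream comparisons of any feature between the
#' labels use two-sided Mann-Whitney tests.
#'
#' @param scores data.frame (`sample_id`, `score`) or named numeric vector.
#' @param subgroup optional logical/index vector: the median is computed
#'   within this subgroup but labels are returned for all samples.
#' @return factor with levels `Frail`, `NonFrail` and the median in
#'   `attr(, "median")`; errors when all scores are equal.
#' @export
frail_split <- function(scores, subgroup = NULL) {
  y <- if (is.data.frame(scores)) stats::setNames(scores$score, scores$sample_id) else scores
  if (length(y) < 4) stop("need >= 4 samples", call. = FALSE)
  ref <- if (is.null(subgroup)) y else y[subgroup]
  if (stats::var(ref) == 0) stop("degenerate split: all scores equal", call. = FALSE)
  med <- stats::median(ref)
  out <- factor(ifelse(y < med, "Frail", "NonFrail"), levels = c("Frail", "NonFrail"))
  names(out) <- names(y)
  attr(out, "median") <- med
  out
}

#' Read / write a species-to-metabolite capability map
#'
#' TSV dialect: a species x profiles 0/1 table whose first column is
#' `species_id`, preceded by a comment line
#' `#direction<TAB><dir1><TAB><dir2>...` naming each profile's direction
#' (production/consumption/degradation).
#'
#' @param path file path.
#' @return a `metabolite_map`.
#' @export
read_metabolite_map <- function(path) {
  first <- readLines(path, n = 1)
  dirs <- NULL
  skip <- 0
  if (startsWith(first, "#direction")) {
    dirs <- strsplit(first, "\t", fixed = TRUE)[[1]][-1]
    skip <- 1
  }
  df <- utils::read.delim(path, skip = skip, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (!all(m %in% c(0, 1))) stop("map entries must be 0/1", call. = FALSE)
  profs <- data.frame(profile_id = colnames(m),
                      direction = dirs %||% rep("production", ncol(m)),
                      stringsAsFactors = FALSE)
  structure(list(matrix = m, profiles = profs), class = "metabolite_map")
}

#' @rdname read_metabolite_map
#' @param map a `metabolite_map`.
#' @export
write_metabolite_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#direction", map$profiles$direction), collapse = "\t"), con)
  df <- data.frame(species_id = rownames(map$matrix), map$matrix, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
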