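#' Area under the ROC curve
#'
#' Rank-based AUC: the probability that a randomly chosen case scores above
#' a randomly chosen control, with ties counted as 1/2.
#'
#' @param scores numeric scores (higher = more case-like).
#' @param labels logical (or coercible) case indicator; both classes must be
#'   present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Fit a probability forest and return a scoring closure plus Gini importances.
fit_rf_classifier <- function(x, y, num_trees, mtry, seed) {
  df <- data.frame(.y = factor(y, levels = c("control", "disease")), x,
                   check.names = FALSE)
  fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                        probability = TRUE, importance = "impurity",
                        num.trees = num_trees, mtry = mtry, seed = seed,
                        num.threads = 1)
  list(score = function(newx) {
    ranger::predictions(predict(fit, data.frame(newx, check.names = FALSE),
                                num.threads = 1))[, "disease"]
  },
  importance = fit$variable.importance)
}

#' Iterative same-age versus different-age disease classification
#'
#' The core age-aware evaluation. For `n_outer` iterations a random-forest
#' classifier is trained on `train_size` diseased plus `train_size` control
#' samples of the training age group. In each of `n_inner` repeats, two
#' disjoint-from-training test sets are drawn: a Same-age set (`test_size`
#' cases + `test_size` controls from the training age group) and a
#' Different-age set (same sizes, pooled from the other two age groups),
#' and the classifier's AUC on each is recorded; medians over the repeats
#' summarise the iteration. A permuted arm merges both test sets, permutes
#' the age-group labels, splits the pool back into two sets of the original
#' sizes and records the AUC difference, building a null for the
#' same-minus-different contrast that preserves the correlation structure
#' induced by testing one classifier on overlapping subject pools.
#'
#' Training and test sizes are kept constant across age groups for a
#' disease; groups lacking `train_size + test_size` cases or controls are
#' not eligible as training groups.
#'
#' @param table samples x species abundances.
#' @param metadata metadata (`condition`, `disease`, `age_group`).
#' @param disease disease label to classify against controls.
#' @param train_age_group `"Young"`, `"Middle"`, `"Elderly"`, or `"YM"`
#'   (Young and Middle pooled, with "different" then meaning Elderly).
#' @param bin optional `cohort_bin` restricting the samples used.
#' @param n_outer outer iterations (classifiers), default 100.
#' @param n_inner inner test-set repeats per classifier, default 20.
#' @param train_size training samples per class; default half the minimum
#'   diseased count over age groups.
#' @param test_size test samples per class per test set; defaults to
#'   `train_size`.
#' @param num_trees,mtry forest parameters (impurity importances are the
#'   mean decrease in Gini).
#' @param seed integer seed.
#' @return object of class `age_aware_run`: list with `iterations`
#'   (data.frame `auc_same`, `auc_diff`, `perm_diff`, one row per outer
#'   iteration of medians over the inner repeats), `importance` (iterations
#'   x species Gini importances) and `config`.
#' @export
age_aware_evaluation <- function(table, metadata, disease, train_age_group,
                                 bin = NULL, n_outer = 100, n_inner = 20,
                                 train_size = NULL, test_size = NULL,
                                 num_trees = 500, mtry = NULL, seed = NULL) {
  check_abundance(table)
  md <- match_meta(table, metadata)
  if (!is.null(bin)) {
    keep <- md$sample_id %in% bin$sample_ids
    table <- table[keep, , drop = FALSE]; md <- md[keep, , drop = FALSE]
  }
  groups <- if (train_age_group == "YM") {
    list(same = c("Young", "Middle"), diff = "Elderly")
  } else {
    all_g <- c("Young", "Middle", "Elderly")
    if (!train_age_group %in% all_g) stop("unknown age group", call. = FALSE)
    list(same = train_age_group, diff = setdiff(all_g, train_age_group))
  }
  is_case <- md$condition == "disease" & md$disease == disease
  is_ctrl <- md$condition == "control"
  pool <- function(grp, case) which((if (case) is_case else is_ctrl) & md$age_group %in% grp)

  if (is.null(train_size)) {
    per_group <- vapply(c("Young", "Middle", "Elderly"),
                        function(g) sum(is_case & md$age_group == g), numeric(1))
    per_group <- per_group[per_group > 0]
    train_size <- floor(0.5 * min(per_group))
  }
  test_size <- test_size %||% train_size
  need <- train_size + test_size
  for (case in c(TRUE, FALSE)) {
    if (length(pool(groups$same, case)) < need)
      stop(sprintf("training group needs >= %d %s samples", need,
                   if (case) "case" else "control"), call. = FALSE)
    if (length(pool(groups$diff, case)) < test_size)
      stop(sprintf("different-age pool needs >= %d %s samples", test_size,
                   if (case) "case" else "control"), call. = FALSE)
  }

  n_sp <- ncol(table)
  res <- with_seed(seed, {
    iters <- matrix(NA_real_, n_outer, 3,
                    dimnames = list(NULL, c("auc_same", "auc_diff", "perm_diff")))
    imp <- matrix(NA_real_, n_outer, n_sp, dimnames = list(NULL, colnames(table)))
    for (i in seq_len(n_outer)) {
      tr_case <- sample(pool(groups$same, TRUE), train_size)
      tr_ctrl <- sample(pool(groups$same, FALSE), train_size)
      tr <- c(tr_case, tr_ctrl)
      fit <- NULL
      for (attempt in 1:2) {
        fit <- tryCatch(fit_rf_classifier(table[tr, , drop = FALSE],
                                          md$condition[tr], num_trees, mtry,
                                          seed = sample.int(.Machine$integer.max, 1)),
                        error = function(e) NULL)
        if (!is.null(fit)) break
      }
      if (is.null(fit)) stop("classifier failed twice in iteration ", i, call. = FALSE)
      imp[i, ] <- fit$importance[colnames(table)]

      same_a <- diff_a <- perm_d <- numeric(n_inner)
      for (j in seq_len(n_inner)) {
        same_case <- sample(setdiff(pool(groups$same, TRUE), tr), test_size)
        same_ctrl <- sample(setdiff(pool(groups$same, FALSE), tr), test_size)
        diff_case <- sample(pool(groups$diff, TRUE), test_size)
        diff_ctrl <- sample(pool(groups$diff, FALSE), test_size)
        idx_same <- c(same_case, same_ctrl); idx_diff <- c(diff_case, diff_ctrl)
        lab_same <- c(rep(TRUE, test_size), rep(FALSE, test_size))
        sc_same <- fit$score(table[idx_same, , drop = FALSE])
        sc_diff <- fit$score(table[idx_diff, , drop = FALSE])
        same_a[j] <- auc(sc_same, lab_same)
        diff_a[j] <- auc(sc_diff, lab_same)
        # permuted arm: reshuffle age-band membership over the merged pool,
        # preserving the case/control split within each permuted set
        perm_case <- sample(c(same_case, diff_case))
        perm_ctrl <- sample(c(same_ctrl, diff_ctrl))
        sc_c <- c(sc_same, sc_diff)[match(c(perm_case, perm_ctrl), c(idx_same, idx_diff))]
        set1 <- c(sc_c[seq_len(test_size)], sc_c[2 * test_size + seq_len(test_size)])
        set2 <- c(sc_c[test_size + seq_len(test_size)], sc_c[3 * test_size + seq_len(test_size)])
        perm_d[j] <- auc(set1, lab_same) - auc(set2, lab_same)
      }
      iters[i, ] <- c(stats::median(same_a), stats::median(diff_a), stats::median(perm_d))
    }
    list(iterations = as.data.frame(iters), importance = imp)
  })
  structure(c(res, list(config = list(disease = disease, train_age_group = train_age_group,
                                      n_outer = n_outer, n_inner = n_inner,
                                      train_size = train_size, test_size = test_size,
                                      num_trees = num_trees, seed = seed))),
            class = "age_aware_run")
}

#' @export
print.age_aware_run <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Age-aware evaluation: %s, trained on %s (%d x %d iterations)\n",
              cfg$disease, cfg$train_age_group, cfg$n_outer, cfg$n_inner))
  cat(sprintf("  median AUC same-age:      %.3f\n", stats::median(x$iterations$auc_same)))
  cat(sprintf("  median AUC different-age: %.3f\n", stats::median(x$iterations$auc_diff)))
  invisible(x)
}

#' @export
summary.age_aware_run <- function(object, ...) {
  it <- object$iterations
  out <- data.frame(
    median_auc_same = stats::median(it$auc_same),
    median_auc_diff = stats::median(it$auc_diff),
    median_gap = stats::median(it$auc_same - it$auc_diff),
    p_paired = paired_auc_test(object)$p_raw,
    p_permutation = permutation_auc_test(object)$p_raw)
  cbind(object$config[c("disease", "train_age_group")], out)
}

wilcox_greater <- function(x, y) {
  d <- x - y
  if (all(d == 0)) return(1)
  stats::wilcox.test(x, y, paired = TRUE, alternative = "greater", exact = FALSE)$p.value
}

#' Paired Wilcoxon test of same-age versus different-age AUCs
#'
#' One-sided (same > different) Wilcoxon signed-rank test over the outer
#' iterations' median AUCs. Given runs for several age groups of one
#' disease, Holm's step-down correction is applied over that family.
#'
#' @param runs a single `age_aware_run` or a (optionally named) list of runs
#'   for the age groups of one disease.
#' @return data.frame with `train_age_group`, `p_raw` and `p_holm`.
#' @export
paired_auc_test <- function(runs) {
  if (inherits(runs, "age_aware_run")) runs <- list(runs)
  if (any(vapply(runs, function(r) nrow(r$iterations), numeric(1)) < 10))
    stop("need >= 10 outer iterations", call. = FALSE)
  p <- vapply(runs, function(r) wilcox_greater(r$iterations$auc_same, r$iterations$auc_diff),
              numeric(1))
  data.frame(train_age_group = vapply(runs, function(r) r$config$train_age_group, character(1)),
             p_raw = p, p_holm = stats::p.adjust(p, method = "holm"),
             row.names = NULL)
}

#' Permutation-null test of the same-minus-different AUC gap
#'
#' One-sided Wilcoxon signed-rank test comparing the actual per-iteration
#' median AUC differences (same - different) against the permuted-label
#' median differences recorded in the permuted arm of
#' [age_aware_evaluation()]. Holm correction is applied across the supplied
#' age groups.
#'
#' @inheritParams paired_auc_test
#' @return data.frame with `train_age_group`, `p_raw` and `p_holm`.
#' @export
permutation_auc_test <- function(runs) {
  if (inherits(runs, "age_aware_run")) runs <- list(runs)
  p <- vapply(runs, function(r) {
    actual <- r$iterations$auc_same - r$iterations$auc_diff
    wilcox_greater(actual, r$iterations$perm_diff)
  }, numeric(1))
  data.frame(train_age_group = vapply(runs, function(r) r$config$train_age_group, character(1)),
             p_raw = p, p_holm = stats::p.adjust(p, method = "holm"),
             row.names = NULL)
}
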