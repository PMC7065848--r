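#' Assign multi-disease shared-response groups (G1--L3)
#'
#' Classifies taxa by the consistency of their gain/loss direction across
#' diseases in two age bands (young/middle and elderly). Within a band a
#' taxon qualifies as *gained* when it is significantly increased (+1) in
#' at least two distinct diseases and decreased in none (mirror for
#' *lost*); age groups Young and Middle are collapsed into the
#' young/middle band, with a within-band conflict (+1 in one age group, -1
#' in the other for the same disease) cancelling that disease's vote.
#' Groups: G1 gained in both bands, G2 gained only in the elderly, G3
#' gained only in young/middle; L1--L3 the loss mirrors. Taxa with mixed
#' gain/loss across bands, or no qualifying band, are labelled `"none"`.
#'
#' @param dir_tables data.frame combining [directionality()] outputs across
#'   diseases, with columns `disease`, `taxon`, `age_group` (or `band`) and
#'   `direction`.
#' @param min_diseases distinct diseases required for a consistent band
#'   call, default 2.
#' @return data.frame (`taxon`, `group`) of class `shared_groups`, one row
#'   per taxon seen in the input.
#' @export
assign_shared_groups <- function(dir_tables, min_diseases = 2) {
  df <- as.data.frame(dir_tables)
  if (!"band" %in% names(df)) {
    df$band <- ifelse(df$age_group == "Elderly", "elderly", "ym")
  }
  needed <- c("disease", "taxon", "band", "direction")
  if (!all(needed %in% names(df)))
    stop("directionality input needs columns: ", paste(needed, collapse = ", "), call. = FALSE)
  taxa <- sort(unique(df$taxon))

  band_status <- function(sub) {
    # per disease: +1 if any +1 and no -1 within the band, mirror for -1
    votes <- tapply(sub$direction, sub$disease, function(d) {
      has_p <- any(d == 1); has_m <- any(d == -1)
      if (has_p && !has_m) 1 else if (has_m && !has_p) -1 else 0
    })
    n_plus <- sum(votes == 1); n_minus <- sum(votes == -1)
    if (n_plus >= min_diseases && n_minus == 0) return("gained")
    if (n_minus >= min_diseases && n_plus == 0) return("lost")
    "none"
  }

  group <- vapply(taxa, function(tx) {
    ym <- band_status(df[df$taxon == tx & df$band == "ym", , drop = FALSE])
    el <- band_status(df[df$taxon == tx & df$band == "elderly", , drop = FALSE])
    if (ym == "gained" && el == "gained") return("G1")
    if (ym == "lost" && el == "lost") return("L1")
    if (ym == "none" && el == "gained") return("G2")
    if (ym == "gained" && el == "none") return("G3")
    if (ym == "none" && el == "lost") return("L2")
    if (ym == "lost" && el == "none") return("L3")
    "none"
  }, character(1))
  structure(data.frame(taxon = taxa, group = group, row.names = NULL),
            class = c("shared_groups", "data.frame"))
}

#' Generic control-versus-any-disease classifiers per age band
#'
#' Trains, separately within the young/middle and elderly bands, a
#' random-forest classifier on an agglomerated case set holding an equal
#' number of samples from each qualifying disease (plus an equal number of
#' controls) and evaluates AUC, sensitivity and specificity (probability
#' threshold 0.5) on held-out samples with identical per-disease
#' composition across bands. A disease lacking the required cases in either
#' band is dropped from *both* bands to preserve cross-band symmetry.
#'
#' @param table samples x species abundances.
#' @param metadata metadata with `condition`, `disease`, `age_group`.
#' @param diseases disease labels to agglomerate; default all in metadata.
#' @param per_disease_n training cases per disease, default 10.
#' @param test_per_disease held-out test cases per disease, default equal to
#'   `per_disease_n`.
#' @param n_repeats repeats with fresh subsamples, default 5.
#' @param num_trees forest size.
#' @param seed integer seed.
#' @return object of class `generic_eval`: list with `results` (data.frame
#'   `band`, `repeat`, `auc`, `sensitivity`, `specificity`), `tests`
#'   (two-sided rank-sum band comparisons per measure) and `diseases` used.
#' @export
generic_classifier_evaluation <- function(table, metadata, diseases = NULL,
                                          per_disease_n = 10, test_per_disease = NULL,
                                          n_repeats = 5, num_trees = 500, seed = NULL) {
  check_abundance(table)
  md <- match_meta(table, metadata)
  md$band <- ifelse(md$age_group == "Elderly", "elderly", "ym")
  diseases <- diseases %||% setdiff(unique(md$disease[md$condition == "disease"]), "none")
  test_per_disease <- test_per_disease %||% per_disease_n
  need <- per_disease_n + test_per_disease
  ok <- vapply(diseases, function(d) {
    all(vapply(c("ym", "elderly"), function(b)
      sum(md$condition == "disease" & md$disease == d & md$band == b) >= need, logical(1)))
  }, logical(1))
  diseases <- diseases[ok]
  if (length(diseases) == 0) stop("no disease qualifies in both bands", call. = FALSE)
  n_case_tr <- per_disease_n * length(diseases)
  n_case_te <- test_per_disease * length(diseases)

  res <- with_seed(seed, {
    rows <- list()
    for (rep_i in seq_len(n_repeats)) {
      for (b in c("ym", "elderly")) {
        tr_case <- unlist(lapply(diseases, function(d)
          sample(which(md$condition == "disease" & md$disease == d & md$band == b),
                 per_disease_n)))
        ctrl_pool <- which(md$condition == "control" & md$band == b)
        if (length(ctrl_pool) < n_case_tr + n_case_te)
          stop("not enough controls in band ", b, call. = FALSE)
        tr_ctrl <- sample(ctrl_pool, n_case_tr)
        fit <- fit_rf_classifier(table[c(tr_case, tr_ctrl), , drop = FALSE],
                                 md$condition[c(tr_case, tr_ctrl)], num_trees,
                                 NULL, seed = sample.int(.Machine$integer.max, 1))
        te_case <- unlist(lapply(diseases, function(d)
          sample(setdiff(which(md$condition == "disease" & md$disease == d & md$band == b),
                         tr_case), test_per_disease)))
        te_ctrl <- sample(setdiff(ctrl_pool, tr_ctrl), n_case_te)
        sc <- fit$score(table[c(te_case, te_ctrl), , drop = FALSE])
        lab <- c(rep(TRUE, n_case_te), rep(FALSE, n_case_te))
        rows[[length(rows) + 1L]] <- data.frame(
          band = b, rep = rep_i,
          auc = auc(sc, lab),
          sensitivity = mean(sc[lab] > 0.5),
          specificity = mean(sc[!lab] <= 0.5))
      }
    }
    do.call(rbind, rows)
  })
  tests <- do.call(rbind, lapply(c("auc", "sensitivity", "specificity"), function(m) {
    data.frame(measure = m,
               p = stats::wilcox.test(res[[m]][res$band == "ym"],
                                      res[[m]][res$band == "elderly"],
                                      exact = FALSE)$p.value)
  }))
  structure(list(results = res, tests = tests, diseases = diseases),
            class = "generic_eval")
}

#' @export
print.generic_eval <- function(x, ...) {
  cat("Generic disease classifiers (", paste(x$diseases, collapse = ", "), ")\n", sep = "")
  agg <- stats::aggregate(cbind(auc, sensitivity, specificity) ~ band, data = x$results, median)
  print(agg, row.names = FALSE)
  print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Cross-cohort stability of feature-rank profiles
#'
#' For each iteration's importance-rank vector in one cohort, computes its
#' mean Spearman distance (1 - rho, range 0--2) to all iterations' rank
#' vectors of the other cohort, pooling both directions. Low distances
#' indicate a reproducible disease signature across cohorts.
#'
#' @param run_a,run_b `age_aware_run` objects (or importance matrices) from
#'   two cohorts for the same age band; taxa are intersected (with a
#'   message) when the universes differ.
#' @return numeric vector of mean cross-cohort distances (one per
#'   iteration, both directions pooled).
#' @export
feature_rank_stability <- function(run_a, run_b) {
  ma <- if (inherits(run_a, "age_aware_run")) run_a$importance else run_a
  mb <- if (inherits(run_b, "age_aware_run")) run_b$importance else run_b
  if (nrow(ma) < 2 || nrow(mb) < 2) stop("need >= 2 iterations per cohort", call. = FALSE)
  common <- intersect(colnames(ma), colnames(mb))
  if (length(common) < 3) stop("fewer than 3 shared taxa", call. = FALSE)
  if (length(common) < ncol(ma) || length(common) < ncol(mb))
    message("taxa universes differ; using the ", length(common), " shared taxa")
  ra <- apply(ma[, common, drop = FALSE], 1, rank)  # taxa x iterations
  rb <- apply(mb[, common, drop = FALSE], 1, rank)
  cors <- stats::cor(ra, rb, method = "spearman")
  c(rowMeans(1 - cors), colMeans(1 - cors))
}

#' Fisher's method for combining p-values
#'
#' `chi^2 = -2 * sum(log(p))` on `2k` degrees of freedom.
#'
#' @param p vector of p-values in (0, 1].
#' @return list with `chisq`, `df`, `p`.
#' @export
fisher_method <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p-values must be in (0, 1]", call. = FALSE)
  chisq <- -2 * sum(log(p))
  list(chisq = chisq, df = 2 * length(p),
       p = stats::pchisq(chisq, 2 * length(p), lower.tail = FALSE))
}

#' Prevalence shift of taxa between elderly and young/middle controls
#'
#' Per cohort, compares each taxon's prevalence (fraction of samples where
#' it is detected, abundance > 0) between elderly and young/middle control
#' samples with a 2x2 Fisher exact test, and reports the log2 prevalence
#' ratio (elderly / young-middle). Per-cohort p-values are combined across
#' cohorts with Fisher's method.
#'
#' @param cohorts named list; each element a list with `table` and
#'   `metadata` for one cohort.
#' @param taxa taxa to assess.
#' @return list with `per_cohort` (data.frame `cohort`, `taxon`,
#'   `prev_elderly`, `prev_ym`, `log2_ratio`, `p`) and `combined`
#'   (data.frame `taxon`, `chisq`, `df`, `p`). A taxon absent from both
#'   bands of a cohort gets an `NA` ratio and p = 1 (flagged `undefined`).
#' @export
prevalence_shift <- function(cohorts, taxa) {
  per <- list()
  for (nm in names(cohorts)) {
    co <- cohorts[[nm]]
    md <- match_meta(co$table, co$metadata)
    ctrl <- md$condition == "control"
    eld <- ctrl & md$age_group == "Elderly"
    ym <- ctrl & md$age_group %in% c("Young", "Middle")
    if (!any(eld) || !any(ym)) stop("cohort ", nm, " lacks controls in a band", call. = FALSE)
    per[[nm]] <- do.call(rbind, lapply(taxa, function(tx) {
      de <- sum(co$table[eld, tx] > 0); dy <- sum(co$table[ym, tx] > 0)
      ne <- sum(eld); ny <- sum(ym)
      undef <- (de + dy) == 0
      p <- if (undef) 1 else
        stats::fisher.test(matrix(c(de, ne - de, dy, ny - dy), 2))$p.value
      data.frame(cohort = nm, taxon = tx,
                 prev_elderly = de / ne, prev_ym = dy / ny,
                 log2_ratio = if (undef) NA else log2((de / ne) / (dy / ny)),
                 p = p, undefined = undef)
    }))
  }
  per <- do.call(rbind, per)
  combined <- do.call(rbind, lapply(unique(per$taxon), function(tx) {
    fm <- fisher_method(per$p[per$taxon == tx])
    data.frame(taxon = tx, chisq = fm$chisq, df = fm$df, p = fm$p)
  }))
  rownames(per) <- rownames(combined) <- NULL
  list(per_cohort = per, combined = combined)
}

#' Cohen's D standardized mean difference
#'
#' `(mean(x) - mean(y)) / pooled sd`; values below 0.2 conventionally
#' indicate a low effect.
#'
#' @param x,y numeric vectors (cases and controls).
#' @return Cohen's D, or `NA` when the pooled sd is zero.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2))
  if (!is.finite(sp) || sp == 0) return(NA_real_)
  (mean(x) - mean(y)) / sp
}

#' Subsampled effect-size distributions per age band
#'
#' Per taxon and age band, repeatedly subsamples `n_per_arm` diseased and
#' `n_per_arm` control samples and records Cohen's D of the abundance
#' difference, yielding an effect-size distribution whose shift toward zero
#' in the elderly reveals masked disease signatures.
#'
#' @param table samples x species abundances.
#' @param metadata metadata with `condition` and `age_group`.
#' @param taxa taxa to assess.
#' @param n_per_arm samples per arm per iteration, default 20.
#' @param n_iter iterations, default 50.
#' @param seed integer seed.
#' @return data.frame `band`, `taxon`, `iter`, `d` (iterations with zero
#'   pooled sd are skipped).
#' @export
effect_size_iterations <- function(table, metadata, taxa, n_per_arm = 20,
                                   n_iter = 50, seed = NULL) {
  check_abundance(table)
  md <- match_meta(table, metadata)
  md$band <- ifelse(md$age_group == "Elderly", "elderly", "ym")
  with_seed(seed, {
    rows <- list()
    for (b in c("ym", "elderly")) {
      case <- which(md$condition == "disease" & md$band == b)
      ctrl <- which(md$condition == "control" & md$band == b)
      if (length(case) < n_per_arm || length(ctrl) < n_per_arm)
        stop("band ", b, " needs >= ", n_per_arm, " samples per arm", call. = FALSE)
      for (it in seq_len(n_iter)) {
        ic <- sample(case, n_per_arm); iq <- sample(ctrl, n_per_arm)
        for (tx in taxa) {
          d <- cohens_d(table[ic, tx], table[iq, tx])
          if (!is.na(d))
            rows[[length(rows) + 1L]] <- data.frame(band = b, taxon = tx, iter = it, d = d)
        }
      }
    }
    do.call(rbind, rows)
  })
}
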