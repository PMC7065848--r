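#' Per-taxon marker scores from iterative classifier runs
#'
#' For each age group's [age_aware_evaluation()] run, computes each taxon's
#' mean Gini importance across iterations, its percentile score (percent
#' rank of the mean importance among taxa, 0--100) and its inclusion
#' fraction (share of iterations in which the taxon carried importance
#' greater than zero, i.e. was used by the forest).
#'
#' @param runs named list `age_group -> age_aware_run` (or importance
#'   matrices, iterations x taxa). All runs must share the same taxa.
#' @return object of class `marker_scores`: named list per age group of
#'   data.frames (`taxon`, `mean_importance`, `percentile`, `inclusion`),
#'   with the per-iteration importance matrices kept in
#'   `attr(, "importance")` for downstream rank tests.
#' @export
compute_marker_scores <- function(runs) {
  mats <- lapply(runs, function(r) if (inherits(r, "age_aware_run")) r$importance else r)
  taxa <- colnames(mats[[1]])
  for (m in mats) {
    if (!identical(colnames(m), taxa)) stop("taxa mismatch across runs", call. = FALSE)
  }
  scores <- lapply(mats, function(m) {
    mi <- colMeans(m)
    data.frame(taxon = taxa,
               mean_importance = mi,
               percentile = 100 * rank(mi, ties.method = "average") / length(mi),
               inclusion = colMeans(m > 0),
               row.names = NULL)
  })
  structure(scores, importance = mats, class = "marker_scores")
}

#' Minimum stable percentile threshold
#'
#' The smallest percentile `t` such that every taxon scoring at or above
#' `t` was included in the classification model (importance > 0) in at
#' least `min_inclusion` of the iterations. Taking the maximum of `t`
#' across disease/age-group scenarios gives a global operating threshold;
#' the conventional operating point for the selection rule is the top 15
#' percentile (percentile >= 85).
#'
#' @param scores a `marker_scores` object.
#' @param min_inclusion required inclusion fraction, default 0.95.
#' @return named numeric vector of thresholds per age group, with the
#'   maximum over groups in `attr(, "global")`. Returns 100 with a warning
#'   for a group whose top-ranked taxon already fails the inclusion rule.
#' @export
stability_threshold <- function(scores, min_inclusion = 0.95) {
  th <- vapply(scores, function(df) {
    failing <- df$percentile[df$inclusion < min_inclusion]
    if (length(failing) == 0) return(0)
    cutoff <- max(failing)
    above <- df$percentile[df$percentile > cutoff]
    if (length(above) == 0) {
      warning("no stable percentile threshold; returning 100")
      return(100)
    }
    min(above)
  }, numeric(1))
  structure(th, global = max(th))
}

#' Select top-percentile marker taxa
#'
#' @param scores a `marker_scores` object.
#' @param percentile selection threshold; taxa with percentile scores at or
#'   above it are the top markers (default 85, i.e. the top 15 percentile).
#' @return named list of taxon vectors per age group.
#' @export
select_markers <- function(scores, percentile = 85) {
  lapply(scores, function(df) df$taxon[df$percentile >= percentile])
}

# Dunn's post-hoc rank-sum test following Kruskal-Wallis: pairwise z
# statistics on mean ranks with the tie correction, two-sided p-values.
dunn_test <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  pairs <- utils::combn(levels(groups), 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
    z <- (rbar[pr[1]] - rbar[pr[2]]) / se
    data.frame(group1 = pr[1], group2 = pr[2], z = as.numeric(z),
               p = 2 * stats::pnorm(-abs(z)), row.names = NULL)
  }))
}

#' Compare taxon importance scores across age groups
#'
#' Per taxon, compares the per-iteration importance-score distributions
#' across age groups: Kruskal-Wallis omnibus with Dunn's pairwise post-hoc
#' for three groups, Mann-Whitney for two. Benjamini-Hochberg FDR is
#' applied across taxa on the omnibus p-values; pairwise Dunn p-values are
#' reported raw.
#'
#' @param scores a `marker_scores` object covering >= 2 age groups.
#' @param fdr significance threshold on the adjusted p, default 0.01.
#' @return data.frame (`taxon`, `p`, `p_adj`, `significant`) with Dunn
#'   pairwise results (3 groups only) in `attr(, "pairwise")`.
#' @export
compare_importance_across_groups <- function(scores, fdr = 0.01) {
  mats <- attr(scores, "importance")
  if (length(mats) < 2) stop("need >= 2 age groups", call. = FALSE)
  taxa <- colnames(mats[[1]])
  glab <- rep(names(mats), vapply(mats, nrow, numeric(1)))
  pair_res <- list()
  p <- vapply(taxa, function(tx) {
    v <- unlist(lapply(mats, function(m) m[, tx]), use.names = FALSE)
    if (stats::var(v) == 0) return(1)
    if (length(mats) == 2) {
      stats::wilcox.test(mats[[1]][, tx], mats[[2]][, tx], exact = FALSE)$p.value
    } else {
      kw <- stats::kruskal.test(v, factor(glab))$p.value
      pair_res[[tx]] <<- cbind(taxon = tx, dunn_test(v, glab))
      if (is.nan(kw)) 1 else kw
    }
  }, numeric(1))
  out <- data.frame(taxon = taxa, p = p, p_adj = stats::p.adjust(p, "BH"), row.names = NULL)
  out$significant <- out$p_adj < fdr
  attr(out, "pairwise") <- if (length(pair_res)) do.call(rbind, pair_res) else NULL
  out
}

#' Linear-model deconvolution of ageing from disease signals
#'
#' For each taxon, fits two nested ordinary-least-squares models of
#' log10(abundance + pseudo-count):
#' Model 1 `~ country + condition + age_group` and Model 2
#' `~ country + condition * age_group` (adding the disease-by-age-group
#' interaction), and tests the improvement with a likelihood-ratio test
#' (`2 * (l2 - l1)` on a chi-square with df = added parameters; the LRT
#' statistic is one-sided by construction). Taxa whose interaction terms
#' are inestimable in the bin (e.g. a disease observed in a single age
#' group) are flagged not testable.
#'
#' @param table samples x species abundances.
#' @param metadata metadata with `country`, `condition`, `age_group`.
#' @param taxa taxa to test; default all columns.
#' @param pseudo_count zero replacement; default half the smallest nonzero
#'   abundance in the table.
#' @return data.frame per taxon: `aic1`, `aic2`, `llr`, `df`, `p`,
#'   `testable`.
#' @export
llr_deconvolution <- function(table, metadata, taxa = colnames(table),
                              pseudo_count = NULL) {
  check_abundance(table)
  md <- match_meta(table, metadata)
  pc <- pseudo_count %||% default_pseudo_count(table)
  md$condition <- factor(md$condition)
  md$age_group <- factor(md$age_group)
  use_country <- "country" %in% names(md) && length(unique(md$country)) > 1
  base_terms <- c(if (use_country) "country", "condition", "age_group")
  out <- lapply(taxa, function(tx) {
    y <- log10(table[, tx] + pc)
    d <- cbind(md, .y = y)
    m1 <- stats::lm(stats::reformulate(base_terms, ".y"), data = d)
    m2 <- stats::lm(stats::reformulate(c(base_terms, "condition:age_group"), ".y"), data = d)
    inter_coef <- stats::coef(m2)[grep(":", names(stats::coef(m2)))]
    df_extra <- sum(!is.na(inter_coef))
    if (df_extra == 0)
      return(data.frame(taxon = tx, aic1 = stats::AIC(m1), aic2 = NA, llr = NA,
                        df = 0, p = NA, testable = FALSE))
    llr <- as.numeric(2 * (stats::logLik(m2) - stats::logLik(m1)))
    data.frame(taxon = tx, aic1 = stats::AIC(m1), aic2 = stats::AIC(m2),
               llr = llr, df = df_extra,
               p = stats::pchisq(llr, df_extra, lower.tail = FALSE),
               testable = TRUE)
  })
  do.call(rbind, out)
}

#' Final validated age-specific disease markers
#'
#' Intersects the three evidence streams: top-percentile marker status in
#' at least one age group, a significant cross-age-group difference in
#' importance scores (FDR), and a significant disease-by-age-group
#' interaction in the linear-model deconvolution -- yielding the strictly
#' age-specific disease markers.
#'
#' @param scores `marker_scores` object.
#' @param cross output of [compare_importance_across_groups()].
#' @param llr output of [llr_deconvolution()].
#' @param percentile marker-selection threshold, default 85.
#' @param alpha LRT significance level, default 0.05.
#' @return character vector of validated taxa.
#' @export
validated_markers <- function(scores, cross, llr, percentile = 85, alpha = 0.05) {
  top <- unique(unlist(select_markers(scores, percentile)))
  sig_cross <- cross$taxon[cross$significant]
  sig_llr <- llr$taxon[llr$testable & !is.na(llr$p) & llr$p < alpha]
  sort(intersect(top, intersect(sig_cross, sig_llr)))
}

#' Directionality of marker-disease associations
#'
#' Two-sided Mann-Whitney test per taxon between region-matched control
#' and diseased samples within each age group; the direction is +1 (gained
#' in disease) when cases tend to rank higher, -1 (lost) when lower, 0 when
#' the significance rule fails. Study-level comparisons use raw p < `alpha`;
#' continent-level comparisons use a Benjamini-Hochberg FDR threshold
#' (default 0.1) across taxa within each age group.
#'
#' @param table samples x species abundances (already restricted to the
#'   matched bin).
#' @param metadata metadata with `condition` and `age_group`.
#' @param markers taxa to test.
#' @param level `"study"` (raw p) or `"continent"` (FDR).
#' @param alpha raw-p threshold for study level, default 0.05.
#' @param fdr FDR threshold for continent level, default 0.1 (0.01 for the
#'   strict variant).
#' @return data.frame: `taxon`, `age_group`, `direction`, `p`, `p_adj`,
#'   `level`.
#' @export
directionality <- function(table, metadata, markers, level = c("study", "continent"),
                           alpha = 0.05, fdr = 0.1) {
  level <- match.arg(level)
  check_abundance(table)
  md <- match_meta(table, metadata)
  out <- list()
  for (g in intersect(c("Young", "Middle", "Elderly"), unique(md$age_group))) {
    case <- md$age_group == g & md$condition == "disease"
    ctrl <- md$age_group == g & md$condition == "control"
    if (!any(case) || !any(ctrl)) next
    res <- do.call(rbind, lapply(markers, function(tx) {
      x <- table[case, tx]; y <- table[ctrl, tx]
      if (all(x == 0) && all(y == 0))
        return(data.frame(taxon = tx, age_group = g, effect = 0, p = 1))
      a <- auc(c(x, y), c(rep(TRUE, length(x)), rep(FALSE, length(y))))
      p <- stats::wilcox.test(x, y, exact = FALSE)$p.value
      data.frame(taxon = tx, age_group = g, effect = sign(a - 0.5), p = p)
    }))
    res$p_adj <- stats::p.adjust(res$p, "BH")
    sig <- if (level == "study") res$p < alpha else res$p_adj < fdr
    res$direction <- ifelse(sig, res$effect, 0)
    out[[g]] <- res[, c("taxon", "age_group", "direction", "p", "p_adj")]
  }
  res <- do.call(rbind, out)
  res$level <- level
  rownames(res) <- NULL
  res
}
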