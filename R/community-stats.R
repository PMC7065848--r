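#' Bray-Curtis dissimilarity matrix
#'
#' `d(i, k) = sum_j |x_ij - x_kj| / sum_j (x_ij + x_kj)`.
#'
#' @param table samples x species abundance matrix.
#' @return symmetric matrix of class `dist_matrix` with a `metric` attribute.
#' @export
bray_curtis <- function(table) {
  check_abundance(table)
  if (nrow(table) < 2) stop("need at least 2 samples", call. = FALSE)
  rs <- rowSums(table)
  if (any(rs == 0))
    stop("all-zero abundance sample: ", rownames(table)[which(rs == 0)[1]], call. = FALSE)
  man <- as.matrix(stats::dist(table, method = "manhattan"))
  denom <- outer(rs, rs, `+`)
  d <- man / denom
  diag(d) <- 0
  structure(d, metric = "bray_curtis", class = c("dist_matrix", "matrix", "array"))
}

#' Spearman distance matrix
#'
#' `1 - rho`, where `rho` is the Spearman rank correlation between two
#' samples' abundance profiles over species; range `[0, 2]`.
#'
#' @inheritParams bray_curtis
#' @export
spearman_distance <- function(table) {
  check_abundance(table)
  if (nrow(table) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(rowSums(table) == 0))
    stop("all-zero abundance sample: ",
         rownames(table)[which(rowSums(table) == 0)[1]], call. = FALSE)
  d <- 1 - stats::cor(t(table), method = "spearman")
  diag(d) <- 0
  structure(d, metric = "spearman", class = c("dist_matrix", "matrix", "array"))
}

# Gower-centred inner-product matrix G = -1/2 * J %*% D^2 %*% J.
gower_center <- function(D) {
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

#' Principal coordinates analysis
#'
#' Classical scaling of the Gower-centred matrix. Axes are ordered by
#' decreasing eigenvalue; axes with non-positive eigenvalues are reported
#' through `eigenvalues` but excluded from the coordinates (no Lingoes or
#' Cailliez correction is applied).
#'
#' @param dist symmetric distance matrix.
#' @param k number of coordinate axes requested.
#' @return list with `coordinates` (samples x k') and `eigenvalues`
#'   (all of them, including negatives). If fewer than `k` positive
#'   eigenvalues exist the coordinates are truncated with a warning.
#' @export
pcoa <- function(dist, k = 2) {
  D <- as.matrix(dist)
  if (nrow(D) < 2) stop("need at least 2 samples", call. = FALSE)
  G <- gower_center(D)
  e <- eigen(G, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  npos <- sum(e$values > tol)
  if (k > npos) {
    if (npos == 0) stop("no positive eigenvalues; distances are degenerate", call. = FALSE)
    warning("only ", npos, " positive eigenvalues; coordinates truncated")
    k <- npos
  }
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(k)]), k, k)
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("PCo", seq_len(k))
  list(coordinates = coords, eigenvalues = e$values)
}

# Cumulative hat matrices for a sequential (Type-I) term decomposition.
# Returns per-term projection matrices and degrees of freedom; errors if a
# term adds no rank to the cumulative design.
sequential_hats <- function(metadata, terms) {
  n <- nrow(metadata)
  hats <- list(intercept = matrix(1 / n, n, n))
  dfs <- numeric(length(terms))
  prev_rank <- 1L
  for (k in seq_along(terms)) {
    f <- stats::reformulate(terms[seq_len(k)])
    X <- stats::model.matrix(f, data = metadata)
    qrX <- qr(X)
    if (qrX$rank <= prev_rank)
      stop("rank-deficient design: term '", terms[k], "' adds no information", call. = FALSE)
    Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
    hats[[terms[k]]] <- tcrossprod(Q)
    dfs[k] <- qrX$rank - prev_rank
    prev_rank <- qrX$rank
  }
  list(hats = hats, dfs = dfs, rank_full = prev_rank)
}

perm_stats <- function(G, hats, dfs, df_res) {
  n_terms <- length(dfs)
  tr_prev <- sum(hats[[1]] * G)
  ss <- numeric(n_terms)
  for (k in seq_len(n_terms)) {
    tr_k <- sum(hats[[k + 1]] * G)
    ss[k] <- tr_k - tr_prev
    tr_prev <- tr_k
  }
  ss_total <- sum(diag(G))
  ss_res <- ss_total - (tr_prev - sum(hats[[1]] * G))
  f <- (ss / dfs) / (ss_res / df_res)
  list(ss = ss, ss_res = ss_res, ss_total = ss_total, f = f)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' PERMANOVA with sequential sums of squares
#'
#' Permutational multivariate analysis of variance on a distance matrix,
#' partitioning the Gower-centred matrix by an ordered list of model terms
#' (sequential, Type-I decomposition via cumulative hat-matrix projections:
#' `SS_term = tr(H_k G) - tr(H_{k-1} G)`). Confounder adjustment is
#' achieved by placing confounders earlier in the term order, mirroring the
#' `adonis`-style formula `species ~ country + disease + age_group +
#' disease:age_group`. Significance comes from simultaneous row/column
#' permutations of the distance matrix with the add-one rule
#' `p = (1 + #\{F* >= F\}) / (1 + n_perm)`, so permutation p-values are
#' never zero.
#'
#' @param dist distance matrix (e.g. from [bray_curtis()]).
#' @param metadata data.frame aligned with the rows of `dist` (matched by
#'   `sample_id` when present, otherwise by position). Samples with missing
#'   values in any used covariate are dropped with a warning.
#' @param terms ordered character vector of model terms; interactions use
#'   the `"A:B"` syntax.
#' @param n_perm number of permutations (>= 99), ignored when
#'   `permutations = "exhaustive"`.
#' @param seed integer seed for the permutation stream.
#' @param permutations `"random"` or `"exhaustive"` (all `n!` orderings;
#'   only feasible for small `n`, and the p-value then is the exact
#'   `#\{F* >= F\}/n!` including the identity).
#' @return object of class `permanova`: an anova-like data.frame with per
#'   term `Df`, `SumOfSqs`, `R2`, `F` and `Pr(>F)` rows plus `Residual` and
#'   `Total`, with the permutation setup in attributes.
#' @export
permanova <- function(dist, metadata, terms, n_perm = 999, seed = NULL,
                      permutations = c("random", "exhaustive")) {
  permutations <- match.arg(permutations)
  D <- as.matrix(dist)
  n <- nrow(D)
  if ("sample_id" %in% names(metadata) && !is.null(rownames(D))) {
    idx <- match(rownames(D), metadata$sample_id)
    if (anyNA(idx)) stop("distance rows missing from metadata", call. = FALSE)
    metadata <- metadata[idx, , drop = FALSE]
  }
  if (nrow(metadata) != n) stop("metadata rows must match distance matrix", call. = FALSE)
  vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  missing_vars <- setdiff(vars, names(metadata))
  if (length(missing_vars))
    stop("metadata lacks covariate(s): ", paste(missing_vars, collapse = ", "), call. = FALSE)
  complete <- stats::complete.cases(metadata[, vars, drop = FALSE])
  if (!all(complete)) {
    warning(sum(!complete), " samples dropped for missing covariate values")
    D <- D[complete, complete, drop = FALSE]
    metadata <- metadata[complete, , drop = FALSE]
    n <- nrow(D)
  }
  if (permutations == "random" && n_perm < 99) stop("n_perm must be >= 99", call. = FALSE)
  metadata[vars] <- lapply(metadata[vars], function(x) if (is.character(x)) factor(x) else x)

  G <- gower_center(D)
  sq <- sequential_hats(metadata, terms)
  df_res <- n - sq$rank_full
  if (df_res <= 0) stop("no residual degrees of freedom", call. = FALSE)
  obs <- perm_stats(G, sq$hats, sq$dfs, df_res)

  if (permutations == "exhaustive") {
    if (n > 8) stop("exhaustive permutations only supported for n <= 8", call. = FALSE)
    perms <- all_permutations(n)
    count <- numeric(length(terms))
    for (r in seq_len(nrow(perms))) {
      Gp <- G[perms[r, ], perms[r, ], drop = FALSE]
      fp <- perm_stats(Gp, sq$hats, sq$dfs, df_res)$f
      count <- count + (fp >= obs$f - 1e-12)
    }
    pvals <- count / nrow(perms)
    n_used <- nrow(perms)
  } else {
    count <- numeric(length(terms))
    with_seed(seed, {
      for (r in seq_len(n_perm)) {
        pr <- sample.int(n)
        Gp <- G[pr, pr, drop = FALSE]
        fp <- perm_stats(Gp, sq$hats, sq$dfs, df_res)$f
        count <- count + (fp >= obs$f - 1e-12)
      }
    })
    pvals <- (1 + count) / (1 + n_perm)
    n_used <- n_perm
  }

  tab <- data.frame(
    Df = c(sq$dfs, df_res, n - 1),
    SumOfSqs = c(obs$ss, obs$ss_res, obs$ss_total),
    R2 = c(obs$ss, obs$ss_res, obs$ss_total) / obs$ss_total,
    F = c(obs$f, NA, NA),
    `Pr(>F)` = c(pvals, NA, NA),
    row.names = c(terms, "Residual", "Total"), check.names = FALSE)
  structure(tab, class = c("permanova", "data.frame"),
            n_perm = n_used, seed = seed, permutations = permutations,
            metric = attr(dist, "metric") %||% "unknown")
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (sequential sums of squares)\n")
  cat("Distance metric:", attr(x, "metric"),
      "| permutations:", attr(x, "n_perm"), paste0("(", attr(x, "permutations"), ")\n"))
  stats::printCoefmat(as.data.frame(x), na.print = "", has.Pvalue = TRUE,
                      P.values = TRUE, cs.ind = integer(0), tst.ind = 4L, ...)
  invisible(x)
}

# Multivariate "factor fit" R2 of a grouping on ordination coordinates:
# 1 - SS_within / SS_total pooled over axes.
coord_r2 <- function(coords, f) {
  total <- sum(scale(coords, scale = FALSE)^2)
  within <- 0
  for (lev in levels(f)) {
    sub <- coords[f == lev, , drop = FALSE]
    within <- within + sum(scale(sub, scale = FALSE)^2)
  }
  1 - within / total
}

#' Bootstrapped screening of a factor's effect on community composition
#'
#' Repeatedly subsamples the data, ordinates the subsample (PCoA of
#' Bray-Curtis distances) and computes the factor's R2 on the coordinates
#' with a label-permutation p-value; a matched null distribution is built
#' from the same subsamples with the factor labels permuted once per
#' iteration. Comparing the observed and null R2 distributions screens
#' host or technical factors for real effects on composition.
#'
#' @param table samples x species abundances.
#' @param metadata metadata with the factor column.
#' @param factor name of the metadata column.
#' @param subsample_size samples drawn per iteration.
#' @param n_iter bootstrap iterations, default 20.
#' @param n_axes PCoA axes used, default 2.
#' @param n_perm label permutations for the per-iteration p-value.
#' @param seed integer seed.
#' @return list with data.frames `observed` (`iter`, `R2`, `p`) and `null`
#'   (`iter`, `R2`).
#' @export
bootstrap_factor_effect <- function(table, metadata, factor, subsample_size = 200,
                                    n_iter = 20, n_axes = 2, n_perm = 99, seed = NULL) {
  check_abundance(table)
  md <- match_meta(table, metadata)
  if (!factor %in% names(md)) stop("metadata lacks factor '", factor, "'", call. = FALSE)
  if (subsample_size > nrow(table)) stop("subsample_size exceeds sample count", call. = FALSE)
  with_seed(seed, {
    obs <- null <- vector("list", n_iter)
    for (it in seq_len(n_iter)) {
      f <- NULL
      for (try in seq_len(10)) {
        idx <- sample.int(nrow(table), subsample_size)
        f <- droplevels(factor(md[[factor]][idx]))
        if (nlevels(f) >= 2) break
        f <- NULL
      }
      if (is.null(f)) stop("could not draw a subsample with >= 2 factor levels", call. = FALSE)
      co <- pcoa(bray_curtis(table[idx, , drop = FALSE]), k = n_axes)$coordinates
      r2 <- coord_r2(co, f)
      null_r2 <- vapply(seq_len(n_perm), function(j) coord_r2(co, sample(f)), numeric(1))
      p <- (1 + sum(null_r2 >= r2)) / (1 + n_perm)
      obs[[it]] <- data.frame(iter = it, R2 = r2, p = p)
      null[[it]] <- data.frame(iter = it, R2 = coord_r2(co, sample(f)))
    }
    list(observed = do.call(rbind, obs), null = do.call(rbind, null))
  })
}

#' Within-group distance variability comparison
#'
#' Collects all within-group pairwise distances per group and compares
#' requested group pairs with two-sided Mann-Whitney tests; used to ask
#' whether one population (e.g. elderly controls) is more variable than
#' another.
#'
#' @param dist distance matrix.
#' @param groups factor or character vector aligned with `dist` rows.
#' @param comparisons list of length-2 character vectors; default all pairs.
#' @return list with `distances` (named list of within-group distance
#'   vectors) and `tests` (data.frame `group1`, `group2`, `p`). Groups with
#'   fewer than 3 samples are excluded with a warning.
#' @export
intra_group_variability <- function(dist, groups, comparisons = NULL) {
  D <- as.matrix(dist)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(D))
  lev <- unique(groups)
  sizes <- table(groups)[lev]
  small <- lev[sizes < 3]
  if (length(small)) {
    warning("groups excluded (fewer than 3 samples): ", paste(small, collapse = ", "))
    lev <- setdiff(lev, small)
  }
  dists <- lapply(stats::setNames(lev, lev), function(g) {
    idx <- which(groups == g)
    D[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))]
  })
  if (is.null(comparisons))
    comparisons <- if (length(lev) >= 2) utils::combn(lev, 2, simplify = FALSE) else list()
  tests <- do.call(rbind, lapply(comparisons, function(pr) {
    data.frame(group1 = pr[1], group2 = pr[2],
               p = stats::wilcox.test(dists[[pr[1]]], dists[[pr[2]]])$p.value)
  }))
  list(distances = dists, tests = tests)
}
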