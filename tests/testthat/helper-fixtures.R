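# Shared fixtures, generated in code and cached per test session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixture_env)) assign(name, make(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# small two-disease cohort with default planted effects
small_cohort <- function() fixture("small_cohort", function() {
  generate_cohort(generator_config(n_species = 60, seed = 101))
})

# tiny deterministic abundance matrix
toy_table <- function() {
  m <- matrix(c(0.5, 0.3, 0.2,
                0.1, 0.6, 0.3,
                0.4, 0.0, 0.6), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), paste0("sp", 1:3)))
  m
}

# independent brute-force PERMANOVA oracle for a single factor: classic
# within/between sum-of-squares formula on squared distances, with the
# permutation p computed by exhaustive enumeration of label orderings.
permanova_oracle <- function(D, f) {
  f <- as.character(f)
  n <- nrow(D)
  ss_total <- sum(D[upper.tri(D)]^2) / n
  ss_within <- 0
  for (lev in unique(f)) {
    idx <- which(f == lev)
    sub <- D[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]^2) / length(idx)
  }
  a <- length(unique(f))
  ss_a <- ss_total - ss_within
  f_stat <- (ss_a / (a - 1)) / (ss_within / (n - a))
  perms <- all_perms_oracle(n)
  f_perm <- apply(perms, 1, function(ord) {
    fp <- f[ord]
    ssw <- 0
    for (lev in unique(fp)) {
      idx <- which(fp == lev)
      sub <- D[idx, idx, drop = FALSE]
      ssw <- ssw + sum(sub[upper.tri(sub)]^2) / length(idx)
    }
    ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
  })
  list(F = f_stat, R2 = ss_a / ss_total,
       p = mean(f_perm >= f_stat - 1e-12))
}

all_perms_oracle <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms_oracle(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) cbind(i, sub + (sub >= i))))
}
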