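#' Specify one synthetic study cohort
#'
#' Helper building the per-cohort entry of [generator_config()]: a study
#' label with its region and DNA-extraction batch, the disease it sampled,
#' and per-age-group counts of control and diseased individuals.
#'
#' @param study,country,continent,dna_extraction categorical labels.
#' @param disease disease label sampled by this cohort.
#' @param n_control,n_case named numeric vectors with entries `Young`,
#'   `Middle`, `Elderly` (zeros allowed, emulating age-skewed cohorts).
#' @export
cohort_spec <- function(study, country, continent, dna_extraction, disease,
                        n_control = c(Young = 20, Middle = 20, Elderly = 20),
                        n_case = c(Young = 20, Middle = 20, Elderly = 20)) {
  grp <- c("Young", "Middle", "Elderly")
  n_control <- n_control[grp]; n_case <- n_case[grp]
  names(n_control) <- names(n_case) <- grp
  n_control[is.na(n_control)] <- 0; n_case[is.na(n_case)] <- 0
  if (any(c(n_control, n_case) < 0)) stop("cohort counts must be >= 0", call. = FALSE)
  list(study = study, country = country, continent = continent,
       dna_extraction = dna_extraction, disease = disease,
       n_control = n_control, n_case = n_case)
}

#' Configuration of the synthetic multi-cohort generator
#'
#' The generator draws per-sample latent log-abundances as the sum of a
#' species baseline, country, study-batch and age-group random effects, a
#' planted disease effect (possibly differing by age group: the
#' disease-by-age interaction), and Gaussian noise. Species are detected
#' with probability following a logistic curve in the latent value
#' (threshold `tau`, slope `s`), which produces zero inflation, and detected
#' abundances are exponentiated and renormalised to relative abundances.
#'
#' @param n_species number of species.
#' @param cohorts list of [cohort_spec()] entries.
#' @param diseases disease labels (must cover the cohorts' diseases).
#' @param baseline_mean,baseline_sd mean/sd of species baselines on the
#'   latent log scale.
#' @param sigma_country,sigma_batch,sigma_age,sigma_noise sds of the
#'   country, study-batch, age-group and residual effects.
#' @param marker_spec named list (one entry per disease) with fields
#'   `fraction` (fraction of species carrying the disease effect),
#'   `effect` (either a named length-3 vector `c(Young=, Middle=, Elderly=)`
#'   applied to every marker, or a markers x 3 matrix; negative = loss) and
#'   optional `loss_fraction` (fraction of markers with flipped sign).
#' @param prevalence list with detection threshold `tau` (use `-Inf` for no
#'   zeros) and slope `s` (`0` gives a hard threshold).
#' @param shared_spec optional list planting multi-disease shared-response
#'   taxa: `n_per_group` (named counts over G1,G2,G3,L1,L2,L3), `effect`
#'   (magnitude) and `n_diseases` (how many diseases carry the effect).
#' @param elderly_control_marker_shift latent shift added to gain-marker
#'   taxa in elderly *controls* (ageing acquisition of pathobionts, which
#'   masks elderly disease signatures).
#' @param elderly_control_carrier_fraction fraction of elderly controls
#'   (a carrier subpopulation) acquiring the gain-marker shift -- a
#'   carriage-prevalence shift rather than a uniform abundance shift;
#'   default 1.
#' @param elderly_control_noise_mult multiplier on the residual sd of
#'   elderly controls (increased inter-individual variability with age).
#' @param antibiotic_rate fraction of samples flagged as antibiotic users.
#' @param frailty list: `base` score (`NULL` auto-centres the scores at the
#'   middle of `bounds`), `weights` (named vector over species; `NULL`
#'   places weight `weight` on `n_taxa` planted taxa), `n_taxa`, `weight`,
#'   `noise_sd`, `bounds` (score clipped to this range; the defaults mimic
#'   the FIM scale where higher = less frail), and `boost_baseline`
#'   (latent baseline increment for the frailty taxa; frailty-associated
#'   pathobionts are typically not rare, and a non-zero boost lets them
#'   contribute materially to community-level capability sums).
#' @param pseudo_count_frac pseudo-count (as fraction of the unit total)
#'   used for log transforms of the generated relative abundances.
#' @param seed integer seed; fixed seed implies byte-identical output.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_species = 100,
                             cohorts = NULL,
                             diseases = c("D1", "D2"),
                             baseline_mean = 0, baseline_sd = 1,
                             sigma_country = 0.5, sigma_batch = 0.3,
                             sigma_age = 0.3, sigma_noise = 1,
                             marker_spec = NULL,
                             prevalence = list(tau = -2, s = 1),
                             shared_spec = NULL,
                             elderly_control_marker_shift = 0,
                             elderly_control_carrier_fraction = 1,
                             elderly_control_noise_mult = 1,
                             antibiotic_rate = 0,
                             frailty = list(base = NULL, weights = NULL, n_taxa = 5,
                                            weight = 4, noise_sd = 2, bounds = c(18, 126)),
                             pseudo_count_frac = 1e-6,
                             seed = 1) {
  if (is.null(cohorts)) {
    cohorts <- list(
      cohort_spec("S1", "C1", "K1", "kitA", diseases[1]),
      cohort_spec("S2", "C2", "K1", "kitB", diseases[1]),
      cohort_spec("S3", "C1", "K1", "kitA", diseases[min(2, length(diseases))])
    )
  }
  for (s in c(baseline_sd, sigma_country, sigma_batch, sigma_age, sigma_noise))
    if (s < 0) stop("effect sds must be >= 0", call. = FALSE)
  if (is.null(marker_spec)) {
    marker_spec <- lapply(stats::setNames(diseases, diseases), function(d)
      list(fraction = 0.1, effect = c(Young = 1.5, Middle = 1.5, Elderly = 1.5),
           loss_fraction = 0.3))
  }
  frailty <- utils::modifyList(list(base = NULL, weights = NULL, n_taxa = 5, weight = 4,
                                    noise_sd = 2, bounds = c(18, 126),
                                    boost_baseline = 0),
                               frailty, keep.null = TRUE)
  prevalence <- utils::modifyList(list(tau = -2, s = 1), prevalence)
  cfg <- list(n_species = n_species, cohorts = cohorts, diseases = diseases,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              sigma_country = sigma_country, sigma_batch = sigma_batch,
              sigma_age = sigma_age, sigma_noise = sigma_noise,
              marker_spec = marker_spec, prevalence = prevalence,
              shared_spec = shared_spec,
              elderly_control_marker_shift = elderly_control_marker_shift,
              elderly_control_carrier_fraction = elderly_control_carrier_fraction,
              elderly_control_noise_mult = elderly_control_noise_mult,
              antibiotic_rate = antibiotic_rate,
              frailty = frailty, pseudo_count_frac = pseudo_count_frac,
              seed = seed)
  class(cfg) <- "generator_config"
  cfg
}

age_bounds <- list(Young = c(20, 39), Middle = c(40, 59), Elderly = c(60, 89))

# Build the planted-effect structures (delta array, shared groups, frailty
# weights). Called under the generator's seed.
plant_effects <- function(config) {
  grp <- c("Young", "Middle", "Elderly")
  species <- sprintf("sp%03d", seq_len(config$n_species))
  delta <- array(0, dim = c(config$n_species, 3, length(config$diseases)),
                 dimnames = list(species, grp, config$diseases))
  taken <- integer(0)
  for (d in config$diseases) {
    ms <- config$marker_spec[[d]]
    if (is.null(ms)) next
    if (!is.null(ms$species)) {
      idx <- match(ms$species, species)
    } else {
      m <- round((ms$fraction %||% 0) * config$n_species)
      idx <- if (m > 0) sample(setdiff(seq_len(config$n_species), taken), m) else integer(0)
    }
    taken <- union(taken, idx)
    if (length(idx) == 0L) next
    eff <- ms$effect
    eff <- if (is.matrix(eff)) eff[, grp, drop = FALSE]
           else matrix(rep(eff[grp], each = length(idx)), nrow = length(idx),
                       dimnames = list(NULL, grp))
    lf <- ms$loss_fraction %||% 0
    if (lf > 0) {
      n_loss <- round(lf * length(idx))
      if (n_loss > 0) eff[seq_len(n_loss), ] <- -eff[seq_len(n_loss), ]
    }
    delta[idx, , d] <- eff
  }
  shared <- stats::setNames(rep("none", config$n_species), species)
  if (!is.null(config$shared_spec)) {
    ss <- config$shared_spec
    eff <- ss$effect %||% 2
    nd <- min(ss$n_diseases %||% 2, length(config$diseases))
    dis <- config$diseases[seq_len(nd)]
    free <- setdiff(seq_len(config$n_species), taken)
    band_groups <- list(G1 = grp, G2 = "Elderly", G3 = c("Young", "Middle"),
                        L1 = grp, L2 = "Elderly", L3 = c("Young", "Middle"))
    for (g in names(ss$n_per_group)) {
      n_g <- ss$n_per_group[[g]]
      if (n_g == 0) next
      if (length(free) < n_g) stop("not enough unassigned species for shared group ", g, call. = FALSE)
      idx <- free[seq_len(n_g)]
      free <- setdiff(free, idx)
      taken <- union(taken, idx)
      sgn <- if (startsWith(g, "G")) 1 else -1
      delta[idx, band_groups[[g]], dis] <- sgn * eff
      shared[idx] <- g
    }
  }
  w <- stats::setNames(rep(0, config$n_species), species)
  if (!is.null(config$frailty$weights)) {
    w[names(config$frailty$weights)] <- config$frailty$weights
  } else if ((config$frailty$n_taxa %||% 0) > 0) {
    cand <- which(shared == "G1")
    if (length(cand) < config$frailty$n_taxa) {
      gain <- which(apply(delta > 0, 1, any))
      cand <- unique(c(cand, gain))
    }
    if (length(cand) < config$frailty$n_taxa)
      cand <- unique(c(cand, seq_len(config$n_species)))
    w[cand[seq_len(config$frailty$n_taxa)]] <- config$frailty$weight
  }
  list(species = species, delta = delta, shared = shared, frailty_weights = w)
}

#' Generate a synthetic multi-cohort dataset
#'
#' Draws compositional species profiles, sample metadata and the planted
#' ground truth from a [generator_config()]. See that help page for the
#' generative model.
#'
#' @param config a `generator_config`.
#' @return list with `table` (samples x species relative abundances summing
#'   to 1 per sample), `metadata` (data.frame) and `truth` (planted effects:
#'   `delta` array species x age-group x disease, per-disease `markers` and
#'   `age_specific` marker ids, `directions` sign array, `shared_groups`,
#'   `frailty_weights`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  grp <- c("Young", "Middle", "Elderly")
  total <- sum(vapply(config$cohorts, function(co) sum(co$n_control) + sum(co$n_case), numeric(1)))
  if (total == 0) stop("zero samples requested", call. = FALSE)
  with_seed(config$seed, {
    planted <- plant_effects(config)
    species <- planted$species
    p <- config$n_species

    rows <- list()
    for (co in config$cohorts) {
      for (g in grp) {
        for (arm in c("control", "disease")) {
          n <- if (arm == "control") co$n_control[[g]] else co$n_case[[g]]
          if (n == 0) next
          rows[[length(rows) + 1L]] <- data.frame(
            study = co$study, country = co$country, continent = co$continent,
            dna_extraction = co$dna_extraction, age_group = g,
            condition = arm,
            disease = if (arm == "disease") co$disease else "none",
            n = n, stringsAsFactors = FALSE)
        }
      }
    }
    md <- do.call(rbind, rows)
    md <- md[rep(seq_len(nrow(md)), md$n), setdiff(names(md), "n")]
    md$age <- vapply(md$age_group, function(g)
      sample(age_bounds[[g]][1]:age_bounds[[g]][2], 1), numeric(1))
    md$antibiotics <- stats::runif(nrow(md)) < config$antibiotic_rate
    md$sample_id <- sprintf("smp%04d", seq_len(nrow(md)))
    rownames(md) <- NULL
    md <- md[, c("sample_id", "study", "country", "continent", "dna_extraction",
                 "age", "age_group", "condition", "disease", "antibiotics")]
    n <- nrow(md)

    mu <- stats::rnorm(p, config$baseline_mean, config$baseline_sd)
    if ((config$frailty$boost_baseline %||% 0) != 0)
      mu <- mu + config$frailty$boost_baseline * (planted$frailty_weights > 0)
    countries <- unique(md$country)
    studies <- unique(md$study)
    C <- matrix(stats::rnorm(length(countries) * p, 0, config$sigma_country),
                length(countries), p, dimnames = list(countries, NULL))
    B <- matrix(stats::rnorm(length(studies) * p, 0, config$sigma_batch),
                length(studies), p, dimnames = list(studies, NULL))
    A <- matrix(stats::rnorm(3 * p, 0, config$sigma_age), 3, p,
                dimnames = list(grp, NULL))

    latent_mean <- matrix(mu, n, p, byrow = TRUE) +
      C[md$country, , drop = FALSE] + B[md$study, , drop = FALSE] +
      A[md$age_group, , drop = FALSE]
    for (d in config$diseases) {
      hit <- which(md$condition == "disease" & md$disease == d)
      if (length(hit))
        latent_mean[hit, ] <- latent_mean[hit, ] + t(planted$delta[, md$age_group[hit], d])
    }
    gain_markers <- which(apply(planted$delta > 0, 1, any))
    eld_ctl <- which(md$condition == "control" & md$age_group == "Elderly")
    if (config$elderly_control_marker_shift != 0 && length(eld_ctl) && length(gain_markers)) {
      frac <- config$elderly_control_carrier_fraction %||% 1
      # a carrier subpopulation of elderly controls acquires the gain-marker
      # taxa: a carriage-prevalence shift, not a uniform population shift
      carriers <- if (frac >= 1) eld_ctl else
        sample(eld_ctl, round(frac * length(eld_ctl)))
      latent_mean[carriers, gain_markers] <-
        latent_mean[carriers, gain_markers] + config$elderly_control_marker_shift
    }
    noise_sd <- rep(config$sigma_noise, n)
    noise_sd[eld_ctl] <- noise_sd[eld_ctl] * config$elderly_control_noise_mult

    draw_sample <- function(i) {
      a <- latent_mean[i, ] + stats::rnorm(p, 0, noise_sd[i])
      tau <- config$prevalence$tau; s <- config$prevalence$s
      det <- if (s == 0) a >= tau else stats::runif(p) < stats::plogis((a - tau) / s)
      x <- exp(a) * det
      x
    }
    tab <- matrix(0, n, p, dimnames = list(md$sample_id, species))
    for (i in seq_len(n)) {
      x <- draw_sample(i)
      if (all(x == 0)) x <- draw_sample(i)  # one resample on an all-miss draw
      if (all(x == 0))
        stop("sample ", md$sample_id[i], " detected no species; raise tau or slope", call. = FALSE)
      tab[i, ] <- x / sum(x)
    }

    dirs <- sign(planted$delta)
    markers <- lapply(stats::setNames(config$diseases, config$diseases), function(d)
      species[apply(planted$delta[, , d, drop = FALSE] != 0, 1, any)])
    age_specific <- lapply(stats::setNames(config$diseases, config$diseases), function(d) {
      dd <- planted$delta[, , d]
      species[apply(dd, 1, function(v) any(v != 0) && length(unique(v)) > 1)]
    })
    truth <- list(species = species, delta = planted$delta, directions = dirs,
                  markers = markers, age_specific = age_specific,
                  shared_groups = planted$shared,
                  frailty_weights = planted$frailty_weights,
                  samples = md)
    list(table = tab, metadata = md, truth = truth)
  })
}

#' Generate per-sample frailty scores from planted taxa
#'
#' Scores emulate a functional-independence measure: higher score = less
#' frail. The score is `clip(base - sum_j w_j * log(x_ij + pc) + noise,
#' bounds)`, so positive weights on pathobiont taxa lower the score (more
#' frail) as those taxa become more abundant.
#'
#' @param table samples x species relative abundances.
#' @param truth planted truth from [generate_cohort()] (supplies the
#'   weights) or `NULL` to take weights from `config$frailty$weights`.
#' @param config the `generator_config` used for the cohort.
#' @return data.frame with `sample_id` and `score`.
#' @export
generate_frailty_scores <- function(table, truth, config) {
  check_abundance(table)
  w_full <- if (!is.null(truth)) truth$frailty_weights else config$frailty$weights
  if (is.null(w_full)) stop("no frailty weights available", call. = FALSE)
  w <- stats::setNames(rep(0, ncol(table)), colnames(table))
  common <- intersect(names(w_full), colnames(table))
  w[common] <- w_full[common]
  pc <- config$pseudo_count_frac
  fr <- config$frailty
  wsum <- as.numeric(log(table + pc) %*% w)
  # NULL base: centre the score distribution at the middle of the bounds
  base <- fr$base %||% (mean(fr$bounds) + mean(wsum))
  with_seed(config$seed + 1000L, {
    raw <- base - wsum + stats::rnorm(nrow(table), 0, fr$noise_sd)
    score <- pmin(pmax(raw, fr$bounds[1]), fr$bounds[2])
    data.frame(sample_id = rownames(table), score = score, stringsAsFactors = FALSE)
  })
}

#' Generate a binary species-to-metabolite capability map
#'
#' Random map with a given fill density, with optional forced capabilities
#' used to plant metabolite signatures on designated marker taxa.
#'
#' @param n_species number of species (or a character vector of species ids).
#' @param profiles data.frame with columns `profile_id` and `direction`
#'   (`production`, `consumption` or `degradation`), or a character vector of
#'   profile labels whose direction is parsed from a `_production` /
#'   `_consumption` / `_degradation` suffix.
#' @param density fill probability in `[0, 1]`.
#' @param seed integer seed.
#' @param forced named list `profile_id -> species ids` set to 1 regardless
#'   of density.
#' @return object of class `metabolite_map`: list with `matrix` (species x
#'   profiles, 0/1) and `profiles` (data.frame with direction labels).
#' @export
generate_metabolite_map <- function(n_species, profiles, density = 0.1, seed = 1,
                                    forced = NULL) {
  if (density < 0 || density > 1) stop("density must be in [0, 1]", call. = FALSE)
  species <- if (is.character(n_species)) n_species else sprintf("sp%03d", seq_len(n_species))
  if (is.character(profiles)) {
    dir <- rep("production", length(profiles))
    dir[grepl("_consumption$", profiles)] <- "consumption"
    dir[grepl("_degradation$", profiles)] <- "degradation"
    profiles <- data.frame(profile_id = profiles, direction = dir, stringsAsFactors = FALSE)
  }
  if (anyDuplicated(profiles$profile_id))
    stop("duplicate profile label: ",
         profiles$profile_id[duplicated(profiles$profile_id)][1], call. = FALSE)
  with_seed(seed, {
    m <- matrix(as.numeric(stats::runif(length(species) * nrow(profiles)) < density),
                length(species), nrow(profiles),
                dimnames = list(species, profiles$profile_id))
    for (pr in names(forced %||% list())) m[forced[[pr]], pr] <- 1
    structure(list(matrix = m, profiles = profiles), class = "metabolite_map")
  })
}

#' @export
print.metabolite_map <- function(x, ...) {
  cat("Species-to-metabolite map:", nrow(x$matrix), "species x",
      ncol(x$matrix), "profiles; fill",
      sprintf("%.3f", mean(x$matrix)), "\n")
  invisible(x)
}

#' Write the planted truth as a sidecar TSV
#'
#' Long-format record of every planted per-species effect (disease,
#' age-group, effect size), the shared-response group label and the frailty
#' weight, so that external tools can score recovery.
#'
#' @param truth truth list from [generate_cohort()].
#' @param path output TSV path.
#' @export
write_truth <- function(truth, path) {
  grid <- expand.grid(species = truth$species,
                      age_group = dimnames(truth$delta)[[2]],
                      disease = dimnames(truth$delta)[[3]],
                      stringsAsFactors = FALSE)
  grid$delta <- as.vector(truth$delta)
  grid$shared_group <- truth$shared_groups[grid$species]
  grid$frailty_weight <- truth$frailty_weights[grid$species]
  utils::write.table(grid, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
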