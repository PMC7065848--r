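#' Pipeline configuration
#'
#' Bundles a synthetic-generator configuration (or paths to input files)
#' with stage toggles and per-stage parameters. Defaults follow the
#' standard protocol: 100 outer x 20 inner classifier iterations, the 85th
#' percentile marker threshold, importance-comparison FDR 0.01,
#' directionality FDR 0.1, 10 samples per disease and 5 repeats for the
#' generic classifiers, and the 20%/80% frailty train/test split.
#'
#' @param generator a [generator_config()], or `NULL` when `paths` supplies
#'   pre-existing input files (`abundance`, `metadata`, `frailty`, `map`).
#' @param paths named list of input paths (used when `generator` is NULL).
#' @param stages named logical vector toggling `permanova`, `age_aware`,
#'   `markers`, `directionality`, `shared`, `frailty`, `metabolome`.
#' @param n_perm,n_outer,n_inner,num_trees,percentile,importance_fdr,
#'   directionality_fdr,per_disease_n,generic_repeats,train_frac stage
#'   parameters (see the stage functions).
#' @param seed global seed; every stage derives its stream from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(generator = generator_config(),
                            paths = NULL,
                            stages = c(permanova = TRUE, age_aware = TRUE,
                                       markers = TRUE, directionality = TRUE,
                                       shared = TRUE, frailty = TRUE,
                                       metabolome = TRUE),
                            n_perm = 999, n_outer = 100, n_inner = 20,
                            num_trees = 500, percentile = 85,
                            importance_fdr = 0.01, directionality_fdr = 0.1,
                            per_disease_n = 10, generic_repeats = 5,
                            train_frac = 0.2, seed = 1) {
  defaults <- c(permanova = TRUE, age_aware = TRUE, markers = TRUE,
                directionality = TRUE, shared = TRUE, frailty = TRUE,
                metabolome = TRUE)
  defaults[names(stages)] <- stages
  structure(list(generator = generator, paths = paths, stages = defaults,
                 n_perm = n_perm, n_outer = n_outer, n_inner = n_inner,
                 num_trees = num_trees, percentile = percentile,
                 importance_fdr = importance_fdr,
                 directionality_fdr = directionality_fdr,
                 per_disease_n = per_disease_n, generic_repeats = generic_repeats,
                 train_frac = train_frac, seed = seed),
            class = "pipeline_config")
}

write_tsv <- function(df, dir, name) {
  utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full age-aware analysis pipeline
#'
#' Executes the stage sequence (generate/load, PERMANOVA, age-aware
#' classification, marker discovery, directionality, shared-response
#' grouping, frailty regression, metabolite inference) in dependency
#' order, writing TSV outputs, a JSON manifest stamped with the config
#' hash and seed, and a log to `out_dir`. With a fixed config the output
#' tree (log excluded: it records wall times) is byte-identical across
#' reruns. A stage whose prerequisite stage is toggled off fails with an
#' error naming the dependency.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  cat("agemark pipeline | seed ", config$seed, " | config ", config_hash(config),
      "\n", sep = "", file = log_path)
  say <- function(...) {
    msg <- paste0(...)
    cat(format(Sys.time(), "%H:%M:%S"), " ", msg, "\n", sep = "",
        file = log_path, append = TRUE)
  }
  st <- config$stages
  need <- function(stage, dep) {
    if (!isTRUE(st[dep]))
      stop("stage '", stage, "' requires disabled stage '", dep, "'", call. = FALSE)
  }
  res <- list()

  say("stage: inputs")
  if (!is.null(config$generator)) {
    gen <- generate_cohort(config$generator)
    frailty <- generate_frailty_scores(gen$table, gen$truth, config$generator)
    frail_taxa <- names(which(gen$truth$frailty_weights > 0))
    map <- generate_metabolite_map(
      colnames(gen$table),
      profiles = c(sprintf("met%02d_production", 1:8),
                   sprintf("met%02d_consumption", 9:14),
                   "cholate_degradation", "frailty_marker_production"),
      density = 0.15, seed = config$seed + 7,
      forced = list(frailty_marker_production = frail_taxa))
    write_abundance(gen$table, file.path(out_dir, "abundance.tsv"))
    write_metadata(gen$metadata, file.path(out_dir, "metadata.tsv"))
    write_truth(gen$truth, file.path(out_dir, "truth.tsv"))
    write_tsv(frailty, out_dir, "frailty_scores.tsv")
    write_metabolite_map(map, file.path(out_dir, "metabolite_map.tsv"))
    table <- gen$table; md <- gen$metadata; truth <- gen$truth
  } else {
    table <- read_abundance(config$paths$abundance)
    md <- read_metadata(config$paths$metadata)
    frailty <- utils::read.delim(config$paths$frailty)
    map <- read_metabolite_map(config$paths$map)
    truth <- NULL
  }
  diseases <- setdiff(unique(md$disease), "none")
  bins <- lapply(stats::setNames(diseases, diseases), function(d)
    build_disease_bins(md, d, "country"))
  res$inputs <- list(table = table, metadata = md, truth = truth,
                     frailty = frailty, map = map, bins = bins)

  if (isTRUE(st["permanova"])) {
    say("stage: permanova")
    out <- lapply(diseases, function(d) {
      keep <- md$sample_id %in% bins[[d]]$sample_ids
      sub <- table[keep, , drop = FALSE]
      sub_md <- md[keep, , drop = FALSE]
      terms <- c(if (length(unique(sub_md$country)) > 1) "country",
                 "condition", "age_group", "condition:age_group")
      pv <- permanova(bray_curtis(sub), sub_md, terms,
                      n_perm = config$n_perm, seed = config$seed + 11)
      cbind(disease = d, term = rownames(pv), as.data.frame(pv))
    })
    out <- do.call(rbind, out)
    write_tsv(out, out_dir, "permanova.tsv")
    res$permanova <- out
  }

  runs <- NULL
  if (isTRUE(st["age_aware"])) {
    say("stage: age_aware")
    runs <- lapply(stats::setNames(diseases, diseases), function(d) {
      grp_runs <- list()
      for (g in c("Young", "Middle", "Elderly")) {
        r <- tryCatch(
          age_aware_evaluation(table, md, d, g, bin = bins[[d]],
                               n_outer = config$n_outer, n_inner = config$n_inner,
                               num_trees = config$num_trees,
                               seed = config$seed + 100 + match(g, c("Young", "Middle", "Elderly"))),
          error = function(e) {
            say("  skipped ", d, "/", g, ": ", conditionMessage(e))
            NULL
          })
        if (!is.null(r)) grp_runs[[g]] <- r
      }
      grp_runs
    })
    summaries <- do.call(rbind, lapply(diseases, function(d) {
      if (length(runs[[d]]) == 0) return(NULL)
      s <- do.call(rbind, lapply(runs[[d]], summary))
      wt <- paired_auc_test(runs[[d]]); pt <- permutation_auc_test(runs[[d]])
      s$p_paired_holm <- wt$p_holm; s$p_permutation_holm <- pt$p_holm
      s
    }))
    write_tsv(summaries, out_dir, "age_aware_summary.tsv")
    res$age_aware <- list(runs = runs, summary = summaries)
  }

  if (isTRUE(st["markers"])) {
    need("markers", "age_aware")
    say("stage: markers")
    marker_out <- lapply(stats::setNames(diseases, diseases), function(d) {
      if (length(runs[[d]]) < 2) return(NULL)
      scores <- compute_marker_scores(runs[[d]])
      cross <- compare_importance_across_groups(scores, fdr = config$importance_fdr)
      keep <- md$sample_id %in% bins[[d]]$sample_ids
      llr <- llr_deconvolution(table[keep, , drop = FALSE], md[keep, , drop = FALSE])
      list(scores = scores, threshold = stability_threshold(scores),
           markers = select_markers(scores, config$percentile),
           cross = cross, llr = llr,
           validated = validated_markers(scores, cross, llr, config$percentile))
    })
    flat <- do.call(rbind, lapply(diseases, function(d) {
      mo <- marker_out[[d]]
      if (is.null(mo)) return(NULL)
      do.call(rbind, lapply(names(mo$scores), function(g)
        cbind(disease = d, age_group = g, mo$scores[[g]])))
    }))
    write_tsv(flat, out_dir, "marker_scores.tsv")
    write_tsv(do.call(rbind, lapply(diseases, function(d) {
      mo <- marker_out[[d]]
      if (is.null(mo) || length(mo$validated) == 0) return(NULL)
      data.frame(disease = d, taxon = mo$validated)
    })) %||% data.frame(disease = character(), taxon = character()),
    out_dir, "validated_markers.tsv")
    res$markers <- marker_out
  }

  dir_all <- NULL
  if (isTRUE(st["directionality"])) {
    need("directionality", "markers")
    say("stage: directionality")
    dir_all <- do.call(rbind, lapply(diseases, function(d) {
      mo <- res$markers[[d]]
      if (is.null(mo)) return(NULL)
      mk <- unique(unlist(mo$markers))
      if (length(mk) == 0) return(NULL)
      keep <- md$sample_id %in% bins[[d]]$sample_ids
      dt <- directionality(table[keep, , drop = FALSE], md[keep, , drop = FALSE],
                           mk, level = "continent", fdr = config$directionality_fdr)
      cbind(disease = d, dt)
    }))
    write_tsv(dir_all, out_dir, "directionality.tsv")
    res$directionality <- dir_all
  }

  if (isTRUE(st["shared"])) {
    need("shared", "directionality")
    say("stage: shared")
    groups <- assign_shared_groups(res$directionality)
    gen_eval <- generic_classifier_evaluation(
      table, md, per_disease_n = config$per_disease_n,
      n_repeats = config$generic_repeats, num_trees = config$num_trees,
      seed = config$seed + 300)
    write_tsv(groups, out_dir, "shared_groups.tsv")
    write_tsv(gen_eval$results, out_dir, "generic_classifier.tsv")
    res$shared <- list(groups = groups, generic = gen_eval)
  }

  if (isTRUE(st["frailty"])) {
    say("stage: frailty")
    model <- frailty_regression(table, res$inputs$frailty,
                                train_frac = config$train_frac,
                                num_trees = config$num_trees,
                                seed = config$seed + 400)
    mm <- minimal_marker_set(table, res$inputs$frailty,
                             train_frac = config$train_frac, n_rep = 3,
                             num_trees = config$num_trees, seed = config$seed + 401)
    out <- data.frame(taxon = names(model$importance_rank),
                      importance = as.numeric(model$importance),
                      rank = as.numeric(model$importance_rank))
    if (!is.null(res$shared)) {
      gmr <- group_mean_ranks(model, res$shared$groups)
      write_tsv(data.frame(group = names(gmr), mean_rank = as.numeric(gmr)),
                out_dir, "frailty_group_ranks.tsv")
    }
    write_tsv(out, out_dir, "frailty_importance.tsv")
    write_tsv(mm$curve, out_dir, "frailty_error_curve.tsv")
    res$frailty <- list(model = model, minimal = mm)
  }

  if (isTRUE(st["metabolome"])) {
    need("metabolome", "frailty")
    say("stage: metabolome")
    prof <- metabolite_profiles(table, res$inputs$map)
    assoc <- metabolite_frailty_association(prof, res$inputs$frailty)
    enr <- marker_metabolite_enrichment(res$inputs$map, res$frailty$minimal$taxa,
                                        profiles = assoc$profile[assoc$significant])
    write_tsv(assoc, out_dir, "metabolite_association.tsv")
    write_tsv(enr, out_dir, "metabolite_enrichment.tsv")
    res$metabolome <- list(association = assoc, enrichment = enr)
  }

  manifest <- list(seed = config$seed, config_hash = config_hash(config),
                   stages_run = names(st)[st])
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  } else {
    writeLines(paste0(names(unlist(manifest)), "\t", unlist(manifest)),
               file.path(out_dir, "manifest.json"))
  }
  say("done")
  invisible(res)
}
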