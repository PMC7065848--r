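#' Read a species relative-abundance table
#'
#' Reads a merged taxonomic-profile TSV with one row per species and one
#' column per sample (the usual merged-profile dialect) or its transpose,
#' and returns a samples x species numeric matrix. Values are interpreted
#' as fractions; tables on a 0--100 scale are detected by per-sample sums
#' close to 100 and rescaled.
#'
#' @param path path to a tab-separated file. The first column holds row
#'   identifiers.
#' @param orientation `"species_rows"` (default merged-profile dialect),
#'   `"samples_rows"`, or `"auto"`, which inspects the header token of the
#'   identifier column (`species`/`taxon`/`clade` versus `sample`).
#' @param scale `"auto"` (detect percent tables by row sums near 100),
#'   `"fraction"` or `"percent"`.
#' @return numeric matrix, samples in rows, species in columns.
#' @export
read_abundance <- function(path, orientation = c("species_rows", "samples_rows", "auto"),
                           scale = c("auto", "fraction", "percent")) {
  orientation <- match.arg(orientation)
  scale <- match.arg(scale)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("abundance file needs an id column plus data columns", call. = FALSE)
  id_name <- names(df)[1]
  if (orientation == "auto") {
    orientation <- if (grepl("sample", id_name, ignore.case = TRUE))
      "samples_rows" else "species_rows"
  }
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicated row id in ", path, ": ", ids[duplicated(ids)][1], call. = FALSE)
  cn <- names(df)[-1]
  if (anyDuplicated(cn))
    stop("duplicated column in ", path, ": ", cn[duplicated(cn)][1], call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric abundance values in ", path, call. = FALSE)
  rownames(m) <- ids
  if (orientation == "species_rows") m <- t(m)
  if (any(m < 0)) {
    bad <- rownames(m)[which(rowSums(m < 0) > 0)[1]]
    stop("negative abundance values in sample ", bad, call. = FALSE)
  }
  rs <- rowSums(m)
  if (scale == "percent" || (scale == "auto" && all(rs > 50) && all(abs(rs - 100) < 25)))
    m <- m / 100
  check_abundance(m)
  m
}

#' Write a species relative-abundance table
#'
#' Writes the merged-profile dialect (species rows, sample columns) so that
#' [read_abundance()] round-trips the table.
#'
#' @param table samples x species matrix.
#' @param path output path.
#' @export
write_abundance <- function(table, path) {
  check_abundance(table)
  out <- data.frame(species_id = colnames(table), t(table), check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write per-sample metadata
#'
#' Metadata is a TSV with one row per sample and a mandatory `sample_id`
#' column; the conventional columns are `age`, `age_group`, `country`,
#' `continent`, `study`, `dna_extraction`, `condition` (`control`/`disease`),
#' `disease` and `antibiotics`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(md)) stop("metadata must have a 'sample_id' column", call. = FALSE)
  if (anyDuplicated(md$sample_id))
    stop("duplicated sample_id: ", md$sample_id[duplicated(md$sample_id)][1], call. = FALSE)
  md
}

#' @rdname read_metadata
#' @param metadata data.frame with a `sample_id` column.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assign adult age groups
#'
#' Bins ages into Young (20--39 years), Middle (40--59) and Elderly (60 and
#' above). Ages below 20 fall outside the adult binning and are marked
#' `"OutOfRange"`; such samples are conventionally dropped by
#' [filter_samples()].
#'
#' @param age numeric vector of ages in years.
#' @return character vector with values in
#'   `c("Young", "Middle", "Elderly", "OutOfRange")`.
#' @export
assign_age_group <- function(age) {
  if (!is.numeric(age)) stop("age must be numeric", call. = FALSE)
  if (any(age < 0, na.rm = TRUE)) stop("negative age", call. = FALSE)
  out <- rep(NA_character_, length(age))
  out[!is.na(age) & age < 20] <- "OutOfRange"
  out[!is.na(age) & age >= 20 & age <= 39] <- "Young"
  out[!is.na(age) & age >= 40 & age <= 59] <- "Middle"
  out[!is.na(age) & age >= 60] <- "Elderly"
  out
}

#' Filter samples by QC rules
#'
#' Applies the standard sample exclusions: minimum age (adult binning),
#' antibiotic use, and excluded studies or DNA-extraction labels. A missing
#' antibiotics flag is treated as non-use (and counted in the report).
#'
#' @param table samples x species matrix.
#' @param metadata matching metadata (see [read_metadata()]).
#' @param rules list with any of `min_age` (numeric), `drop_antibiotics`
#'   (logical), `exclude_studies`, `exclude_extraction` (character vectors).
#' @return list with elements `table`, `metadata` and `report` (named counts
#'   of removals per rule).
#' @export
filter_samples <- function(table, metadata,
                           rules = list(min_age = 20, drop_antibiotics = TRUE)) {
  check_abundance(table)
  md <- match_meta(table, metadata)
  keep <- rep(TRUE, nrow(md))
  report <- c()
  if (!is.null(rules$min_age)) {
    if (!"age" %in% names(md)) stop("rule 'min_age' needs an 'age' metadata field", call. = FALSE)
    drop <- keep & (is.na(md$age) | md$age < rules$min_age)
    report["min_age"] <- sum(drop)
    keep <- keep & !drop
  }
  if (isTRUE(rules$drop_antibiotics)) {
    if (!"antibiotics" %in% names(md))
      stop("rule 'drop_antibiotics' needs an 'antibiotics' metadata field", call. = FALSE)
    abx <- md$antibiotics
    n_missing <- sum(keep & is.na(abx))
    if (n_missing > 0)
      message(n_missing, " samples with missing antibiotics flag treated as non-users")
    drop <- keep & !is.na(abx) & as.logical(abx)
    report["antibiotics"] <- sum(drop)
    keep <- keep & !drop
  }
  if (!is.null(rules$exclude_studies)) {
    if (!"study" %in% names(md)) stop("rule 'exclude_studies' needs a 'study' field", call. = FALSE)
    drop <- keep & md$study %in% rules$exclude_studies
    report["exclude_studies"] <- sum(drop)
    keep <- keep & !drop
  }
  if (!is.null(rules$exclude_extraction)) {
    if (!"dna_extraction" %in% names(md))
      stop("rule 'exclude_extraction' needs a 'dna_extraction' field", call. = FALSE)
    drop <- keep & md$dna_extraction %in% rules$exclude_extraction
    report["exclude_extraction"] <- sum(drop)
    keep <- keep & !drop
  }
  list(table = table[keep, , drop = FALSE],
       metadata = md[keep, , drop = FALSE],
       report = as.list(report))
}

#' Drop sparse and redundant metadata fields
#'
#' Removes fields recorded for less than `min_coverage` of the samples
#' (strictly less: a field present in exactly the threshold fraction is
#' kept) and, for each redundant pair, the designated duplicate field.
#'
#' @param metadata data.frame.
#' @param min_coverage minimum non-missing fraction, default 0.30.
#' @param redundant_pairs list of length-2 character vectors `c(keep, drop)`.
#' @return filtered data.frame.
#' @export
filter_metadata_fields <- function(metadata, min_coverage = 0.30, redundant_pairs = list()) {
  coverage <- vapply(metadata, function(x) mean(!is.na(x) & x != ""), numeric(1))
  keep <- coverage >= min_coverage | names(metadata) == "sample_id"
  md <- metadata[, keep, drop = FALSE]
  for (pair in redundant_pairs) {
    if (length(pair) != 2L) stop("redundant pairs must be c(keep, drop)", call. = FALSE)
    if (pair[2] %in% names(md) && pair[1] %in% names(metadata))
      md[[pair[2]]] <- NULL
  }
  md
}

#' Build a region-matched disease bin
#'
#' Collects all cases of a disease together with every control sample whose
#' region matches the region of at least one case, at the study, country or
#' continent level. Pooling region-matched controls preserves regional
#' homogeneity while recovering statistical power across age groups.
#'
#' @param metadata metadata data.frame with `condition`, `disease` and the
#'   region column named by `level`.
#' @param disease disease label.
#' @param level one of `"study"`, `"country"`, `"continent"`.
#' @return an object of class `cohort_bin`: list with `disease`, `level`,
#'   `case_ids`, `control_ids`, `sample_ids`.
#' @export
build_disease_bins <- function(metadata, disease, level = c("country", "study", "continent")) {
  level <- match.arg(level)
  if (!level %in% names(metadata)) stop("metadata lacks a '", level, "' column", call. = FALSE)
  cases <- metadata$condition == "disease" & metadata$disease == disease
  cases[is.na(cases)] <- FALSE
  if (!any(cases)) stop("no samples with disease '", disease, "'", call. = FALSE)
  regions <- unique(metadata[[level]][cases])
  ctrl <- metadata$condition == "control" & metadata[[level]] %in% regions
  structure(list(disease = disease, level = level,
                 case_ids = metadata$sample_id[cases],
                 control_ids = metadata$sample_id[ctrl],
                 sample_ids = c(metadata$sample_id[cases], metadata$sample_id[ctrl])),
            class = "cohort_bin")
}

#' @export
print.cohort_bin <- function(x, ...) {
  cat("Disease bin:", x$disease, "at", x$level, "level\n")
  cat("  cases:   ", length(x$case_ids), "\n")
  cat("  controls:", length(x$control_ids), "\n")
  invisible(x)
}
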