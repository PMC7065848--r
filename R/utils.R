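# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a local RNG state seeded with `seed`, restoring the global
# .Random.seed afterwards so package functions never disturb user RNG flow.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
}

# Default zero-replacement for log transforms: half the smallest nonzero value.
default_pseudo_count <- function(values) {
  nz <- values[values > 0]
  if (length(nz) == 0L) return(1e-6)
  min(nz) / 2
}

check_abundance <- function(table) {
  if (!is.matrix(table) || !is.numeric(table))
    stop("abundance table must be a numeric matrix (samples x species)", call. = FALSE)
  if (is.null(rownames(table)) || is.null(colnames(table)))
    stop("abundance table must carry sample (row) and species (column) names", call. = FALSE)
  if (anyDuplicated(rownames(table)))
    stop("duplicated sample ids: ", rownames(table)[duplicated(rownames(table))][1], call. = FALSE)
  if (anyDuplicated(colnames(table)))
    stop("duplicated species ids: ", colnames(table)[duplicated(colnames(table))][1], call. = FALSE)
  if (any(table < 0))
    stop("negative abundances in sample ", rownames(table)[which(rowSums(table < 0) > 0)[1]],
         call. = FALSE)
  invisible(table)
}

match_meta <- function(table, metadata) {
  if (!"sample_id" %in% names(metadata))
    stop("metadata must contain a 'sample_id' column", call. = FALSE)
  idx <- match(rownames(table), metadata$sample_id)
  if (anyNA(idx))
    stop("samples absent from metadata: ", rownames(table)[which(is.na(idx))[1]], call. = FALSE)
  metadata[idx, , drop = FALSE]
}

# Small stable content hash (FNV-1a over the serialized object) used for
# provenance stamps in pipeline outputs.
config_hash <- function(x) {
  bytes <- serialize(x, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}
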