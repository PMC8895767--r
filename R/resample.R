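# By-position resampling: depth-capped partitioning of pileup columns with
# quality-preferential retention and last-partition refill.

#' Resampling configuration
#'
#' @param max_depth Maximum observations per partition (default 100).
#' @param max_partitions Maximum number of partitions at a downsampled
#'   position (default 5).
#' @param base_q_cutoff Base-quality cutoff applied only when resampling
#'   triggers (default Phred 5).
#' @param min_mapq Minimum mapping quality for retained alignments
#'   (default 60).
#' @param seed Integer seed for the per-column shuffles.
#' @return A list of class `capcall_resample_config`.
#' @export
resample_config <- function(max_depth = 100, max_partitions = 5,
                            base_q_cutoff = 5, min_mapq = 60, seed = 1L) {
  check_scalar_number(max_depth, "max_depth", min = 1)
  check_scalar_number(max_partitions, "max_partitions", min = 1)
  check_scalar_number(base_q_cutoff, "base_q_cutoff", min = 0)
  check_scalar_number(min_mapq, "min_mapq", min = 0)
  cfg <- list(max_depth = as.integer(max_depth),
              max_partitions = as.integer(max_partitions),
              base_q_cutoff = base_q_cutoff, min_mapq = min_mapq,
              seed = as.integer(seed))
  class(cfg) <- "capcall_resample_config"
  cfg
}

#' Partition one pileup column into depth-capped replicates
#'
#' With raw depth `d` at or below `max_depth` the column passes through
#' unchanged as a single partition — no base-quality filter is applied, so
#' low-depth positions lose no information. Above `max_depth`:
#' observations below `base_q_cutoff` are dropped; if the remaining pool
#' still exceeds `max_depth` it is capped at `max_partitions * max_depth`
#' observations keeping the highest qualities (ties broken by ascending
#' `read_id`), shuffled, and chunked into partitions of exactly
#' `max_depth`; a short last chunk is refilled by sampling (without
#' replacement, within the partition) from the other retained
#' observations, so a read may appear in two partitions but never twice in
#' one. Deterministic for a fixed seed: the column position perturbs the
#' configured seed so each column shuffles independently but reproducibly.
#'
#' @param column Observation tibble for a single position (as one group of
#'   [build_pileup()] output); must be non-empty.
#' @param config A [resample_config()].
#' @return An object of class `capcall_partitions`: a list with `column`
#'   (the input), `partitions` (list of observation tibbles) and `config`.
#' @export
partition_column <- function(column, config = resample_config()) {
  if (!is.data.frame(column) || nrow(column) == 0) {
    abort("column must be a non-empty observation tibble")
  }
  stopifnot(all(c("read_id", "kind", "allele", "qual") %in% names(column)))
  if (length(unique(column$pos %||% 0L)) > 1) {
    abort("column spans more than one position")
  }
  if (anyDuplicated(column$read_id)) {
    abort("column has more than one observation for a read")
  }
  d <- nrow(column)
  md <- config$max_depth
  if (d <= md) {
    return(new_partitions(column, list(column), config))
  }
  pool <- column[column$qual >= config$base_q_cutoff, ]
  dp <- nrow(pool)
  if (dp <= md) {
    return(new_partitions(column, list(pool), config))
  }
  n_part <- min(config$max_partitions, ceiling(dp / md))
  if (dp > n_part * md) {
    keep <- order(-pool$qual, pool$read_id)[seq_len(n_part * md)]
    pool <- pool[sort(keep), ]
    dp <- nrow(pool)
  }
  pos_key <- column$pos[1] %||% 0L
  chrom_key <- column$chrom[1] %||% ""
  parts <- with_seed(derive_seed(config$seed, chrom_key, pos_key), {
    perm <- sample.int(dp)
    chunks <- split(perm, ceiling(seq_along(perm) / md))
    last <- chunks[[length(chunks)]]
    short <- md - length(last)
    if (short > 0) {
      remaining <- setdiff(perm, last)
      refill <- sample(remaining, short)
      chunks[[length(chunks)]] <- c(last, refill)
    }
    lapply(chunks, function(ix) pool[sort(ix), ])
  })
  new_partitions(column, unname(parts), config)
}

new_partitions <- function(column, partitions, config) {
  structure(list(column = column, partitions = partitions, config = config),
            class = "capcall_partitions")
}

#' @export
print.capcall_partitions <- function(x, ...) {
  cat(sprintf("<capcall_partitions> depth %d -> %d partition(s) of sizes %s\n",
              nrow(x$column), length(x$partitions),
              paste(vapply(x$partitions, nrow, integer(1)), collapse = ", ")))
  invisible(x)
}

#' Partition statistics across columns
#'
#' Diagnostic summary of how the by-position resampling treated each
#' column.
#'
#' @param pileup A pileup observation tibble (possibly many positions).
#' @param config A [resample_config()].
#' @return A tibble with one row per column: `chrom`, `pos`, `raw_depth`,
#'   `filtered_depth`, `n_partitions`, `resampled`.
#' @export
partition_stats <- function(pileup, config = resample_config()) {
  pileup |>
    group_by(.data$chrom, .data$pos) |>
    dplyr::group_map(function(df, key) {
      cp <- partition_column(mutate(df, chrom = key$chrom, pos = key$pos), config)
      tibble(chrom = key$chrom, pos = key$pos,
             raw_depth = nrow(df),
             filtered_depth = sum(vapply(cp$partitions, nrow, integer(1))),
             n_partitions = length(cp$partitions),
             resampled = nrow(df) > config$max_depth)
    }) |>
    bind_rows()
}
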