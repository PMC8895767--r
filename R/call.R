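# End-to-end ensemble variant calling over target regions.

#' Caller configuration
#'
#' @param min_alt_fraction Minimum fraction of non-reference observations
#'   for a position to become a candidate (default 0.125).
#' @param min_alt_reads Minimum number of non-reference observations
#'   (default 4).
#' @param resample A [resample_config()] controlling alignment filtering
#'   and by-position partitioning.
#' @param pass_qual QUAL at or above which a non-conflicted call is marked
#'   PASS (below: LowQual).
#' @return A list of class `capcall_caller_config`.
#' @export
caller_config <- function(min_alt_fraction = 0.125, min_alt_reads = 4,
                          resample = resample_config(), pass_qual = 2) {
  check_scalar_number(min_alt_fraction, "min_alt_fraction", min = 0, max = 1)
  check_scalar_number(min_alt_reads, "min_alt_reads", min = 0)
  check_scalar_number(pass_qual, "pass_qual", min = 0)
  cfg <- list(min_alt_fraction = min_alt_fraction,
              min_alt_reads = min_alt_reads,
              resample = resample, pass_qual = pass_qual)
  class(cfg) <- "capcall_caller_config"
  cfg
}

#' Call variants over target regions with a model ensemble
#'
#' The full per-column pipeline: alignment filtering (primary, MAPQ) ->
#' pileup -> candidate test (non-reference fraction and count) ->
#' depth-capped partitioning -> every (partition x model) produces task
#' probabilities -> ensemble average -> decision -> VCF-style records.
#' Columns whose reference base is N are never candidates. Positions
#' falling inside an already-emitted deletion are suppressed so one
#' deletion event yields one record.
#'
#' @param reads A reads tibble.
#' @param ref Reference tibble.
#' @param regions Target regions tibble.
#' @param models A non-empty list of [probability_model()] objects.
#' @param config A [caller_config()].
#' @return A sorted variants tibble (`chrom`, `pos`, `ref`, `alt`, `gt`,
#'   `qual`, `filter`) of variant calls.
#' @export
call_targets <- function(reads, ref, regions, models = default_models(),
                         config = caller_config()) {
  if (!is.list(models) || length(models) == 0) {
    abort("at least one probability model is required")
  }
  for (m in models) {
    if (!inherits(m, "capcall_model")) abort("models must be probability_model objects")
  }
  validate_regions(regions)
  freads <- filter_alignments(reads, config$resample)
  if (nrow(freads) == 0) return(new_variants())
  idx <- index_reads(freads, ref)
  cands <- scan_candidates(idx, regions, config$min_alt_fraction,
                           config$min_alt_reads)
  if (nrow(cands) == 0) return(new_variants())
  ref_vec <- ref_as_vector(ref)

  records <- list()
  for (chr in unique(cands$chrom)) {
    positions <- sort(cands$pos[cands$chrom == chr])
    obs_all <- collect_observations(idx, chr, positions)
    refseq <- ref_vec[[chr]]
    covered_until <- 0L
    for (p in positions) {
      if (p <= covered_until) next
      ref_base <- substr(refseq, p, p)
      if (ref_base == "N") next
      column <- obs_all[obs_all$pos == p, ]
      if (nrow(column) == 0) next
      column$chrom <- chr
      parts <- partition_column(column, config$resample)$partitions
      outputs <- list()
      for (part in parts) {
        if (nrow(part) == 0) next
        for (m in models) outputs <- c(outputs, list(m$fn(part, ref_base)))
      }
      if (length(outputs) == 0) next
      avg <- average_probabilities(outputs)
      dec <- decide(avg, ref_base, column)
      if (!dec$is_variant) next
      rec <- decision_to_record(dec, chr, p, refseq)
      if (is.null(rec)) next
      if (rec$filter == "PASS" && !dec$conflict && dec$qual < config$pass_qual) {
        rec$filter <- "LowQual"
      }
      records <- c(records, list(rec))
      del_lens <- vapply(dec$alts, function(a) if (a$type == "del") a$len else 0L,
                         integer(1))
      if (any(del_lens > 0)) {
        covered_until <- max(covered_until, p + max(del_lens) - 1L)
      }
    }
  }
  if (length(records) == 0) return(new_variants())
  bind_rows(records) |>
    arrange(.data$chrom, .data$pos) |>
    validate_variants()
}

# Render a decision at column (chrom, p) as a VCF-style record.
# Deletions are anchored one base left; a multi-allelic record that mixes a
# deletion with another allele cannot share one anchor, so the
# better-supported allele is kept and the record flagged TASK_CONFLICT.
decision_to_record <- function(dec, chrom, p, refseq) {
  alts <- dec$alts
  gt <- dec$gt
  conflict <- dec$conflict
  types <- vapply(alts, `[[`, character(1), "type")
  if (length(alts) == 2 && any(types == "del")) {
    alts <- alts[1]
    types <- types[1]
    gt <- if (types[1] == "del") "0/1" else "0/1"
    conflict <- TRUE
  }
  if (length(alts) == 1) {
    a <- alts[[1]]
    if (a$type == "snv") {
      rec <- tibble(chrom = chrom, pos = p,
                    ref = substr(refseq, p, p), alt = a$base)
    } else if (a$type == "ins") {
      rb <- substr(refseq, p, p)
      rec <- tibble(chrom = chrom, pos = p, ref = rb, alt = paste0(rb, a$seq))
    } else {
      if (p == 1L || p + a$len - 1L > nchar(refseq) || is.na(a$len) || a$len < 1) {
        return(NULL)
      }
      rec <- tibble(chrom = chrom, pos = p - 1L,
                    ref = substr(refseq, p - 1L, p - 1L + a$len),
                    alt = substr(refseq, p - 1L, p - 1L))
    }
  } else {
    # two alleles anchored at p: snv and/or insertion
    render <- function(a) {
      if (a$type == "snv") a$base else paste0(substr(refseq, p, p), a$seq)
    }
    rec <- tibble(chrom = chrom, pos = p, ref = substr(refseq, p, p),
                  alt = paste(vapply(alts, render, character(1)), collapse = ","))
  }
  rec$gt <- gt
  rec$qual <- round(dec$qual, 2)
  rec$filter <- if (conflict) "TASK_CONFLICT" else "PASS"
  rec
}
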