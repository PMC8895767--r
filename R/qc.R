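# Capture QC: per-base depth over targets, threshold exceedance,
# uniformity, flanked-site coverage, uncovered regions, read statistics.

#' Compute per-base depth over target regions
#'
#' A read contributes depth at every reference position consumed by a
#' match/mismatch CIGAR operation; deletions, skips and clips contribute
#' nothing. Reads failing the MAPQ / primary filters are excluded.
#'
#' @param reads A reads tibble.
#' @param regions Target regions tibble.
#' @param min_mapq Minimum mapping quality (0 keeps everything).
#' @param primary_only Drop secondary/supplementary alignments.
#' @return A coverage profile: the regions tibble with a `depth`
#'   list-column holding one integer depth per reference base of the
#'   region, class `capcall_coverage`.
#' @export
compute_depth <- function(reads, regions, min_mapq = 0, primary_only = FALSE) {
  validate_reads(reads)
  validate_regions(regions)
  keep <- reads$mapq >= min_mapq & (!primary_only | reads$is_primary)
  reads <- reads[keep, ]
  unknown <- setdiff(regions$chrom, unique(c(reads$chrom, regions$chrom)))
  idx <- if (nrow(reads) > 0) index_reads(reads, ref = NULL) else NULL
  depths <- vector("list", nrow(regions))
  for (chr in unique(regions$chrom)) {
    rix <- which(regions$chrom == chr)
    ms <- if (is.null(idx)) NULL else {
      on_chrom <- idx$reads$chrom == chr
      idx$msegs[on_chrom[idx$msegs$read], ]
    }
    width <- max(regions$end[rix])
    if (!is.null(ms)) ms <- ms[ms$rs <= width, ]
    cov <- if (is.null(ms) || nrow(ms) == 0) {
      S4Vectors::Rle(0L, width)
    } else {
      IRanges::coverage(IRanges::IRanges(ms$rs, pmin(ms$re, width)), width = width)
    }
    for (i in rix) {
      depths[[i]] <- as.integer(cov[(regions$start[i] + 1L):regions$end[i]])
    }
  }
  out <- regions
  out$depth <- depths
  class(out) <- c("capcall_coverage", class(regions))
  out
}

#' Summarise a coverage profile
#'
#' @param profile A coverage profile from [compute_depth()].
#' @param thresholds Depth thresholds for exceedance percentages.
#' @param uniformity_factor Uniformity counts target bases with depth at
#'   least this multiple of the mean on-target depth (default 0.2).
#' @return A one-row tibble: `mean_doc`, one `pct_ge_<t>` column per
#'   threshold, `uniformity` (all percentages in \[0, 100\]), and
#'   `total_bases`.
#' @export
coverage_summary <- function(profile, thresholds = c(30, 60, 100),
                             uniformity_factor = 0.2) {
  stopifnot(inherits(profile, "capcall_coverage"))
  if (nrow(profile) == 0) abort("empty coverage profile")
  d <- unlist(profile$depth)
  if (length(d) == 0) abort("coverage profile has no bases")
  mean_doc <- sum(d) / length(d)
  out <- tibble(mean_doc = mean_doc)
  for (t in thresholds) {
    out[[sprintf("pct_ge_%g", t)]] <- 100 * mean(d >= t)
  }
  out$uniformity <- 100 * mean(d >= uniformity_factor * mean_doc)
  out$total_bases <- length(d)
  out
}

#' Coverage of flanked sites
#'
#' Fraction of positions in the union of `[site - flank, site + flank]`
#' windows, intersected with the profiled bases, whose depth reaches the
#' threshold. Window bases outside every profiled region are not part of
#' the denominator; sites whose whole window is unprofiled are reported in
#' `n_sites_unprofiled` and counted as below threshold via
#' `fraction_with_unprofiled`.
#'
#' @param profile A coverage profile.
#' @param sites 1-based positions: integer vector (single-chromosome
#'   profile) or tibble with `chrom`, `pos`.
#' @param flank Bases included on each side of a site (default 10).
#' @param threshold Depth threshold (default 60).
#' @return A one-row tibble: `fraction`, `n_window_bases`, `n_below`,
#'   `n_sites`, `n_sites_unprofiled`, `fraction_with_unprofiled`.
#' @export
site_coverage <- function(profile, sites, flank = 10, threshold = 60) {
  stopifnot(inherits(profile, "capcall_coverage"), flank >= 0)
  if (!is.data.frame(sites)) {
    chroms <- unique(profile$chrom)
    if (length(chroms) > 1) abort("sites must carry chrom for multi-chromosome profiles")
    sites <- tibble(chrom = chroms, pos = as.integer(sites))
  }
  if (nrow(sites) == 0) {
    warn("no sites supplied; site coverage is vacuously 1")
    return(tibble(fraction = 1, n_window_bases = 0L, n_below = 0L,
                  n_sites = 0L, n_sites_unprofiled = 0L,
                  fraction_with_unprofiled = 1))
  }
  n_ok <- 0L; n_tot <- 0L; unprofiled_sites <- 0L
  for (chr in unique(sites$chrom)) {
    pr <- profile[profile$chrom == chr, ]
    pos_chr <- sites$pos[sites$chrom == chr]
    prof_pos <- unlist(purrr::map2(pr$start + 1L, pr$end, seq.int))
    prof_depth <- unlist(pr$depth)
    win <- IRanges::reduce(IRanges::IRanges(pmax(1L, pos_chr - flank),
                                            pos_chr + flank))
    win_pos <- unlist(lapply(seq_along(win), function(i) {
      seq.int(IRanges::start(win)[i], IRanges::end(win)[i])
    }))
    hit <- match(win_pos, prof_pos)
    n_tot <- n_tot + sum(!is.na(hit))
    n_ok <- n_ok + sum(prof_depth[hit[!is.na(hit)]] >= threshold)
    # a site whose whole window is unprofiled counts as below threshold:
    # its window bases enter the denominator
    per_site_hit <- vapply(pos_chr, function(p) {
      any(!is.na(match(seq.int(max(1L, p - flank), p + flank), prof_pos)))
    }, logical(1))
    unprofiled_sites <- unprofiled_sites + sum(!per_site_hit)
    n_tot <- n_tot + sum((pos_chr[!per_site_hit] + flank) -
                           pmax(1L, pos_chr[!per_site_hit] - flank) + 1L)
  }
  fraction <- if (n_tot > 0) n_ok / n_tot else 0
  tibble(fraction = fraction,
         n_window_bases = n_tot,
         n_below = n_tot - n_ok,
         n_sites = nrow(sites),
         n_sites_unprofiled = unprofiled_sites)
}

#' Find target regions with insufficient read coverage
#'
#' Returns regions whose maximum number of distinct overlapping reads
#' (counted on the reads' aligned reference spans, so deletion gaps still
#' count as overlap) is below `min_reads`. With `min_reads = 1` these are
#' the regions no read touches at all.
#'
#' @param reads A reads tibble.
#' @param regions Target regions tibble.
#' @param min_reads Minimum distinct overlapping reads (default 1).
#' @param min_mapq,primary_only Alignment filters, as in [compute_depth()].
#' @return The subset of `regions` below the threshold, with a
#'   `max_overlap` column.
#' @export
uncovered_regions <- function(reads, regions, min_reads = 1,
                              min_mapq = 0, primary_only = FALSE) {
  validate_reads(reads)
  validate_regions(regions)
  stopifnot(min_reads >= 0)
  keep <- reads$mapq >= min_mapq & (!primary_only | reads$is_primary)
  reads <- reads[keep, ]
  max_overlap <- integer(nrow(regions))
  if (nrow(reads) > 0) {
    span <- vapply(reads$cigar, cigar_ref_span, numeric(1), USE.NAMES = FALSE)
    for (chr in unique(regions$chrom)) {
      rix <- which(regions$chrom == chr)
      on_chr <- which(reads$chrom == chr)
      if (length(on_chr) == 0) next
      width <- max(regions$end[rix], reads$pos[on_chr] + span[on_chr])
      cov <- IRanges::coverage(
        IRanges::IRanges(reads$pos[on_chr],
                         reads$pos[on_chr] + as.integer(span[on_chr]) - 1L),
        width = width)
      for (i in rix) {
        max_overlap[i] <- max(as.integer(cov[(regions$start[i] + 1L):regions$end[i]]))
      }
    }
  }
  out <- regions
  out$max_overlap <- max_overlap
  out[out$max_overlap < min_reads, ]
}

#' Read-level statistics
#'
#' @param reads A reads tibble.
#' @param regions Optional target regions; enables the on-target rate
#'   (fraction of aligned — reference-consuming — bases inside targets).
#' @return A one-row tibble: `n_reads`, `n50`, `mean_length`,
#'   `mean_read_q` (Phred of the mean per-base error probability),
#'   `pct_reads_ge_q10`, `on_target_rate` (percent, `NA` without regions).
#' @export
read_stats <- function(reads, regions = NULL) {
  validate_reads(reads)
  if (nrow(reads) == 0) abort("read_stats requires at least one read")
  lens <- nchar(reads$seq)
  read_q <- vapply(phred_from_string(reads$qual), function(q) {
    error_to_phred(mean(phred_to_error(q)))
  }, numeric(1))
  on_target <- NA_real_
  if (!is.null(regions)) {
    validate_regions(regions)
    idx <- index_reads(reads, ref = NULL)
    total_aligned <- sum(idx$msegs$re - idx$msegs$rs + 1)
    in_target <- 0
    for (chr in unique(regions$chrom)) {
      on_chrom <- idx$reads$chrom == chr
      ms <- idx$msegs[on_chrom[idx$msegs$read], ]
      if (nrow(ms) == 0) next
      r <- regions[regions$chrom == chr, ]
      hits <- IRanges::findOverlaps(IRanges::IRanges(ms$rs, ms$re),
                                    IRanges::reduce(IRanges::IRanges(r$start + 1L, r$end)))
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      tgt <- IRanges::reduce(IRanges::IRanges(r$start + 1L, r$end))
      in_target <- in_target + sum(
        pmin(ms$re[qh], IRanges::end(tgt)[sh]) -
          pmax(ms$rs[qh], IRanges::start(tgt)[sh]) + 1)
    }
    on_target <- 100 * in_target / total_aligned
  }
  tibble(n_reads = nrow(reads),
         n50 = n50(lens),
         mean_length = mean(lens),
         mean_read_q = mean(read_q),
         pct_reads_ge_q10 = 100 * mean(read_q >= 10),
         on_target_rate = on_target)
}

#' Read-length N50
#'
#' The largest length L such that reads of length at least L together
#' contain at least half of all sequenced bases.
#'
#' @param lengths Integer vector of read lengths.
#' @return The N50 length.
#' @export
n50 <- function(lengths) {
  stopifnot(length(lengths) > 0)
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(as.numeric(s)) >= sum(as.numeric(s)) / 2)[1]]
}

#' GC content of a region
#'
#' @param ref Reference tibble.
#' @param region A one-row regions tibble (0-based half-open).
#' @return Fraction (G+C)/(A+C+G+T) over the region; N bases are excluded
#'   from the denominator; `NA` if the region is all N.
#' @export
gc_content <- function(ref, region) {
  stopifnot(nrow(region) == 1)
  ref_vec <- ref_as_vector(ref)
  s <- ref_slice(ref_vec, region$chrom, region$start + 1L, region$end)
  counts <- table(strsplit(s, "", fixed = TRUE)[[1]])
  acgt <- sum(counts[intersect(names(counts), c("A", "C", "G", "T"))])
  if (acgt == 0) {
    warn(sprintf("region %s:%d-%d is all N; GC content undefined",
                 region$chrom, region$start, region$end))
    return(NA_real_)
  }
  gc <- sum(counts[intersect(names(counts), c("G", "C"))])
  gc / acgt
}

#' Full capture QC report
#'
#' @param reads A reads tibble.
#' @param regions Target regions tibble.
#' @param ref Optional reference (adds GC annotation of uncovered regions).
#' @param thresholds Depth thresholds.
#' @param min_mapq,primary_only Alignment filters for depth.
#' @param min_reads Threshold for [uncovered_regions()].
#' @return A list of class `capcall_qc` with `summary` (one-row tibble),
#'   `profile`, `uncovered` (with `gc` column when `ref` given) and
#'   `read_stats`.
#' @export
qc_report <- function(reads, regions, ref = NULL, thresholds = c(30, 60, 100),
                      min_mapq = 0, primary_only = FALSE, min_reads = 1) {
  profile <- compute_depth(reads, regions, min_mapq, primary_only)
  cov <- coverage_summary(profile, thresholds)
  rs <- read_stats(reads, regions)
  unc <- uncovered_regions(reads, regions, min_reads, min_mapq, primary_only)
  if (!is.null(ref) && nrow(unc) > 0) {
    unc$gc <- vapply(seq_len(nrow(unc)),
                     function(i) gc_content(ref, unc[i, ]), numeric(1))
  }
  summary <- dplyr::bind_cols(cov, rs) |>
    mutate(uncovered_region_count = nrow(unc))
  structure(list(summary = summary, profile = profile, uncovered = unc,
                 read_stats = rs),
            class = "capcall_qc")
}

#' @export
print.capcall_qc <- function(x, ...) {
  cat("<capcall_qc>\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.capcall_qc <- function(x, ...) {
  x$summary |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "metric",
                        values_to = "value")
}

#' @exportS3Method generics::glance
glance.capcall_qc <- function(x, ...) x$summary
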