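# Synthetic capture-sequencing simulator: reference, target regions,
# planted diploid variants with a truth set, and error-bearing long reads
# emitted pre-aligned at their true positions (no external aligner needed).

#' Simulation configuration
#'
#' Defaults describe an ONT-like medical-exome capture library: ~1 kb reads,
#' exon-sized targets (mean 164 bp), mean read quality around Q11, deep
#' (120x) but uneven coverage with a log-normal per-region capture/PCR
#' efficiency multiplier.
#'
#' @param ref_length Reference length in bases.
#' @param n_regions Number of target regions.
#' @param region_length_mean Mean target region length (bases).
#' @param read_length_mean,read_length_sd Read length distribution (bases).
#' @param mean_depth Mean fold-coverage of a region before capture bias.
#' @param capture_bias_sigma Standard deviation of the log-normal per-region
#'   depth multiplier (log scale).
#' @param sub_error_rate Per-base substitution error probability.
#' @param indel_error_rate Per-base 1-bp indel error probability (half
#'   insertions, half deletions).
#' @param snv_rate,indel_rate Planted variants per covered target base.
#' @param het_fraction Probability a planted variant is heterozygous.
#' @param mean_read_phred Target mean per-read Phred quality.
#' @param gc_fraction Reference GC fraction.
#' @param low_mapq_fraction Fraction of reads assigned a mapping quality
#'   below 60 (emulating non-uniquely mapped reads).
#' @param secondary_fraction Fraction of reads flagged secondary.
#' @param seed Integer seed; all stage seeds are derived from it.
#' @return A list of class `capcall_sim_config`.
#' @export
sim_config <- function(ref_length = 200000,
                       n_regions = 300,
                       region_length_mean = 164,
                       read_length_mean = 1000,
                       read_length_sd = 250,
                       mean_depth = 120,
                       capture_bias_sigma = 0.6,
                       sub_error_rate = 0.05,
                       indel_error_rate = 0.02,
                       snv_rate = 0.0061,
                       indel_rate = 0.00102,
                       het_fraction = 0.5,
                       mean_read_phred = 11,
                       gc_fraction = 0.5,
                       low_mapq_fraction = 0.04,
                       secondary_fraction = 0.02,
                       seed = 1L) {
  check_scalar_number(ref_length, "ref_length", min = 1)
  check_scalar_number(n_regions, "n_regions", min = 1)
  check_scalar_number(region_length_mean, "region_length_mean", min = 1)
  check_scalar_number(read_length_mean, "read_length_mean", min = 1)
  check_scalar_number(read_length_sd, "read_length_sd", min = 0)
  check_scalar_number(mean_depth, "mean_depth", min = 0)
  check_scalar_number(capture_bias_sigma, "capture_bias_sigma", min = 0)
  for (r in c("sub_error_rate", "indel_error_rate", "snv_rate", "indel_rate",
              "het_fraction", "gc_fraction", "low_mapq_fraction",
              "secondary_fraction")) {
    check_scalar_number(get(r), r, min = 0, max = 1)
  }
  check_scalar_number(mean_read_phred, "mean_read_phred", min = 1)
  cfg <- as.list(environment())
  class(cfg) <- "capcall_sim_config"
  cfg
}

#' Generate a random reference sequence
#'
#' @param length Sequence length.
#' @param gc_fraction Probability a base is G or C.
#' @param seed Integer seed.
#' @param name Sequence name.
#' @return A one-row reference tibble (`name`, `seq`).
#' @export
sim_reference <- function(length, gc_fraction = 0.5, seed = 1L, name = "chr1") {
  check_scalar_number(length, "length", min = 1)
  check_scalar_number(gc_fraction, "gc_fraction", min = 0, max = 1)
  with_seed(derive_seed(seed, "ref"), {
    p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
           G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
    bases <- sample(names(p), length, replace = TRUE, prob = p)
    tibble(name = name, seq = paste(bases, collapse = ""))
  })
}

#' Generate non-overlapping target regions
#'
#' Region lengths are drawn around `region_length_mean` (normal, sd one
#' third of the mean, floored at `min_length`); regions are packed without
#' overlap, separated by at least `min_gap`, and kept `margin` bases away
#' from the reference ends so that full-length reads fit around them.
#'
#' @param ref_length Reference length.
#' @param n_regions Number of regions.
#' @param region_length_mean Mean region length.
#' @param seed Integer seed.
#' @param min_length Minimum region length.
#' @param min_gap Minimum gap between adjacent regions.
#' @param margin Reference bases left free at each end.
#' @param chrom Chromosome name.
#' @return A sorted regions tibble.
#' @export
sim_target_bed <- function(ref_length, n_regions, region_length_mean = 164,
                           seed = 1L, min_length = 50, min_gap = 20,
                           margin = 1500, chrom = "chr1") {
  with_seed(derive_seed(seed, "bed"), {
    lens <- pmax(min_length,
                 round(rnorm(n_regions, region_length_mean, region_length_mean / 3)))
    margin <- min(margin, floor(ref_length / 10))
    avail <- ref_length - 2 * margin - sum(lens) - (n_regions - 1) * min_gap
    if (avail < 0) {
      abort(sprintf(
        "cannot pack %d regions of total length %d into reference of length %d",
        n_regions, sum(lens), ref_length))
    }
    w <- runif(n_regions + 1)
    extra <- floor(avail * w / sum(w))[seq_len(n_regions)]
    gaps <- c(extra[1], extra[-1] + min_gap)
    starts <- margin + cumsum(gaps) + cumsum(c(0, lens[-n_regions]))
    tibble(chrom = chrom, start = as.integer(starts),
           end = as.integer(starts + lens),
           name = sprintf("target_%04d", seq_len(n_regions)))
  })
}

# ---- variant planting ---------------------------------------------------

#' Plant diploid variants inside target regions
#'
#' SNVs and 1-10 bp indels are placed uniformly inside the regions with a
#' minimum spacing of 15 bp so variants never overlap. Heterozygous variants
#' land on one haplotype (chosen at random), homozygous variants on both.
#'
#' @param ref Reference tibble (single sequence).
#' @param regions Target regions tibble.
#' @param config A [sim_config()].
#' @return A list with `truth` (variants tibble with `gt`, `type`, `hap1`,
#'   `hap2`), `events` (per-haplotype event tables used by the read
#'   simulator) and `haplotypes` (two-sequence tibble with the variants
#'   applied).
#' @export
sim_variants <- function(ref, regions, config) {
  stopifnot(nrow(ref) == 1)
  validate_regions(regions)
  refseq <- ref$seq[[1]]
  chrom <- ref$name[[1]]
  merged <- merge_regions(regions)
  bases <- sum(merged$end - merged$start)
  with_seed(derive_seed(config$seed, "variants"), {
    n_snv <- rpois(1, config$snv_rate * bases)
    n_indel <- rpois(1, config$indel_rate * bases)
    # 1-based candidate anchor positions, shuffled; greedy spacing filter
    cand <- unlist(purrr::map2(merged$start + 1L, merged$end, seq.int))
    cand <- cand[cand + 12 <= nchar(refseq)]
    cand <- sample(cand)
    chosen <- integer(0)
    for (p in cand) {
      if (length(chosen) >= n_snv + n_indel) break
      if (all(abs(chosen - p) >= 15)) chosen <- c(chosen, p)
    }
    if (length(chosen) < n_snv + n_indel) {
      warn("target space too dense: planted fewer variants than requested")
      n_indel <- max(0, length(chosen) - n_snv)
      n_snv <- min(n_snv, length(chosen))
    }
    chosen <- sample(chosen)  # decouple type from acceptance order
    snv_pos <- head(chosen, n_snv)
    indel_pos <- head(tail(chosen, -n_snv), n_indel)

    mk_base <- function(p) substr(refseq, p, p)
    snvs <- purrr::map_dfr(snv_pos, function(p) {
      refb <- mk_base(p)
      tibble(pos = p, type = "snv",
             ref = refb, alt = sample(setdiff(c("A", "C", "G", "T"), refb), 1))
    })
    indels <- purrr::map_dfr(indel_pos, function(p) {
      len <- sample(1:10, 1)
      refb <- mk_base(p)
      if (runif(1) < 0.5) {
        ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = "")
        tibble(pos = p, type = "ins", ref = refb, alt = paste0(refb, ins))
      } else {
        tibble(pos = p, type = "del",
               ref = substr(refseq, p, p + len), alt = refb)
      }
    })
    truth <- bind_rows(snvs, indels)
    if (nrow(truth) == 0) {
      truth <- tibble(pos = integer(), type = character(),
                      ref = character(), alt = character())
    }
    het <- runif(nrow(truth)) < config$het_fraction
    hap_of_het <- sample(c(TRUE, FALSE), nrow(truth), replace = TRUE)
    truth <- truth |>
      mutate(chrom = chrom,
             gt = ifelse(het, "0/1", "1/1"),
             hap1 = !het | hap_of_het,
             hap2 = !het | !hap_of_het,
             qual = NA_real_, filter = "PASS") |>
      select("chrom", "pos", "ref", "alt", "gt", "qual", "filter",
             "type", "hap1", "hap2") |>
      arrange(.data$pos)

    events <- list(hap1 = truth[truth$hap1, ], hap2 = truth[truth$hap2, ])
    haplotypes <- tibble(
      name = c("hap1", "hap2"),
      seq = c(apply_events(refseq, events$hap1),
              apply_events(refseq, events$hap2)))
    list(truth = truth, events = events, haplotypes = haplotypes)
  })
}

# Apply anchor-based variant events (sorted by pos) to a sequence.
apply_events <- function(refseq, events) {
  if (nrow(events) == 0) return(refseq)
  out <- character(0)
  cursor <- 1L
  for (i in seq_len(nrow(events))) {
    p <- events$pos[i]
    rl <- nchar(events$ref[i])
    out <- c(out, substr(refseq, cursor, p - 1L), events$alt[i])
    cursor <- p + rl
  }
  paste0(paste(out, collapse = ""), substr(refseq, cursor, nchar(refseq)))
}

# ---- read simulation ----------------------------------------------------

#' Simulate capture reads over target regions
#'
#' Per region the expected depth is `mean_depth` times a log-normal
#' multiplier (`capture_bias_sigma`); fragment midpoints are uniform over
#' the region extended by half a read length on each side, which yields flat
#' expected coverage across the region and tapering flank coverage. Reads
#' are drawn from either haplotype, substitution and 1-bp indel errors are
#' injected at the configured rates, and alignments are emitted at the true
#' placement with CIGARs reflecting both planted indels and indel errors.
#'
#' @param ref Reference tibble (single sequence).
#' @param events Per-haplotype event tables from [sim_variants()].
#' @param regions Target regions tibble.
#' @param config A [sim_config()].
#' @return A reads tibble (see [read_alignments()]).
#' @export
sim_reads <- function(ref, events, regions, config) {
  stopifnot(nrow(ref) == 1)
  validate_regions(regions)
  refseq <- ref$seq[[1]]
  chrom <- ref$name[[1]]
  ref_len <- nchar(refseq)
  with_seed(derive_seed(config$seed, "reads"), {
    rl <- config$read_length_mean
    n_per_region <- rpois(
      nrow(regions),
      config$mean_depth *
        stats::rlnorm(nrow(regions), 0, config$capture_bias_sigma) *
        (region_width(regions) + rl) / rl)
    total <- sum(n_per_region)
    if (total == 0) return(empty_reads())
    region_idx <- rep(seq_len(nrow(regions)), n_per_region)
    lens <- pmax(50, round(rnorm(total, rl, config$read_length_sd)))
    # midpoint uniform over the region extended by this read's half-length:
    # flat expected coverage across the region, tapering over the flanks
    mids <- runif(total,
                  min = regions$start[region_idx] + 1 - lens / 2,
                  max = regions$end[region_idx] + lens / 2)
    starts <- pmax(1L, pmin(ref_len, as.integer(round(mids - lens / 2))))
    ends <- pmax(starts, pmin(ref_len, as.integer(starts + lens - 1)))
    haps <- sample(c("hap1", "hap2"), total, replace = TRUE)
    mapq <- ifelse(runif(total) < config$low_mapq_fraction,
                   sample(0:59, total, replace = TRUE), 60L)
    secondary <- runif(total) < config$secondary_fraction

    out <- vector("list", total)
    for (i in seq_len(total)) {
      aln <- build_read_alignment(refseq, events[[haps[i]]], starts[i], ends[i])
      aln <- inject_errors(aln, config$sub_error_rate, config$indel_error_rate)
      qmean <- max(3, rnorm(1, config$mean_read_phred, 3))
      n_bases <- length(aln$seq_chars)
      # jitter sd 3 on the Phred scale lowers the probability-scale mean by
      # 10*(sd*ln10/10)^2/(2*ln10) dB; shift so the per-read mean error
      # probability lands at qmean
      bias <- 10 * (3 * log(10) / 10)^2 / (2 * log(10))
      quals <- pmin(41L, pmax(2L, as.integer(round(rnorm(n_bases, qmean + bias, 3)))))
      out[[i]] <- list(
        pos = aln$pos,
        cigar = aln$cigar,
        seq = paste(aln$seq_chars, collapse = ""),
        qual = phred_to_string(quals))
    }
    tibble(
      read_id = sprintf("read_%06d", seq_len(total)),
      chrom = chrom,
      pos = vapply(out, `[[`, numeric(1), "pos"),
      cigar = vapply(out, `[[`, character(1), "cigar"),
      seq = vapply(out, `[[`, character(1), "seq"),
      qual = vapply(out, `[[`, character(1), "qual"),
      mapq = as.integer(mapq),
      is_primary = !secondary,
      flag = ifelse(secondary, 256L, 0L))
  })
}

empty_reads <- function() {
  tibble(read_id = character(), chrom = character(), pos = integer(),
         cigar = character(), seq = character(), qual = character(),
         mapq = integer(), is_primary = logical(), flag = integer())
}

# Alignment of the haplotype-derived fragment [start1, end1] (reference
# 1-based, inclusive) against the reference, as parallel per-column vectors:
# op (M/I/D), refpos (NA for I), base (NA for D).
build_read_alignment <- function(refseq, hap_events, start1, end1) {
  op <- rep("M", end1 - start1 + 1L)
  refpos <- seq.int(start1, end1)
  base <- strsplit(substr(refseq, start1, end1), "", fixed = TRUE)[[1]]
  ev <- hap_events[hap_events$pos >= start1 - 12L & hap_events$pos <= end1, ,
                   drop = FALSE]
  if (nrow(ev) > 0) {
    for (i in rev(seq_len(nrow(ev)))) {
      p <- ev$pos[i]
      type <- ev$type[i]
      if (type == "snv") {
        if (p >= start1) base[p - start1 + 1L] <- ev$alt[i]
      } else if (type == "del") {
        dlen <- nchar(ev$ref[i]) - 1L
        del_range <- intersect(seq.int(p + 1L, p + dlen), seq.int(start1, end1))
        if (length(del_range) > 0) {
          cols <- del_range - start1 + 1L
          op[cols] <- "D"
          base[cols] <- NA_character_
        }
      } else if (type == "ins" && p >= start1 && p < end1) {
        ins_chars <- strsplit(substr(ev$alt[i], 2, nchar(ev$alt[i])), "",
                              fixed = TRUE)[[1]]
        at <- p - start1 + 1L
        idx_before <- seq_len(at)
        idx_after <- if (at < length(op)) seq.int(at + 1L, length(op)) else integer(0)
        op <- c(op[idx_before], rep("I", length(ins_chars)), op[idx_after])
        refpos <- c(refpos[idx_before], rep(NA_integer_, length(ins_chars)),
                    refpos[idx_after])
        base <- c(base[idx_before], ins_chars, base[idx_after])
      }
    }
  }
  finalize_alignment(op, refpos, base)
}

# Substitution then 1-bp indel errors on the per-column alignment vectors.
inject_errors <- function(aln, sub_rate, indel_rate) {
  op <- aln$op; refpos <- aln$refpos; base <- aln$base
  qcols <- which(op != "D")
  if (length(qcols) == 0) return(aln)
  if (sub_rate > 0) {
    hit <- qcols[runif(length(qcols)) < sub_rate]
    for (j in hit) base[j] <- sample(setdiff(c("A", "C", "G", "T"), base[j]), 1)
  }
  if (indel_rate > 0) {
    hit <- qcols[runif(length(qcols)) < indel_rate]
    is_ins <- runif(length(hit)) < 0.5
    # deletion errors first (indices stay valid), then insertion errors
    for (j in hit[!is_ins]) {
      if (op[j] == "M") {
        op[j] <- "D"; base[j] <- NA_character_
      } else {
        op[j] <- "X_DROP"
      }
    }
    ins_at <- hit[is_ins]
    if (length(ins_at) > 0) {
      ord <- order(ins_at, decreasing = TRUE)
      for (j in ins_at[ord]) {
        nb <- sample(c("A", "C", "G", "T"), 1)
        idx_before <- seq_len(j)
        idx_after <- if (j < length(op)) seq.int(j + 1L, length(op)) else integer(0)
        op <- c(op[idx_before], "I", op[idx_after])
        refpos <- c(refpos[idx_before], NA_integer_, refpos[idx_after])
        base <- c(base[idx_before], nb, base[idx_after])
      }
    }
    keep <- op != "X_DROP"
    op <- op[keep]; refpos <- refpos[keep]; base <- base[keep]
  }
  finalize_alignment(op, refpos, base)
}

# Trim non-ref-consuming edges, encode CIGAR, extract seq chars and pos.
finalize_alignment <- function(op, refpos, base) {
  first_m <- match("M", op)
  last_m <- length(op) + 1L - match("M", rev(op))
  if (is.na(first_m)) abort("degenerate alignment with no matched base")
  keep <- seq.int(first_m, last_m)
  op <- op[keep]; refpos <- refpos[keep]; base <- base[keep]
  r <- rle(op)
  list(op = op, refpos = refpos, base = base,
       pos = refpos[1],
       cigar = paste0(r$lengths, r$values, collapse = ""),
       seq_chars = base[op != "D"])
}

#' Run the full simulator
#'
#' Generates reference, target regions, planted variants and reads under one
#' configuration, optionally writing FASTA/BED/VCF/SAM/FASTQ files.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory for
#'   `reference.fasta`, `targets.bed`, `truth.vcf`, `reads.sam`,
#'   `reads.fastq`.
#' @return A list with `ref`, `regions`, `truth`, `events`, `haplotypes`,
#'   `reads`, `contigs` and `config`.
#' @export
simulate_capture <- function(config = sim_config(), out_dir = NULL) {
  ref <- sim_reference(config$ref_length, config$gc_fraction, config$seed)
  regions <- sim_target_bed(config$ref_length, config$n_regions,
                            config$region_length_mean, config$seed)
  planted <- sim_variants(ref, regions, config)
  reads <- sim_reads(ref, planted$events, regions, config)
  contigs <- tibble(name = ref$name, length = nchar(ref$seq))
  sim <- list(ref = ref, regions = regions, truth = planted$truth,
              events = planted$events, haplotypes = planted$haplotypes,
              reads = reads, contigs = contigs, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(ref, file.path(out_dir, "reference.fasta"))
    write_bed(regions, file.path(out_dir, "targets.bed"))
    write_vcf(planted$truth |> select(-"type", -"hap1", -"hap2"),
              file.path(out_dir, "truth.vcf"), contigs)
    write_sam(reads, file.path(out_dir, "reads.sam"), contigs)
    write_fastq(reads, file.path(out_dir, "reads.fastq"))
  }
  sim
}
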