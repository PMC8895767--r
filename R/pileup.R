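# Pileup assembly: decoding alignments into per-position observations.
#
# Observation semantics (per retained read, at most one per column):
#  * kind "base": the read consumes the reference base; allele = read base,
#    qual = that base's Phred.
#  * kind "insertion": inserted sequence immediately follows the column;
#    attaches to the anchor base before it; allele = inserted sequence,
#    qual = minimum Phred over inserted bases. Takes precedence over the
#    anchor's base observation.
#  * kind "deletion": the read deletes this reference base; allele = number
#    of deleted bases remaining from this column (full event length at the
#    first deleted base), qual = Phred of the last aligned base before the
#    deletion.

#' Filter alignments for calling
#'
#' Retains primary alignments with mapping quality at or above the
#' configured minimum (default 60), preserving order.
#'
#' @param reads A reads tibble.
#' @param config A [resample_config()] (uses `min_mapq`).
#' @return The filtered reads tibble.
#' @export
filter_alignments <- function(reads, config = resample_config()) {
  validate_reads(reads)
  reads[reads$is_primary & reads$mapq >= config$min_mapq, ]
}

# Decode all reads against the reference into flat event tables. Internal
# index shared by pileup, candidate scanning and depth computation.
# ref = NULL skips mismatch detection (enough for depth/overlap queries).
index_reads <- function(reads, ref = NULL) {
  validate_reads(reads)
  ref_vec <- if (is.null(ref)) NULL else ref_as_vector(ref)
  n <- nrow(reads)
  msegs <- vector("list", n)
  dels <- vector("list", n)
  inss <- vector("list", n)
  ref_ints <- if (is.null(ref_vec)) NULL else lapply(ref_vec, utf8ToInt)
  mm <- vector("list", n)
  for (i in seq_len(n)) {
    cg <- parse_cigar(reads$cigar[i])
    if (!is.null(ref_vec) && !reads$chrom[i] %in% names(ref_vec)) {
      abort(sprintf("read %s aligned to unknown chrom '%s'",
                    reads$read_id[i], reads$chrom[i]))
    }
    refpos <- reads$pos[i]
    qpos <- 1L
    m_start_r <- integer(0); m_end_r <- integer(0); m_start_q <- integer(0)
    d_start <- integer(0); d_end <- integer(0); d_qual <- integer(0)
    i_anchor <- integer(0); i_seq <- character(0); i_qual <- integer(0)
    quals <- NULL  # decoded lazily
    for (k in seq_len(nrow(cg))) {
      op <- cg$op[k]; len <- cg$len[k]
      if (op %in% c("M", "=", "X")) {
        m_start_r <- c(m_start_r, refpos)
        m_end_r <- c(m_end_r, refpos + len - 1L)
        m_start_q <- c(m_start_q, qpos)
        refpos <- refpos + len
        qpos <- qpos + len
      } else if (op == "D" || op == "N") {
        if (op == "D") {
          if (is.null(quals)) quals <- utf8ToInt(reads$qual[i]) - PHRED_OFFSET
          d_start <- c(d_start, refpos)
          d_end <- c(d_end, refpos + len - 1L)
          d_qual <- c(d_qual, if (qpos > 1L) quals[qpos - 1L] else 0L)
        }
        refpos <- refpos + len
      } else if (op == "I") {
        if (qpos > 1L && length(m_start_r) > 0) {
          if (is.null(quals)) quals <- utf8ToInt(reads$qual[i]) - PHRED_OFFSET
          i_anchor <- c(i_anchor, refpos - 1L)
          i_seq <- c(i_seq, substr(reads$seq[i], qpos, qpos + len - 1L))
          i_qual <- c(i_qual, min(quals[qpos:(qpos + len - 1L)]))
        }
        qpos <- qpos + len
      } else if (op == "S") {
        qpos <- qpos + len
      }  # H, P consume nothing
    }
    if (!is.null(ref_vec) && max(c(m_end_r, d_end, 0L)) > nchar(ref_vec[[reads$chrom[i]]])) {
      abort(sprintf("read %s extends beyond reference '%s'",
                    reads$read_id[i], reads$chrom[i]))
    }
    msegs[[i]] <- list(rs = m_start_r, re = m_end_r, qs = m_start_q)
    dels[[i]] <- list(ds = d_start, de = d_end, dq = d_qual)
    inss[[i]] <- list(ia = i_anchor, is = i_seq, iq = i_qual)
    # mismatches over matched segments
    if (!is.null(ref_vec) && length(m_start_r) > 0) {
      qidx <- unlist(purrr::pmap(list(m_start_q, m_start_r, m_end_r),
                                 function(qs, rs, re) seq.int(qs, qs + re - rs)))
      ridx <- unlist(purrr::map2(m_start_r, m_end_r, seq.int))
      sint <- utf8ToInt(reads$seq[i])
      bad <- which(sint[qidx] != ref_ints[[reads$chrom[i]]][ridx])
      mm[[i]] <- list(refpos = ridx[bad], qidx = qidx[bad])
    } else {
      mm[[i]] <- list(refpos = integer(0), qidx = integer(0))
    }
  }
  mseg_tab <- tibble(
    read = rep(seq_len(n), vapply(msegs, function(x) length(x$rs), integer(1))),
    rs = unlist(lapply(msegs, `[[`, "rs")),
    re = unlist(lapply(msegs, `[[`, "re")),
    qs = unlist(lapply(msegs, `[[`, "qs")))
  del_tab <- tibble(
    read = rep(seq_len(n), vapply(dels, function(x) length(x$ds), integer(1))),
    ds = unlist(lapply(dels, `[[`, "ds")),
    de = unlist(lapply(dels, `[[`, "de")),
    dq = unlist(lapply(dels, `[[`, "dq")))
  ins_tab <- tibble(
    read = rep(seq_len(n), vapply(inss, function(x) length(x$ia), integer(1))),
    ia = unlist(lapply(inss, `[[`, "ia")),
    iseq = unlist(lapply(inss, `[[`, "is")),
    iq = unlist(lapply(inss, `[[`, "iq")))
  mm_tab <- tibble(
    read = rep(seq_len(n), vapply(mm, function(x) length(x$refpos), integer(1))),
    refpos = unlist(lapply(mm, `[[`, "refpos")),
    qidx = unlist(lapply(mm, `[[`, "qidx")))
  list(reads = reads, ref_vec = ref_vec, msegs = mseg_tab, dels = del_tab,
       inss = ins_tab, mismatches = mm_tab)
}

# observations for a set of 1-based positions on one chrom, from an index
collect_observations <- function(idx, chrom, positions) {
  on_chrom <- idx$reads$chrom == chrom
  pr <- IRanges::IRanges(start = positions, width = 1L)

  base_obs <- {
    ms <- idx$msegs[on_chrom[idx$msegs$read], ]
    hits <- IRanges::findOverlaps(pr, IRanges::IRanges(ms$rs, ms$re))
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    pos <- positions[qh]
    qidx <- ms$qs[sh] + pos - ms$rs[sh]
    rd <- ms$read[sh]
    tibble(pos = pos, read = rd, kind = "base",
           allele = substr(idx$reads$seq[rd], qidx, qidx),
           qual = utf8ToInt(paste(substr(idx$reads$qual[rd], qidx, qidx),
                                  collapse = ""))[seq_along(rd)] - PHRED_OFFSET)
  }
  del_obs <- {
    dl <- idx$dels[on_chrom[idx$dels$read], ]
    hits <- IRanges::findOverlaps(pr, IRanges::IRanges(dl$ds, dl$de))
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    pos <- positions[qh]
    tibble(pos = pos, read = dl$read[sh], kind = "deletion",
           allele = as.character(dl$de[sh] - pos + 1L),
           qual = dl$dq[sh])
  }
  ins_obs <- {
    it <- idx$inss[on_chrom[idx$inss$read], ]
    keep <- it$ia %in% positions
    tibble(pos = it$ia[keep], read = it$read[keep], kind = "insertion",
           allele = it$iseq[keep], qual = it$iq[keep])
  }
  obs <- bind_rows(ins_obs, base_obs, del_obs)
  if (nrow(obs) == 0) return(obs |> mutate(read_id = character(0)))
  # one observation per read per column; insertion outranks the anchor base
  obs <- obs[!duplicated(obs[, c("pos", "read")]), ]
  obs$read_id <- idx$reads$read_id[obs$read]
  obs
}

#' Build pileup columns at given positions
#'
#' @param reads A reads tibble (already filtered as desired).
#' @param ref Reference tibble.
#' @param positions Either an integer vector of 1-based positions (single
#'   reference sequence) or a tibble with `chrom` and `pos`.
#' @return A tibble of observations with columns `chrom`, `pos`,
#'   `ref_base`, `read_id`, `kind` (`base`/`insertion`/`deletion`),
#'   `allele` and `qual`, sorted by position. Positions covered by no read
#'   yield no rows.
#' @export
build_pileup <- function(reads, ref, positions) {
  if (!is.data.frame(positions)) {
    if (nrow(ref) != 1) abort("positions must carry chrom when ref is multi-sequence")
    positions <- tibble(chrom = ref$name[[1]], pos = as.integer(positions))
  }
  ref_vec <- ref_as_vector(ref)
  for (i in seq_len(nrow(positions))) {
    chrom <- positions$chrom[i]
    if (!chrom %in% names(ref_vec)) abort(sprintf("unknown chrom '%s'", chrom))
    if (positions$pos[i] < 1 || positions$pos[i] > nchar(ref_vec[[chrom]])) {
      abort(sprintf("position %s:%d outside reference", chrom, positions$pos[i]))
    }
  }
  idx <- index_reads(reads, ref)
  out <- positions |>
    group_by(.data$chrom) |>
    dplyr::group_map(function(df, key) {
      obs <- collect_observations(idx, key$chrom[[1]], sort(unique(df$pos)))
      if (nrow(obs) == 0) return(NULL)
      obs |>
        mutate(chrom = key$chrom[[1]],
               ref_base = substr(ref_vec[[key$chrom[[1]]]], .data$pos, .data$pos))
    }) |>
    bind_rows()
  if (nrow(out) == 0) {
    return(tibble(chrom = character(), pos = integer(), ref_base = character(),
                  read_id = character(), kind = character(),
                  allele = character(), qual = integer()))
  }
  out |>
    arrange(.data$chrom, .data$pos) |>
    select("chrom", "pos", "ref_base", "read_id", "kind", "allele", "qual")
}

# Candidate variant positions inside target regions: per-position fraction
# and count of non-reference observations (mismatches + deletion-gapped
# reads + insertion anchors) against match depth.
scan_candidates <- function(idx, regions, min_alt_fraction = 0.125,
                            min_alt_reads = 4) {
  out <- list()
  for (chr in unique(regions$chrom)) {
    r <- regions[regions$chrom == chr, ]
    on_chrom <- idx$reads$chrom == chr
    ms <- idx$msegs[on_chrom[idx$msegs$read], ]
    dl <- idx$dels[on_chrom[idx$dels$read], ]
    it <- idx$inss[on_chrom[idx$inss$read], ]
    mmt <- idx$mismatches[on_chrom[idx$mismatches$read], ]
    if (nrow(ms) == 0) next
    max_pos <- nchar(idx$ref_vec[[chr]])
    depth_rle <- IRanges::coverage(IRanges::IRanges(ms$rs, ms$re), width = max_pos)
    del_rle <- IRanges::coverage(IRanges::IRanges(dl$ds, dl$de), width = max_pos)
    region_pos <- unlist(purrr::map2(r$start + 1L, r$end, seq.int))
    depth <- as.integer(depth_rle[region_pos])
    delc <- as.integer(del_rle[region_pos])
    mmc <- tabulate(mmt$refpos, nbins = max_pos)[region_pos]
    insc <- tabulate(it$ia, nbins = max_pos)[region_pos]
    alt <- mmc + delc + insc
    tot <- depth + delc
    keep <- tot > 0 & alt >= min_alt_reads & alt / tot >= min_alt_fraction
    if (any(keep)) out[[chr]] <- tibble(chrom = chr, pos = region_pos[keep])
  }
  bind_rows(out)
}
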