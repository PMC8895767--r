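# Aligned reads: SAM text in/out. Reads live in a tibble, one row per
# alignment: read_id, chrom, pos (1-based leftmost), cigar, seq, qual
# (Phred+33 string), mapq, is_primary, flag.

CIGAR_QUERY_OPS <- c("M", "I", "S", "=", "X")
CIGAR_REF_OPS <- c("M", "D", "=", "X", "N")

#' Parse a CIGAR string
#'
#' @param cigar A single CIGAR string (e.g. `"10M2D5M"`).
#' @return A data frame with columns `op` (character) and `len` (integer),
#'   in order.
#' @export
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*") {
    return(data.frame(op = character(), len = integer()))
  }
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(lens) != length(ops) || length(ops) == 0) {
    abort(sprintf("malformed CIGAR '%s'", cigar))
  }
  data.frame(op = ops, len = lens)
}

cigar_query_length <- function(cigar) {
  cg <- parse_cigar(cigar)
  sum(cg$len[cg$op %in% CIGAR_QUERY_OPS])
}

cigar_ref_span <- function(cigar) {
  cg <- parse_cigar(cigar)
  sum(cg$len[cg$op %in% CIGAR_REF_OPS])
}

validate_reads <- function(reads) {
  stopifnot(is.data.frame(reads))
  need <- c("read_id", "chrom", "pos", "cigar", "seq", "qual", "mapq", "is_primary")
  missing <- setdiff(need, names(reads))
  if (length(missing) > 0) {
    abort(paste("reads tibble is missing columns:", paste(missing, collapse = ", ")))
  }
  if (nrow(reads) > 0) {
    qlen <- vapply(reads$cigar, cigar_query_length, integer(1), USE.NAMES = FALSE)
    bad <- qlen != nchar(reads$seq) | nchar(reads$seq) != nchar(reads$qual)
    if (any(bad)) {
      abort(sprintf("read %s: CIGAR query length, seq and qual lengths disagree",
                    reads$read_id[which(bad)[1]]))
    }
    if (any(reads$mapq < 0)) abort("mapq must be >= 0")
  }
  invisible(reads)
}

#' Read aligned reads from a SAM file
#'
#' Parses a SAM file (text dialect with header) through `Rsamtools` and
#' returns mapped reads as a tibble. Secondary (0x100) and supplementary
#' (0x800) alignments are kept but flagged `is_primary = FALSE`; unmapped
#' reads are dropped.
#'
#' @param path Path to a SAM file with a header.
#' @param regions Optional regions tibble; only reads whose reference span
#'   overlaps at least one region are returned.
#' @return A tibble with columns `read_id`, `chrom`, `pos` (1-based),
#'   `cigar`, `seq`, `qual`, `mapq`, `is_primary`, `flag`.
#' @export
read_alignments <- function(path, regions = NULL) {
  if (!file.exists(path)) abort(sprintf("SAM file not found: %s", path))
  first <- readr::read_lines(path, n_max = 1)
  if (length(first) == 0 || !startsWith(first, "@")) {
    abort(sprintf("SAM file %s has no header", path))
  }
  bam <- suppressMessages(Rsamtools::asBam(
    path, destination = tempfile(), overwrite = TRUE, indexDestination = FALSE))
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual")))[[1]]
  mapped <- !bitwAnd(res$flag, 4L)
  reads <- tibble(
    read_id = res$qname[mapped],
    chrom = as.character(res$rname[mapped]),
    pos = res$pos[mapped],
    cigar = res$cigar[mapped],
    seq = as.character(res$seq[mapped]),
    qual = as.character(res$qual[mapped]),
    mapq = res$mapq[mapped],
    flag = res$flag[mapped]
  ) |>
    mutate(is_primary = bitwAnd(.data$flag, bitwOr(256L, 2048L)) == 0L) |>
    select("read_id", "chrom", "pos", "cigar", "seq", "qual", "mapq",
           "is_primary", "flag")
  if (!is.null(regions)) {
    validate_regions(regions)
    span <- vapply(reads$cigar, cigar_ref_span, numeric(1), USE.NAMES = FALSE)
    keep <- rep(FALSE, nrow(reads))
    for (chr in unique(regions$chrom)) {
      on_chr <- which(reads$chrom == chr)
      if (length(on_chr) == 0) next
      r <- regions[regions$chrom == chr, ]
      q <- IRanges::IRanges(start = reads$pos[on_chr],
                            end = reads$pos[on_chr] + span[on_chr] - 1)
      s <- IRanges::IRanges(start = r$start + 1L, end = r$end)
      keep[on_chr] <- IRanges::overlapsAny(q, s)
    }
    reads <- reads[keep, ]
  }
  validate_reads(reads)
  reads
}

#' Write aligned reads to a SAM file
#'
#' @param reads A reads tibble (see [read_alignments()] for columns; `flag`
#'   is derived from `is_primary` when absent).
#' @param path Output path.
#' @param contigs A tibble with `name` and `length` for the `@SQ` header
#'   lines.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, contigs) {
  validate_reads(reads)
  stopifnot(all(c("name", "length") %in% names(contigs)))
  if (!all(reads$chrom %in% contigs$name)) {
    abort("reads reference a chrom absent from contigs")
  }
  flag <- if ("flag" %in% names(reads)) reads$flag else ifelse(reads$is_primary, 0L, 256L)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", contigs$name, as.integer(contigs$length)))
  ord <- order(reads$chrom, reads$pos)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  reads$read_id[ord], flag[ord], reads$chrom[ord],
                  reads$pos[ord], reads$mapq[ord], reads$cigar[ord],
                  reads$seq[ord], reads$qual[ord])
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Write reads to FASTQ
#'
#' @param reads A reads tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  validate_reads(reads)
  lines <- rbind(paste0("@", reads$read_id), reads$seq, "+", reads$qual)
  readr::write_lines(as.vector(lines), path)
  invisible(path)
}
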