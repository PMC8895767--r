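# Reference sequences: FASTA in/out via Biostrings, plain character storage
# (named list of uppercase ACGTN strings) for cheap substring access.

#' Read reference sequences from FASTA
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `name` (to first whitespace) and `seq`
#'   (uppercase). Only A/C/G/T/N are accepted.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    sym <- unique(unlist(strsplit(gsub("[ACGTN]", "", seqs[bad]), "")))
    abort(sprintf("FASTA contains non-ACGTN characters: %s",
                  paste(sym, collapse = ", ")))
  }
  tibble(name = unname(names(seqs)), seq = unname(seqs))
}

#' Write reference sequences to FASTA
#'
#' @param ref A tibble with `name` and `seq` columns (as from [read_fasta()]).
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ref, path, width = 70) {
  ss <- Biostrings::DNAStringSet(setNames(ref$seq, ref$name))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

# named character vector chrom -> sequence, for fast substr access
ref_as_vector <- function(ref) setNames(ref$seq, ref$name)

ref_slice <- function(ref_vec, chrom, start1, end1) {
  s <- ref_vec[[chrom]]
  if (is.null(s)) abort(sprintf("unknown reference sequence '%s'", chrom))
  if (start1 < 1 || end1 > nchar(s)) {
    abort(sprintf("slice [%d, %d] outside reference '%s' (length %d)",
                  start1, end1, chrom, nchar(s)))
  }
  substr(s, start1, end1)
}
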