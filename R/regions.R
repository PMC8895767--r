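# Target regions: BED-style tibble intervals (chrom, start, end, name),
# 0-based half-open, the unit of target capture.

#' Read a BED file of target regions
#'
#' Reads BED3/BED4 into a tibble of 0-based half-open intervals. Comment
#' (`#`), `track` and `browser` lines and blank lines are skipped. Extra
#' columns beyond the fourth are ignored.
#'
#' @param path Path to a tab-separated BED file.
#' @return A tibble with columns `chrom` (character), `start`, `end`
#'   (integers, 0-based half-open) and `name` (character, `NA` when absent),
#'   one row per data line in file order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  lines <- readr::read_lines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) {
    return(tibble(chrom = character(), start = integer(),
                  end = integer(), name = character()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  parse_line <- function(f, lineno) {
    if (length(f) < 3) {
      abort(sprintf("BED line %d: expected at least 3 tab-separated fields", lineno))
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      abort(sprintf("BED line %d: non-integer coordinates '%s'/'%s'", lineno, f[2], f[3]))
    }
    if (start < 0 || start >= end) {
      abort(sprintf("BED line %d: invalid interval [%d, %d)", lineno, start, end))
    }
    if (!nzchar(f[1])) abort(sprintf("BED line %d: empty chrom", lineno))
    tibble(chrom = f[1], start = start, end = end,
           name = if (length(f) >= 4) f[4] else NA_character_)
  }
  purrr::map2_dfr(fields, idx, parse_line)
}

#' Write regions to a BED file
#'
#' @param regions A tibble with `chrom`, `start`, `end` and optionally `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  validate_regions(regions)
  has_name <- "name" %in% names(regions) && !all(is.na(regions$name))
  cols <- if (has_name) {
    paste(regions$chrom, regions$start, regions$end,
          ifelse(is.na(regions$name), ".", regions$name), sep = "\t")
  } else {
    paste(regions$chrom, regions$start, regions$end, sep = "\t")
  }
  readr::write_lines(cols, path)
  invisible(path)
}

validate_regions <- function(regions) {
  stopifnot(is.data.frame(regions),
            all(c("chrom", "start", "end") %in% names(regions)))
  if (nrow(regions) > 0) {
    if (any(regions$start < 0) || any(regions$start >= regions$end)) {
      abort("regions must satisfy 0 <= start < end")
    }
    if (any(!nzchar(regions$chrom))) abort("regions must have non-empty chrom")
  }
  invisible(regions)
}

#' Merge overlapping or adjacent regions
#'
#' Sorts regions by (chrom, start) and merges overlapping and bookended
#' intervals on the same chromosome, preserving the set of covered bases.
#'
#' @param regions A regions tibble (`chrom`, `start`, `end`, optional `name`).
#' @return A sorted, non-overlapping regions tibble; `name` is dropped
#'   (merged intervals have no single label).
#' @export
merge_regions <- function(regions) {
  validate_regions(regions)
  if (nrow(regions) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character()))
  }
  # IRanges is 1-based closed; shift once at the boundary
  split(regions, regions$chrom) |>
    purrr::imap(function(df, chr) {
      ir <- IRanges::reduce(IRanges::IRanges(start = df$start + 1L, end = df$end))
      tibble(chrom = chr, start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
             name = NA_character_)
    }) |>
    bind_rows() |>
    arrange(.data$chrom, .data$start)
}

# total number of bases covered by a (merged or unmerged) region set
covered_bases <- function(regions) {
  m <- merge_regions(regions)
  sum(m$end - m$start)
}
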