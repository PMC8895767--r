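# Variant records: tibble with chrom, pos (1-based), ref, alt
# (comma-separated for multi-allelic), gt ("0/1" style), qual, filter.

new_variants <- function(chrom = character(), pos = integer(), ref = character(),
                         alt = character(), gt = character(), qual = numeric(),
                         filter = character()) {
  tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
         gt = gt, qual = as.numeric(qual), filter = filter)
}

validate_variants <- function(variants) {
  need <- c("chrom", "pos", "ref", "alt", "gt")
  missing <- setdiff(need, names(variants))
  if (length(missing) > 0) {
    abort(paste("variants tibble is missing columns:", paste(missing, collapse = ", ")))
  }
  if (nrow(variants) > 0) {
    if (any(!nzchar(variants$ref))) abort("ref alleles must be non-empty")
    alts <- strsplit(variants$alt, ",", fixed = TRUE)
    bad <- purrr::map2_lgl(alts, variants$ref,
                           ~ any(!nzchar(.x)) || any(.x == .y))
    if (any(bad)) abort("every alt must be non-empty and differ from ref")
    idx <- gt_indices(variants$gt)
    n_allele <- lengths(alts) + 1L
    if (any(purrr::map2_lgl(idx, n_allele, ~ any(.x >= .y)))) {
      abort("genotype index exceeds allele count")
    }
  }
  invisible(variants)
}

# "0/1" -> c(0L, 1L); tolerant of phased separator
gt_indices <- function(gt) {
  lapply(strsplit(gt, "[/|]"), function(x) sort(as.integer(x)))
}

#' Write variant records to a VCF 4.2 file
#'
#' Writes a single-sample VCF with `GT` genotypes. Records must be sorted by
#' (chrom, pos).
#'
#' @param variants A variants tibble (`chrom`, `pos`, `ref`, `alt`, `gt`,
#'   optional `qual` and `filter`).
#' @param path Output path.
#' @param contigs A tibble with `name` and `length` used for `##contig`
#'   header lines.
#' @param sample Sample name for the genotype column.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, contigs, sample = "SAMPLE") {
  validate_variants(variants)
  if (nrow(variants) > 1) {
    o <- order(variants$chrom, variants$pos)
    if (!identical(o, seq_len(nrow(variants)))) {
      abort("variants must be sorted by (chrom, pos) before writing")
    }
  }
  qual <- if ("qual" %in% names(variants)) variants$qual else rep(NA_real_, nrow(variants))
  filt <- if ("filter" %in% names(variants)) variants$filter else rep("PASS", nrow(variants))
  filt[is.na(filt) | !nzchar(filt)] <- "PASS"
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=capcall",
    sprintf("##contig=<ID=%s,length=%d>", contigs$name, as.integer(contigs$length)),
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    "##FILTER=<ID=TASK_CONFLICT,Description=\"Classification tasks disagreed; resolved by precedence rules\">",
    "##INFO=<ID=.,Number=0,Type=Flag,Description=\"None\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t%s\t%s\t.\tGT\t%s",
                  variants$chrom, variants$pos, variants$ref, variants$alt,
                  ifelse(is.na(qual), ".", formatC(qual, format = "f", digits = 2)),
                  filt, variants$gt)
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Read a VCF file into a variants tibble
#'
#' Reads through `vcfR`; the first sample's `GT` field is used.
#'
#' @param path Path to an uncompressed VCF file.
#' @return A variants tibble (`chrom`, `pos`, `ref`, `alt`, `gt`, `qual`,
#'   `filter`).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort(sprintf("VCF file not found: %s", path))
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(new_variants())
  gt <- if (ncol(v@gt) >= 2) {
    vapply(strsplit(v@gt[, 2], ":", fixed = TRUE), `[`, character(1), 1)
  } else {
    rep(NA_character_, nrow(fix))
  }
  new_variants(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    gt = gt,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    filter = ifelse(is.na(fix$FILTER), "PASS", fix$FILTER)
  )
}
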