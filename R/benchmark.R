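# Benchmarking called variants against a truth set: genotype-aware exact
# matching within confident regions, stratified SNP vs INDEL.

#' Normalize a variant record
#'
#' Canonical representation: shared suffix then prefix trimmed (always
#' keeping at least one base on each allele) and indels left-aligned by
#' repeated leftward shifts while the reference context permits.
#' Single-alt records only; decompose multi-allelics first
#' (see [decompose_variants()]).
#'
#' @param record A one-row variants tibble.
#' @param ref Reference tibble.
#' @return The normalized one-row record.
#' @export
normalize_variant <- function(record, ref) {
  stopifnot(nrow(record) == 1)
  if (grepl(",", record$alt, fixed = TRUE)) {
    abort("normalize_variant expects a single-alt record; decompose first")
  }
  ref_vec <- ref_as_vector(ref)
  refseq <- ref_vec[[record$chrom]]
  if (is.null(refseq)) abort(sprintf("unknown chrom '%s'", record$chrom))
  pos <- record$pos
  ra <- record$ref
  aa <- record$alt
  observed <- substr(refseq, pos, pos + nchar(ra) - 1L)
  if (observed != ra) {
    abort(sprintf("record at %s:%d: ref allele '%s' does not match reference '%s'",
                  record$chrom, pos, ra, observed))
  }
  last <- function(s) substr(s, nchar(s), nchar(s))
  repeat {
    if (nchar(ra) > 0 && nchar(aa) > 0 && last(ra) == last(aa)) {
      if (nchar(ra) == 1L || nchar(aa) == 1L) {
        if (pos == 1L) break
        prev <- substr(refseq, pos - 1L, pos - 1L)
        ra <- paste0(prev, substr(ra, 1, nchar(ra) - 1L))
        aa <- paste0(prev, substr(aa, 1, nchar(aa) - 1L))
        pos <- pos - 1L
      } else {
        ra <- substr(ra, 1, nchar(ra) - 1L)
        aa <- substr(aa, 1, nchar(aa) - 1L)
      }
    } else {
      break
    }
  }
  while (nchar(ra) >= 2 && nchar(aa) >= 2 &&
         substr(ra, 1, 1) == substr(aa, 1, 1)) {
    ra <- substr(ra, 2, nchar(ra))
    aa <- substr(aa, 2, nchar(aa))
    pos <- pos + 1L
  }
  record$pos <- pos
  record$ref <- ra
  record$alt <- aa
  record
}

#' Decompose multi-allelic records
#'
#' Splits records with comma-separated alts into per-alt records; a `1/2`
#' genotype becomes two heterozygous (`0/1`) records.
#'
#' @param variants A variants tibble.
#' @return A variants tibble with single-alt records.
#' @export
decompose_variants <- function(variants) {
  if (nrow(variants) == 0) return(variants)
  multi <- grepl(",", variants$alt, fixed = TRUE)
  if (!any(multi)) return(variants)
  singles <- variants[!multi, ]
  split_rows <- purrr::map_dfr(which(multi), function(i) {
    alts <- strsplit(variants$alt[i], ",", fixed = TRUE)[[1]]
    idx <- gt_indices(variants$gt[i])[[1]]
    purrr::map_dfr(seq_along(alts), function(k) {
      row <- variants[i, ]
      row$alt <- alts[k]
      row$gt <- if (all(idx == k)) "1/1" else "0/1"
      row
    })
  })
  bind_rows(singles, split_rows) |> arrange(.data$chrom, .data$pos)
}

normalize_all <- function(variants, ref) {
  if (nrow(variants) == 0) return(variants)
  purrr::map_dfr(seq_len(nrow(variants)),
                 function(i) normalize_variant(variants[i, ], ref)) |>
    arrange(.data$chrom, .data$pos)
}

in_regions <- function(variants, regions) {
  if (nrow(variants) == 0) return(logical(0))
  keep <- rep(FALSE, nrow(variants))
  for (chr in unique(regions$chrom)) {
    r <- regions[regions$chrom == chr, ]
    on_chr <- which(variants$chrom == chr)
    if (length(on_chr) == 0) next
    # membership decided by the record's (1-based) POS
    keep[on_chr] <- IRanges::overlapsAny(
      IRanges::IRanges(variants$pos[on_chr], width = 1L),
      IRanges::IRanges(r$start + 1L, r$end))
  }
  keep
}

variant_stratum <- function(variants) {
  ifelse(nchar(variants$ref) != nchar(variants$alt), "INDEL", "SNP")
}

#' Compare called variants against a truth set
#'
#' Both sets are decomposed to single-alt records, optionally normalized
#' against the reference, restricted to the intersection of the confident
#' and target regions (by record position), and matched exactly on
#' (chrom, pos, ref, alt, unordered genotype). A genotype mismatch at a
#' true site counts as one false positive plus one false negative.
#' Precision, recall and F1 are reported overall and stratified SNP vs
#' INDEL; zero-denominator metrics are reported as 0 and flagged.
#'
#' @param truth Truth variants tibble.
#' @param called Called variants tibble.
#' @param confident_regions Optional regions tibble of confident intervals.
#' @param target_regions Optional regions tibble; scoring is restricted to
#'   the intersection with `confident_regions`.
#' @param ref Optional reference tibble; when given, both sides are
#'   normalized before matching.
#' @return An object of class `capcall_benchmark`: list with `result`
#'   (tibble with one row per stratum: tp, fp, fn, precision, recall, f1,
#'   zero_denominator), `fp_records`, `fn_records`.
#' @export
compare_calls <- function(truth, called, confident_regions = NULL,
                          target_regions = NULL, ref = NULL) {
  validate_variants(truth)
  validate_variants(called)
  truth <- decompose_variants(truth)
  called <- decompose_variants(called)
  if (!is.null(ref)) {
    truth <- normalize_all(truth, ref)
    called <- normalize_all(called, ref)
  }
  scope <- confident_regions
  if (!is.null(target_regions)) {
    scope <- if (is.null(scope)) target_regions else
      intersect_regions(scope, target_regions)
  }
  if (!is.null(scope)) {
    truth <- truth[in_regions(truth, scope), ]
    called <- called[in_regions(called, scope), ]
  }
  key <- function(v) {
    gt_norm <- vapply(gt_indices(v$gt), paste, character(1), collapse = "/")
    k <- paste(v$chrom, v$pos, v$ref, v$alt, gt_norm, sep = "\r")
    # occurrence index: duplicate identical records match one-for-one
    stats::ave(seq_along(k), k, FUN = seq_along) |>
      paste(k, sep = "\r")
  }
  tk <- key(truth)
  ck <- key(called)
  truth$matched <- tk %in% ck
  called$matched <- ck %in% tk
  strata <- list(overall = function(v) rep(TRUE, nrow(v)),
                 SNP = function(v) variant_stratum(v) == "SNP",
                 INDEL = function(v) variant_stratum(v) == "INDEL")
  result <- purrr::imap_dfr(strata, function(f, name) {
    tt <- truth[f(truth), ]
    cc <- called[f(called), ]
    tp <- sum(cc$matched)
    fp <- sum(!cc$matched)
    fn <- sum(!tt$matched)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    tibble(stratum = name, tp = tp, fp = fp, fn = fn,
           precision = precision, recall = recall, f1 = f1,
           zero_denominator = (tp + fp == 0) || (tp + fn == 0))
  })
  structure(list(result = result,
                 fp_records = called[!called$matched, ],
                 fn_records = truth[!truth$matched, ]),
            class = "capcall_benchmark")
}

#' Intersect two region sets
#'
#' @param a,b Regions tibbles.
#' @return Regions tibble covering the bases present in both.
#' @export
intersect_regions <- function(a, b) {
  validate_regions(a)
  validate_regions(b)
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  purrr::map_dfr(chroms, function(chr) {
    ia <- IRanges::reduce(IRanges::IRanges(a$start[a$chrom == chr] + 1L,
                                           a$end[a$chrom == chr]))
    ib <- IRanges::reduce(IRanges::IRanges(b$start[b$chrom == chr] + 1L,
                                           b$end[b$chrom == chr]))
    ov <- IRanges::intersect(ia, ib)
    tibble(chrom = chr, start = IRanges::start(ov) - 1L,
           end = IRanges::end(ov), name = NA_character_)
  }) |> arrange(.data$chrom, .data$start)
}

#' @export
print.capcall_benchmark <- function(x, ...) {
  cat("<capcall_benchmark>\n")
  print(as.data.frame(x$result), row.names = FALSE)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.capcall_benchmark <- function(x, ...) x$result

#' @exportS3Method generics::glance
glance.capcall_benchmark <- function(x, ...) {
  ov <- x$result[x$result$stratum == "overall", ]
  tibble(tp = ov$tp, fp = ov$fp, fn = ov$fn, precision = ov$precision,
         recall = ov$recall, f1 = ov$f1)
}
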