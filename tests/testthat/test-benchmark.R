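# Variant normalization and truth-set benchmarking.

vrec <- function(chrom, pos, ref, alt, gt = "0/1", qual = 50, filter = "PASS") {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 gt = gt, qual = qual, filter = filter)
}

test_that("normalize_variant leaves SNPs alone and trims padded alleles", {
  ref <- tiny_ref("GGCATTTTAC")
  snp <- vrec("chr1", 4, "A", "C")
  expect_equal(normalize_variant(snp, ref), snp)
  # CAT -> CGT at pos 3 trims to A -> G at pos 4
  padded <- vrec("chr1", 3, "CAT", "CGT")
  out <- normalize_variant(padded, ref)
  expect_equal(out$pos, 4L)
  expect_equal(out$ref, "A")
  expect_equal(out$alt, "G")
})

test_that("indels left-align to the representation an enumeration oracle finds", {
  withr::local_seed(41)
  apply_rec <- function(refseq, rec) {
    paste0(substr(refseq, 1, rec$pos - 1), rec$alt,
           substr(refseq, rec$pos + nchar(rec$ref), nchar(refseq)))
  }
  # hand case: insertion inside a run shifts to the run's left edge
  ref <- tiny_ref("GGTAAAACGG")
  rec <- vrec("chr1", 5, "A", "AA")
  out <- normalize_variant(rec, ref)
  expect_equal(out$pos, 3L)
  expect_equal(out$ref, "T")
  expect_equal(out$alt, "TA")
  expect_equal(apply_rec(ref$seq, out), apply_rec(ref$seq, rec))

  # random indels: result must be the leftmost equivalent representation
  for (i in 1:40) {
    refseq <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                    collapse = "")
    ref <- tiny_ref(refseq)
    p <- sample(20:40, 1)
    if (runif(1) < 0.5) {
      ins <- paste(sample(c("A", "C", "G", "T"), sample(1:4, 1),
                          replace = TRUE), collapse = "")
      rec <- vrec("chr1", p, substr(refseq, p, p),
                  paste0(substr(refseq, p, p), ins))
    } else {
      dl <- sample(1:4, 1)
      rec <- vrec("chr1", p, substr(refseq, p, p + dl), substr(refseq, p, p))
    }
    out <- normalize_variant(rec, ref)
    mutated <- apply_rec(refseq, rec)
    expect_equal(apply_rec(refseq, out), mutated)
    # oracle: exhaustively enumerate anchor-based representations of the
    # same net indel and keep those whose application matches; the
    # normalized record must be the leftmost of them
    k <- abs(nchar(rec$ref) - nchar(rec$alt))
    is_del <- nchar(rec$ref) > nchar(rec$alt)
    alphabet <- c("A", "C", "G", "T")
    ins_strings <- if (is_del) NULL else
      apply(expand.grid(rep(list(alphabet), k)), 1, paste, collapse = "")
    leftmost <- Inf
    for (q in seq(max(1, p - 15), p)) {
      anchor <- substr(refseq, q, q)
      if (is_del) {
        cand <- vrec("chr1", q, substr(refseq, q, q + k), anchor)
        if (apply_rec(refseq, cand) == mutated) leftmost <- min(leftmost, q)
      } else {
        for (t in ins_strings) {
          cand <- vrec("chr1", q, anchor, paste0(anchor, t))
          if (apply_rec(refseq, cand) == mutated) {
            leftmost <- min(leftmost, q)
            break
          }
        }
      }
    }
    expect_equal(out$pos, as.integer(leftmost))
  }
})

test_that("normalize_variant rejects records that contradict the reference", {
  ref <- tiny_ref("ACGTACGT")
  expect_error(normalize_variant(vrec("chr1", 2, "A", "T"), ref),
               "does not match")
})

test_that("identical call sets score 1.0 everywhere", {
  truth <- dplyr::bind_rows(vrec("chr1", 10, "A", "C", "0/1"),
                            vrec("chr1", 20, "G", "GTT", "1/1"),
                            vrec("chr1", 30, "TAC", "T", "0/1"))
  bench <- compare_calls(truth, truth)
  expect_equal(bench$result$precision, c(1, 1, 1))
  expect_equal(bench$result$recall, c(1, 1, 1))
  expect_equal(bench$result$f1, c(1, 1, 1))
})

test_that("an empty call set gives recall 0 and flagged precision 0", {
  truth <- vrec("chr1", 10, "A", "C")
  bench <- compare_calls(truth, truth[0, ])
  ov <- bench$result[bench$result$stratum == "overall", ]
  expect_equal(ov$recall, 0)
  expect_equal(ov$precision, 0)
  expect_true(ov$zero_denominator)
  expect_equal(ov$fn, 1L)
})

test_that("8 matched, 2 spurious, 2 missed gives P = R = F1 = 0.8", {
  shared <- purrr::map_dfr(1:8, ~ vrec("chr1", 10 * .x, "A", "C", "0/1"))
  truth <- dplyr::bind_rows(shared,
                            vrec("chr1", 200, "A", "G"),
                            vrec("chr1", 210, "A", "G"))
  called <- dplyr::bind_rows(shared,
                             vrec("chr1", 300, "T", "G"),
                             vrec("chr1", 310, "T", "G"))
  # positions fabricated: skip reference-based normalization
  ov <- compare_calls(truth, called)$result
  ov <- ov[ov$stratum == "overall", ]
  expect_equal(ov$tp, 8L)
  expect_equal(c(ov$precision, ov$recall, ov$f1), c(0.8, 0.8, 0.8))
})

test_that("a genotype mismatch at a true site counts FP plus FN", {
  truth <- vrec("chr1", 10, "A", "C", "0/1")
  called <- vrec("chr1", 10, "A", "C", "1/1")
  ov <- compare_calls(truth, called)$result
  ov <- ov[ov$stratum == "overall", ]
  expect_equal(c(ov$tp, ov$fp, ov$fn), c(0L, 1L, 1L))
})

test_that("swapping truth and calls exchanges precision and recall", {
  withr::local_seed(43)
  mk <- function(n, offset) {
    purrr::map_dfr(seq_len(n), function(i) {
      vrec("chr1", offset + 7L * i, "A", sample(c("C", "G", "T"), 1),
           sample(c("0/1", "1/1"), 1))
    })
  }
  a <- dplyr::bind_rows(mk(10, 0), mk(4, 500))
  b <- dplyr::bind_rows(mk(10, 0), mk(6, 900))
  ab <- compare_calls(a, b)$result
  ba <- compare_calls(b, a)$result
  expect_equal(ab$precision, ba$recall)
  expect_equal(ab$recall, ba$precision)
})

test_that("shrinking confident regions never increases true positives", {
  withr::local_seed(47)
  truth <- purrr::map_dfr(1:20, ~ vrec("chr1", 10L * .x, "A", "C"))
  called <- truth[sample(20, 15), ] |> dplyr::arrange(pos)
  wide <- tibble::tibble(chrom = "chr1", start = 0L, end = 300L)
  narrow <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L)
  tp_wide <- compare_calls(truth, called, wide)$result$tp[1]
  tp_narrow <- compare_calls(truth, called, narrow)$result$tp[1]
  expect_lte(tp_narrow, tp_wide)
})

test_that("matching is invariant to allele representation after normalization", {
  refseq <- paste0("GG", strrep("A", 6), "CTTTG", strrep("A", 5), "C")
  ref <- tiny_ref(refseq)
  # same deletion of one A from the run, written at two different anchors
  truth <- vrec("chr1", 2, "GA", "G")
  called <- vrec("chr1", 7, "AA", "A")
  ov <- compare_calls(truth, called, ref = ref)$result
  expect_equal(ov$tp[1], 1L)
  expect_equal(ov$fp[1], 0L)
  expect_equal(ov$fn[1], 0L)
})

test_that("multi-allelic records are decomposed before matching", {
  truth <- dplyr::bind_rows(vrec("chr1", 10, "A", "C", "0/1"),
                            vrec("chr1", 10, "A", "G", "0/1"))
  called <- vrec("chr1", 10, "A", "C,G", "1/2")
  ov <- compare_calls(truth, called)$result
  expect_equal(ov$tp[1], 2L)
  expect_equal(ov$fp[1], 0L)
})

test_that("intersect_regions covers exactly the shared bases", {
  a <- tibble::tibble(chrom = "chr1", start = c(0L, 50L), end = c(20L, 80L))
  b <- tibble::tibble(chrom = "chr1", start = 10L, end = 60L)
  out <- intersect_regions(a, b)
  expect_equal(out$start, c(10L, 50L))
  expect_equal(out$end, c(20L, 60L))
})
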