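# Capture QC metrics against closed forms and brute-force oracles.

# build a coverage profile directly from a depth vector
profile_from_depth <- function(depths, start = 0L, chrom = "chr1") {
  pr <- tibble::tibble(chrom = chrom, start = start,
                       end = start + length(depths),
                       name = "r1", depth = list(as.integer(depths)))
  class(pr) <- c("capcall_coverage", class(tibble::tibble()))
  pr
}

test_that("coverage_summary closed forms: constant and half-zero profiles", {
  const <- coverage_summary(profile_from_depth(rep(50L, 100)))
  expect_equal(const$mean_doc, 50)
  expect_equal(const$pct_ge_30, 100)
  expect_equal(const$pct_ge_60, 0)
  expect_equal(const$uniformity, 100)

  half <- coverage_summary(profile_from_depth(c(rep(0L, 50), rep(100L, 50))))
  expect_equal(half$mean_doc, 50)
  expect_equal(half$pct_ge_30, 50)
  expect_equal(half$uniformity, 50)

  expect_error(coverage_summary(profile_from_depth(rep(1L, 5))[0, ]), "empty")
})

test_that("coverage_summary equals brute-force recomputation and is monotone", {
  withr::local_seed(11)
  for (i in 1:20) {
    d <- sample(0:200, sample(50:300, 1), replace = TRUE)
    cs <- coverage_summary(profile_from_depth(d), thresholds = c(30, 60, 100))
    expect_equal(cs$mean_doc, sum(d) / length(d))
    expect_equal(cs$pct_ge_30, 100 * sum(d >= 30) / length(d))
    expect_equal(cs$pct_ge_60, 100 * sum(d >= 60) / length(d))
    expect_equal(cs$pct_ge_100, 100 * sum(d >= 100) / length(d))
    expect_equal(cs$uniformity, 100 * sum(d >= 0.2 * mean(d)) / length(d))
    expect_true(cs$pct_ge_30 >= cs$pct_ge_60 && cs$pct_ge_60 >= cs$pct_ge_100)
  }
})

test_that("site_coverage closed forms and vacuous case", {
  pr <- profile_from_depth(rep(100L, 200), start = 0L)
  out <- site_coverage(pr, c(50L, 120L), flank = 10, threshold = 60)
  expect_equal(out$fraction, 1)
  expect_warning(out0 <- site_coverage(pr, integer(0)), "no sites")
  expect_equal(out0$fraction, 1)
  # flank 0, threshold 0 is always satisfied inside profiled regions
  expect_equal(site_coverage(pr, c(1L, 199L), flank = 0, threshold = 0)$fraction, 1)
})

test_that("site_coverage equals a brute-force window enumeration oracle", {
  withr::local_seed(13)
  for (i in 1:20) {
    len <- 300L
    start <- 50L
    d <- sample(0:120, len, replace = TRUE)
    pr <- profile_from_depth(d, start = start)
    sites <- sample.int(450, 12)
    flank <- sample(0:10, 1)
    thr <- sample(c(20, 60), 1)
    got <- site_coverage(pr, sites, flank = flank, threshold = thr)
    # oracle: enumerate the union of windows position by position
    win_pos <- sort(unique(unlist(lapply(sites, function(p) {
      seq.int(max(1L, p - flank), p + flank)
    }))))
    prof_pos <- seq.int(start + 1L, start + len)
    depth_at <- function(p) d[p - start]
    in_prof <- win_pos %in% prof_pos
    n_ok <- sum(vapply(win_pos[in_prof], depth_at, integer(1)) >= thr)
    unprof_sites <- sites[vapply(sites, function(p) {
      !any(seq.int(max(1L, p - flank), p + flank) %in% prof_pos)
    }, logical(1))]
    denom <- sum(in_prof) +
      sum((unprof_sites + flank) - pmax(1L, unprof_sites - flank) + 1L)
    expect_equal(got$fraction, if (denom > 0) n_ok / denom else 0)
    expect_equal(got$n_sites_unprofiled, length(unprof_sites))
  }
})

test_that("uncovered_regions finds exactly the regions below the read threshold", {
  regions <- tibble::tibble(chrom = "chr1",
                            start = c(0L, 100L, 200L),
                            end = c(50L, 150L, 250L),
                            name = c("covered", "empty", "thin"))
  reads <- dplyr::bind_rows(
    purrr::map_dfr(1:5, ~ make_read(sprintf("c%d", .x), 10, strrep("A", 30))),
    make_read("t1", 210, strrep("A", 20)))
  out <- uncovered_regions(reads, regions, min_reads = 1)
  expect_equal(out$name, "empty")
  out2 <- uncovered_regions(reads, regions, min_reads = 2)
  expect_setequal(out2$name, c("empty", "thin"))
})

test_that("uncovered_regions agrees with brute-force overlap counting", {
  withr::local_seed(17)
  for (i in 1:10) {
    n <- 60
    pos <- sample.int(400, n, replace = TRUE)
    len <- sample(10:50, n, replace = TRUE)
    reads <- purrr::map_dfr(seq_len(n), function(j) {
      make_read(sprintf("r%03d", j), pos[j], strrep("A", len[j]))
    })
    regions <- tibble::tibble(chrom = "chr1",
                              start = seq(0L, 440L, by = 40L),
                              end = seq(30L, 470L, by = 40L))
    min_reads <- sample(1:4, 1)
    got <- uncovered_regions(reads, regions, min_reads)
    oracle_max <- vapply(seq_len(nrow(regions)), function(k) {
      p <- seq.int(regions$start[k] + 1L, regions$end[k])
      max(vapply(p, function(x) sum(pos <= x & pos + len - 1L >= x), integer(1)))
    }, integer(1))
    expect_equal(got$start, regions$start[oracle_max < min_reads])
  }
})

test_that("read_stats closed forms: N50, quality and on-target rate", {
  single <- make_read("r1", 1, strrep("A", 1000), qual = qstr(10, 1000))
  rs <- read_stats(single)
  expect_equal(rs$n50, 1000L)
  expect_equal(rs$mean_length, 1000)
  expect_equal(rs$mean_read_q, 10)
  expect_equal(rs$pct_reads_ge_q10, 100)

  # N50 of lengths 1,1,1,4: the length-4 read alone holds >= half the bases
  expect_equal(n50(c(1L, 1L, 1L, 4L)), 4L)
  # brute-force n50 over random length sets
  withr::local_seed(19)
  for (i in 1:20) {
    lens <- sample.int(2000, sample(3:50, 1), replace = TRUE)
    cand <- sort(unique(lens), decreasing = TRUE)
    brute <- max(cand[vapply(cand, function(L) {
      sum(lens[lens >= L]) >= sum(lens) / 2
    }, logical(1))])
    expect_equal(n50(lens), brute)
  }

  reads <- dplyr::bind_rows(
    make_read("a", 1, strrep("A", 100)),    # 40 of 100 bases on target
    make_read("b", 201, strrep("A", 50)))   # 0 on target
  regions <- tibble::tibble(chrom = "chr1", start = 60L, end = 100L)
  expect_equal(read_stats(reads, regions)$on_target_rate, 100 * 40 / 150)
  expect_error(read_stats(reads[0, ]), "at least one read")
})

test_that("gc_content counts letters exactly and excludes N", {
  expect_equal(gc_content(tiny_ref("ATAT"),
                          tibble::tibble(chrom = "chr1", start = 0L, end = 4L)), 0)
  expect_equal(gc_content(tiny_ref("GCGC"),
                          tibble::tibble(chrom = "chr1", start = 0L, end = 4L)), 1)
  expect_equal(gc_content(tiny_ref("GCNNAT"),
                          tibble::tibble(chrom = "chr1", start = 0L, end = 6L)), 0.5)
  expect_warning(
    allN <- gc_content(tiny_ref("NNNN"),
                       tibble::tibble(chrom = "chr1", start = 0L, end = 4L)),
    "undefined")
  expect_true(is.na(allN))
  withr::local_seed(23)
  s <- paste(sample(c("A", "C", "G", "T", "N"), 500, replace = TRUE),
             collapse = "")
  chars <- strsplit(s, "")[[1]]
  expect_equal(gc_content(tiny_ref(s),
                          tibble::tibble(chrom = "chr1", start = 0L, end = 500L)),
               sum(chars %in% c("G", "C")) / sum(chars != "N"))
})

test_that("depth mass equals on-target matched bases (conservation)", {
  sim <- small_sim(seed = 29)
  profile <- compute_depth(sim$reads, sim$regions)
  # oracle: walk every read's CIGAR and count matched bases inside regions
  region_pos <- unlist(Map(seq.int, sim$regions$start + 1L, sim$regions$end))
  in_region <- logical(nchar(sim$ref$seq))
  in_region[region_pos] <- TRUE
  matched <- 0
  for (i in seq_len(nrow(sim$reads))) {
    cg <- parse_cigar(sim$reads$cigar[i])
    rp <- sim$reads$pos[i]
    for (k in seq_len(nrow(cg))) {
      if (cg$op[k] %in% c("M", "=", "X")) {
        matched <- matched + sum(in_region[rp:(rp + cg$len[k] - 1L)])
        rp <- rp + cg$len[k]
      } else if (cg$op[k] %in% c("D", "N")) {
        rp <- rp + cg$len[k]
      }
    }
  }
  expect_equal(sum(unlist(profile$depth)), matched)
})

test_that("qc_report assembles the full summary with GC-annotated gaps", {
  sim <- small_sim(seed = 35)
  qc <- qc_report(sim$reads, sim$regions, ref = sim$ref,
                  min_mapq = 60, primary_only = TRUE)
  s <- qc$summary
  expect_true(all(c("mean_doc", "pct_ge_30", "uniformity", "n50",
                    "mean_read_q", "on_target_rate",
                    "uncovered_region_count") %in% names(s)))
  pcts <- unlist(s[c("pct_ge_30", "pct_ge_60", "pct_ge_100", "uniformity",
                     "pct_reads_ge_q10", "on_target_rate")])
  expect_true(all(pcts >= 0 & pcts <= 100))
  expect_s3_class(tidy(qc), "tbl_df")
  expect_equal(nrow(glance(qc)), 1L)
})
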