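# Synthetic capture simulator: reference, regions, planted variants, reads.

test_that("sim_reference respects length and GC composition", {
  ref <- sim_reference(1000, gc_fraction = 0.4, seed = 3)
  expect_equal(nchar(ref$seq), 1000L)
  expect_true(grepl("^[ACGT]+$", ref$seq))

  at_only <- sim_reference(500, gc_fraction = 0, seed = 3)
  expect_true(grepl("^[AT]+$", at_only$seq))

  big <- sim_reference(1e5, gc_fraction = 0.5, seed = 3)
  gc <- sum(strsplit(big$seq, "")[[1]] %in% c("G", "C"))
  # within 3 binomial standard deviations of 0.5
  expect_lt(abs(gc - 5e4), 3 * sqrt(1e5 * 0.25))
})

test_that("sim_target_bed packs sorted non-overlapping regions of the right size", {
  bed <- sim_target_bed(2e6, 1000, region_length_mean = 164, seed = 9)
  expect_equal(nrow(bed), 1000L)
  expect_true(all(bed$start[-1] > bed$end[-1000]))
  expect_true(all(bed$end - bed$start >= 50))
  expect_lt(abs(mean(bed$end - bed$start) - 164) / 164, 0.10)

  expect_identical(bed, sim_target_bed(2e6, 1000, 164, seed = 9))
  expect_error(sim_target_bed(1000, 100, region_length_mean = 164, seed = 1),
               "pack")
})

test_that("zero variant rates leave haplotypes equal to the reference", {
  cfg <- sim_config(ref_length = 20000, n_regions = 10, snv_rate = 0,
                    indel_rate = 0, seed = 2)
  ref <- sim_reference(cfg$ref_length, seed = cfg$seed)
  regions <- sim_target_bed(cfg$ref_length, cfg$n_regions, seed = cfg$seed)
  planted <- sim_variants(ref, regions, cfg)
  expect_equal(nrow(planted$truth), 0L)
  expect_equal(planted$haplotypes$seq, rep(ref$seq, 2))
})

test_that("applying the truth set to the reference reproduces the haplotypes", {
  sim <- small_sim(seed = 31)
  # independent splice oracle, walking variants right-to-left
  apply_oracle <- function(refseq, events) {
    s <- refseq
    for (i in rev(seq_len(nrow(events)))) {
      p <- events$pos[i]
      s <- paste0(substr(s, 1, p - 1), events$alt[i],
                  substr(s, p + nchar(events$ref[i]), nchar(s)))
    }
    s
  }
  expect_gt(nrow(sim$truth), 0)
  expect_equal(apply_oracle(sim$ref$seq, sim$truth[sim$truth$hap1, ]),
               sim$haplotypes$seq[1])
  expect_equal(apply_oracle(sim$ref$seq, sim$truth[sim$truth$hap2, ]),
               sim$haplotypes$seq[2])
  # hom variants present on both haplotypes, het on exactly one
  hom <- sim$truth$gt == "1/1"
  expect_true(all(sim$truth$hap1[hom] & sim$truth$hap2[hom]))
  expect_true(all(xor(sim$truth$hap1[!hom], sim$truth$hap2[!hom])))
})

test_that("planted variant counts follow the configured rate", {
  counts <- vapply(1:10, function(s) {
    cfg <- sim_config(ref_length = 50000, n_regions = 60, snv_rate = 0.01,
                      indel_rate = 0, seed = s)
    ref <- sim_reference(cfg$ref_length, seed = s)
    regions <- sim_target_bed(cfg$ref_length, cfg$n_regions, seed = s)
    nrow(sim_variants(ref, regions, cfg)$truth)
  }, numeric(1))
  bases <- sum(with(sim_target_bed(50000, 60, seed = 1), end - start))
  lambda <- 0.01 * bases  # ~constant across seeds (region sampling varies a bit)
  expect_lt(abs(mean(counts) - lambda),
            3 * sqrt(lambda / 10) + 0.05 * lambda)
})

test_that("error-free hom-ref reads reproduce reference slices exactly", {
  cfg <- sim_config(ref_length = 20000, n_regions = 8, mean_depth = 10,
                    snv_rate = 0, indel_rate = 0, sub_error_rate = 0,
                    indel_error_rate = 0, seed = 4)
  ref <- sim_reference(cfg$ref_length, seed = cfg$seed)
  regions <- sim_target_bed(cfg$ref_length, cfg$n_regions, seed = cfg$seed)
  planted <- sim_variants(ref, regions, cfg)
  reads <- sim_reads(ref, planted$events, regions, cfg)
  expect_gt(nrow(reads), 0)
  expect_true(all(grepl("^[0-9]+M$", reads$cigar)))
  for (i in seq_len(nrow(reads))) {
    expect_identical(reads$seq[i],
                     substr(ref$seq, reads$pos[i],
                            reads$pos[i] + nchar(reads$seq[i]) - 1L))
  }
})

test_that("with no errors, mismatches sit exactly at planted SNVs", {
  cfg <- sim_config(ref_length = 20000, n_regions = 10, mean_depth = 15,
                    snv_rate = 0.01, indel_rate = 0, sub_error_rate = 0,
                    indel_error_rate = 0, het_fraction = 0, seed = 8)
  ref <- sim_reference(cfg$ref_length, seed = cfg$seed)
  regions <- sim_target_bed(cfg$ref_length, cfg$n_regions, seed = cfg$seed)
  planted <- sim_variants(ref, regions, cfg)
  reads <- sim_reads(ref, planted$events, regions, cfg)
  idx <- capcall:::index_reads(reads, ref)
  snv_pos <- planted$truth$pos[planted$truth$type == "snv"]
  expect_gt(nrow(idx$mismatches), 0)
  expect_true(all(idx$mismatches$refpos %in% snv_pos))
})

test_that("mean realized on-target depth matches the log-normal expectation", {
  # regions spaced far apart so neighbouring regions' read flanks do not
  # add coverage on top of the region's own draw
  sigma <- 0.3
  cfg <- sim_config(ref_length = 3e6, n_regions = 150, mean_depth = 30,
                    capture_bias_sigma = sigma, snv_rate = 0, indel_rate = 0,
                    sub_error_rate = 0, indel_error_rate = 0,
                    low_mapq_fraction = 0, secondary_fraction = 0, seed = 6)
  ref <- sim_reference(cfg$ref_length, seed = cfg$seed)
  regions <- sim_target_bed(cfg$ref_length, cfg$n_regions, seed = cfg$seed)
  planted <- sim_variants(ref, regions, cfg)
  reads <- sim_reads(ref, planted$events, regions, cfg)
  profile <- compute_depth(reads, regions)
  mean_doc <- coverage_summary(profile)$mean_doc
  expected <- 30 * exp(sigma^2 / 2)
  expect_lt(abs(mean_doc - expected) / expected, 0.10)
})

test_that("the simulator is deterministic per seed, including SAM bytes", {
  cfg <- sim_config(ref_length = 15000, n_regions = 6, mean_depth = 8, seed = 12)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_capture(cfg, out_dir = d1)
  simulate_capture(cfg, out_dir = d2)
  for (f in c("reference.fasta", "targets.bed", "truth.vcf", "reads.sam",
              "reads.fastq")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("read qualities land near the configured read-level Phred mean", {
  sim <- small_sim(seed = 44)
  rs <- read_stats(sim$reads)
  expect_lt(abs(rs$mean_read_q - 11), 1)
  expect_lt(abs(rs$mean_length - 1000), 50)
})
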