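# Shared fixture builders: everything is generated in code at test time.

tiny_ref <- function(seq, name = "chr1") {
  tibble::tibble(name = name, seq = toupper(seq))
}

# quality string of n bases at Phred q
qstr <- function(q, n) capcall::phred_to_string(rep(as.integer(q), n))

# one aligned read row; cigar defaults to all-match
make_read <- function(read_id, pos, seq, qual = NULL, cigar = NULL,
                      chrom = "chr1", mapq = 60L, is_primary = TRUE) {
  if (is.null(cigar)) cigar <- sprintf("%dM", nchar(seq))
  if (is.null(qual)) qual <- qstr(20, nchar(seq))
  tibble::tibble(read_id = read_id, chrom = chrom, pos = as.integer(pos),
                 cigar = cigar, seq = seq, qual = qual,
                 mapq = as.integer(mapq), is_primary = is_primary,
                 flag = ifelse(is_primary, 0L, 256L))
}

# pileup observation column at one position
make_column <- function(alleles, quals, kinds = NULL, pos = 100L,
                        chrom = "chr1", ref_base = "A") {
  n <- length(alleles)
  if (is.null(kinds)) kinds <- rep("base", n)
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref_base = ref_base,
                 read_id = sprintf("r%05d", seq_len(n)),
                 kind = kinds, allele = as.character(alleles),
                 qual = as.integer(quals))
}

# column of n_ref reference-base and n_alt alternate-base observations
ref_alt_column <- function(n_ref, n_alt, ref_base = "A", alt_base = "C",
                           qual = 20L, pos = 100L) {
  make_column(c(rep(ref_base, n_ref), rep(alt_base, n_alt)),
              rep(qual, n_ref + n_alt), pos = pos, ref_base = ref_base)
}

# random valid task-probability set (uniform on the simplex per task)
random_task_probs <- function() {
  rnd <- function(k) { x <- stats::runif(k); x / sum(x) }
  capcall::task_probabilities(rnd(21), rnd(4), rnd(33), rnd(33))
}

# one-hot task probabilities by class name / bin value
onehot_task_probs <- function(gt21_class, zyg_class, len1 = 0, len2 = 0) {
  g <- numeric(21); names(g) <- capcall:::GT21_CLASSES; g[gt21_class] <- 1
  z <- numeric(4); names(z) <- capcall:::ZYGOSITY_CLASSES; z[zyg_class] <- 1
  l1 <- numeric(33); l1[capcall:::len_bin(len1)] <- 1
  l2 <- numeric(33); l2[capcall:::len_bin(len2)] <- 1
  capcall::task_probabilities(g, z, l1, l2)
}

# small deterministic simulated dataset shared by several tests
small_sim <- function(seed = 5, ...) {
  capcall::simulate_capture(capcall::sim_config(
    ref_length = 30000, n_regions = 25, mean_depth = 50, seed = seed, ...))
}

truth_variants <- function(sim) {
  dplyr::select(sim$truth, -"type", -"hap1", -"hap2")
}
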