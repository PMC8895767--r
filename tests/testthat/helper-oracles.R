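# Independent oracles used by both the unit and the acceptance suites.
# These re-derive expected behaviour from first principles and share no
# code with the implementation they check.

# --- depth-capped partitioning: expected shape accounting ----------------
partition_oracle <- function(quals, config) {
  d <- length(quals)
  if (d <= config$max_depth) {
    return(list(n_parts = 1L, sizes = d, distinct = d, filtered = FALSE))
  }
  dp <- sum(quals >= config$base_q_cutoff)
  if (dp <= config$max_depth) {
    return(list(n_parts = 1L, sizes = dp, distinct = dp, filtered = TRUE))
  }
  n <- min(config$max_partitions, ceiling(dp / config$max_depth))
  retained <- min(dp, n * config$max_depth)
  list(n_parts = as.integer(ceiling(retained / config$max_depth)),
       sizes = rep(config$max_depth,
                   as.integer(ceiling(retained / config$max_depth))),
       distinct = retained, filtered = TRUE)
}

# run all partition invariants for one random column; returns invisibly
check_partition_invariants <- function(col, config) {
  cp <- capcall::partition_column(col, config)
  o <- partition_oracle(col$qual, config)
  sizes <- vapply(cp$partitions, nrow, integer(1))
  expect_length(cp$partitions, o$n_parts)
  expect_equal(sizes, o$sizes)
  expect_true(all(sizes <= config$max_depth))
  ids <- unlist(lapply(cp$partitions, `[[`, "read_id"))
  expect_equal(length(unique(ids)), o$distinct)
  if (nrow(col) <= config$max_depth) {
    expect_identical(cp$partitions[[1]], col)  # low-depth transparency
  } else {
    expect_true(all(unlist(lapply(cp$partitions, `[[`, "qual")) >=
                      config$base_q_cutoff))
  }
  for (p in cp$partitions) expect_false(anyDuplicated(p$read_id) > 0)
  # determinism
  again <- capcall::partition_column(col, config)
  expect_identical(cp$partitions, again$partitions)
  invisible(cp)
}

# --- diploid-likelihood closed form for n clean reference reads ----------
analytic_hom_ref <- function(n, eps, het_prior) {
  lik <- c(rr = (1 - eps)^n,
           hom_alt = (eps / 3)^n,                  # x3 classes
           het_ref = ((1 - eps) / 2 + eps / 6)^n,  # x3 classes
           het_non = (eps / 3)^n)                  # x3 classes
  prior_hom <- (1 - het_prior) / 4
  prior_het <- het_prior / 6
  z <- prior_hom * (lik[["rr"]] + 3 * lik[["hom_alt"]]) +
    prior_het * (3 * lik[["het_ref"]] + 3 * lik[["het_non"]])
  prior_hom * lik[["rr"]] / z
}

# --- decision-table transcription of the documented calling contract -----
oracle_decide <- function(avg, ref_base, column) {
  zyg_names <- c("hom_ref", "hom_alt", "het_alt", "het_multi")
  z <- zyg_names[which.max(avg$zygosity)]
  if (z == "hom_ref") return(list(is_variant = FALSE, conflict = FALSE))
  cls <- capcall:::GT21_CLASSES[which.max(avg$gt21)]
  pair <- c(substr(cls, 1, 1), substr(cls, 2, 2))
  nra <- unique(pair[pair != ref_base])
  if (length(nra) == 0) return(list(is_variant = FALSE, conflict = TRUE))
  rank6 <- c(A = 1, C = 2, G = 3, T = 4, I = 5, D = 6)
  letter_of <- ifelse(column$kind == "insertion", "I",
                      ifelse(column$kind == "deletion", "D", column$allele))
  supp <- vapply(nra, function(a) sum(letter_of == a), numeric(1))
  nra <- nra[order(-supp, rank6[nra])]
  hom_pair <- pair[1] == pair[2]
  ref_in_pair <- ref_base %in% pair
  if (z == "hom_alt") {
    alts <- nra[1]; gt <- "1/1"
    conflict <- !(hom_pair && !ref_in_pair)
  } else if (z == "het_alt") {
    alts <- nra[1]; gt <- "0/1"
    conflict <- !(ref_in_pair && !hom_pair)
  } else {
    if (length(nra) == 2) {
      alts <- nra; gt <- "1/2"; conflict <- FALSE
    } else {
      alts <- nra[1]
      gt <- if (hom_pair) "1/1" else "0/1"
      conflict <- TRUE
    }
  }
  consulted <- c(max(avg$zygosity), max(avg$gt21))
  if (any(alts %in% c("I", "D"))) {
    consulted <- c(consulted, max(avg$len1), max(avg$len2))
  }
  qual <- min(99, -10 * log10(max(1 - min(consulted), 1e-10)))
  list(is_variant = TRUE, gt = gt, alts = alts, conflict = conflict,
       qual = qual)
}

decision_letters <- function(dec) {
  vapply(dec$alts, function(a) {
    switch(a$type, snv = a$base, ins = "I", del = "D")
  }, character(1))
}

# random observation column rich enough to realize any allele choice
random_decision_column <- function(ref_base) {
  make_column(
    c(sample(c("A", "C", "G", "T"), 12, replace = TRUE),
      sample(c("GG", "T", "ACA"), 3, replace = TRUE),
      sample(as.character(1:5), 3, replace = TRUE)),
    quals = sample(5:40, 18, replace = TRUE),
    kinds = c(rep("base", 12), rep("insertion", 3), rep("deletion", 3)),
    ref_base = ref_base)
}
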