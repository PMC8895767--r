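# Ensemble averaging of task probabilities and the variant decision rule.

#' Average task probabilities across partitions and models
#'
#' Element-wise arithmetic mean of each task vector over all inputs — the
#' ensemble step that combines every (partition x model) output at a
#' position into one robust set of distributions.
#'
#' @param outputs A non-empty list of [task_probabilities()] objects.
#' @return A [task_probabilities()] object.
#' @export
average_probabilities <- function(outputs) {
  if (!is.list(outputs) || length(outputs) == 0) {
    abort("outputs must be a non-empty list of task probabilities")
  }
  for (o in outputs) validate_task_probs(o)
  avg <- function(task) {
    m <- vapply(outputs, function(o) o[[task]],
                numeric(length(outputs[[1]][[task]])))
    rowMeans(matrix(m, ncol = length(outputs)))
  }
  task_probabilities(avg("gt21"), avg("zygosity"), avg("len1"), avg("len2"))
}

# support (observation count) for each allele letter in a column
allele_support <- function(column) {
  al <- obs_allele6(column)
  vapply(ALLELE_ORDER, function(a) sum(al == a), numeric(1))
}

# order candidate alt letters by support (desc), ties by allele rank
order_by_support <- function(letters, support) {
  letters[order(-support[letters], match(letters, ALLELE_ORDER))]
}

#' Decide the variant call from averaged task probabilities
#'
#' The zygosity argmax decides hom-ref versus variant; the 21-class
#' genotype argmax fixes the allele pair; insertion/deletion alleles are
#' realized as the most frequent event of the length given by the
#' indel-length task argmax among the column's observations. When the
#' tasks disagree (e.g. zygosity heterozygous but a homozygous genotype
#' argmax) zygosity wins on hom-ref versus variant, the genotype task wins
#' on allele identity, and the decision is flagged `conflict`. QUAL is
#' `-10 log10(1 - p)` with `p` the smallest argmax probability over the
#' consulted tasks, capped at 99.
#'
#' @param avg Averaged [task_probabilities()].
#' @param ref_base Reference base at the column.
#' @param column The full observation tibble for the column (used to
#'   realize insertion sequences and deletion lengths and to rank alleles
#'   by support).
#' @return A list of class `capcall_decision` with elements `is_variant`,
#'   `gt` (genotype string), `alts` (list of allele descriptors with
#'   `type` = snv/ins/del, `base`, `seq`, `len`), `qual`, `conflict`, and
#'   the consulted argmax classes.
#' @export
decide <- function(avg, ref_base, column) {
  validate_task_probs(avg)
  z <- ZYGOSITY_CLASSES[which.max(avg$zygosity)]
  decision <- function(is_variant, gt = NA_character_, alts = list(),
                       qual = 0, conflict = FALSE) {
    structure(list(is_variant = is_variant, gt = gt, alts = alts,
                   qual = qual, conflict = conflict,
                   zygosity = z,
                   gt21 = GT21_CLASSES[which.max(avg$gt21)]),
              class = "capcall_decision")
  }
  if (z == "hom_ref") return(decision(FALSE))

  g_cls <- GT21_CLASSES[which.max(avg$gt21)]
  pair <- gt21_alleles(g_cls)
  nra <- unique(pair[pair != ref_base])
  if (length(nra) == 0) {
    # zygosity says variant, genotype argmax is homozygous reference:
    # no allele can be emitted; hom-ref wins, flagged
    return(decision(FALSE, conflict = TRUE))
  }
  support <- allele_support(column)
  nra <- order_by_support(nra, support)

  pair_is_hom <- pair[1] == pair[2]
  pair_has_ref <- any(pair == ref_base)
  if (z == "hom_alt") {
    alts <- nra[1]
    gt <- "1/1"
    conflict <- !(pair_is_hom && !pair_has_ref) || length(nra) > 1
  } else if (z == "het_alt") {
    alts <- nra[1]
    gt <- "0/1"
    conflict <- !(pair_has_ref && !pair_is_hom) || length(nra) > 1
  } else {  # het_multi
    if (length(nra) == 2) {
      alts <- nra
      gt <- "1/2"
      conflict <- FALSE
    } else {
      alts <- nra[1]
      gt <- if (pair_is_hom) "1/1" else "0/1"
      conflict <- TRUE
    }
  }

  has_indel <- any(alts %in% c("I", "D"))
  descs <- lapply(alts, function(a) realize_allele(a, avg, column))
  consulted <- c(max(avg$zygosity), max(avg$gt21),
                 if (has_indel) c(max(avg$len1), max(avg$len2)))
  p_min <- min(consulted)
  qual <- min(99, -10 * log10(max(1 - p_min, 1e-10)))
  decision(TRUE, gt = gt, alts = descs, qual = qual, conflict = conflict)
}

# realize an allele letter as a concrete descriptor using the length-task
# argmaxes and the column's observations
realize_allele <- function(a, avg, column) {
  if (a %in% c("A", "C", "G", "T")) {
    return(list(type = "snv", base = a, seq = NULL, len = 0L))
  }
  l1 <- LEN_BIN_VALUES[which.max(avg$len1)]
  l2 <- LEN_BIN_VALUES[which.max(avg$len2)]
  if (a == "I") {
    target <- if (l2 > 0) l2 else if (l1 > 0) l1 else NA_integer_
    o <- column[column$kind == "insertion", ]
    if (nrow(o) == 0) abort("cannot realize insertion allele: no insertion observations")
    lens <- nchar(o$allele)
    cand <- if (!is.na(target) && any(lens == target)) o$allele[lens == target] else o$allele
    tab <- sort(table(cand), decreasing = TRUE)
    seqs <- names(tab)[tab == tab[1]]
    s <- min(seqs)
    list(type = "ins", base = NULL, seq = s, len = nchar(s))
  } else {
    target <- if (l1 < 0) -l1 else if (l2 < 0) -l2 else NA_integer_
    o <- column[column$kind == "deletion", ]
    if (nrow(o) == 0) abort("cannot realize deletion allele: no deletion observations")
    lens <- as.integer(o$allele)
    len <- if (!is.na(target) && any(lens == target)) target else mode_indel_length(column, "deletion")
    list(type = "del", base = NULL, seq = NULL, len = as.integer(len))
  }
}

#' @export
print.capcall_task_probs <- function(x, ...) {
  cat("<capcall_task_probs>\n")
  cat("  gt21 argmax:    ", GT21_CLASSES[which.max(x$gt21)],
      sprintf("(%.3f)\n", max(x$gt21)))
  cat("  zygosity argmax:", ZYGOSITY_CLASSES[which.max(x$zygosity)],
      sprintf("(%.3f)\n", max(x$zygosity)))
  cat("  len1/len2 argmax:", LEN_BIN_LABELS[which.max(x$len1)], "/",
      LEN_BIN_LABELS[which.max(x$len2)], "\n")
  invisible(x)
}
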