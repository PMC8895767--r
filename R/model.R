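# Per-partition probability models. A model maps (partition of
# observations, reference base) to four per-position classification
# distributions: 21-class genotype, 4-class zygosity, and two 33-bin
# indel-length tasks (one per haplotype). Any conforming model can be
# plugged into the ensemble; the package ships a diploid-likelihood model.

ALLELE_ORDER <- c("A", "C", "G", "T", "I", "D")

# 21 unordered pairs over A,C,G,T plus insertion (I) and deletion (D)
# pseudo-alleles.
GT21_CLASSES <- c("AA", "AC", "AG", "AT", "CC", "CG", "CT", "GG", "GT", "TT",
                  "AI", "CI", "GI", "TI", "AD", "CD", "GD", "TD",
                  "II", "ID", "DD")

ZYGOSITY_CLASSES <- c("hom_ref", "hom_alt", "het_alt", "het_multi")

# 33 indel-length bins: <=-16, -15..-1, 0, +1..+15, >=+16
LEN_BIN_VALUES <- -16:16
LEN_BIN_LABELS <- c("<=-16", as.character(-15:15), ">=+16")

len_bin <- function(l) pmin(pmax(as.integer(l), -16L), 16L) + 17L

gt21_class <- function(a1, a2) {
  r <- match(c(a1, a2), ALLELE_ORDER)
  paste0(ALLELE_ORDER[min(r)], ALLELE_ORDER[max(r)])
}

gt21_alleles <- function(cls) {
  c(substr(cls, 1, 1), substr(cls, 2, 2))
}

#' Construct a validated set of task probabilities
#'
#' @param gt21 Numeric vector of length 21, named or in the canonical class
#'   order (see `capcall:::GT21_CLASSES`).
#' @param zygosity Numeric vector of length 4 (hom-ref, hom-alt, het-alt,
#'   het-multi).
#' @param len1,len2 Numeric vectors of length 33 (indel-length bins -16..16,
#'   clamped) for the lower/higher-length haplotype.
#' @return A list of class `capcall_task_probs`.
#' @export
task_probabilities <- function(gt21, zygosity, len1, len2) {
  tp <- list(gt21 = as.numeric(gt21), zygosity = as.numeric(zygosity),
             len1 = as.numeric(len1), len2 = as.numeric(len2))
  names(tp$gt21) <- GT21_CLASSES
  names(tp$zygosity) <- ZYGOSITY_CLASSES
  names(tp$len1) <- LEN_BIN_LABELS
  names(tp$len2) <- LEN_BIN_LABELS
  validate_task_probs(tp)
  class(tp) <- "capcall_task_probs"
  tp
}

validate_task_probs <- function(tp) {
  sizes <- c(gt21 = 21L, zygosity = 4L, len1 = 33L, len2 = 33L)
  for (task in names(sizes)) {
    v <- tp[[task]]
    if (length(v) != sizes[[task]]) {
      abort(sprintf("task '%s' must have %d classes, got %d",
                    task, sizes[[task]], length(v)))
    }
    if (any(v < 0) || abs(sum(v) - 1) > 1e-6) {
      abort(sprintf("task '%s' is not a probability distribution", task))
    }
  }
  invisible(tp)
}

# map observations to the 6-letter allele space
obs_allele6 <- function(obs) {
  ifelse(obs$kind == "insertion", "I",
         ifelse(obs$kind == "deletion", "D", obs$allele))
}

# most frequent event length among indel observations; ties -> smallest
mode_indel_length <- function(obs, kind) {
  o <- obs[obs$kind == kind, ]
  if (nrow(o) == 0) return(NA_integer_)
  lens <- if (kind == "insertion") nchar(o$allele) else as.integer(o$allele)
  tab <- sort(table(lens), decreasing = TRUE)
  cand <- as.integer(names(tab)[tab == tab[1]])
  min(cand)
}

#' Diploid-likelihood probability model
#'
#' A transparent stand-in for a trained network, used as the default
#' pluggable model: a diploid genotype posterior over the observed alleles
#' plus the reference. Each observation contributes likelihood
#' `0.5 p(obs|a1) + 0.5 p(obs|a2)` for genotype `{a1, a2}`, with
#' `p(obs|a) = 1 - eps` when the observation supports allele `a` and
#' `eps / 3` otherwise; `eps` comes from the observation's Phred score,
#' floored at `error_rate_prior` (and capped at 0.75). The prior places
#' `het_prior` mass uniformly over the active heterozygous genotypes and
#' the rest uniformly over the active homozygous genotypes. The four base
#' alleles are always active; insertion/deletion pseudo-alleles are active
#' only when supporting observations exist. The normalized posterior is
#' reported as the 21-class genotype task and marginalized into zygosity
#' and the two indel-length tasks (non-indel genotypes put their length
#' mass on 0).
#'
#' @param partition Non-empty observation tibble (one partition).
#' @param ref_base Reference base at the column (A/C/G/T).
#' @param error_rate_prior Floor on the per-observation error rate.
#' @param het_prior Prior mass on heterozygous genotypes.
#' @return A [task_probabilities()] object.
#' @export
naive_model <- function(partition, ref_base, error_rate_prior = 0.05,
                        het_prior = 0.5) {
  if (!is.data.frame(partition) || nrow(partition) == 0) {
    abort("partition must be a non-empty observation tibble")
  }
  if (!ref_base %in% c("A", "C", "G", "T")) {
    abort(sprintf("ref_base must be one of A/C/G/T, got '%s'", ref_base))
  }
  al <- obs_allele6(partition)
  active <- c("A", "C", "G", "T",
              if (any(al == "I")) "I", if (any(al == "D")) "D")
  eps <- pmin(pmax(phred_to_error(partition$qual), error_rate_prior), 0.75)

  # per-observation likelihood for each active allele
  p_mat <- vapply(active, function(a) ifelse(al == a, 1 - eps, eps / 3),
                  numeric(nrow(partition)))
  p_mat <- matrix(p_mat, nrow = nrow(partition),
                  dimnames = list(NULL, active))

  pairs <- which(upper.tri(diag(length(active)), diag = TRUE), arr.ind = TRUE)
  n_hom <- length(active)
  n_het <- nrow(pairs) - n_hom
  loglik <- numeric(nrow(pairs))
  lprior <- numeric(nrow(pairs))
  cls <- character(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    a1 <- active[pairs[k, "row"]]
    a2 <- active[pairs[k, "col"]]
    loglik[k] <- sum(log(0.5 * p_mat[, a1] + 0.5 * p_mat[, a2]))
    lprior[k] <- if (a1 == a2) log((1 - het_prior) / n_hom) else log(het_prior / n_het)
    cls[k] <- gt21_class(a1, a2)
  }
  w <- loglik + lprior
  post <- exp(w - max(w))
  post <- post / sum(post)

  gt21 <- setNames(numeric(21), GT21_CLASSES)
  gt21[cls] <- post

  ref_cls <- gt21_class(ref_base, ref_base)
  zyg <- setNames(numeric(4), ZYGOSITY_CLASSES)
  len1 <- numeric(33)
  len2 <- numeric(33)
  ins_len <- mode_indel_length(partition, "insertion")
  del_len <- mode_indel_length(partition, "deletion")
  allele_len <- function(a) {
    if (a == "I") ins_len else if (a == "D") -del_len else 0L
  }
  for (k in seq_len(nrow(pairs))) {
    a1 <- active[pairs[k, "row"]]
    a2 <- active[pairs[k, "col"]]
    pk <- post[k]
    if (cls[k] == ref_cls) {
      zyg["hom_ref"] <- zyg["hom_ref"] + pk
    } else if (a1 == a2) {
      zyg["hom_alt"] <- zyg["hom_alt"] + pk
    } else if (a1 == ref_base || a2 == ref_base) {
      zyg["het_alt"] <- zyg["het_alt"] + pk
    } else {
      zyg["het_multi"] <- zyg["het_multi"] + pk
    }
    ls <- sort(c(allele_len(a1), allele_len(a2)))
    len1[len_bin(ls[1])] <- len1[len_bin(ls[1])] + pk
    len2[len_bin(ls[2])] <- len2[len_bin(ls[2])] + pk
  }
  task_probabilities(gt21, zyg, len1, len2)
}

#' Declare a pluggable probability model
#'
#' @param id Model identifier (echoed in output provenance).
#' @param fn A function `(partition, ref_base) -> task_probabilities`.
#' @return A list of class `capcall_model`.
#' @export
probability_model <- function(id, fn) {
  stopifnot(is.character(id), length(id) == 1, is.function(fn))
  structure(list(id = id, fn = fn), class = "capcall_model")
}

#' Bundled naive-model variants
#'
#' Convenience constructors for ensemble members differing in their prior
#' assumptions, mirroring an ensemble of models trained under different
#' conditions.
#'
#' @param error_rate_prior,het_prior Passed to [naive_model()].
#' @param id Model identifier.
#' @return A [probability_model()].
#' @export
naive_model_spec <- function(error_rate_prior = 0.05, het_prior = 0.5,
                             id = sprintf("naive_e%g_h%g", error_rate_prior, het_prior)) {
  probability_model(id, function(partition, ref_base) {
    naive_model(partition, ref_base, error_rate_prior, het_prior)
  })
}

#' Default two-model ensemble
#'
#' @return A list of two [probability_model()] objects with different error
#'   and heterozygosity priors.
#' @export
default_models <- function() {
  list(naive_model_spec(error_rate_prior = 0.05, het_prior = 0.5),
       naive_model_spec(error_rate_prior = 0.10, het_prior = 1 / 3))
}
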