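# Weighted genetic risk score from effect-allele dosages.

#' Construct and validate a SNP weight panel
#'
#' A panel holds one row per variant: its identifier, effect and other
#' allele, and the per-allele effect size (beta, diopters of refractive
#' error per effect allele). Weights are stored oriented so the effect
#' allele is the refraction-decreasing (myopia-risk) allele: rows supplied
#' with a negative beta have their alleles swapped and the beta negated.
#' Zero betas and duplicate variant identifiers are rejected.
#'
#' @param variant_id Character vector of variant identifiers (e.g. rsIDs).
#' @param effect_allele,other_allele Allele strings; must differ per row.
#' @param beta Numeric effect sizes in diopters per effect allele.
#' @param freq Optional effect-allele frequencies in (0, 1) (used by the
#'   synthetic generator and by mean imputation).
#' @return A `snp_panel`: a data.frame with columns `variant_id`,
#'   `effect_allele`, `other_allele`, `beta` (all > 0) and optionally `freq`.
#' @export
snp_panel <- function(variant_id, effect_allele, other_allele, beta, freq = NULL) {
  variant_id <- as.character(variant_id)
  effect_allele <- toupper(as.character(effect_allele))
  other_allele <- toupper(as.character(other_allele))
  beta <- as.numeric(beta)
  n <- length(variant_id)
  stopifnot(length(effect_allele) == n, length(other_allele) == n,
            length(beta) == n)
  if (n < 1) stop("panel must contain at least one variant", call. = FALSE)
  dup <- variant_id[duplicated(variant_id)]
  if (length(dup))
    stop("duplicate variant id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(beta)) || any(beta == 0))
    stop("betas must be finite and non-zero (zero carries no information)",
         call. = FALSE)
  if (any(effect_allele == other_allele))
    stop("effect and other allele must differ", call. = FALSE)
  # orient: effect allele is always the risk (beta > 0) allele
  flip <- beta < 0
  if (any(flip)) {
    tmp <- effect_allele[flip]
    effect_allele[flip] <- other_allele[flip]
    other_allele[flip] <- tmp
    beta[flip] <- -beta[flip]
    if (!is.null(freq)) freq[flip] <- 1 - freq[flip]
  }
  out <- data.frame(variant_id = variant_id, effect_allele = effect_allele,
                    other_allele = other_allele, beta = beta,
                    stringsAsFactors = FALSE)
  if (!is.null(freq)) {
    freq <- as.numeric(freq)
    stopifnot(length(freq) == n)
    if (any(!is.finite(freq)) || any(freq <= 0 | freq >= 1))
      stop("allele frequencies must lie strictly in (0, 1)", call. = FALSE)
    out$freq <- freq
  }
  class(out) <- c("snp_panel", "data.frame")
  out
}

#' Weighted genetic risk score
#'
#' For each subject, the weighted sum of effect-allele dosages,
#' `score = sum_i beta_i * dosage_i`, with betas in diopters. With the
#' weights used here the score is on a diopter-weighted scale (population
#' scores around 1.4-4.0 for a 26-variant refractive-error panel). The
#' optional `normalize` mode rescales by `n_variants / sum(beta)`, the other
#' common convention, which puts the score on a risk-allele-count scale.
#'
#' @param dosage Numeric vector of effect-allele dosages in \[0, 2\] for one
#'   subject, or a subjects x variants matrix. Column order must match the
#'   panel row order.
#' @param panel A [snp_panel()].
#' @param normalize Logical; rescale to the allele-count convention
#'   (default `FALSE`).
#' @return Numeric score, one per subject.
#' @export
weighted_grs <- function(dosage, panel, normalize = FALSE) {
  stopifnot(inherits(panel, "snp_panel"))
  if (is.null(dim(dosage))) dosage <- matrix(dosage, nrow = 1)
  if (ncol(dosage) != nrow(panel))
    stop("alignment error: ", ncol(dosage), " dosage columns for ",
         nrow(panel), " panel variants", call. = FALSE)
  if (any(dosage < 0 | dosage > 2))
    stop("dosages must lie in [0, 2]", call. = FALSE)
  score <- as.numeric(dosage %*% panel$beta)
  if (normalize) score <- score * nrow(panel) / sum(panel$beta)
  score
}

#' Count of carried risk alleles
#'
#' Sum of effect-allele dosages over the panel: a homozygote for the risk
#' allele contributes 2, a heterozygote 1. Fractional for imputed dosages.
#'
#' @param dosage Dosage vector or subjects x variants matrix in \[0, 2\].
#' @return Numeric count per subject, in \[0, 2 * n_variants\].
#' @export
risk_allele_count <- function(dosage) {
  if (is.null(dim(dosage))) dosage <- matrix(dosage, nrow = 1)
  if (any(dosage < 0 | dosage > 2))
    stop("dosages must lie in [0, 2]", call. = FALSE)
  as.numeric(rowSums(dosage))
}

#' Categorise a genetic risk score into low / medium / high load
#'
#' Half-open-below intervals sharing their printed endpoints: low is
#' `score < cut_points[1]`, medium is `[cut_points[1], cut_points[2])`,
#' high is `score >= cut_points[2]`. Defaults are the 2.25 / 3.00 diopter
#' cut-points used for the 26-SNP refractive-error score.
#'
#' @param score Numeric score(s).
#' @param cut_points Strictly increasing pair of cut-points.
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
categorize_grs <- function(score, cut_points = c(2.25, 3.00)) {
  stopifnot(length(cut_points) == 2, cut_points[1] < cut_points[2])
  score <- as.numeric(score)
  if (any(!is.na(score) & !is.finite(score)))
    stop("score must be finite", call. = FALSE)
  lab <- ifelse(score < cut_points[1], "low",
         ifelse(score < cut_points[2], "medium", "high"))
  factor(lab, levels = c("low", "medium", "high"))
}

#' Per-subject risk scores from a genotype matrix
#'
#' Convenience wrapper combining [weighted_grs()], [risk_allele_count()] and
#' [categorize_grs()] over a full cohort.
#'
#' @param genotypes A `genotype_matrix` (see [read_genotypes()]) or a plain
#'   subjects x variants dosage matrix with subject row names.
#' @param panel A [snp_panel()]; order must match the genotype columns.
#' @param cut_points Passed to [categorize_grs()].
#' @param normalize Passed to [weighted_grs()].
#' @return data.frame with columns `subject_id`, `score`, `n_risk_alleles`,
#'   `category`.
#' @export
compute_grs <- function(genotypes, panel, cut_points = c(2.25, 3.00),
                        normalize = FALSE) {
  if (inherits(genotypes, "genotype_matrix")) {
    dos <- genotypes$dosage
    ids <- genotypes$subject_ids
    if (!identical(genotypes$variant_ids, panel$variant_id))
      stop("alignment error: genotype variant order does not match the panel",
           call. = FALSE)
  } else {
    dos <- as.matrix(genotypes)
    ids <- rownames(dos)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(dos)))
  }
  score <- weighted_grs(dos, panel, normalize = normalize)
  data.frame(subject_id = ids,
             score = score,
             n_risk_alleles = risk_allele_count(dos),
             category = categorize_grs(score, cut_points),
             stringsAsFactors = FALSE)
}
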