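# Synthetic-cohort generator: SNP panels, Hardy-Weinberg dosages,
# demographics, and a refraction outcome whose genetic slope steepens with
# education. Defaults emulate the published structure of an elderly Dutch
# population cohort: 26 refractive-error SNPs, a 3-level education variable
# at proportions 43.2 / 38.8 / 18.0%, age 64.9 +/- 9.2 years (minimum 45),
# 43% men, and education-specific score slopes (-0.47, -0.53, -0.78) D per
# score unit.

#' Specification of a synthetic SNP weight panel
#'
#' @param n_snps Number of variants (default 26, the refractive-error
#'   genome-wide-significant panel size).
#' @param beta_range Interval of per-allele effect sizes in diopters;
#'   betas are drawn uniformly (default \[0.03, 0.25\], bracketing the
#'   published small refractive-error effects).
#' @param freq_range Interval of effect-allele frequencies, uniform draws
#'   (default \[0.2, 0.8\]: common variants).
#' @param seed Integer master seed for the panel substream.
#' @return A `snp_panel_spec` list.
#' @export
snp_panel_spec <- function(n_snps = 26, beta_range = c(0.03, 0.25),
                           freq_range = c(0.2, 0.8), seed = 1) {
  stopifnot(n_snps >= 1, length(beta_range) == 2, length(freq_range) == 2)
  if (beta_range[1] > beta_range[2] || beta_range[1] <= 0)
    stop("spec error: beta_range must be positive and non-empty", call. = FALSE)
  if (freq_range[1] > freq_range[2] || freq_range[1] <= 0 || freq_range[2] >= 1)
    stop("spec error: freq_range must lie within (0, 1)", call. = FALSE)
  structure(list(n_snps = as.integer(n_snps), beta_range = beta_range,
                 freq_range = freq_range, seed = as.integer(seed)),
            class = "snp_panel_spec")
}

#' Generate a synthetic SNP weight panel
#'
#' Draws betas and effect-allele frequencies uniformly from the spec ranges;
#' deterministic under the spec seed. Variant identifiers are synthetic
#' rsID-style strings; allele pairs are drawn from the four bases.
#'
#' @param spec A [snp_panel_spec()].
#' @return A [snp_panel()] with a `freq` column.
#' @export
generate_snp_panel <- function(spec = snp_panel_spec()) {
  stopifnot(inherits(spec, "snp_panel_spec"))
  set.seed(derive_seed(spec$seed, 101L))
  n <- spec$n_snps
  betas <- stats::runif(n, spec$beta_range[1], spec$beta_range[2])
  freqs <- stats::runif(n, spec$freq_range[1], spec$freq_range[2])
  bases <- c("A", "C", "G", "T")
  ea <- sample(bases, n, replace = TRUE)
  oa <- vapply(ea, function(b) sample(setdiff(bases, b), 1), character(1))
  snp_panel(variant_id = sprintf("rs%07d", seq_len(n) * 13 + 1000000),
            effect_allele = ea, other_allele = oa, beta = betas, freq = freqs)
}

#' Specification of a synthetic cohort
#'
#' @param n_subjects Cohort size.
#' @param education_probs Probabilities of primary / intermediate / higher
#'   education (default `c(0.432, 0.388, 0.180)`).
#' @param age_mean,age_sd Age distribution in years before truncation
#'   (defaults 64.9 and 9.2); ages are truncated at `age_min`.
#' @param age_min Lower truncation bound in years (default 45, the youngest
#'   recruitment age across the emulated cohorts).
#' @param male_prob Probability of male sex (default 0.43).
#' @param intercept Refraction intercept in diopters (default 2.5,
#'   calibrated so the default panel's mean score yields a cohort mean
#'   refraction of about +0.5 D).
#' @param slopes_by_education Diopters of refraction per score unit for
#'   primary, intermediate, higher education (default
#'   `c(-0.47, -0.53, -0.78)`).
#' @param noise_sd Residual refraction SD in diopters (default 2.0,
#'   approximating the portion of the observed 2.5 D outcome SD not
#'   explained by the score and demographics).
#' @param cylinder_split If `TRUE`, split each eye's spherical equivalent
#'   into a random sphere/cylinder pair (exercising the SE formula
#'   nontrivially); default `FALSE` writes cylinder 0.
#' @param seed Integer master seed; dosage, covariate, noise and eye
#'   substreams are derived from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 9194,
                        education_probs = c(0.432, 0.388, 0.180),
                        age_mean = 64.9, age_sd = 9.2, age_min = 45,
                        male_prob = 0.43, intercept = 2.5,
                        slopes_by_education = c(-0.47, -0.53, -0.78),
                        noise_sd = 2.0, cylinder_split = FALSE, seed = 1) {
  if (n_subjects < 1) stop("spec error: n_subjects must be >= 1", call. = FALSE)
  stopifnot(length(education_probs) == 3, length(slopes_by_education) == 3)
  if (abs(sum(education_probs) - 1) > 1e-8)
    stop("spec error: education_probs must sum to 1", call. = FALSE)
  if (noise_sd <= 0) stop("spec error: noise_sd must be > 0", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 education_probs = education_probs, age_mean = age_mean,
                 age_sd = age_sd, age_min = age_min, male_prob = male_prob,
                 intercept = intercept,
                 slopes_by_education = slopes_by_education,
                 noise_sd = noise_sd, cylinder_split = cylinder_split,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Dosages are Hardy-Weinberg: `Binomial(2, freq_i)` per variant,
#' LD-free. Education is categorical, age truncated-normal, sex Bernoulli.
#' The refraction outcome is
#' `se_mean = intercept + slope[education] * GRS + Normal(0, noise_sd)`,
#' so higher education steepens the (negative) genetic slope. Per-eye
#' sphere/cylinder are back-filled so [spherical_equivalent()] and
#' [mean_se()] round-trip `se_mean` exactly.
#'
#' @param panel A [snp_panel()] with a `freq` column.
#' @param spec A [cohort_spec()].
#' @return A `generated_cohort`: list with `genotypes` (a
#'   `genotype_matrix`), `panel`, `phenotypes` (phenotype-CSV-conformant
#'   data.frame) and `truth` (all generative parameters plus realised
#'   per-subject scores).
#' @export
generate_cohort <- function(panel, spec = cohort_spec()) {
  stopifnot(inherits(panel, "snp_panel"), inherits(spec, "cohort_spec"))
  if (is.null(panel$freq))
    stop("panel needs a freq column to simulate dosages", call. = FALSE)
  n <- spec$n_subjects
  m <- nrow(panel)

  set.seed(derive_seed(spec$seed, 1L))  # dosage substream
  dosage <- matrix(stats::rbinom(n * m, 2L, rep(panel$freq, each = n)),
                   nrow = n, ncol = m)

  set.seed(derive_seed(spec$seed, 2L))  # covariate substream
  education <- sample(0:2, n, replace = TRUE, prob = spec$education_probs)
  p_lo <- stats::pnorm((spec$age_min - spec$age_mean) / spec$age_sd)
  age <- spec$age_mean +
    spec$age_sd * stats::qnorm(stats::runif(n, p_lo, 1))
  sex_male <- stats::rbinom(n, 1L, spec$male_prob)

  grs <- weighted_grs(dosage, panel)

  set.seed(derive_seed(spec$seed, 3L))  # noise substream
  se_mean <- spec$intercept + spec$slopes_by_education[education + 1] * grs +
    stats::rnorm(n, 0, spec$noise_sd)

  if (spec$cylinder_split) {
    set.seed(derive_seed(spec$seed, 4L))  # eye substream
    cyl_r <- -stats::runif(n, 0, 3)
    cyl_l <- -stats::runif(n, 0, 3)
  } else {
    cyl_r <- cyl_l <- rep(0, n)
  }
  sphere_r <- se_mean - cyl_r / 2
  sphere_l <- se_mean - cyl_l / 2

  ids <- sprintf("S%05d", seq_len(n))
  phenotypes <- data.frame(
    subject_id = ids, age = age,
    sex = ifelse(sex_male == 1, "M", "F"),
    education = education,
    sphere_r = sphere_r, cyl_r = cyl_r,
    sphere_l = sphere_l, cyl_l = cyl_l,
    exclusion_flags = "", stringsAsFactors = FALSE)

  genotypes <- genotype_matrix(ids, panel$variant_id, dosage)
  truth <- list(panel = as.data.frame(panel),
                panel_spec = NULL,
                cohort_spec = unclass(spec),
                grs = grs, education = education, noise_free_se =
                  spec$intercept + spec$slopes_by_education[education + 1] * grs)
  structure(list(genotypes = genotypes, panel = panel,
                 phenotypes = phenotypes, truth = truth),
            class = "generated_cohort")
}

#' Simulate a cohort calibrated to a 3x3 odds-ratio grid
#'
#' Draws subjects into (genetic-load category x education) cells and assigns
#' case/control status at `odds = reference_odds * cell_OR`, enabling
#' strata-OR-shaped simulations without modelling refraction continuously.
#' Phenotype SE is set to a sentinel consistent with the
#' hyperopia-control scheme (-4 D cases, +4 D controls); scores are cell
#' sentinels (2.0 / 2.6 / 3.3).
#'
#' @param or_grid 3x3 numeric matrix of odds ratios, rows = genetic load
#'   (low, medium, high), columns = education (primary, intermediate,
#'   higher); the (low, primary) entry is the reference and should be 1.
#' @param ref_case_fraction Case probability in the reference cell, in
#'   (0, 1).
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @param grs_probs Marginal cell probabilities for the three load
#'   categories (default `c(0.087, 0.683, 0.230)`, the published category
#'   mix).
#' @param education_probs Marginal education probabilities (default
#'   `c(0.432, 0.388, 0.180)`).
#' @return List with `cohort` (a cohort table ready for
#'   [joint_strata_or()]) and `truth` (the generating grid and odds).
#' @export
calibrate_to_or_grid <- function(or_grid, ref_case_fraction = 0.2, n = 5000,
                                 seed = 1,
                                 grs_probs = c(0.087, 0.683, 0.230),
                                 education_probs = c(0.432, 0.388, 0.180)) {
  or_grid <- as.matrix(or_grid)
  stopifnot(all(dim(or_grid) == c(3, 3)))
  if (any(!is.finite(or_grid)) || any(or_grid <= 0))
    stop("calibration error: odds ratios must be positive and finite",
         call. = FALSE)
  if (ref_case_fraction <= 0 || ref_case_fraction >= 1)
    stop("calibration error: reference case fraction must lie in (0, 1)",
         call. = FALSE)
  ref_odds <- ref_case_fraction / (1 - ref_case_fraction)
  odds <- ref_odds * or_grid
  p_case <- odds / (1 + odds)
  if (any(p_case >= 1))
    stop("calibration error: implied case probability >= 1", call. = FALSE)

  set.seed(derive_seed(seed, 11L))
  grs_cat <- sample(c("low", "medium", "high"), n, replace = TRUE,
                    prob = grs_probs)
  edu <- sample(c("primary", "intermediate", "higher"), n, replace = TRUE,
                prob = education_probs)
  gi <- match(grs_cat, c("low", "medium", "high"))
  ei <- match(edu, c("primary", "intermediate", "higher"))
  case <- stats::rbinom(n, 1L, p_case[cbind(gi, ei)])
  age <- stats::rnorm(n, 64.9, 9.2)
  sex_male <- stats::rbinom(n, 1L, 0.43)

  se_mean <- ifelse(case == 1, -4, 4)
  score <- c(2.0, 2.6, 3.3)[gi]
  cohort <- data.frame(
    subject_id = sprintf("C%05d", seq_len(n)),
    age = age, sex_male = sex_male,
    education = factor(edu, levels = c("primary", "intermediate", "higher")),
    education_ordinal = ei - 1L,
    se_mean = se_mean,
    category = classify_refraction(se_mean),
    excluded = FALSE,
    grs_score = score,
    grs_category = factor(grs_cat, levels = c("low", "medium", "high")),
    stringsAsFactors = FALSE)
  cohort$status <- assign_case_control(cohort$se_mean,
                                       case_control_scheme("hyperopia_control"))
  list(cohort = cohort,
       truth = list(or_grid = or_grid, ref_case_fraction = ref_case_fraction,
                    p_case = p_case, n = n, seed = seed))
}

#' Write a generated cohort to plain-text fixture files
#'
#' Emits `weights.tsv` (the panel), `dosages.tsv` (subjects x variants),
#' `genotypes.vcf` (VCF 4.2, dosages in the DS FORMAT field, ALT = effect
#' allele), `phenotypes.csv`, and `truth.json`. Numeric fields are written
#' with 17 significant digits so reading the files back reproduces the
#' in-memory cohort exactly.
#'
#' @param cohort A `generated_cohort`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the file paths.
#' @export
write_fixtures <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "generated_cohort"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(weights = file.path(out_dir, "weights.tsv"),
             dosages = file.path(out_dir, "dosages.tsv"),
             vcf = file.path(out_dir, "genotypes.vcf"),
             phenotypes = file.path(out_dir, "phenotypes.csv"),
             truth = file.path(out_dir, "truth.json"))

  panel <- cohort$panel
  pw <- data.frame(variant_id = panel$variant_id,
                   effect_allele = panel$effect_allele,
                   other_allele = panel$other_allele,
                   beta = format_exact(panel$beta))
  if (!is.null(panel$freq)) pw$freq <- format_exact(panel$freq)
  utils::write.table(pw, paths["weights"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  gm <- cohort$genotypes
  dos <- as.data.frame(gm$dosage)
  names(dos) <- gm$variant_ids
  utils::write.table(cbind(subject_id = gm$subject_ids, dos),
                     paths["dosages"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  write_vcf_dosages(gm, panel, paths["vcf"])

  ph <- cohort$phenotypes
  for (col in c("age", "sphere_r", "cyl_r", "sphere_l", "cyl_l"))
    ph[[col]] <- format_exact(ph[[col]])
  utils::write.csv(ph, paths["phenotypes"], row.names = FALSE, quote = FALSE)

  truth <- cohort$truth
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

# minimal VCF 4.2 writer: one record per panel variant, REF = other allele,
# ALT = effect allele, dosages in the per-sample DS field
write_vcf_dosages <- function(gm, panel, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=myopiaGxE synthetic cohort generator",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Effect allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$subject_ids), collapse = "\t"))
  records <- vapply(seq_len(nrow(panel)), function(i) {
    ds <- vapply(gm$dosage[, i], function(v) sprintf("%.17g", v), character(1))
    paste(c("1", as.character(i * 1000), panel$variant_id[i],
            panel$other_allele[i], panel$effect_allele[i], ".", "PASS", ".",
            "DS", ds), collapse = "\t")
  }, character(1))
  writeLines(c(header, records), path)
}
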