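# Readers for the weight table, genotype dosages (VCF or TSV) and the
# phenotype CSV, plus the end-to-end pipeline that produces the cohort
# characteristics, adjusted associations, strata odds ratios and synergy
# index as TSV reports with a full-precision JSON sidecar.

#' Construct a genotype dosage matrix
#'
#' @param subject_ids,variant_ids Ordered identifier vectors.
#' @param dosage Subjects x variants numeric matrix of effect-allele
#'   dosages in \[0, 2\] (fractional permitted for imputed data). No
#'   missing cells are allowed once constructed.
#' @return A `genotype_matrix`.
#' @export
genotype_matrix <- function(subject_ids, variant_ids, dosage) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  stopifnot(nrow(dosage) == length(subject_ids),
            ncol(dosage) == length(variant_ids))
  if (anyNA(dosage))
    stop("genotype matrix contains missing dosages; use impute_mean in the ",
         "reader or fix the input", call. = FALSE)
  if (any(dosage < 0 | dosage > 2))
    stop("range error: dosages outside [0, 2]", call. = FALSE)
  dimnames(dosage) <- list(as.character(subject_ids),
                           as.character(variant_ids))
  structure(list(subject_ids = as.character(subject_ids),
                 variant_ids = as.character(variant_ids),
                 dosage = dosage),
            class = "genotype_matrix")
}

#' Read a SNP weight table
#'
#' Tab-separated with header columns `variant_id`, `effect_allele`,
#' `other_allele`, `beta` (optionally `freq`). Rows with negative betas are
#' re-oriented (alleles swapped, beta negated) so stored weights are
#' positive; duplicate variants and zero betas are errors.
#'
#' @param path Path to the TSV file.
#' @return A [snp_panel()].
#' @export
read_weights <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "effect_allele", "other_allele", "beta")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("weight table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  snp_panel(df$variant_id, df$effect_allele, df$other_allele, df$beta,
            freq = df$freq)
}

#' Read genotype dosages aligned to a weight panel
#'
#' Accepts either a dosage-matrix TSV (first column `subject_id`, one
#' column per variant) or a VCF. For VCF input the per-sample `DS` FORMAT
#' field is preferred, falling back to hard-call `GT` counted as 0/1/2;
#' the record's ALT allele is matched against the panel's effect allele,
#' and when the effect allele is REF the dosage is flipped to `2 - d`.
#' A variant whose alleles match the panel neither way is a hard error
#' (no strand heuristics). All panel variants must be present; the output
#' columns follow panel order.
#'
#' @param path Path to a `.vcf` file or a dosage TSV.
#' @param panel A [snp_panel()].
#' @param impute_mean Substitute `2 * freq` for missing dosages instead of
#'   failing (requires a `freq` column in the panel); default `FALSE`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, panel, impute_mean = FALSE) {
  stopifnot(inherits(panel, "snp_panel"))
  if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path, ignore.case = TRUE)) {
    read_genotypes_vcf(path, panel, impute_mean)
  } else {
    read_genotypes_tsv(path, panel, impute_mean)
  }
}

fill_missing <- function(dosage, panel, impute_mean) {
  if (anyNA(dosage)) {
    if (!impute_mean)
      stop("missing dosages present; pass impute_mean = TRUE to substitute ",
           "2 * effect-allele frequency", call. = FALSE)
    if (is.null(panel$freq))
      stop("impute_mean requires allele frequencies in the panel",
           call. = FALSE)
    for (j in seq_len(ncol(dosage))) {
      miss <- is.na(dosage[, j])
      dosage[miss, j] <- 2 * panel$freq[j]
    }
  }
  dosage
}

read_genotypes_tsv <- function(path, panel, impute_mean) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!"subject_id" %in% names(df))
    stop("dosage TSV needs a subject_id column", call. = FALSE)
  absent <- setdiff(panel$variant_id, names(df))
  if (length(absent))
    stop("missing panel variant(s) in dosage file: ",
         paste(absent, collapse = ", "), call. = FALSE)
  dosage <- as.matrix(df[, panel$variant_id, drop = FALSE])
  storage.mode(dosage) <- "double"
  dosage <- fill_missing(dosage, panel, impute_mean)
  genotype_matrix(df$subject_id, panel$variant_id, dosage)
}

read_genotypes_vcf <- function(path, panel, impute_mean) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCF requires the VariantAnnotation package", call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path)
  ids <- rownames(vcf)
  absent <- setdiff(panel$variant_id, ids)
  if (length(absent))
    stop("missing panel variant(s) in VCF: ",
         paste(absent, collapse = ", "), call. = FALSE)
  idx <- match(panel$variant_id, ids)
  ref <- as.character(VariantAnnotation::ref(vcf))[idx]
  alt <- vapply(as.list(VariantAnnotation::alt(vcf))[idx],
                function(a) paste(as.character(a), collapse = ","),
                character(1))
  gen <- VariantAnnotation::geno(vcf)
  if ("DS" %in% names(gen)) {
    d <- gen$DS[idx, , drop = FALSE]
    storage.mode(d) <- "double"
  } else if ("GT" %in% names(gen)) {
    gt <- gen$GT[idx, , drop = FALSE]
    d <- apply(gt, c(1, 2), function(g) {
      if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
      sum(strsplit(g, "[/|]")[[1]] == "1")
    })
  } else {
    stop("VCF carries neither DS nor GT genotype fields", call. = FALSE)
  }
  # d counts ALT alleles; orient every variant onto the effect allele
  dosage <- matrix(NA_real_, nrow = ncol(d), ncol = nrow(panel))
  for (i in seq_len(nrow(panel))) {
    if (alt[i] == panel$effect_allele[i] && ref[i] == panel$other_allele[i]) {
      dosage[, i] <- d[i, ]
    } else if (ref[i] == panel$effect_allele[i] &&
               alt[i] == panel$other_allele[i]) {
      dosage[, i] <- 2 - d[i, ]
    } else {
      stop("allele mismatch for ", panel$variant_id[i], ": VCF ", ref[i],
           "/", alt[i], " vs panel ", panel$effect_allele[i], "/",
           panel$other_allele[i], " (strand flips are not attempted)",
           call. = FALSE)
    }
  }
  dosage <- fill_missing(dosage, panel, impute_mean)
  genotype_matrix(colnames(d), panel$variant_id, dosage)
}

#' Read and phenotype a subject CSV
#'
#' Expects columns `subject_id`, `age`, `sex` (M/F), `education`
#' (0 = primary, 1 = intermediate, 2 = higher), `sphere_r`, `cyl_r`,
#' `sphere_l`, `cyl_l` (empty cell = unavailable eye) and
#' `exclusion_flags` (semicolon-separated, possibly empty). Spherical
#' equivalents, the mean SE with single-eye fallback, refraction category
#' and exclusion decisions are computed on read.
#'
#' @param path Path to the CSV file (UTF-8, decimal point).
#' @return A cohort table data.frame (one row per subject, excluded
#'   subjects carried with `excluded = TRUE`).
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  as_cohort_table(df)
}

#' Build a cohort table from raw phenotype rows (and optional risk scores)
#'
#' @param phenotypes data.frame in the phenotype-CSV layout (see
#'   [read_phenotypes()]).
#' @param grs Optional per-subject risk score data.frame from
#'   [compute_grs()]; merged on `subject_id`.
#' @param scheme Optional [case_control_scheme()] (or its name); when given,
#'   a `status` column is added.
#' @return data.frame with columns `subject_id`, `age`, `sex_male`,
#'   `education` (factor), `education_ordinal`, `se_right`, `se_left`,
#'   `se_mean`, `category`, `excluded`, `exclusion_reason`, plus
#'   `grs_score`/`grs_category`/`n_risk_alleles` and `status` when
#'   requested.
#' @export
as_cohort_table <- function(phenotypes, grs = NULL, scheme = NULL) {
  df <- phenotypes
  need <- c("subject_id", "age", "sex", "education", "sphere_r", "cyl_r",
            "sphere_l", "cyl_l")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("phenotype table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad_sex <- which(!df$sex %in% c("M", "F"))
  if (length(bad_sex))
    stop("unknown sex code at data row ", bad_sex[1], ": '",
         df$sex[bad_sex[1]], "'", call. = FALSE)
  bad_edu <- which(!df$education %in% 0:2)
  if (length(bad_edu))
    stop("unknown education code at data row ", bad_edu[1], ": '",
         df$education[bad_edu[1]], "'", call. = FALSE)

  eye_se <- function(sphere, cyl) {
    out <- rep(NA_real_, length(sphere))
    ok <- !is.na(sphere)
    cyl[ok & is.na(cyl)] <- 0
    out[ok] <- spherical_equivalent(sphere[ok], cyl[ok])
    out
  }
  se_right <- eye_se(df$sphere_r, df$cyl_r)
  se_left <- eye_se(df$sphere_l, df$cyl_l)
  se_mean <- mean_se(se_right, se_left)

  flags <- if ("exclusion_flags" %in% names(df)) {
    raw <- as.character(df$exclusion_flags)
    raw[is.na(raw)] <- ""  # an empty CSV cell means no flags
    lapply(strsplit(raw, ";", fixed = TRUE),
           function(x) x[!is.na(x) & nzchar(x)])
  } else {
    rep(list(character(0)), nrow(df))
  }
  exc <- apply_exclusions(flags)

  out <- data.frame(
    subject_id = as.character(df$subject_id),
    age = as.numeric(df$age),
    sex_male = as.integer(df$sex == "M"),
    education = factor(c("primary", "intermediate", "higher")[df$education + 1],
                       levels = c("primary", "intermediate", "higher")),
    education_ordinal = as.integer(df$education),
    se_right = se_right, se_left = se_left, se_mean = se_mean,
    category = classify_refraction(se_mean),
    excluded = exc$excluded, exclusion_reason = exc$reason,
    stringsAsFactors = FALSE)
  out$se_mean[out$excluded] <- NA_real_
  out$category[out$excluded] <- NA

  if (!is.null(grs)) {
    idx <- match(out$subject_id, grs$subject_id)
    if (anyNA(idx))
      stop("risk scores missing for subject(s): ",
           paste(utils::head(out$subject_id[is.na(idx)], 5), collapse = ", "),
           call. = FALSE)
    out$grs_score <- grs$score[idx]
    out$grs_category <- grs$category[idx]
    out$n_risk_alleles <- grs$n_risk_alleles[idx]
  }
  if (!is.null(scheme)) {
    if (is.character(scheme)) scheme <- case_control_scheme(scheme)
    out$status <- assign_case_control(out$se_mean, scheme)
  }
  out
}

#' Run the full gene-by-education analysis pipeline
#'
#' Executes phenotype -> risk score -> association -> interaction on the
#' given input files and writes a report bundle: `table1.tsv` (cohort
#' characteristics), `table2.tsv` (adjusted associations of education and
#' the risk score with refraction and with myopia), `table3.tsv` (joint
#' strata odds ratios, per-row trend p, synergy index), `fig1_data.tsv`
#' (mean refraction per load category per education plus stratified
#' slopes), `report.json` (every value at full precision) and
#' `run_log.txt` (per-stage subject counts). ORs and the SI are rounded to
#' one decimal in the TSVs, betas to two; the JSON sidecar is unrounded.
#'
#' @param config Named list (or path to a JSON file) with entries
#'   `weights`, `genotypes`, `phenotypes` (paths), `out_dir`, and optional
#'   `scheme` (default `"hyperopia_control"`), `cut_points` (default
#'   `c(2.25, 3)`), `collapse` (default `"corners"`), `covariates`
#'   (default `c("age", "sex_male")`), `per_sd` (default `FALSE`),
#'   `impute_mean` (default `FALSE`), `seed` (logged only; the pipeline
#'   itself is deterministic).
#' @return Invisibly, the `report_bundle` list that `report.json`
#'   serialises.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  defaults <- list(scheme = "hyperopia_control", cut_points = c(2.25, 3),
                   collapse = "corners", covariates = c("age", "sex_male"),
                   per_sd = FALSE, impute_mean = FALSE, seed = NA)
  config <- utils::modifyList(defaults, config)
  for (f in c("weights", "genotypes", "phenotypes", "out_dir"))
    if (is.null(config[[f]]))
      stop("pipeline config lacks '", f, "'", call. = FALSE)
  for (f in c("weights", "genotypes", "phenotypes"))
    if (!file.exists(config[[f]]))
      stop("pipeline input not found: ", config[[f]], call. = FALSE)
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)

  written <- character(0)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  stage <- "setup"
  on_error <- function(e) {
    unlink(written)  # never leave partial reports behind
    stop("pipeline stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  }

  bundle <- tryCatch({
    note("myopiaGxE %s; seed=%s; scheme=%s; collapse=%s",
         as.character(utils::packageVersion("myopiaGxE")),
         as.character(config$seed), config$scheme, config$collapse)

    stage <- "read_inputs"
    panel <- read_weights(config$weights)
    genotypes <- read_genotypes(config$genotypes, panel,
                                impute_mean = isTRUE(config$impute_mean))
    phenotypes <- utils::read.csv(config$phenotypes, stringsAsFactors = FALSE,
                                  colClasses = c(subject_id = "character"))
    note("read: %d variants, %d genotyped subjects, %d phenotype rows",
         nrow(panel), length(genotypes$subject_ids), nrow(phenotypes))

    stage <- "phenotype"
    scheme <- case_control_scheme(config$scheme)
    grs <- compute_grs(genotypes, panel, cut_points = config$cut_points)
    cohort <- as_cohort_table(phenotypes, grs = grs, scheme = scheme)
    n_input <- nrow(cohort)
    n_excluded <- sum(cohort$excluded)
    n_missing <- sum(!cohort$excluded & is.na(cohort$se_mean))
    n_case <- sum(cohort$status == "case", na.rm = TRUE)
    n_control <- sum(cohort$status == "control", na.rm = TRUE)
    n_neither <- sum(!cohort$excluded & !is.na(cohort$se_mean) &
                       cohort$status == "neither", na.rm = TRUE)
    note("phenotype: n_input=%d n_excluded=%d n_missing_se=%d n_cases=%d n_controls=%d n_neither=%d",
         n_input, n_excluded, n_missing, n_case, n_control, n_neither)
    stopifnot(n_input == n_excluded + n_missing + n_case + n_control + n_neither)

    stage <- "table1"
    table1 <- cohort_characteristics(cohort)

    stage <- "association"
    table2 <- table2_associations(cohort, scheme, per_sd = isTRUE(config$per_sd))
    slopes <- stratified_slopes(cohort)
    note("association: pooled slope homogeneity F(%d,%d)=%.3f p=%.3g",
         slopes$df[1], slopes$df[2], slopes$f_statistic, slopes$p_value)

    stage <- "strata_or"
    strata <- joint_strata_or(cohort, scheme, covariates = config$covariates)
    trend <- vapply(c("low", "medium", "high"), function(g)
      tryCatch(trend_test(cohort, g, scheme, covariates = config$covariates),
               error = function(e) NA_real_), numeric(1))

    stage <- "interaction"
    si <- synergy_index(strata, mode = config$collapse)
    note("interaction: SI=%.4f estimable=%s (mode=%s)",
         si$si, si$estimable, config$collapse)

    stage <- "fig1"
    fig1 <- fig1_means(cohort)

    stage <- "write_reports"
    bundle <- list(
      config = config[c("scheme", "cut_points", "collapse", "covariates",
                        "per_sd", "seed")],
      counts = list(n_input = n_input, n_excluded = n_excluded,
                    n_missing_se = n_missing, n_cases = n_case,
                    n_controls = n_control, n_neither = n_neither),
      table1 = table1, table2 = table2,
      slopes = list(per_stratum = slopes$slopes,
                    f_statistic = slopes$f_statistic, df = slopes$df,
                    p_value = slopes$p_value),
      table3 = list(cells = strata$cells[, setdiff(names(strata$cells), "term")],
                    trend_p = as.list(trend)),
      synergy = list(si = si$si, theta = si$theta, se_theta = si$se_theta,
                     ci = c(si$ci_low, si$ci_high), method = si$method,
                     collapse_mode = si$collapse_mode,
                     corner_ors = as.list(si$corner_ors),
                     estimable = si$estimable),
      fig1_data = fig1)
    written <- write_report_bundle(bundle, slopes, strata, trend, si, fig1,
                                   config$out_dir)
    writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
    bundle
  }, error = on_error)
  invisible(bundle)
}

# Table-1-style cohort characteristics
cohort_characteristics <- function(cohort) {
  ok <- !cohort$excluded & !is.na(cohort$se_mean)
  cc <- cohort[ok, , drop = FALSE]
  list(
    n = nrow(cc),
    pct_male = 100 * mean(cc$sex_male),
    age_mean = mean(cc$age), age_sd = stats::sd(cc$age),
    se_mean = mean(cc$se_mean), se_sd = stats::sd(cc$se_mean),
    refraction_categories = as.list(table(cc$category)),
    education = as.list(table(cc$education)),
    grs_mean = if (!is.null(cc$grs_score)) mean(cc$grs_score) else NA,
    grs_sd = if (!is.null(cc$grs_score)) stats::sd(cc$grs_score) else NA,
    grs_categories = if (!is.null(cc$grs_category))
      as.list(table(cc$grs_category)) else NULL,
    risk_alleles_by_grs = if (!is.null(cc$n_risk_alleles))
      lapply(split(cc$n_risk_alleles, cc$grs_category), function(x)
        list(mean = mean(x), sd = stats::sd(x))) else NULL)
}

# Table-2-style adjusted associations for both exposures
table2_associations <- function(cohort, scheme, per_sd = FALSE) {
  specs <- list(
    education = list(exposure = "education_ordinal",
                     covariates = c("age", "sex_male", "grs_score")),
    grs = list(exposure = "grs_score",
               covariates = c("age", "sex_male", "education_ordinal")))
  lapply(specs, function(s) {
    lin <- fit_linear_refraction(cohort, s$exposure, s$covariates)
    b <- lin$coefficients[s$exposure]
    se <- sqrt(lin$covariance[s$exposure, s$exposure])
    logi <- fit_myopia_logistic(cohort, s$exposure, s$covariates, scheme,
                                per_sd = per_sd)
    list(exposure = s$exposure, n_linear = lin$n_used,
         beta = unname(b), se = unname(se),
         p_linear = unname(2 * stats::pnorm(-abs(b / se))),
         n_logistic = logi$n, or = logi$or,
         ci_low = logi$ci_low, ci_high = logi$ci_high, p_logistic = logi$p)
  })
}

# mean refraction per genetic-load category per education stratum
fig1_means <- function(cohort) {
  ok <- !cohort$excluded & !is.na(cohort$se_mean) &
    !is.na(cohort$grs_category)
  cc <- cohort[ok, , drop = FALSE]
  agg <- stats::aggregate(se_mean ~ grs_category + education, data = cc,
                          FUN = mean)
  cnt <- stats::aggregate(se_mean ~ grs_category + education, data = cc,
                          FUN = length)
  agg$n <- cnt$se_mean
  names(agg)[names(agg) == "se_mean"] <- "mean_se"
  agg
}

round_to <- function(x, digits) ifelse(is.na(x), NA, round(x, digits))

write_report_bundle <- function(bundle, slopes, strata, trend, si, fig1,
                                out_dir) {
  paths <- c(json = file.path(out_dir, "report.json"),
             table1 = file.path(out_dir, "table1.tsv"),
             table2 = file.path(out_dir, "table2.tsv"),
             table3 = file.path(out_dir, "table3.tsv"),
             fig1 = file.path(out_dir, "fig1_data.tsv"))
  jsonlite::write_json(bundle, paths["json"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  t1 <- bundle$table1
  t1_rows <- data.frame(
    characteristic = c("n", "pct_male", "age_mean", "age_sd", "se_mean",
                       "se_sd", "grs_mean", "grs_sd"),
    value = c(t1$n, round_to(t1$pct_male, 1), round_to(t1$age_mean, 1),
              round_to(t1$age_sd, 1), round_to(t1$se_mean, 2),
              round_to(t1$se_sd, 2), round_to(t1$grs_mean, 2),
              round_to(t1$grs_sd, 2)))
  utils::write.table(t1_rows, paths["table1"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  t2 <- do.call(rbind, lapply(bundle$table2, function(r) data.frame(
    exposure = r$exposure, n_linear = r$n_linear,
    beta = round_to(r$beta, 2), se = round_to(r$se, 2),
    p_linear = signif(r$p_linear, 2), n_logistic = r$n_logistic,
    or = round_to(r$or, 1), ci_low = round_to(r$ci_low, 1),
    ci_high = round_to(r$ci_high, 1), p_logistic = signif(r$p_logistic, 2))))
  utils::write.table(t2, paths["table2"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  t3 <- strata$cells
  t3$or <- round_to(t3$or, 1)
  t3$ci_low <- round_to(t3$ci_low, 1)
  t3$ci_high <- round_to(t3$ci_high, 1)
  t3$p <- signif(t3$p, 2)
  t3$trend_p <- signif(trend[as.character(t3$grs_category)], 2)
  t3$term <- NULL
  si_line <- if (si$estimable)
    sprintf("# SI %.1f; 95 %% CI %.1f-%.1f (%s)", si$si, si$ci_low,
            si$ci_high, si$collapse_mode)
  else "# SI inestimable"
  con <- file(paths["table3"], "w")
  writeLines(si_line, con)
  utils::write.table(t3, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)

  f1 <- fig1
  f1$mean_se <- round_to(f1$mean_se, 2)
  utils::write.table(f1, paths["fig1"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}
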