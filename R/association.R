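# Linear and logistic association models: covariate-adjusted effects,
# education-stratified slopes with a homogeneity F test, the 3x3 joint
# genetic-load x education odds-ratio grid, and per-stratum trend tests.

Z95 <- 1.959964  # two-sided 95% normal quantile, fixed for reproducibility

new_gxe_fit <- function(coefficients, covariance, n_used, converged,
                        model_kind, separation = FALSE, model = NULL) {
  structure(list(coefficients = coefficients, covariance = covariance,
                 n_used = n_used, converged = converged,
                 model_kind = model_kind, separation = separation,
                 model = model),
            class = "gxe_fit")
}

#' @export
print.gxe_fit <- function(x, ...) {
  cat(sprintf("<gxe_fit: %s model, n = %d%s%s>\n", x$model_kind, x$n_used,
              if (!x$converged) ", NOT converged" else "",
              if (x$separation) ", separation detected" else ""))
  se <- sqrt(pmax(diag(x$covariance), 0))
  print(data.frame(estimate = x$coefficients, se = se,
                   row.names = names(x$coefficients)))
  invisible(x)
}

# rows usable for modelling: not excluded, complete on the given variables
model_rows <- function(cohort, vars) {
  keep <- if ("excluded" %in% names(cohort)) !cohort$excluded else TRUE
  keep & stats::complete.cases(cohort[, vars, drop = FALSE])
}

# detect (quasi-)separation in a fitted binomial glm
detect_separation <- function(fit) {
  eps <- 1e-8
  probs <- stats::fitted(fit)
  degenerate <- probs > 1 - eps | probs < eps
  any(degenerate) && any(abs(stats::coef(fit)[-1]) > 12, na.rm = TRUE)
}

#' Covariate-adjusted linear model for refractive error
#'
#' Least-squares fit of mean spherical equivalent on a single exposure plus
#' covariates, the model behind per-cohort adjusted beta estimates (diopters
#' per exposure unit). The exposure coefficient keeps the exposure's name.
#'
#' @param cohort A cohort table (see [as_cohort_table()]) with columns
#'   `se_mean`, the exposure, and the covariates. Excluded subjects and rows
#'   with missing values are dropped.
#' @param exposure `"grs_score"` or `"education_ordinal"` (or any numeric
#'   column present in `cohort`).
#' @param covariates Character vector of adjustment columns.
#' @return A `gxe_fit` with coefficients, their covariance, `n_used`,
#'   `converged` and `model_kind = "linear"`.
#' @export
fit_linear_refraction <- function(cohort,
                                  exposure = c("grs_score", "education_ordinal"),
                                  covariates = c("age", "sex_male")) {
  exposure <- if (length(exposure) > 1) match.arg(exposure) else exposure
  vars <- c("se_mean", exposure, covariates)
  missing_cols <- setdiff(vars, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  dat <- cohort[model_rows(cohort, vars), vars, drop = FALSE]
  if (nrow(dat) < 10)
    stop("fewer than 10 complete rows available for the linear model",
         call. = FALSE)
  fml <- stats::reformulate(c(exposure, covariates), response = "se_mean")
  fit <- stats::lm(fml, data = dat)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("singular design: collinear terms ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  V <- stats::vcov(fit)
  # an exactly-constant outcome gives 0 residual variance, not NaN
  if (all(abs(stats::residuals(fit)) < 1e-12)) V[] <- 0
  new_gxe_fit(cf, V, nrow(dat), converged = TRUE, model_kind = "linear",
              model = fit)
}

#' Education-stratified genetic-score slopes and homogeneity test
#'
#' Fits, per education stratum, the least-squares slope of mean spherical
#' equivalent on the genetic risk score, and tests whether the three slopes
#' differ with the F test of the score-by-education interaction block
#' (2 numerator df) in the pooled model.
#'
#' @param cohort Cohort table with `se_mean`, `grs_score` and `education`
#'   (factor: primary, intermediate, higher).
#' @param covariates Optional extra adjustment columns used in both the
#'   per-stratum and pooled fits (default none: crude slopes).
#' @return A `slope_panel`: list with `slopes` (data.frame education, beta,
#'   se, n), `f_statistic`, `df`, `p_value`.
#' @export
stratified_slopes <- function(cohort, covariates = character(0)) {
  vars <- c("se_mean", "grs_score", "education", covariates)
  dat <- cohort[model_rows(cohort, vars), vars, drop = FALSE]
  dat$education <- as.factor(dat$education)
  levs <- levels(dat$education)
  counts <- table(dat$education)
  if (any(counts == 0))
    stop("stratification error: empty education stratum (",
         paste(levs[counts == 0], collapse = ", "), ")", call. = FALSE)
  per <- lapply(levs, function(lv) {
    sub <- dat[dat$education == lv, , drop = FALSE]
    if (length(unique(sub$grs_score)) < 3)
      stop("stratification error: stratum ", lv,
           " has fewer than 3 distinct score values", call. = FALSE)
    f <- stats::lm(stats::reformulate(c("grs_score", covariates), "se_mean"),
                   data = sub)
    data.frame(education = lv,
               beta = unname(stats::coef(f)["grs_score"]),
               se = sqrt(stats::vcov(f)["grs_score", "grs_score"]),
               n = nrow(sub), stringsAsFactors = FALSE)
  })
  slopes <- do.call(rbind, per)
  slopes$education <- factor(slopes$education, levels = levs)
  base <- stats::lm(stats::reformulate(c("grs_score", "education", covariates),
                                       "se_mean"), data = dat)
  full <- stats::lm(stats::reformulate(
    c("grs_score", "education", "grs_score:education", covariates),
    "se_mean"), data = dat)
  an <- stats::anova(base, full)
  structure(list(slopes = slopes,
                 f_statistic = an$F[2],
                 df = c(an$Df[2], an$Res.Df[2]),
                 p_value = an$`Pr(>F)`[2]),
            class = "slope_panel")
}

#' @export
print.slope_panel <- function(x, ...) {
  cat("Education-stratified slopes of refraction on the genetic risk score\n")
  print(x$slopes, row.names = FALSE)
  cat(sprintf("Homogeneity: F(%d, %d) = %.3f, p = %.3g\n",
              x$df[1], x$df[2], x$f_statistic, x$p_value))
  invisible(x)
}

or_result <- function(or, ci_low, ci_high, n, p, fit = NULL,
                      exposure = NULL, estimable = TRUE) {
  structure(list(or = or, ci_low = ci_low, ci_high = ci_high, n = n, p = p,
                 fit = fit, exposure = exposure, estimable = estimable),
            class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  if (!x$estimable) {
    cat("<or_result: inestimable>\n")
  } else {
    cat(sprintf("OR %.2f (95%% CI %.2f-%.2f), n = %d, p = %.3g\n",
                x$or, x$ci_low, x$ci_high, x$n, x$p))
  }
  invisible(x)
}

#' Logistic model for myopia risk
#'
#' Case/control logistic regression of moderate-to-high myopia (spherical
#' equivalent <= -3 D) against the scheme's controls, returning the odds
#' ratio per one-unit exposure increment with a Wald 95% CI. Subjects whose
#' refraction is neither case nor control under the scheme are dropped.
#'
#' @param cohort Cohort table; `status` is computed from `se_mean` under
#'   `scheme` if not already present.
#' @param exposure Exposure column name (e.g. `"grs_score"`,
#'   `"education_ordinal"`); may also be logical/binary.
#' @param covariates Adjustment columns (default age and sex).
#' @param scheme A [case_control_scheme()] or its name.
#' @param per_sd Report the OR per standard deviation of the exposure
#'   instead of per unit (default `FALSE`).
#' @return An `or_result` (OR, 95% CI, n, p) carrying the underlying
#'   `gxe_fit`. Under complete separation `converged` is `FALSE`, the
#'   separation flag is set, and no OR is reported.
#' @export
fit_myopia_logistic <- function(cohort, exposure,
                                covariates = c("age", "sex_male"),
                                scheme = case_control_scheme(),
                                per_sd = FALSE) {
  if (is.character(scheme)) scheme <- case_control_scheme(scheme)
  if (!"status" %in% names(cohort))
    cohort$status <- assign_case_control(cohort$se_mean, scheme)
  vars <- c("status", exposure, covariates)
  dat <- cohort[model_rows(cohort, vars) & cohort$status != "neither",
                vars, drop = FALSE]
  n_case <- sum(dat$status == "case")
  if (n_case < 1 || nrow(dat) - n_case < 1)
    stop("need at least one case and one control", call. = FALSE)
  dat$case <- as.integer(dat$status == "case")
  if (per_sd) dat[[exposure]] <- dat[[exposure]] / stats::sd(dat[[exposure]])
  fml <- stats::reformulate(c(exposure, covariates), response = "case")
  fit <- suppressWarnings(stats::glm(fml, data = dat, family = stats::binomial(),
                                     control = stats::glm.control(epsilon = 1e-12, maxit = 50)))
  sep <- detect_separation(fit)
  gf <- new_gxe_fit(stats::coef(fit), stats::vcov(fit), nrow(dat),
                    converged = fit$converged && !sep,
                    model_kind = "logistic", separation = sep, model = fit)
  term <- grep(paste0("^", exposure), names(stats::coef(fit)), value = TRUE)[1]
  if (sep || !fit$converged)
    return(or_result(NA_real_, NA_real_, NA_real_, nrow(dat), NA_real_,
                     fit = gf, exposure = exposure, estimable = FALSE))
  b <- stats::coef(fit)[term]
  se <- sqrt(stats::vcov(fit)[term, term])
  or_result(exp(unname(b)), exp(unname(b - Z95 * se)), exp(unname(b + Z95 * se)),
            nrow(dat), unname(2 * stats::pnorm(-abs(b / se))),
            fit = gf, exposure = exposure)
}

#' Joint genetic-load by education strata odds ratios
#'
#' One logistic fit of case status on eight cell indicators (all
#' combinations of genetic-load category and education except the
#' low-load/primary-education reference) plus covariates. Each cell's OR is
#' the exponentiated indicator coefficient; the reference cell's OR is 1 by
#' construction. Empty cells are flagged inestimable rather than aborting,
#' as is per-cell separation.
#'
#' @param cohort Cohort table with `grs_category`, `education`, `se_mean`
#'   (or `status`), and covariates.
#' @param scheme A [case_control_scheme()] or its name.
#' @param covariates Adjustment columns (default age and sex).
#' @return A `strata_or_table`: `cells` data.frame (9 rows: grs_category,
#'   education, term, n, n_cases, or, ci_low, ci_high, p, estimable), the
#'   joint `fit`, the model `data`, `scheme` and `covariates`.
#' @export
joint_strata_or <- function(cohort, scheme = case_control_scheme(),
                            covariates = c("age", "sex_male")) {
  if (is.character(scheme)) scheme <- case_control_scheme(scheme)
  if (!"status" %in% names(cohort))
    cohort$status <- assign_case_control(cohort$se_mean, scheme)
  vars <- c("status", "grs_category", "education", covariates)
  dat <- cohort[model_rows(cohort, vars) & cohort$status != "neither",
                vars, drop = FALSE]
  dat$case <- as.integer(dat$status == "case")
  grs_levels <- c("low", "medium", "high")
  edu_levels <- c("primary", "intermediate", "higher")
  dat$grs_category <- factor(dat$grs_category, levels = grs_levels)
  dat$education <- factor(dat$education, levels = edu_levels)
  dat$cell <- factor(paste(dat$grs_category, dat$education, sep = "_"),
                     levels = as.vector(outer(grs_levels, edu_levels,
                                              paste, sep = "_")))
  ref <- "low_primary"
  if (sum(dat$cell == ref & dat$case == 1, na.rm = TRUE) < 1 ||
      sum(dat$cell == ref & dat$case == 0, na.rm = TRUE) < 1)
    stop("reference cell (low genetic load, primary education) needs at ",
         "least one case and one control", call. = FALSE)
  present <- levels(dat$cell)[table(dat$cell) > 0]
  dat$cell <- factor(as.character(dat$cell), levels = present)
  dat$cell <- stats::relevel(dat$cell, ref = ref)
  fml <- stats::reformulate(c("cell", covariates), response = "case")
  fit <- suppressWarnings(stats::glm(fml, data = dat, family = stats::binomial(),
                                     control = stats::glm.control(epsilon = 1e-12, maxit = 50)))
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  gf <- new_gxe_fit(cf, V, nrow(dat), converged = fit$converged,
                    model_kind = "logistic",
                    separation = detect_separation(fit), model = fit)
  grid <- expand.grid(grs_category = grs_levels, education = edu_levels,
                      stringsAsFactors = FALSE)
  cells <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    lv <- paste(grid$grs_category[i], grid$education[i], sep = "_")
    term <- paste0("cell", lv)
    in_cell <- dat$cell == lv
    n <- sum(in_cell)
    n_cases <- sum(dat$case[in_cell])
    if (lv == ref) {
      return(data.frame(grid[i, ], term = NA_character_, n = n,
                        n_cases = n_cases, or = 1, ci_low = 1, ci_high = 1,
                        p = NA_real_, estimable = TRUE,
                        stringsAsFactors = FALSE))
    }
    if (!term %in% names(cf) || is.na(cf[term])) {
      return(data.frame(grid[i, ], term = term, n = n, n_cases = n_cases,
                        or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        p = NA_real_, estimable = FALSE,
                        stringsAsFactors = FALSE))
    }
    b <- cf[term]; se <- sqrt(V[term, term])
    cell_sep <- abs(b) > 12 || se > 100 ||
      n_cases == 0 || n_cases == n  # all-case / all-control cell
    data.frame(grid[i, ], term = term, n = n, n_cases = n_cases,
               or = exp(unname(b)),
               ci_low = exp(unname(b - Z95 * se)),
               ci_high = exp(unname(b + Z95 * se)),
               p = unname(2 * stats::pnorm(-abs(b / se))),
               estimable = !cell_sep, stringsAsFactors = FALSE)
  }))
  cells$grs_category <- factor(cells$grs_category, levels = grs_levels)
  cells$education <- factor(cells$education, levels = edu_levels)
  structure(list(cells = cells, fit = gf, data = dat, scheme = scheme,
                 covariates = covariates),
            class = "strata_or_table")
}

#' @export
print.strata_or_table <- function(x, ...) {
  cat(sprintf("Myopia odds ratios by genetic load and education (%s; adjusted: %s)\n",
              x$scheme$name, paste(x$covariates, collapse = ", ")))
  df <- x$cells
  df$or_ci <- ifelse(!df$estimable, "inestimable",
                     ifelse(is.na(df$p), "1.0 (reference)",
                            sprintf("%.1f (%.1f-%.1f)", df$or, df$ci_low,
                                    df$ci_high)))
  print(df[, c("grs_category", "education", "n", "or_ci")], row.names = FALSE)
  invisible(x)
}

#' Trend test for education within a genetic-load stratum
#'
#' Wald p-value of the ordinal education coefficient (0 = primary,
#' 1 = intermediate, 2 = higher) in a logistic case/control fit restricted
#' to one genetic-load category, adjusted for covariates.
#'
#' @param cohort Cohort table.
#' @param within Genetic-load category: `"low"`, `"medium"` or `"high"`.
#' @param scheme A [case_control_scheme()] or its name.
#' @param covariates Adjustment columns (default age and sex).
#' @return Two-sided p-value.
#' @export
trend_test <- function(cohort, within = c("low", "medium", "high"),
                       scheme = case_control_scheme(),
                       covariates = c("age", "sex_male")) {
  within <- match.arg(within)
  if (is.character(scheme)) scheme <- case_control_scheme(scheme)
  if (!"status" %in% names(cohort))
    cohort$status <- assign_case_control(cohort$se_mean, scheme)
  vars <- c("status", "education_ordinal", "grs_category", covariates)
  dat <- cohort[model_rows(cohort, vars) & cohort$status != "neither" &
                  cohort$grs_category == within, vars, drop = FALSE]
  if (length(unique(dat$education_ordinal)) < 2)
    stop("trend undefined: a single education level is populated in the ",
         within, " stratum", call. = FALSE)
  dat$case <- as.integer(dat$status == "case")
  fml <- stats::reformulate(c("education_ordinal", covariates), "case")
  fit <- suppressWarnings(stats::glm(fml, data = dat, family = stats::binomial(),
                                     control = stats::glm.control(epsilon = 1e-12, maxit = 50)))
  b <- stats::coef(fit)["education_ordinal"]
  se <- sqrt(stats::vcov(fit)["education_ordinal", "education_ordinal"])
  unname(2 * stats::pnorm(-abs(b / se)))
}
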