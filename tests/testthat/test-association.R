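test_that("adjusted linear model recovers a generative refraction slope", {
  panel <- generate_snp_panel(snp_panel_spec(seed = 5))
  gc <- generate_cohort(panel, cohort_spec(
    n_subjects = 9000, slopes_by_education = rep(-0.69, 3), seed = 5))
  cohort <- as_cohort_table(gc$phenotypes,
                            grs = compute_grs(gc$genotypes, panel))
  fit <- fit_linear_refraction(cohort, "grs_score",
                               c("education_ordinal", "age", "sex_male"))
  b <- fit$coefficients["grs_score"]
  se <- sqrt(fit$covariance["grs_score", "grs_score"])
  expect_lt(abs(b - (-0.69)), 2 * se)
  expect_equal(fit$model_kind, "linear")
  expect_equal(fit$n_used, 9000)

  # permuted exposure: slope indistinguishable from 0
  set.seed(99)
  cohort$grs_score <- sample(cohort$grs_score)
  fit0 <- fit_linear_refraction(cohort, "grs_score",
                                c("education_ordinal", "age", "sex_male"))
  expect_lt(abs(fit0$coefficients["grs_score"]),
            2 * sqrt(fit0$covariance["grs_score", "grs_score"]))
})

test_that("a constant outcome gives zero slope and zero variance", {
  dat <- data.frame(se_mean = 0, grs_score = runif(50), age = rnorm(50, 65),
                    sex_male = rbinom(50, 1, 0.5), excluded = FALSE)
  fit <- fit_linear_refraction(dat, "grs_score")
  expect_equal(unname(fit$coefficients["grs_score"]), 0)
  expect_equal(unname(fit$covariance["grs_score", "grs_score"]), 0)
  expect_error(fit_linear_refraction(dat[1:5, ], "grs_score"),
               "fewer than 10")
})

test_that("stratified slopes recover education-specific truth with a 2-df homogeneity test", {
  panel <- generate_snp_panel(snp_panel_spec(seed = 6))
  gc <- generate_cohort(panel, cohort_spec(n_subjects = 9194, seed = 6))
  cohort <- as_cohort_table(gc$phenotypes,
                            grs = compute_grs(gc$genotypes, panel))
  sp <- stratified_slopes(cohort)
  truth <- c(primary = -0.47, intermediate = -0.53, higher = -0.78)
  expect_equal(as.character(sp$slopes$education), names(truth))
  for (i in 1:3)
    expect_lt(abs(sp$slopes$beta[i] - truth[i]), 2 * sp$slopes$se[i])
  expect_equal(sp$df[1], 2)
  expect_equal(sum(sp$slopes$n), 9194)
})

test_that("identical data in every stratum gives a zero homogeneity F", {
  base <- data.frame(grs_score = runif(200, 1.4, 4),
                     noise = rnorm(200, 0, 0.5))
  dat <- do.call(rbind, lapply(c("primary", "intermediate", "higher"),
    function(e) data.frame(education = e, grs_score = base$grs_score,
                           se_mean = 1 - 0.5 * base$grs_score + base$noise)))
  dat$education <- factor(dat$education,
                          levels = c("primary", "intermediate", "higher"))
  dat$excluded <- FALSE
  sp <- stratified_slopes(dat)
  expect_equal(sp$f_statistic, 0, tolerance = 1e-10)
  expect_equal(sp$slopes$beta[1], sp$slopes$beta[2])
  expect_error(stratified_slopes(dat[dat$education != "higher", ]),
               "stratification error")
})

test_that("unadjusted logistic OR on a saturated 2x2 equals the cross-product", {
  cohort <- counts_to_cohort(30, 10, 10, 30)
  res <- fit_myopia_logistic(cohort, "exposure", covariates = character(0))
  expect_equal(res$or, 9.0, tolerance = 1e-7)
  expect_equal(res$n, 80)
  expect_true(res$estimable)

  # exposure independent of status: OR within 2 SE of 1
  set.seed(21)
  null <- data.frame(exposure = rbinom(4000, 1, 0.5),
                     status = factor(sample(c("case", "control"), 4000, TRUE),
                                     levels = c("case", "control", "neither")),
                     excluded = FALSE)
  r0 <- fit_myopia_logistic(null, "exposure", covariates = character(0))
  expect_lt(abs(log(r0$or)), 2 * (log(r0$ci_high) - log(r0$or)) / 1.959964)
})

test_that("logistic model recovers a generative OR of 2.7 per score unit", {
  set.seed(31)
  n <- 20000
  score <- rnorm(n, 2.7, 0.4)
  age <- rnorm(n, 65, 9)
  p <- plogis(-3.5 + log(2.7) * score + 0.002 * (age - 65))
  dat <- data.frame(
    grs_score = score, age = age,
    status = factor(ifelse(rbinom(n, 1, p) == 1, "case", "control"),
                    levels = c("case", "control", "neither")),
    excluded = FALSE)
  res <- fit_myopia_logistic(dat, "grs_score", covariates = "age")
  se_log <- (log(res$ci_high) - log(res$or)) / 1.959964
  expect_lt(abs(log(res$or) - log(2.7)), 2 * se_log)
})

test_that("complete separation is flagged, not reported as an OR", {
  sep <- data.frame(exposure = rep(c(1, 0), c(40, 40)),
                    status = factor(rep(c("case", "control"), c(40, 40)),
                                    levels = c("case", "control", "neither")),
                    excluded = FALSE)
  res <- fit_myopia_logistic(sep, "exposure", covariates = character(0))
  expect_false(res$estimable)
  expect_true(res$fit$separation)
  expect_true(is.na(res$or))
  expect_error(fit_myopia_logistic(sep[sep$status == "case", ], "exposure",
                                   covariates = character(0)),
               "at least one case")
})

test_that("joint strata ORs equal contingency cross-products on a fixed table", {
  counts <- expand.grid(grs = c("low", "medium", "high"),
                        edu = c("primary", "intermediate", "higher"),
                        stringsAsFactors = FALSE)
  set.seed(41)
  counts$cases <- c(12, 25, 40, 18, 35, 60, 15, 30, 80)
  counts$controls <- c(90, 80, 60, 70, 65, 45, 40, 30, 15)
  cohort <- grid_counts_to_cohort(counts)
  tab <- joint_strata_or(cohort, covariates = character(0))
  oracle <- grid_cross_product_ors(counts)
  for (i in seq_len(nrow(oracle))) {
    got <- tab$cells$or[tab$cells$grs_category == oracle$grs[i] &
                          tab$cells$education == oracle$edu[i]]
    expect_equal(got, oracle$or[i], tolerance = 1e-7)
  }
  ref <- tab$cells[tab$cells$grs_category == "low" &
                     tab$cells$education == "primary", ]
  expect_identical(ref$or, 1)        # reference contrast, exactly
  expect_identical(c(ref$ci_low, ref$ci_high), c(1, 1))
  expect_equal(tab$cells$n, counts$cases + counts$controls)
})

test_that("null joint strata stay within 2 SE of OR 1 and empty cells are flagged", {
  sim <- calibrate_to_or_grid(matrix(1, 3, 3), ref_case_fraction = 0.3,
                              n = 6000, seed = 13)
  tab <- joint_strata_or(sim$cohort)
  off <- tab$cells[!is.na(tab$cells$p), ]
  for (i in seq_len(nrow(off))) {
    se_log <- (log(off$ci_high[i]) - log(off$or[i])) / 1.959964
    expect_lt(abs(log(off$or[i])), 2 * se_log)
  }

  # drop one non-reference cell entirely: flagged inestimable, rest intact
  cohort2 <- sim$cohort[!(sim$cohort$grs_category == "low" &
                            sim$cohort$education == "higher"), ]
  tab2 <- joint_strata_or(cohort2)
  bad <- tab2$cells[tab2$cells$grs_category == "low" &
                      tab2$cells$education == "higher", ]
  expect_false(bad$estimable)
  expect_equal(sum(tab2$cells$estimable), 8)
})

test_that("trend test reduces to the single-dummy Wald p with two levels", {
  set.seed(51)
  n <- 800
  edu <- sample(0:1, n, replace = TRUE)
  age <- rnorm(n, 65, 9); sex <- rbinom(n, 1, 0.4)
  p <- plogis(-0.5 + 0.6 * edu)
  dat <- data.frame(
    education_ordinal = edu, age = age, sex_male = sex,
    grs_category = factor("high", levels = c("low", "medium", "high")),
    status = factor(ifelse(rbinom(n, 1, p) == 1, "case", "control"),
                    levels = c("case", "control", "neither")),
    excluded = FALSE)
  p_trend <- trend_test(dat, "high")
  fit <- glm(I(status == "case") ~ education_ordinal + age + sex_male,
             data = dat, family = binomial())
  z <- coef(summary(fit))["education_ordinal", "z value"]
  expect_equal(p_trend, 2 * pnorm(-abs(z)), tolerance = 1e-12)

  dat$education_ordinal <- 0L
  expect_error(trend_test(dat, "high"), "trend undefined")
})

test_that("trend test is powered against risk rising with education", {
  grid <- matrix(c(1, 2, 4, 1.2, 2.4, 5, 1.5, 3, 6), nrow = 3, byrow = FALSE)
  sim <- calibrate_to_or_grid(grid, ref_case_fraction = 0.2, n = 8000,
                              seed = 61)
  expect_lt(trend_test(sim$cohort, "medium"), 0.001)
})

test_that("a covariate independent of exposure and outcome leaves the OR near 1", {
  set.seed(71)
  n <- 6000
  dat <- data.frame(exposure = rbinom(n, 1, 0.5),
                    noise_cov = rnorm(n),
                    status = factor(sample(c("case", "control"), n, TRUE),
                                    levels = c("case", "control", "neither")),
                    excluded = FALSE)
  crude <- fit_myopia_logistic(dat, "exposure", covariates = character(0))
  adj <- fit_myopia_logistic(dat, "exposure", covariates = "noise_cov")
  se_log <- (log(crude$ci_high) - log(crude$or)) / 1.959964
  expect_lt(abs(log(adj$or) - log(crude$or)), 2 * se_log)
})
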