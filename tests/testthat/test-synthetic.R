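test_that("panel generation is deterministic and honours its spec", {
  spec <- snp_panel_spec(seed = 7)
  expect_identical(generate_snp_panel(spec), generate_snp_panel(spec))
  expect_equal(nrow(generate_snp_panel(spec)), 26)

  # collapsed beta range: every beta exactly the point value
  point <- generate_snp_panel(snp_panel_spec(beta_range = c(0.1, 0.1),
                                             seed = 2))
  expect_true(all(point$beta == 0.1))

  expect_error(snp_panel_spec(beta_range = c(-0.1, 0.2)), "spec error")
  expect_error(snp_panel_spec(freq_range = c(0.2, 1.1)), "spec error")
  expect_error(cohort_spec(n_subjects = 0), "spec error")
  expect_error(cohort_spec(education_probs = c(0.5, 0.5, 0.5)), "spec error")
  expect_error(cohort_spec(noise_sd = 0), "spec error")
})

test_that("dosages match their binomial expectation", {
  panel <- generate_snp_panel(snp_panel_spec(seed = 8))
  gc <- generate_cohort(panel, cohort_spec(n_subjects = 10000, seed = 8))
  counts <- risk_allele_count(gc$genotypes$dosage)
  mu <- 2 * sum(panel$freq)                      # binomial expectation
  sd_mu <- sqrt(sum(2 * panel$freq * (1 - panel$freq)) / 10000)
  expect_lt(abs(mean(counts) - mu), 4 * sd_mu)
  expect_true(all(gc$genotypes$dosage %in% 0:2))
})

test_that("cohort generation is deterministic and seed substreams are isolated", {
  panel <- generate_snp_panel(snp_panel_spec(seed = 9))
  spec <- cohort_spec(n_subjects = 500, seed = 9)
  g1 <- generate_cohort(panel, spec)
  g2 <- generate_cohort(panel, spec)
  expect_identical(g1$phenotypes, g2$phenotypes)
  expect_identical(g1$genotypes$dosage, g2$genotypes$dosage)

  # growing the cohort must not perturb the panel or the first subjects'
  # dosage stream is allowed to change, but the panel itself never does
  big <- generate_cohort(panel, cohort_spec(n_subjects = 800, seed = 9))
  expect_identical(big$panel, g1$panel)
})

test_that("default demographics match the emulated cohort structure", {
  panel <- generate_snp_panel(snp_panel_spec(seed = 10))
  gc <- generate_cohort(panel, cohort_spec(n_subjects = 9194, seed = 10))
  ph <- gc$phenotypes
  # education proportions within binomial 99% bounds of (43.2, 38.8, 18.0)%
  probs <- c(0.432, 0.388, 0.180)
  for (k in 0:2) {
    phat <- mean(ph$education == k)
    half <- 2.576 * sqrt(probs[k + 1] * (1 - probs[k + 1]) / 9194)
    expect_lt(abs(phat - probs[k + 1]), half)
  }
  expect_true(all(ph$age >= 45))
  expect_lt(abs(mean(ph$sex == "M") - 0.43), 0.02)
  # per-eye back-fill round-trips the generated spherical equivalent
  cohort <- as_cohort_table(ph)
  expect_equal(mean_se(spherical_equivalent(ph$sphere_r, ph$cyl_r),
                       spherical_equivalent(ph$sphere_l, ph$cyl_l)),
               cohort$se_mean)
})

test_that("cylinder splitting still round-trips the spherical equivalent", {
  panel <- generate_snp_panel(snp_panel_spec(seed = 12))
  gc <- generate_cohort(panel, cohort_spec(n_subjects = 300, seed = 12,
                                           cylinder_split = TRUE))
  ph <- gc$phenotypes
  expect_true(any(ph$cyl_r != 0))
  se <- mean_se(spherical_equivalent(ph$sphere_r, ph$cyl_r),
                spherical_equivalent(ph$sphere_l, ph$cyl_l))
  flat <- generate_cohort(panel, cohort_spec(n_subjects = 300, seed = 12))
  se_flat <- as_cohort_table(flat$phenotypes)$se_mean
  expect_equal(se, se_flat, tolerance = 1e-12)  # same noise substream
})

test_that("the noiseless equal-slope limit reproduces the slope exactly", {
  panel <- generate_snp_panel(snp_panel_spec(seed = 14))
  gc <- generate_cohort(panel, cohort_spec(
    n_subjects = 400, slopes_by_education = rep(-0.6, 3), noise_sd = 1e-10,
    seed = 14))
  cohort <- as_cohort_table(gc$phenotypes,
                            grs = compute_grs(gc$genotypes, panel))
  fit <- fit_linear_refraction(cohort, "grs_score", covariates = character(0))
  expect_equal(unname(fit$coefficients["grs_score"]), -0.6, tolerance = 1e-6)
})

test_that("OR-grid calibration recovers its truth and scales with n", {
  null <- calibrate_to_or_grid(matrix(1, 3, 3), ref_case_fraction = 0.25,
                               n = 5000, seed = 15)
  tab <- joint_strata_or(null$cohort)
  off <- tab$cells[!is.na(tab$cells$p), ]
  se_log <- (log(off$ci_high) - log(off$or)) / 1.959964
  # 8 simultaneous 2-SE checks: allow the expected multiplicity (P of >2
  # exceedances under a true null is below 1%)
  expect_lte(sum(abs(log(off$or)) >= 2 * se_log), 2)

  # doubling n shrinks the total squared SE roughly twofold
  tot_var <- function(n, seed) {
    sim <- calibrate_to_or_grid(combined_or_grid, ref_case_fraction = 0.2,
                                n = n, seed = seed)
    cells <- joint_strata_or(sim$cohort)$cells
    se_log <- (log(cells$ci_high) - log(cells$or)) / 1.959964
    sum(se_log^2, na.rm = TRUE)
  }
  ratio <- tot_var(6000, 16) / tot_var(12000, 16)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.6)

  expect_error(calibrate_to_or_grid(matrix(-1, 3, 3)), "calibration error")
  expect_error(calibrate_to_or_grid(matrix(1, 3, 3), ref_case_fraction = 1),
               "calibration error")
})

test_that("fixtures round-trip bit-exactly across formats", {
  dir <- withr::local_tempdir()
  panel <- generate_snp_panel(snp_panel_spec(seed = 17))
  gc <- generate_cohort(panel, cohort_spec(n_subjects = 40, seed = 17,
                                           cylinder_split = TRUE))
  paths <- write_fixtures(gc, dir)
  expect_true(all(file.exists(paths)))

  panel_back <- read_weights(paths["weights"])
  expect_equal(panel_back$beta, panel$beta)
  expect_equal(panel_back$variant_id, panel$variant_id)

  tsv <- read_genotypes(paths["dosages"], panel_back)
  expect_identical(tsv$dosage, gc$genotypes$dosage)
  skip_if_not_installed("VariantAnnotation")
  vcf <- suppressWarnings(read_genotypes(paths["vcf"], panel_back))
  expect_equal(vcf$dosage, gc$genotypes$dosage,
               ignore_attr = FALSE)

  ph <- read_phenotypes(paths["phenotypes"])
  expect_equal(ph$se_mean, as_cohort_table(gc$phenotypes)$se_mean)

  # truth JSON reseeds an identical cohort
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  spec2 <- do.call(cohort_spec, truth$cohort_spec)
  gc2 <- generate_cohort(panel, spec2)
  expect_identical(gc2$phenotypes, gc$phenotypes)
  expect_identical(gc2$genotypes$dosage, gc$genotypes$dosage)

  # byte-identical rerun under the same seed
  dir2 <- withr::local_tempdir()
  write_fixtures(gc2, dir2)
  for (f in c("weights.tsv", "dosages.tsv", "genotypes.vcf",
              "phenotypes.csv", "truth.json"))
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
})
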