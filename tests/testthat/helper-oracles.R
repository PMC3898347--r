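# Independent oracles and small fixture builders used across tests.

# contingency-table cross-product odds ratio for a 2x2 of counts
cross_product_or <- function(case_exp, ctrl_exp, case_unexp, ctrl_unexp) {
  (case_exp * ctrl_unexp) / (ctrl_exp * case_unexp)
}

# expand 2x2 counts (exposure x case) into a minimal cohort for the
# logistic fitters; exposure is binary 0/1
counts_to_cohort <- function(case_exp, ctrl_exp, case_unexp, ctrl_unexp) {
  n <- c(case_exp, ctrl_exp, case_unexp, ctrl_unexp)
  data.frame(
    exposure = rep(c(1, 1, 0, 0), n),
    status = factor(rep(c("case", "control", "case", "control"), n),
                    levels = c("case", "control", "neither")),
    excluded = FALSE)
}

# expand per-cell case/control counts over a 3x3 (or partial) grid into a
# cohort table ready for joint_strata_or; counts is a data.frame with
# columns grs, edu, cases, controls
grid_counts_to_cohort <- function(counts) {
  rows <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    with(counts[i, ], data.frame(
      grs_category = grs, education = edu,
      status = rep(c("case", "control"), c(cases, controls))))
  }))
  rows$grs_category <- factor(rows$grs_category,
                              levels = c("low", "medium", "high"))
  rows$education <- factor(rows$education,
                           levels = c("primary", "intermediate", "higher"))
  rows$education_ordinal <- as.integer(rows$education) - 1L
  rows$status <- factor(rows$status, levels = c("case", "control", "neither"))
  rows$excluded <- FALSE
  rows$age <- 0
  rows$sex_male <- 0L
  rows
}

# crude cross-product ORs of every non-reference cell against (low, primary)
grid_cross_product_ors <- function(counts) {
  ref <- counts[counts$grs == "low" & counts$edu == "primary", ]
  ors <- mapply(function(ca, co) cross_product_or(ca, co, ref$cases,
                                                  ref$controls),
                counts$cases, counts$controls)
  data.frame(grs = counts$grs, edu = counts$edu, or = ors)
}

# closed-form synergy index (the published formula, reimplemented here so
# the model-based path is checked against an independent expression)
si_closed_form <- function(or11, or10, or01) {
  (or11 - 1) / ((or10 - 1) + (or01 - 1))
}

# delta-method SE of ln(SI) via numerical central differences, sharing only
# the covariance matrix with the analytic path
numerical_se_theta <- function(b, V, h = 1e-6) {
  theta_of <- function(bb) log(exp(bb[1]) - 1) - log(exp(bb[2]) + exp(bb[3]) - 2)
  g <- vapply(1:3, function(i) {
    up <- b; up[i] <- up[i] + h
    dn <- b; dn[i] <- dn[i] - h
    (theta_of(up) - theta_of(dn)) / (2 * h)
  }, numeric(1))
  sqrt(as.numeric(g %*% V %*% g))
}

# panel spec calibrated to the published score distribution: mean beta
# 0.115 D and mean effect-allele frequency 0.45 give a mean weighted score
# near 2.7 with low/medium/high category mass in every education stratum
calibrated_panel_spec <- function(seed) {
  snp_panel_spec(beta_range = c(0.03, 0.20), freq_range = c(0.20, 0.70),
                 seed = seed)
}

# default synthetic world used when a test just needs a plausible cohort
make_default_cohort <- function(n = 3000, seed = 1, panel_seed = 1, ...) {
  panel <- generate_snp_panel(snp_panel_spec(seed = panel_seed))
  gc <- generate_cohort(panel, cohort_spec(n_subjects = n, seed = seed, ...))
  grs <- compute_grs(gc$genotypes, panel)
  as_cohort_table(gc$phenotypes, grs = grs, scheme = "hyperopia_control")
}

# Published strata odds-ratio grids (combined-cohort block), rows = genetic
# load low/medium/high, columns = education primary/intermediate/higher.
combined_or_grid <- matrix(c(1, 2.0, 6.1,
                             3.5, 6.4, 18.8,
                             7.2, 21.6, 51.3),
                           nrow = 3, byrow = TRUE,
                           dimnames = list(c("low", "medium", "high"),
                                           c("primary", "intermediate",
                                             "higher")))
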