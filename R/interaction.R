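# Additive-scale interaction: Rothman's synergy index with a log-scale
# delta-method confidence interval, plus RERI and attributable proportion.
#
# Notation: in the 2x2 contrast formed from the extreme strata, or11 is the
# odds ratio for carrying both factors (high genetic load AND higher
# education), or10 for the genetic factor alone, or01 for education alone,
# all against the doubly-unexposed reference.

#' Rothman's synergy index from three odds ratios
#'
#' `SI = (or11 - 1) / ((or10 - 1) + (or01 - 1))`: the ratio of the joint
#' excess odds to the sum of the separate excess odds. SI > 1 indicates
#' super-additivity (biological interaction); SI = 1 exact additivity.
#' The index is undefined (flagged, not an error) when the joint effect is
#' protective-or-null (`or11 <= 1`) or the summed separate excess effects
#' are non-positive.
#'
#' @param or11 Odds ratio for both factors combined.
#' @param or10,or01 Odds ratios for each factor alone.
#' @return Numeric SI with attribute `estimable`; `NA` when the denominator
#'   is exactly zero.
#' @examples
#' synergy_index_from_ors(37.2, 7.5, 5.5) # about 3.3
#' @export
synergy_index_from_ors <- function(or11, or10, or01) {
  ors <- c(or11 = or11, or10 = or10, or01 = or01)
  if (any(!is.finite(ors)) || any(ors <= 0))
    stop("odds ratios must be positive and finite", call. = FALSE)
  denom <- (or10 - 1) + (or01 - 1)
  estimable <- or11 > 1 && denom > 0
  si <- if (denom == 0) NA_real_ else (or11 - 1) / denom
  structure(si, estimable = estimable)
}

new_synergy_result <- function(si, theta, se_theta, ci_low, ci_high,
                               corner_ors, estimable,
                               method = "delta_log_si",
                               collapse_mode = NA_character_) {
  structure(list(si = si, theta = theta, se_theta = se_theta,
                 ci_low = ci_low, ci_high = ci_high,
                 corner_ors = corner_ors, estimable = estimable,
                 method = method, collapse_mode = collapse_mode),
            class = "synergy_result")
}

#' @export
print.synergy_result <- function(x, ...) {
  if (!x$estimable) {
    cat("Synergy index: inestimable (joint effect <= 1 or summed separate",
        "excess effects <= 0)\n")
  } else {
    cat(sprintf("SI %.1f; 95 %% CI %.1f-%.1f\n", x$si, x$ci_low, x$ci_high))
  }
  cat(sprintf("  corner ORs (both, genetic only, education only): %.2f, %.2f, %.2f\n",
              x$corner_ors[1], x$corner_ors[2], x$corner_ors[3]))
  invisible(x)
}

# extract the 3 corner coefficients and their covariance block from a fit
corner_block <- function(fit, corner_terms) {
  stopifnot(inherits(fit, "gxe_fit"), length(corner_terms) == 3)
  missing_terms <- setdiff(corner_terms, names(fit$coefficients))
  if (length(missing_terms))
    stop("fit lacks corner coefficient(s): ",
         paste(missing_terms, collapse = ", "), call. = FALSE)
  list(b = fit$coefficients[corner_terms],
       V = fit$covariance[corner_terms, corner_terms])
}

#' Synergy index from a fitted joint logistic model
#'
#' Model-based SI with the log-scale delta-method standard error of
#' Hosmer and Lemeshow. Writing `b11`, `b10`, `b01` for the three corner
#' log-odds-ratio coefficients,
#' `theta = ln(SI) = ln(e^b11 - 1) - ln(e^b10 + e^b01 - 2)`,
#' its gradient is
#' `(e^b11/(e^b11 - 1), -e^b10/(e^b10 + e^b01 - 2), -e^b01/(e^b10 + e^b01 - 2))`,
#' and `se(theta)^2 = g' V g` over the 3x3 coefficient covariance block.
#' The 95% CI is `exp(theta +/- 1.959964 se)`.
#'
#' When `b11 <= 0` or `e^b10 + e^b01 - 2 <= 0` the log transform is
#' undefined: the result is returned flagged inestimable, never raised.
#'
#' @param fit A converged logistic `gxe_fit` containing the corner terms.
#' @param corner_terms Coefficient names, in the order (both, genetic-only,
#'   education-only).
#' @param collapse_mode Optional label recorded in the result.
#' @return A `synergy_result`.
#' @export
synergy_index_from_fit <- function(fit, corner_terms,
                                   collapse_mode = NA_character_) {
  blk <- corner_block(fit, corner_terms)
  b <- unname(blk$b)
  ors <- exp(b)
  names(ors) <- c("or11", "or10", "or01")
  denom <- ors[2] + ors[3] - 2
  if (b[1] <= 0 || denom <= 0) {
    si <- if (denom != 0) unname((ors[1] - 1) / denom) else NA_real_
    return(new_synergy_result(si, NA_real_, NA_real_, NA_real_, NA_real_,
                              ors, estimable = FALSE,
                              collapse_mode = collapse_mode))
  }
  theta <- log(ors[1] - 1) - log(denom)
  grad <- c(ors[1] / (ors[1] - 1), -ors[2] / denom, -ors[3] / denom)
  se_theta <- sqrt(max(0, as.numeric(grad %*% blk$V %*% grad)))
  new_synergy_result(si = unname(exp(theta)), theta = unname(theta),
                     se_theta = se_theta,
                     ci_low = unname(exp(theta - Z95 * se_theta)),
                     ci_high = unname(exp(theta + Z95 * se_theta)),
                     corner_ors = ors, estimable = TRUE,
                     collapse_mode = collapse_mode)
}

#' Collapse a 3x3 strata table to the 2x2 extreme-corner contrast
#'
#' Additive-interaction measures need one OR per factor combination; a
#' 3-level genetic load crossed with 3-level education is reduced either by
#' taking the extreme cells of the joint fit as they stand (`"corners"`:
#' high load/higher education, high load/primary education, low
#' load/higher education) or by refitting after dichotomising both factors
#' (`"dichotomized"`: high vs low+medium load, higher vs
#' primary+intermediate education).
#'
#' @param table A `strata_or_table` from [joint_strata_or()].
#' @param mode `"corners"` (default) or `"dichotomized"`.
#' @return List with `fit` (a logistic `gxe_fit`), `corner_terms` (names of
#'   the both / genetic-only / education-only coefficients in `fit`),
#'   `corner_ors`, and `mode`.
#' @export
collapse_extremes <- function(table, mode = c("corners", "dichotomized")) {
  stopifnot(inherits(table, "strata_or_table"))
  mode <- match.arg(mode)
  if (mode == "corners") {
    want <- data.frame(grs_category = c("high", "high", "low"),
                       education = c("higher", "primary", "higher"))
    terms <- character(3)
    for (i in 1:3) {
      row <- table$cells[table$cells$grs_category == want$grs_category[i] &
                           table$cells$education == want$education[i], ]
      if (!row$estimable)
        stop("collapse error: corner cell (", want$grs_category[i], ", ",
             want$education[i], ") is inestimable", call. = FALSE)
      terms[i] <- row$term
    }
    return(list(fit = table$fit, corner_terms = terms,
                corner_ors = unname(exp(table$fit$coefficients[terms])),
                mode = mode))
  }
  # dichotomized: refit the joint model on merged factor levels
  dat <- table$data
  dat$i11 <- as.integer(dat$grs_category == "high" & dat$education == "higher")
  dat$i10 <- as.integer(dat$grs_category == "high" & dat$education != "higher")
  dat$i01 <- as.integer(dat$grs_category != "high" & dat$education == "higher")
  fml <- stats::reformulate(c("i11", "i10", "i01", table$covariates), "case")
  fit <- suppressWarnings(stats::glm(fml, data = dat,
                                     family = stats::binomial(),
                                     control = stats::glm.control(epsilon = 1e-12, maxit = 50)))
  gf <- new_gxe_fit(stats::coef(fit), stats::vcov(fit), nrow(dat),
                    converged = fit$converged, model_kind = "logistic",
                    separation = detect_separation(fit), model = fit)
  list(fit = gf, corner_terms = c("i11", "i10", "i01"),
       corner_ors = unname(exp(stats::coef(fit)[c("i11", "i10", "i01")])),
       mode = mode)
}

#' Synergy index of a strata OR table
#'
#' Convenience wrapper: [collapse_extremes()] then
#' [synergy_index_from_fit()].
#'
#' @inheritParams collapse_extremes
#' @return A `synergy_result`.
#' @export
synergy_index <- function(table, mode = c("corners", "dichotomized")) {
  cl <- collapse_extremes(table, mode)
  synergy_index_from_fit(cl$fit, cl$corner_terms, collapse_mode = cl$mode)
}

#' RERI and attributable proportion from a fitted joint model
#'
#' Companion additive-interaction measures sharing the synergy-index
#' machinery: the relative excess risk due to interaction
#' `RERI = e^b11 - e^b10 - e^b01 + 1` and the attributable proportion
#' `AP = RERI / e^b11`, with delta-method 95% CIs from the same 3x3
#' covariance block. Both are 0 under exact additivity.
#'
#' @inheritParams synergy_index_from_fit
#' @return List with components `reri` and `ap`, each holding `estimate`,
#'   `se`, `ci_low`, `ci_high`; plus `corner_ors`.
#' @export
reri_ap_from_fit <- function(fit, corner_terms) {
  blk <- corner_block(fit, corner_terms)
  b <- unname(blk$b)
  ors <- exp(b)
  reri <- ors[1] - ors[2] - ors[3] + 1
  g_reri <- c(ors[1], -ors[2], -ors[3])
  se_reri <- sqrt(max(0, as.numeric(g_reri %*% blk$V %*% g_reri)))
  ap <- reri / ors[1]
  # AP = 1 - (e^b10 + e^b01 - 1) * e^-b11
  g_ap <- c((ors[2] + ors[3] - 1) / ors[1], -ors[2] / ors[1], -ors[3] / ors[1])
  se_ap <- sqrt(max(0, as.numeric(g_ap %*% blk$V %*% g_ap)))
  mk <- function(est, se) list(estimate = est, se = se,
                               ci_low = est - Z95 * se,
                               ci_high = est + Z95 * se)
  list(reri = mk(reri, se_reri), ap = mk(ap, se_ap),
       corner_ors = stats::setNames(ors, c("or11", "or10", "or01")))
}
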