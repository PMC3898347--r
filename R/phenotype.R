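# Refraction phenotyping: spherical equivalent, clinical categories,
# exclusion rules, and case/control assignment.

#' Refraction category labels, from most myopic to most hyperopic
#'
#' Seven clinical categories of spherical-equivalent refraction, ordered from
#' high myopia to high hyperopia.
#'
#' @format Character vector of length 7.
#' @export
refraction_categories <- c(
  "high_myopia", "moderate_myopia", "low_myopia", "emmetropia",
  "low_hyperopia", "medium_hyperopia", "high_hyperopia"
)

#' Recognised clinical exclusion flags, in priority order
#'
#' Subjects carrying any of these history flags are excluded from analysis;
#' when several flags are present the first in this order is reported as the
#' exclusion reason.
#'
#' @format Character vector of length 5.
#' @export
exclusion_flag_vocabulary <- c(
  "cataract_surgery_no_prior_refraction",
  "laser_refractive_no_prior_refraction",
  "other_iop_procedure",
  "keratoconus",
  "syndrome"
)

#' Spherical equivalent of a sphere/cylinder refraction
#'
#' The standard summary refraction, `SE = sphere + cylinder / 2`, in diopters.
#'
#' @param sphere Sphere component in diopters. Vectorised.
#' @param cylinder Cylinder component in diopters (either sign convention).
#' @return Numeric vector of spherical equivalents in diopters.
#' @examples
#' spherical_equivalent(-2.0, -1.0) # -2.5
#' @export
spherical_equivalent <- function(sphere, cylinder) {
  if (!is.numeric(sphere) || !is.numeric(cylinder))
    stop("invalid measurement: sphere and cylinder must be numeric", call. = FALSE)
  bad <- is.nan(sphere) | is.nan(cylinder) |
    (!is.na(sphere) & !is.finite(sphere)) |
    (!is.na(cylinder) & !is.finite(cylinder))
  if (any(bad))
    stop("invalid measurement: non-finite sphere or cylinder", call. = FALSE)
  sphere + cylinder / 2
}

#' Mean spherical equivalent over two eyes with single-eye fallback
#'
#' Averages the right- and left-eye spherical equivalents. When one eye is
#' unavailable (`NA`) the SE of the other eye is used; when both are missing
#' the result is `NA`. Absence is a value here, never an error.
#'
#' @param se_right,se_left Per-eye spherical equivalents in diopters; `NA`
#'   marks an unavailable eye. Vectorised.
#' @return Numeric vector: mean SE, single available SE, or `NA`.
#' @export
mean_se <- function(se_right, se_left) {
  n <- max(length(se_right), length(se_left))
  se_right <- rep_len(as.numeric(se_right), n)
  se_left <- rep_len(as.numeric(se_left), n)
  out <- (se_right + se_left) / 2
  only_r <- !is.na(se_right) & is.na(se_left)
  only_l <- is.na(se_right) & !is.na(se_left)
  out[only_r] <- se_right[only_r]
  out[only_l] <- se_left[only_l]
  out
}

#' Classify spherical equivalent into the seven refraction categories
#'
#' Bins, in diopters: high myopia (SE <= -6), moderate myopia (-6, -3],
#' low myopia (-3, -0.75], emmetropia (-0.75, 0.75), low hyperopia [0.75, 3),
#' medium hyperopia [3, 6), high hyperopia (SE >= 6). Boundaries on the
#' negative side belong to the more myopic bin and on the positive side to
#' the hyperopic bin, matching the printed inequality conventions of the
#' CREAM consortium classification.
#'
#' @param se_mean Spherical equivalent in diopters. Vectorised; `NA` passes
#'   through as `NA`.
#' @return Factor with levels [refraction_categories].
#' @export
classify_refraction <- function(se_mean) {
  se_mean <- as.numeric(se_mean)
  if (any(!is.na(se_mean) & !is.finite(se_mean)))
    stop("invalid measurement: non-finite spherical equivalent", call. = FALSE)
  lab <- ifelse(se_mean <= -6, "high_myopia",
         ifelse(se_mean <= -3, "moderate_myopia",
         ifelse(se_mean <= -0.75, "low_myopia",
         ifelse(se_mean < 0.75, "emmetropia",
         ifelse(se_mean < 3, "low_hyperopia",
         ifelse(se_mean < 6, "medium_hyperopia", "high_hyperopia"))))))
  factor(lab, levels = refraction_categories)
}

#' Apply clinical-history exclusion rules
#'
#' A subject is excluded iff any recognised flag is present; the reported
#' reason is the first matching flag in [exclusion_flag_vocabulary] order.
#' Unknown flags are a configuration error, not silently ignored.
#'
#' @param flags Character vector of flags for one subject (may be empty), or
#'   a list of such vectors for many subjects.
#' @return For a single subject, a list with `excluded` (logical) and
#'   `reason` (flag name or `NA`). For a list input, a data.frame with those
#'   two columns.
#' @export
apply_exclusions <- function(flags) {
  one <- function(fl) {
    fl <- fl[nzchar(fl)]
    unknown <- setdiff(fl, exclusion_flag_vocabulary)
    if (length(unknown))
      stop("unknown exclusion flag(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    hit <- exclusion_flag_vocabulary[exclusion_flag_vocabulary %in% fl]
    list(excluded = length(hit) > 0,
         reason = if (length(hit)) hit[[1]] else NA_character_)
  }
  if (is.list(flags)) {
    res <- lapply(flags, one)
    data.frame(excluded = vapply(res, `[[`, logical(1), "excluded"),
               reason = vapply(res, `[[`, character(1), "reason"),
               stringsAsFactors = FALSE)
  } else {
    one(as.character(flags))
  }
}

#' Define a myopia case/control scheme
#'
#' Cases are always moderate-to-high myopes (SE <= -3 D). The control
#' definition is either moderate-to-high hyperopia (SE >= +3 D, the primary
#' analysis) or emmetropia (-0.75 < SE < 0.75 D, the sensitivity analysis).
#'
#' @param name `"hyperopia_control"` or `"emmetropia_control"`.
#' @return An object of class `case_control_scheme`.
#' @export
case_control_scheme <- function(name = c("hyperopia_control", "emmetropia_control")) {
  name <- match.arg(name)
  control_rule <- switch(name,
    hyperopia_control = c(3, Inf),
    emmetropia_control = c(-0.75, 0.75))
  structure(
    list(name = name, case_threshold = -3, control_rule = control_rule),
    class = "case_control_scheme")
}

#' Assign case/control status from spherical equivalent
#'
#' @param se_mean Spherical equivalent in diopters (vectorised).
#' @param scheme A [case_control_scheme()] or its name.
#' @return Factor with levels `case`, `control`, `neither`; `NA` in, `NA` out.
#' @export
assign_case_control <- function(se_mean, scheme = case_control_scheme()) {
  if (is.character(scheme)) scheme <- case_control_scheme(scheme)
  stopifnot(inherits(scheme, "case_control_scheme"))
  se_mean <- as.numeric(se_mean)
  is_case <- se_mean <= scheme$case_threshold
  is_control <- if (scheme$name == "hyperopia_control") {
    se_mean >= scheme$control_rule[1]
  } else {
    se_mean > scheme$control_rule[1] & se_mean < scheme$control_rule[2]
  }
  lab <- ifelse(is_case, "case", ifelse(is_control, "control", "neither"))
  factor(lab, levels = c("case", "control", "neither"))
}
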