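---
title: "Methods: genetic risk, education, and additive interaction in myopia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetic risk, education, and additive interaction in myopia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myopiaGxE)
```

## The scientific question

Refractive error is measured in diopters (D) as the spherical equivalent
(SE): negative values are myopic, positive hyperopic. Common variants
identified by genome-wide association raise myopia risk each by a small
amount, conventionally summarised as a weighted genetic risk score; years
of schooling (near work) is the strongest environmental risk factor. The
question this package operationalises is whether the two risk factors
*interact on the additive scale* — whether carrying both confers more risk
than the sum of the separate excess risks — which is the scale on which
biological interaction is usually argued.

## Phenotyping

Each eye contributes `SE = sphere + cylinder/2`. The per-subject outcome is
the mean SE over available eyes; with one eye missing the other eye's SE is
used, and a subject with neither eye measured has no outcome (a value, not
an error). Subjects with a history that invalidates the measured refraction
(cataract surgery or laser refractive procedures without known prior
refraction, other intra-ocular procedures, keratoconus, syndromes) are
excluded; flags are precomputed booleans in the input table because these
criteria reference clinical history that cannot be derived from refraction
data.

SE is categorised into seven clinical bins with every printed boundary
assigned deterministically: boundaries on the myopic side belong to the
more myopic bin (−6 D is high myopia, −3 D moderate myopia, −0.75 D low
myopia) and boundaries on the hyperopic side belong upward (0.75, 3 and
6 D open their hyperopic bins). This is the unique assignment consistent
with all the printed inequalities, and it makes the seven bins a partition
of the real line — a property the test suite checks on a dense grid.

Case/control schemes: cases are always moderate-to-high myopes
(SE ≤ −3 D). The primary control definition is moderate-to-high hyperopia
(SE ≥ 3 D) — contrasting the extreme ends of the physiological spectrum
maximises the genetic contrast — with emmetropia (−0.75 < SE < 0.75 D) as
a sensitivity scheme; on the same data the emmetropia scheme is expected
to, and in our synthetic worlds does, produce uniformly smaller strata
odds ratios. Subjects who are neither case nor control are dropped from
the logistic models only; status is computed last, so this ordering cannot
change any estimate.

## The weighted genetic risk score

With effect-allele dosages `d_i` in [0, 2] (fractional after imputation)
and per-allele refraction effects `beta_i` in diopters (oriented positive:
a negative supplied weight has its alleles swapped at load time, which
makes score monotonicity testable),

`score = sum_i beta_i * d_i`.

The upstream weighting method is not fully specified by its source, so the
score convention was an open choice. We keep the plain diopter-weighted sum
because it reproduces the published calibration: a cohort mean of 23.4
carried risk alleles with a mean score of 2.7 implies a mean per-allele
weight of about 0.115 D, squarely in the published effect-size range, and
yields the published 1.4–4.0 score span. The other common convention —
rescaling by `n_snps / sum(beta)` onto an allele-count scale — is available
as `normalize = TRUE` and is off by default.

Scores are categorised into low / medium / high genetic load at cut-points
2.25 and 3.00 D. The printed intervals share their endpoints, so intervals
are half-open below with the top interval closed: 2.25 is medium, 3.00 is
high. Missing dosages fail loudly in the readers; an explicit
`impute_mean = TRUE` substitutes `2 * freq` (silent imputation would be
invisible bias). Genotype input is either a dosage TSV or a VCF (DS field
preferred, hard-call GT fallback); variants are matched by identifier and
alleles only, the dosage is flipped to `2 − d` when the effect allele is
REF, and an allele pair matching neither way is a hard error — strand
heuristics are deliberately not attempted for a 26-variant curated panel.

## Association models

*Adjusted associations.* Linear least squares of SE on one exposure plus
covariates, and case/control logistic regression returning
`OR = exp(coef)` per exposure unit with Wald 95% CIs (z = 1.959964
throughout; Wald rather than profile intervals match the reported analysis
style and are exactly reproducible). Education enters adjusted models
ordinally (0/1/2) so a single per-level-step coefficient is reported; sex
is coded male = 1, age in years uncentered — arbitrary but fixed, and the
exposure ORs are invariant to these codings. An optional `per_sd` flag
reports the score OR per standard deviation instead of per unit; per-unit
is the default as the more common convention for this kind of score.

*Stratified slopes.* Per education stratum, the least-squares slope of SE
on the score; homogeneity of the three slopes is tested as the F test of
the score-by-education interaction block (2 numerator df) in the pooled
model, the regression form of a one-way test on slopes.

*Joint strata.* One logistic fit with eight indicator terms — every
(genetic load × education) cell except the low-load / primary-education
reference — plus age and sex. Each cell's OR is its exponentiated
indicator; the reference OR is exactly 1 with a degenerate CI. Empty cells
and per-cell separation are flagged `estimable = FALSE` rather than
aborting, so simulation sweeps survive degenerate draws. Quasi-separation
is detected as fitted probabilities within 1e−8 of 0/1 together with a
coefficient magnitude above 12 on the log-odds scale; separated fits carry
the flag and report no OR, and no penalised fallback is applied (the
analysis style this reproduces predates routine penalisation).

*Trend.* Within one load stratum, the Wald p-value of the ordinal
education coefficient, adjusted for age and sex. With only two populated
levels this reduces to the single-dummy Wald p, which the tests assert.

All logistic fits use a tightened IRLS tolerance (deviance epsilon 1e−12)
so that saturated-design ORs match contingency-table cross-products to at
least six significant digits — the oracle equivalence the acceptance suite
enforces.

## Additive interaction

From the joint model's extreme strata — writing `b11` for the
(high load, higher education) coefficient, `b10` for (high load, primary)
and `b01` for (low load, higher) — the synergy index is

`SI = (e^b11 − 1) / (e^b10 + e^b01 − 2)`,

with `theta = ln SI`, delta-method variance `g' V g` over the 3×3
coefficient covariance block using the analytic gradient
`(e^b11/(e^b11−1), −e^b10/(e^b10+e^b01−2), −e^b01/(e^b10+e^b01−2))`, and
CI `exp(theta ± 1.959964 se)`. The source of the reproduced analysis cites
only the index itself; the variance method for an *adjusted* SI was an
open choice, and we use the Hosmer–Lemeshow log-scale delta method as the
standard model-based approach, cross-checked in the acceptance suite
against a numerical gradient (4 significant digits) and a 500-resample
nonparametric bootstrap (CI endpoints within 15% relative at n = 5,000).

SI is undefined when the joint effect is not harmful (`b11 ≤ 0`) or the
summed separate excess effects are non-positive; such results are values
flagged `estimable = FALSE`, never exceptions. RERI
(`e^b11 − e^b10 − e^b01 + 1`) and the attributable proportion
(`RERI / e^b11`) share the machinery; SI = 1, RERI = 0 and AP = 0 coincide
at exact additivity, and SI > 1 iff RERI > 0 — a property test.

*Collapsing 3×3 to 2×2.* A 3-level load by 3-level education grid has no
canonical 2×2 contrast; the reproduced analysis does not state one. Mode
`"corners"` (default) takes the three extreme cells of the joint fit as
they stand; back-computing SI from the published replication-cohort corner
ORs (37.2, 7.5, 5.5) reproduces the published 3.3 at one decimal, which is
why corners is the default. Mode `"dichotomized"` refits after merging
(high vs low+medium load; higher vs primary+intermediate education). The
published discovery/combined SIs do not round-trip from their printed
rounded corner ORs (they give 5.7 and 4.5 against printed 5.5 and 4.2),
consistent with unrounded model coefficients — and possibly a different
collapse — having been used; both modes are therefore provided and no
further intent is guessed.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, at
the published margins: 26 biallelic SNPs with uniform betas (default range
0.03–0.25 D) and effect-allele frequencies (0.2–0.8), Hardy–Weinberg,
LD-free dosages `Binomial(2, f_i)`; education categorical at
(43.2, 38.8, 18.0)%; age normal 64.9 ± 9.2 years truncated at 45 (the
youngest recruitment age emulated); sex Bernoulli(0.43); and

`SE = intercept + slope[education] * score + Normal(0, noise_sd)`

with default slopes (−0.47, −0.53, −0.78) D per score unit — the
education-modified genetic effect that is the point of the analysis.
Defaults chosen where the emulated study is silent: `noise_sd = 2.0` D
approximates the part of the observed 2.54 D outcome SD not explained by
the score and demographics (it is a free parameter and documented as
such); `intercept = 2.5` D puts the default panel's cohort mean refraction
near the observed +0.5 D. Note the default beta/frequency ranges imply a
mean score near 3.2; a panel calibrated to the published mean score of 2.7
(betas 0.03–0.20, frequencies 0.2–0.7, mean per-allele weight 0.115 D) is
used where tests target the published score distribution. Per-eye
sphere/cylinder are back-filled so the SE formula round-trips exactly
(cylinder 0 by default; `cylinder_split = TRUE` exercises the formula
nontrivially).

All randomness flows from one master seed through named substreams (panel,
dosages, covariates, noise, eyes), so enlarging the cohort never perturbs
the panel and reruns are byte-identical — fixture files included.

`calibrate_to_or_grid()` generates Table-shaped case/control worlds
directly: subjects land in (load × education) cells at the published
marginal mixes and become cases at `odds = reference_odds × cell_OR`, with
sentinel SEs (−4/+4 D) consistent with the hyperopia scheme and sentinel
scores per category. The reference-cell case fraction defaults to 0.2 —
the low-load/primary-education group is predominantly controls, as in the
emulated data — and infeasible odds raise a calibration error.

What a green test establishes, and what it does not: the generator shares
the analysis' own assumptions (linear score effects within education
strata, logistic cell odds, independence of loci, no age-dependent
refraction drift, no cohort-period education drift). Parameter recovery
and null-calibration results therefore validate the estimators and their
implementation, not the biological model; they cannot detect
misspecification that real data might exhibit.

## Numerical and degenerate-input choices

- Constant outcome in the linear model: slope 0 with zero variance, not
  NaN.
- Rank-deficient linear designs raise a singular-design error naming the
  collinear terms; near-singular logistic fits return `converged = FALSE`.
- SI at the exact additivity boundary (denominator 0) is `NA`: the ratio
  is numerically undefined there and no comparison is meaningful.
- Report rounding: ORs and SI to 1 decimal, betas to 2 decimals in the
  TSVs, mirroring the reproduced table style; the JSON sidecar always
  carries full precision, and the duality is tested.
- The pipeline is deterministic given its inputs; the seed in its config
  is logged for provenance only.

## Interfaces

The R functions are the primary interface; `inst/cli/gxe-sim.R` and
`inst/cli/gxe-run.R` are thin Rscript wrappers for shell use, and the
pipeline config schema ships in `inst/schema/`. Formats: weight TSV,
dosage TSV or VCF 4.x (DS/GT), phenotype CSV, JSON sidecars.

## Known limitations

- No LD, imputation quality filtering, or per-SNP interaction scan; the
  26 loci are treated as independent additive contributors, as the
  reproduced analysis does.
- Education is a 3-level proxy; absolute years of schooling are not
  modelled.
- No penalised (Firth-type) fallback under separation; affected cells are
  flagged instead.
- The emmetropia-control comparison is directional only; no formal
  equivalence test between schemes is provided.
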