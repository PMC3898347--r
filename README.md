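# myopiaGxE

Gene-by-environment interaction analysis for refractive error: does
educational attainment modify the effect of common myopia risk variants?

Myopia is strongly heritable, and education is its strongest known
environmental risk factor. `myopiaGxE` implements the full analysis used to
ask whether the two interact on the *additive* (biological) scale in a
population-based cohort:

1. **Phenotyping** — per-eye spherical equivalent `SE = sphere + ½ cylinder`
   (diopters), mean over eyes with single-eye fallback, seven clinical
   refraction categories (high myopia ≤ −6 D … high hyperopia ≥ 6 D),
   clinical-history exclusions, and case/control assignment (cases:
   SE ≤ −3 D; controls: hyperopes SE ≥ 3 D, or emmetropes as a sensitivity
   scheme).
2. **Genetic risk score** — the weighted polygenic score
   `GRS = Σᵢ βᵢ·dᵢ` over 26 refractive-error SNPs, with `dᵢ` the
   effect-allele dosage (0–2, fractional for imputed genotypes) and `βᵢ` the
   per-allele effect in diopters, categorised into low / medium / high
   genetic load at cut-points 2.25 and 3.00.
3. **Association models** — covariate-adjusted linear (refraction) and
   logistic (myopia odds) fits; education-stratified score slopes with a
   2-df interaction F test; a single joint logistic model giving the 3 × 3
   grid of (genetic load × education) odds ratios against the low-load /
   primary-education reference, adjusted for age and sex; per-stratum
   ordinal trend tests.
4. **Additive interaction** — Rothman's synergy index over the extreme
   strata,

   `SI = (OR₁₁ − 1) / ((OR₁₀ − 1) + (OR₀₁ − 1))`,

   with the Hosmer–Lemeshow log-scale delta-method 95% CI computed from the
   joint model's coefficient covariance, plus RERI
   (`OR₁₁ − OR₁₀ − OR₀₁ + 1`) and the attributable proportion
   `AP = RERI / OR₁₁`. SI > 1 means the joint effect exceeds the sum of the
   separate effects.
5. **Synthetic cohorts** — individual-level data of the motivating study
   are not public, so a generator reproduces their statistical structure
   (Hardy–Weinberg dosages, education mix 43.2/38.8/18.0%, age
   64.9 ± 9.2 y truncated at 45, 43% men, education-specific genetic
   slopes −0.47/−0.53/−0.78 D per score unit), making every stage testable
   end to end.

## Worked example

A fully synthetic cohort of 6,000 subjects, scored, phenotyped and analysed:

```r
library(myopiaGxE)

panel <- generate_snp_panel(snp_panel_spec(beta_range = c(0.03, 0.20),
                                           freq_range = c(0.20, 0.70), seed = 23))
sim    <- generate_cohort(panel, cohort_spec(n_subjects = 6000, seed = 23))
grs    <- compute_grs(sim$genotypes, panel)
cohort <- as_cohort_table(sim$phenotypes, grs = grs, scheme = "hyperopia_control")

stratified_slopes(cohort)
#> Education-stratified slopes of refraction on the genetic risk score
#>     education       beta        se    n
#>       primary -0.2579759 0.1054310 2553
#>  intermediate -0.5996517 0.1147833 2372
#>        higher -0.7506047 0.1700033 1075
#> Homogeneity: F(2, 5994) = 3.989, p = 0.0186

tab <- joint_strata_or(cohort)
tab
#> Myopia odds ratios by genetic load and education (hyperopia_control; adjusted: age, sex_male)
#>  grs_category    education   n           or_ci
#>           low      primary  89 1.0 (reference)
#>        medium      primary 365   1.8 (0.6-5.3)
#>          high      primary  69   2.8 (0.8-9.9)
#>           low intermediate  71   2.4 (0.7-8.5)
#>        medium intermediate 345   2.1 (0.7-6.2)
#>          high intermediate  60  4.8 (1.4-15.8)
#>           low       higher  23  2.0 (0.3-11.6)
#>        medium       higher 106  9.1 (3.1-27.0)
#>          high       higher  23 18.8 (5.1-68.9)

synergy_index(tab)
#> SI 6.3; 95 % CI 1.2-33.3
#>   corner ORs (both, genetic only, education only): 18.79, 2.84, 1.98
```

Reading it: the genetic slope on refraction steepens from −0.26 D per score
unit under primary education to −0.75 D under higher education (the 2-df F
test rejects slope homogeneity at p = 0.019); myopia odds rise across the
grid to OR 18.8 for high genetic load combined with higher education; and
the synergy index of 6.3 (> 1, CI excluding 1) indicates the joint effect
exceeds the sum of the separate effects — the super-additivity this
synthetic world was generated with.

The same analysis runs from files: `write_fixtures()` emits the weight TSV,
dosage TSV / VCF and phenotype CSV, and `run_pipeline()` (or
`inst/cli/gxe-run.R`) produces the characteristics, association, strata-OR
and interaction reports as TSVs with a full-precision JSON sidecar.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, at run time with the installed package, the synergy index
implied by the three published adjusted corner odds ratios of the
replication cohort (joint 37.2, genetic load alone 7.5, education alone
5.5), rounded to one decimal, and writes it as JSON.
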