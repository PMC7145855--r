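# twinherit

Quantitative-genetic and multivariate analysis of extended-twin cohorts in
R: twin-based heritability and genetic correlation by maximum-likelihood
variance decomposition, covariate-adjusted rank-correlation mapping across
cortical parcels with false-discovery control, and partial-least-squares
(PLS) latent brain–behavior analysis with permutation and bootstrap
inference. A synthetic twin-cohort generator with known generative
parameters makes the whole pipeline testable end to end without access to
restricted cohort data.

The package is aimed at researchers studying how behavioral phenotypes
(sleep duration and quality, cognition, BMI, depression) relate to
parcel-wise brain structure in family-structured samples such as twin
cohorts, and at methodologists who need a verifiable reference
implementation of the classical twin-design machinery.

## The models

**Polygenic variance decomposition.** For a trait *y* on *n* individuals
with fixed-effect design *X* (intercept, age, sex, age×sex, age², age²×sex,
optional extras), the model is

    y ~ N(X β, σp² (h² K + (1 − h²) I))

where *K* is the expected additive-genetic relatedness matrix (2Φ scale: 1
for MZ co-twins, 0.5 for DZ co-twins and full siblings, 0 across families)
and *h² = σg²/σp²* is the narrow-sense heritability. *K* is block-diagonal
by family, so the likelihood factorizes and is evaluated in each family
block's eigenbasis; β and σp² have closed-form generalized-least-squares
solutions at fixed h², and h² is profiled over [0, 1). Significance of h²
uses the boundary likelihood-ratio test (50:50 mixture of χ²₀ and χ²₁).

**Bivariate decomposition.** Two traits are fitted jointly with genetic and
environmental 2×2 covariance components (G ⊗ K + E ⊗ I), yielding the
genetic correlation ρg, the environmental correlation ρe, and the implied
phenotypic correlation

    ρp = ρg √(h₁² h₂²) + ρe √((1 − h₁²)(1 − h₂²)).

Each correlation is tested by a likelihood-ratio test against the model
with that correlation fixed at zero (χ²₁).

**PLS correlation.** For prepared matrices *X* (individuals × parcels) and
*Y* (individuals × traits) — each column residualized on covariates and
z-scored — the SVD of the cross-covariance `t(Y) X / (n−1)` yields paired
brain/behavior saliences. Component significance comes from permuting
individual labels of *Y* (1000 permutations by default); salience stability
from bootstrap ratios (salience / bootstrap SE, resamples Procrustes-aligned
to the original), with |BSR| > 2 the conventional threshold; results are
summarized at the level of seven canonical functional networks, controlling
for network size.

## Worked example

```r
library(twinherit)

spec <- cohort_spec(
  traits = list(sleep_duration = list(h2 = 0.24, mean = 6.8,   var = 1.21),
                iq             = list(h2 = 0.66, mean = 121.8, var = 213.2)),
  rho_g = matrix(c(1, 0.42, 0.42, 1), 2),
  rho_e = matrix(c(1, 0.19, 0.19, 1), 2))
cohort <- simulate_cohort(spec, seed = 1)
cohort$pedigree
#> <pedigree> 1106 individuals in 878 families (286 MZ, 170 DZ, 0 SIB, 650 singletons)

kin    <- expected_relatedness(cohort$pedigree)
design <- covariate_design(cohort$pedigree$id, cohort$pedigree$age, cohort$pedigree$sex)

fit_univariate(cohort$phenotypes$sleep_duration, design, kin)
#> <herit_fit> h2 = 0.258 (SE 0.077), sigma_p2 = 1.213, n = 1106
#>   boundary LRT p = 0.0009562 (logLik full -1670.41, null -1675.22)

biv <- fit_bivariate(cohort$phenotypes$sleep_duration, cohort$phenotypes$iq,
                     design, kin, seed = 1)
tidy(biv)
#> # A tibble: 2 × 4
#>   term  estimate std.error   p.value
#> 1 rho_g    0.487    0.119  0.0000412
#> 2 rho_e    0.166    0.0780 0.0358
```

The heritability estimate (0.258 ± 0.077) and the genetic correlation
(0.487 ± 0.119) recover the generative values (0.24 and 0.42) within one
standard error at this cohort size; the boundary-LRT p-value says the
familial signal is far beyond chance. `implied_phenotypic_correlation(0.24,
0.66, 0.42, 0.19)` evaluates the decomposition formula exactly (0.2637407).

Association mapping (`parcelwise_association()`, `map_similarity()`) and
the PLS pipeline (`run_pls()`, with `prepare_matrices()`, `fit_pls()`,
`permutation_pvalues()`, `bootstrap_ratios()`, `network_summary()`,
`project_pls()`) follow the same tibble-in / tibble-out style; see the
methods vignette (`vignettes/twin-brain-behavior.Rmd`) for the modelling
choices and their rationale.

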