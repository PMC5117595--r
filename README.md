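# pedvc — pedigree variance components and measured-genotype association

`pedvc` is an R package for family-based genetic analysis of quantitative
traits in field studies: albuminuria (urinary albumin:creatinine ratio,
UACR), blood pressure, plasma glucose and similar phenotypes measured on
members of known pedigrees.  It answers two questions that community health
surveys with recorded family relationships make tractable:

1. **How heritable is a trait?**  Decompose phenotypic variance into
   additive genetic and residual environmental components using the
   relatedness structure of the pedigree.
2. **How much of that genetic variance is due to measured candidate
   variants?**  Test coded genotypes as fixed effects inside the same mixed
   model and convert fitted effect sizes into shares of genetic variance.

## The model

For a trait vector *y* on *n* pedigree members,

    y = Xβ + g + e,    g ~ N(0, A σ²_A),    e ~ N(0, I σ²_E)

where *A* is the additive genetic relationship matrix (twice the kinship
matrix, computed from the pedigree by the tabular method), *X* holds
covariates and coded genotypes, and heritability is
h² = σ²_A / (σ²_A + σ²_E).  Multiple traits are modelled jointly with
covariance A⊗G + I⊗E, yielding genetic correlations r_G and environmental
correlations r_E.  Estimation is REML (ML optional) with exact dense
likelihood evaluation available as an oracle for the fast eigen-rotated
fitting path.  Supporting statistics include the boundary-mixture
(½χ²₀ + ½χ²₁) likelihood-ratio test for h², Wald tests for fixed effects,
Hardy–Weinberg and transmission-disequilibrium tests, relative risks,
MDRD eGFR, and albuminuria classification.

A gene-dropping simulator (`generate_study_like_dataset()`) produces
study-shaped synthetic datasets — ~770 members in ~135 families of mean
size 5.7, ~357 phenotyped, a rare carrier-coded locus (risk frequency 0.10)
and a common additive locus (0.57), four correlated traits with configured
heritabilities — so the full pipeline is testable without any field data.

## Worked example

```r
library(pedvc)

st <- generate_study_like_dataset(seed = 1)       # synthetic study
A  <- additive_relationship(st$pedigree)          # 747 x 747 relationship matrix
ph <- subset(st$phenotypes, !is.na(logacr))       # phenotyped subset
ph$ace <- code_genotype(st$genotypes, "ACE", "carrier", "D")[ph$id]

spec <- vc_spec("logacr", c("sex", "age", "weight", "ace"), A)
fit  <- fit_univariate(spec, ph)
fit
#> Univariate variance-components fit (REML), trait logacr, n = 386
#>   V_A = 0.3795  V_E = 0.2597  h2 = 0.594 (SE 0.122)
#>   logLik = -461.74592

wald_fixed_effects(fit)
#>          term estimate     ase     z        p
#> 1 (Intercept) -0.25174 0.23261 -1.08 2.79e-01
#> 2     sexmale -0.17254 0.07687 -2.24 2.48e-02
#> 3         age  0.02757 0.00243 11.36 6.34e-30
#> 4      weight -0.00569 0.00304 -1.87 6.15e-02
#> 5         ace  0.50810 0.10699  4.75 2.05e-06
```

Here h² = 0.59 (SE 0.12) estimates the proportion of log₁₀-UACR variance
that is additive-genetic after covariate adjustment (this replicate was
generated at h² = 0.55), and the `ace` row says carriers of the risk allele
average 0.51 log₁₀ units higher UACR — a 10^0.51 ≈ 3.2-fold increase
(`fold_change_from_log10(0.51)`).  Testing and partitioning:

```r
lrt_heritability(fit, fit_univariate(spec, ph, constrain = "va_zero"))
#> $statistic 18.98;  $p 6.6e-06       # h2 significantly > 0

measured_genotype_association(vc_spec("logacr", c("sex", "age", "weight"), A),
                              ph, st$genotypes, "ACE", "D", "carrier")
#> Measured-genotype association: ACE ( carrier , risk D ) on logacr
#>   beta = 0.5081 (ASE 0.107), Wald p = 2.045e-06
#>   V_A: 0.4449 -> 0.3795; proportion of genetic variance: 0.093
```

i.e. this locus accounts for ~9% of the genetic variance of log UACR in
this replicate.

Real data enter through standard text formats: `read_pedigree()` parses
pre-makeped LINKAGE/PED files (optionally with allele-pair genotype
columns), `read_phenotypes()` reads delimited trait tables with a
column-mapping schema.  A thin command-line front end
(`inst/cli/pedvc`, or `pedvc_run()` from R) wires the stages together:
`simulate`, `kinship`, `describe`, `fit`, `assoc`.

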