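---
title: "Pedigree variance components: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree variance components: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedvc)
```

## The model

`pedvc` fits the classical biometrical decomposition of a quantitative trait
measured on members of known pedigrees.  For a trait vector $y$ on $n$
individuals,

$$ y = X\beta + g + e, \qquad
   g \sim N(0,\, A\,\sigma^2_A), \qquad e \sim N(0,\, I\,\sigma^2_E), $$

where $X$ holds fixed covariates (always including an intercept; typically
age, sex, weight, and coded genotypes at measured candidate loci), $A$ is the
additive genetic relationship matrix derived from the pedigree, and
$h^2 = \sigma^2_A/(\sigma^2_A + \sigma^2_E)$ is the narrow-sense
heritability.  For $t$ traits jointly, the random effects have covariance
$A \otimes G + I \otimes E$ with $t \times t$ genetic and environmental
covariance matrices $G$ and $E$; genetic and environmental correlations are
the correlation forms of $G$ and $E$, and per-trait heritabilities are
$G_{tt}/(G_{tt}+E_{tt})$.

Assumptions worth keeping in view:

* Random effects are multivariate normal.  Strongly skewed traits (urinary
  albumin:creatinine ratio, fasting glucose) should be log-transformed first
  (`log_transform()`, base 10 by default so coefficients convert to fold
  changes as $10^\beta$).
* Shared-household and other common-environment effects are **not** modelled.
  Where families share environments, $h^2$ estimates absorb that resemblance
  and should be read as upper bounds on strictly genetic variance.
* Relationships come from the recorded pedigree only; genotype data are used
  as fixed-effect predictors, not to re-estimate relatedness.

## Relationship matrices

`additive_relationship()` implements the tabular (recursive) method in
topological order: $a_{ii} = 1 + \tfrac12 a_{f m}$ and
$a_{ij} = \tfrac12(a_{jf} + a_{jm})$, with terms dropping when a parent is
unknown.  An individual with exactly one recorded parent is treated as having
a unique, unrelated, non-inbred second parent — the standard convention.
Storage is dense, which is exact and fast at the scales this package targets
(hundreds to a few thousands of individuals).  The test suite checks the
recursion entrywise against an independent path-counting (Wright's paths)
oracle over hundreds of randomly grown pedigrees, including inbred loops.

## Estimation

REML is the default (ML is available, and is what should be used when
comparing fixed-effect structures).  Two evaluation paths coexist on purpose:

* a **dense direct evaluator** (`vc_loglik()`) that builds the full
  covariance $A V_A + I V_E$ (or $A \otimes G + I \otimes E$), usable with
  arbitrary per-individual missing-trait patterns (observed-block
  likelihood).  A non-positive-definite covariance is an error, never
  silently clamped;
* a **rotated fast path** used by the fitters: with the eigendecomposition
  $A = U D U'$, the univariate REML profile over the variance ratio is
  one-dimensional (coarse grid then Brent refinement), and the multivariate
  likelihood factors into $n$ blocks of size $t$.

The fitters are validated against the dense evaluator at their own converged
parameters (agreement to $10^{-8}$) and against random multi-starts.
Numerical choices: deterministic initialisation at half the phenotypic
variance per component (no seeds involved in fitting); multivariate $G$ and
$E$ parameterised through Cholesky factors with log diagonals, so both stay
positive semi-definite by construction; optimisation by Nelder–Mead followed
by BFGS at relative tolerance $10^{-12}$.  Estimates of $V_A$ at the
boundary are reported as exactly zero with a `boundary` flag; founders-only
data (where $A = I$ and the decomposition is unidentifiable) are flagged
`non_identifiable`.  Standard errors come from the numerically
differentiated observed information, with the delta method for $h^2$ and
correlations; they are omitted (NA) at boundaries, where the quadratic
approximation fails.

Testing $h^2 = 0$ places the null on the boundary of the parameter space, so
`lrt_heritability()` refers the likelihood-ratio statistic to the mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$.  Fixed effects get two-sided normal
Wald tests.

## Measured-genotype association

`code_genotype()` turns allele pairs into carrier (any risk allele) or
additive (risk-allele count) covariates.  Carrier coding is the sensible
default for a rare allele whose homozygotes are nearly absent (as for an
insertion/deletion at risk frequency 0.10, where the two codings coincide in
practice); additive coding suits common variants.
`measured_genotype_association()` adds the coded genotype to the fixed
effects, refits, and reports the Wald test plus the drop in $\hat V_A$.  The
share of genetic variance attributable to the locus is computed under
Hardy–Weinberg proportions: $2p(1-p)\beta^2/V_A$ for additive coding,
$c(1-c)\beta^2/V_A$ with carrier frequency $c = 1-(1-p)^2$ for carrier
coding, using the *base* model's $V_A$ as denominator.  Because the choice
of coding changes the answer by a few points, both codings are exposed and
results state which was used.  Multiple traits and loci are tested without
multiplicity adjustment by default — transparency over silent correction —
and `stats::p.adjust` can be applied downstream.

The within-family transmission-disequilibrium test (`tdt()`) is included as
a stratification-robust cross-check; it requires both parents genotyped and
errors informatively when no heterozygous-parent transmissions exist.

## The synthetic study generator

No field data ship with this package; `generate_study_like_dataset()`
produces datasets with the statistical shape of a community pedigree study
so that every stage of the pipeline is testable end to end:

* **Pedigree shape**: families founded by couples, offspring counts
  $1 + \mathrm{Pois}(0.75)$, marry-in probability 0.25 per non-final
  generation child, at most 5 generations, 135 families.  These defaults
  target a mean family size of 5.7 (range ~3–40) and ~770 members, of whom
  a fraction 357/771 are phenotyped (applied as random masking).
* **Genotypes** by gene dropping: founders drawn from Hardy–Weinberg at the
  configured frequencies (risk frequencies 0.10 for the carrier-coded
  ACE-like locus, 0.57 for the additively coded TP53-like locus), offspring
  alleles transmitted uniformly at random, hence Mendelian-consistent by
  construction.
* **Phenotypes** as the model's exact forward process:
  $Y = \mathbf{1}\mu' + XB + \sum_\ell x_\ell\beta_\ell' + g + e$, with
  $\mathrm{vec}(g')$ drawn with covariance $A \otimes G$.  Heritabilities
  (0.26, 0.11, 0.55, 0.06 for sBP, dBP, log10 UACR, log FPG), genetic and
  environmental correlations (e.g. $r_G = 0.81$ between log UACR and dBP),
  covariate coefficients and genotype effects (0.47 on log10 UACR for the
  ACE-like carrier, 0.20 per TP53-like risk allele) are the generating
  truth recorded in the returned object.

Some generator constants are deliberate emulation choices, not estimates
from any dataset: total phenotypic variances (0.64 for log10 UACR, 225 and
144 mm Hg$^2$ for sBP/dBP, 0.04 for log FPG), covariate distributions (age
uniform 18–76; weight normal 62 ± 12 kg; height normal 165 ± 9 cm; male
fraction 0.515), and target trait means.  They are flagged in the truth
record.  Features of real community data that the generator does **not**
emulate: household/environmental clustering, nonlinear age trends,
assortative mating, genotyping error, and informative (non-random)
phenotyping.  Passing recovery tests therefore demonstrates correctness of
the estimation machinery under the model's own assumptions — not robustness
to these real-data complications.

Fitting the generated data with measured genotypes included as fixed
effects recovers the configured heritabilities; omitting them inflates
$\hat h^2$ slightly, since gene-dropped genotype effects are themselves
familially correlated.  The small upward drift of mean $\hat h^2$ (a couple
of points at $n \approx 357$) visible in the recovery studies is the
expected finite-sample behaviour of a ratio of variance estimates, and
shrinks with sample size.

## Problem sizes used in validation

The test suite validates at sizes chosen to make Monte-Carlo error small
relative to the effects checked: 500 random pedigrees (≤ 12 members) for
the kinship oracle; 100 study-shaped replicates (~770 members, ~357
phenotyped) for parameter recovery; 1000 replicates of 300-member nuclear
family sets for likelihood-ratio calibration; 500 replicates for
measured-genotype type-I error; 20 study-shaped replicates for the
variance-accounting check, whose analytic target is the Hardy–Weinberg
variance of the coded causal genotype.  `scripts/acceptance.R` re-runs the
pipeline on 25 study-shaped replicates and reports mean estimates.

## Units, thresholds and conventions

* UACR in g/mol; microalbuminuria 3.4–33 g/mol, macroalbuminuria > 33 g/mol
  (the macro threshold is configurable; 30 g/mol is also in clinical use).
* eGFR by the re-expressed 4-variable MDRD equation,
  $175 \times (\mathrm{Scr}/88.4)^{-1.154} \times \mathrm{age}^{-0.203}
  \times 0.742^{[\mathrm{female}]}$, creatinine in µmol/L; no ethnicity
  multiplier is applied.
* Relative risks carry log-scale Wald confidence intervals; swapping the
  reference group returns the exact reciprocal.
* Correlation tables use pairwise-complete observations and report the per-
  cell $N$, since field phenotype tables are rarely rectangular.

## Known limitations

* Dense linear algebra bounds practical pedigree size at a few thousand.
* No dominance, epistatic, or shared-household variance components.
* The multivariate fitter supports 2–4 traits; larger trait sets would want
  factor-analytic structures it does not implement.
* Carrier-coded variance partitioning assumes Hardy–Weinberg proportions
  when converting effect sizes into variance shares.

## A worked example

```{r example, eval = FALSE}
st <- generate_study_like_dataset(seed = 1)
A <- additive_relationship(st$pedigree)
ph <- subset(st$phenotypes, !is.na(logacr))
ph$ace <- code_genotype(st$genotypes, "ACE", "carrier", "D")[ph$id]

spec <- vc_spec("logacr", c("sex", "age", "weight", "ace"), A)
fit <- fit_univariate(spec, ph)
print(fit)
wald_fixed_effects(fit)

lrt_heritability(fit, fit_univariate(spec, ph, constrain = "va_zero"))
```
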