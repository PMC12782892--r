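---
title: "Deviation-based genomics-assisted prediction for apple fruit storability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deviation-based genomics-assisted prediction for apple fruit storability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markergap)
library(dplyr)
```

## The problem

Apple fruit storability is a quantitative trait: how long a fruit keeps
acceptable flesh firmness and crispness in cold storage depends on many
loci of unequal effect with both allelic (dominance) and nonallelic
(epistatic) interactions. Breeders quantify it through four traits:

* **FF**, **FC** — flesh firmness and crispness at harvest (kg/cm²);
* **FFR**, **FCR** — flesh firmness and crispness *retainability*, the
  maximum number of months of cold storage during which the fruit kept
  firmness ≥ 7.0 kg/cm² or crispness ≥ 0.7 kg/cm².

Genomics-assisted prediction (GAP) predicts these traits from a fixed
panel of QTL-derived and functional markers — tens of markers placed on
mapped loci and validated causal variants — rather than the genome-wide
marker density of classical genomic selection. `markergap` implements the
whole GAP workflow: retainability phenotyping, deviation-based effect
estimation, additive and non-additive prediction, and seeded
cross-validation, together with a synthetic-population generator so that
every stage can be exercised and verified without access to a breeding
program's data.

## The model

Let $\mu$ be the grand mean observed phenotype value (OPV) of the
training population. For marker $m$ and genotype class $g$, the
**genotype effect** is the deviation of the class mean from the grand
mean:

$$\hat{e}_m(g) = \overline{\mathrm{OPV}}_{\{i:\, g_i(m) = g\}} - \mu .$$

For a declared set $S$ of interacting markers, the **joint effect** of a
multi-marker genotype combination $c$ is the same deviation computed on
individuals carrying that combination:

$$\hat{j}_S(c) = \overline{\mathrm{OPV}}_{\{i:\, c_i(S) = c\}} - \mu .$$

The **genotype predicted value** of an individual is

$$\mathrm{GPV}_i = \mu \;+\; \sum_{m \notin \cup S} \hat{e}_m(g_i(m))
\;+\; \sum_{S} \hat{j}_S(c_i(S)),$$

the additive model being the special case with no interacting sets.
Because a combination's class mean already carries its members' allelic
effects, markers inside a set contribute **only** through the joint
effect; summing both terms would count each member twice. The literal
both-terms variant is available behind `double_count = TRUE` for
sensitivity analysis, but the replacement form is the default and the one
whose self-consistency properties the test suite verifies.

Joint effects subsume dominance (within a marker) and epistasis (between
markers): in a pure-epistasis configuration — e.g. four combinations with
phenotypes 10/6/6/10 — every per-marker effect is exactly zero while the
four joint effects are ±2, so the non-additive information lives only in
the joint table.

**Prediction accuracy** is the Pearson correlation between GPV and OPV on
held-out individuals, estimated by seeded $k$-fold cross-validation
(default $k = 5$, unstratified random folds whose sizes differ by at most
one). Folds with undefined correlation (zero variance) are excluded from
the mean with an explicit count rather than imputed as 0.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `min_class_n` | 3 | Minimum individuals per genotype class/combination; smaller classes are flagged `low_support` and contribute 0 to prediction. |
| `fallback` | `"additive_sum"` | Contribution of an interacting set when a member call is missing or the combination was unseen/low-support: the sum of the members' individual effects (graceful degradation) or `"zero"`. |
| `k` | 5 | Cross-validation folds. |
| thresholds | 7.0, 0.7 kg/cm² | Retainability acceptability thresholds for firmness and crispness; overridable per call. |

Missing genotypes never contribute an imputed call: a missing call at a
marker contributes 0 (the expectation of a class-mean deviation) and is
counted in `n_fallback`, and excludes the individual from that marker's
class means but **not** from the grand mean.

## Retainability phenotyping

`retainability()` returns the largest month $t$ such that all monthly
measurements $1..t$ are at or above the threshold — retention is read as
*uninterrupted*, so a single sub-threshold month ends it. A series that
never fails is right-censored at its last month and flagged (attribute
`censored`) rather than given a sentinel value. Month indexing starts at
1: the at-harvest measurement is the FF/FC phenotype, not part of the
retention series. Replicates are averaged per month before thresholding
by default; `per_replicate = TRUE` thresholds each fruit first and
averages the months, since measurement protocols differ on this point and
the choice is not neutral for noisy series.

On a noiseless linear-decay series with initial value $v_0$, monthly
decay $\delta$ and threshold $\tau$, retainability has the closed form
$\min(\max(\lfloor (v_0 - \tau)/\delta \rfloor, 0), T)$; the test suite
checks this identity on 500 random series and monotonicity in the
threshold as a property.

## The synthetic-population generator

The generator emulates the structure of a storability training
population — biparental F1 families (Mendelian segregation from two
genotyped parents) and germplasm accessions (Hardy–Weinberg draws from
allele frequencies) — with a fully specified truth:

* per-marker effects via the $(a, d)$ parameterization
  `{ref-hom: +a, het: d·a, alt-hom: −a}`, giving additive ($d = 0$),
  partial-dominant ($0 < |d| < 1$) and dominant ($|d| = 1$) architectures;
* joint-effect maps for interacting sets (members contribute only through
  the set, mirroring the estimator);
* i.i.d. Gaussian residual noise and independent per-call missingness.

`storability_architecture()` is the package's reference configuration: a
population mean of 8 (a months-scale retainability), four
additive/partial-dominant markers with $a$ = 1.5, 1.0, 0.8, 0.5 and $d$ =
0.4, 0.3, 0.5, 0.2 — partial dominance being the allelic action typical
of functional storability markers — plus one interacting pair with
product-structure joint effects $4\,s_1 s_2$, $s \in \{+1, 0, -1\}$.
Under 1:2:1 segregation that interaction has exactly zero marginal
per-marker effect and standard deviation 2, i.e. twice the residual SD of
1: a strong, purely non-additive signal. Simulation studies use n = 1800
F1 individuals, matching the order of magnitude of a realistic training
population of hybrid lines. Residual variance and heritability for the
storability traits are not published quantities, so these defaults are
declared choices, not calibrations; the realized signal fraction
var(genetic)/var(phenotype) of every simulated cohort is attached to its
phenotype table so a user can see what was generated.

What the generator deliberately does **not** emulate: linkage and LD
between markers (the predictor treats markers as exchangeable, so
independent segregation is the relevant regime), multi-year phenotyping
and genotype-by-environment variance, population structure beyond a
single cross or HWE pool, and heteroscedastic or non-Gaussian residuals.
Passing tests therefore demonstrate the estimator's correctness and its
qualitative behaviour (non-additive gain, missing-data degradation,
consistency in n), not the accuracy level to expect on any real orchard
population.

```{r cohort}
arch <- storability_architecture()
g <- simulate_biparental_genotypes(arch$parent1, arch$parent2,
                                   n_offspring = 600, seed = 1)
cohort <- simulate_cohort(arch$config, g, trait = "FFR", seed = 1)
cohort
```

```{r cv}
cv_add <- kfold_cv(cohort$genotypes, cohort$phenotypes, "FFR",
                   mode = "additive", k = 5, seed = 1)
cv_non <- kfold_cv(cohort$genotypes, cohort$phenotypes, "FFR",
                   sets = arch$sets, mode = "nonadditive", k = 5, seed = 1)
bind_rows(glance(cv_add), glance(cv_non))
```

The non-additive model's gain over the additive one is exactly the
epistatic variance the additive sum cannot see. The package's acceptance
checks run this comparison at n = 1800 over 20 seeds and require the
non-additive model to win in at least 18.

## Numerical choices and degenerate inputs

* **Coordinates** are 1-based. Interval length in kb defaults to the
  *difference* convention (end − start), which is how narrowed QTL
  windows are conventionally quoted — e.g. Chr03 28,907,974–29,398,499
  gives 490,525 bp → 490.5 kb; deletion sizes use the *inclusive*
  convention (end − start + 1), e.g. Chr16 9,126,219–9,126,434 → 216 bp.
  For windows of hundreds of kb the two conventions round to the same one
  decimal, so the choice is cosmetic there and explicit everywhere.
* **Rounding** of kb values is half-up to one decimal, implemented as
  `floor(x·10 + 0.5)/10` to avoid banker's rounding.
* **Heterozygote storage** is canonical: `"A/T"` and `"T/A"` compare
  equal. With marker metadata the declared allele order fixes the
  canonical form; without it, byte order (locale-independent) is used.
  All effect-map lookups additionally normalize both sides, so models and
  cohorts produced under different conventions interoperate.
* **Missing** is a distinct state (`"."` in TSV, `"./."` from VCF), never
  an allele.
* **Zero-variance folds** raise a classed condition in
  `prediction_accuracy()` and become flagged `NA` folds in `kfold_cv()`.
* **Ties at the retainability threshold** pass (the definition is ≥).
* **Weighted zero-sum**: with every individual called and all classes
  usable, $\sum_g n_g \hat{e}_m(g) = 0$ exactly per marker; this is
  asserted as a property over random cohorts. With `min_class_n` > 1 a
  flagged class carries effect 0, deliberately breaking the identity in
  exchange for not predicting from single-fruit class means.
* **Truth maps must be total** over combinations that occur (a simulation
  with an unmapped combination is a configuration error); *estimated*
  maps may be partial, with the fallback policy covering the gap at
  prediction time.

## Parameter recovery

`parameter_recovery()` compares estimated effects with the truth's
deviations. The truth's per-marker effects are first re-centered under
the cohort's *realized* genotype frequencies, because an estimated effect
is a deviation from the grand mean, not an absolute effect. Set members
are compared at the combination level only — in the truth they act
through the joint effect, so no per-marker truth deviation exists for
them. On noiseless balanced cohorts recovery is exact; with residual
noise the RMSE shrinks as the training population grows (checked at
n = 200 vs n = 2000 over 10 seeds).

## Allelic interaction classification

From a biallelic marker's three genotype effects, `a` is half the
homozygote spread, `d` the heterozygote's deviation from the homozygote
midpoint, and the dominance ratio `d/a` is labelled: additive
(|d/a| ≤ 0.2), partial dominant (< 0.8), dominant (≤ 1.2), overdominant
(> 1.2). The labels are standard; the numeric boundaries are this
package's convention, stated here because published marker tables name
the classes without defining cut-offs. Similarly,
`marker_effect_magnitude()` summarises a marker as the *range* of its
usable genotype effects — one reasonable scalarization among several, and
documented as such rather than presented as a community standard.

## Known limitations

* Effects are plain class means: no shrinkage, no significance testing,
  no multiple-marker joint fitting. With many markers and modest n the
  summed deviations can over-count shared variance; that is the method
  being implemented, not an oversight.
* Sets are user-declared. The package does not search for interacting
  marker pairs.
* No linkage map, GBLUP or Bayesian whole-genome regression — the method
  is deliberately a fixed-panel effect-sum predictor.
* Single value per individual and trait; multi-year repeatability
  modelling is up to the caller (e.g. feed in per-individual means).

## Problem sizes used in the checks

The test suite and the acceptance script size their simulations as
follows, chosen to make the statistical assertions stable under their
fixed seeds: oracle-equivalence on 100 cohorts of ≤ 50 individuals;
zero-sum on 200 random cohorts; the non-additive-superiority comparison
on 20 cohorts of n = 1800; recovery-consistency at n = 200 vs 2000 over
10 seeds; retainability properties on 500 random decay series.
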