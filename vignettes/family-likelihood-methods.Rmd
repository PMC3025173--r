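---
title: "Multinomial likelihood models for maternal, imprinting and child genotype effects"
author: "famlik"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multinomial likelihood models for maternal, imprinting and child genotype effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famlik)
```

## The scientific problem

Case-control association studies cannot distinguish a risk allele acting in
the affected child from one acting in the child's mother (through the
intra-uterine environment), from a parent-of-origin (imprinting) effect, or
from a maternal-fetal genotype interaction: all of these produce correlated
apparent genotype relative risks in cases, because mothers and children
share alleles.  Genotyping the mothers of cases (case/mother duos), or both
parents (case/parent trios), makes these mechanisms separable.  `famlik`
implements the retrospective multinomial-likelihood approach to this
problem: the observed genotype-combination counts of each family structure
are modelled as a multinomial over its observable cells, whose
probabilities follow from a multiplicative penetrance model and a model
for parental mating-type frequencies, and the joint likelihood of any
collection of structures (trios, duos, single parents, various control
samples) is the product of the per-structure multinomials.

## The penetrance model

Disease risk for a child is parameterised multiplicatively:

* `alpha` — baseline penetrance for an 11 child of an 11 x 11 mating
  (allele 2 is, by convention, the putative risk allele);
* `R1`, `R2` — factors for one / two copies of allele 2 in the child;
* `S1`, `S2` — factors for one / two copies in the mother;
* `Im`, `Ip` — factors applied when the child's copy of allele 2 was
  inherited from the mother / the father (imprinting);
* `g11, g12, g21, g22` — interaction factors applied when the mother
  carries *i* and the child *j* copies.

Only eight ordered-origin combinations of maternal genotype and child
genotype-with-origin are Mendelian-compatible; collapsing the unobservable
origin of a heterozygous child's allele leaves seven observable cells.
In the collapsed double-heterozygote cell the maternal-origin weight is
the low-risk allele frequency `A1` under HWE and random mating; the
package defaults to 0.5 whenever no allele frequency is in scope.

Because baseline risk cancels from every retrospective (case-conditional)
probability, `alpha` is needed only for simulation and penetrance
reporting, where the package verifies that no cell's penetrance exceeds 1.

## Cell tables and the nuisance model

The likelihood is driven by one frozen enumeration of the sixteen
ordered-origin trio outcomes (the fifteen observable trio cells, with the
double-heterozygote-everybody cell split into its maternal- and
paternal-origin halves).  Each raw weight is

    risk product x Mendelian transmission factor x ordered parental-pair frequency,

and the divisor `Sigma` is the sum of all sixteen weights; the implied
population prevalence is `K = alpha * Sigma` when mating frequencies are on
the probability scale.  Every partial structure — case/mother and
case/father duos, case genotypes alone, single parents, parents of cases —
is a row-sum collapse of this enumeration, so collapse consistency is an
identity rather than a theorem, and the test suite checks it against an
independently written brute-force enumeration oracle.

Parental mating types enter through one of four nuisance regimes:

* `hwe_rm_fixed_af` — HWE + random mating with the allele-2 frequency
  fixed externally;
* `hwe_rm_free_af` — HWE + random mating, allele frequency estimated;
* `pae` — parental allelic exchangeability, `mu3 = mu4`;
* `mating_symmetry` — six freely estimated mating-type parameters
  `mu1..mu6`.

The `mu` parameters are identified only up to scale; the optimiser fixes
`mu6 = 1` and reported values are rescaled so the implied ordered-pair
frequencies sum to one.  Under HWE, `mu = (p^4, p^3 q, p^2 q^2, p^2 q^2,
p q^3, q^4)` with `p` the risk-allele frequency — a testable identity that
also shows `pae` and `mating_symmetry` nest HWE.

Control samples (unrelated controls, parents of controls, control/mother
or control/father duos) are modelled as random population samples of
unknown disease status; their cell tables are the null-model collapses.
Genuinely unaffected controls are acceptable only for a rare disease; no
common-disease correction is implemented.

## Identifiability and parameterisation dialects

With trios, seven relative-risk parameters are identifiable; the package's
canonical identification fixes `Ip = g12 = g21 = 1` and estimates
`(R1, R2, S1, S2, Im, g11, g22)`.  If the fixing assumption fails these
estimates are composites (`R1*Ip`, `R2*Ip^2*g12`, `S1`, `S2*g21`,
`Im/Ip`, `g11`, `g22/(g12*g21)`), which `identifiable_set()` reports.  A
mirror convention fixing `Im` is selectable.  Duos alone support at most
six free parameters (seven cells minus normalisation), and the joint
estimability of five risk parameters plus a free allele frequency must be
established at the fit level; `fit_model()` flags an information-matrix
condition number above `1e10` and suppresses standard errors.

The same penetrance-table family has been published under several
parameterisations ("dialects"): the original and later imprinting
conventions, the two maternal-fetal genotype incompatibility (MFG) forms,
the diallelic matching model, the log-scale additive/dominance form, the
saturated seven-cell model, and the maternal/paternal transmission-factor
form.  `famlik` implements each dialect *by its table*: conversions solve
one table against the other parameter set and verify the result cell by
cell at `1e-10` relative tolerance.  This was a deliberate design choice:
the closed-form relations between the imprinting conventions are fragile
to transcribe (for instance, the later convention's `R2` equals the
original convention's `R2 * Im`), and numerical table-matching cannot
drift from the definitions.  Dialects without imprinting terms represent
only origin-symmetric tables and reject others; the saturated dialect is
matched on the seven observable cells.  Likelihood maximisation is
invariant to the dialect whenever two dialects span the same table family
— the suite asserts equality of maximised log-likelihoods to `1e-6`
across the four imprinting conventions, across MFG-1B versus the default
two-interaction model, and across the two saturated identifications.

## Fitting

`fit_model()` maximises the joint multinomial log-likelihood over
log-transformed risk factors (logit allele frequency, log `mu`) with a
quasi-Newton optimiser (`nlminb`, relative tolerance `1e-10`, up to three
deterministically perturbed restarts — no RNG involvement, so fits are
seed-independent).  Standard errors come from the inverse observed
information (`optimHess`) on the working scale.  Cells whose fitted
probability underflows are floored at `1e-300` inside logarithms solely to
keep the objective finite.  The likelihood-ratio test profiles nuisance
parameters under both hypotheses and counts only free risk parameters as
degrees of freedom; `model_sequence()` ranks specifications by
`AIC = 2k - 2 logL` with `k` the total number of free parameters, breaking
ties in favour of the model listed first.

The numbered method presets follow the standard analysis menu: method 0
is the prospective logistic comparator (implemented directly by
Newton-Raphson on the aggregated binomial likelihood, with imprinting
covariates given fractional weight `A1` — plugged in from the control
duos — in the ambiguous double-heterozygote cell); method 1 fixes the
allele frequency; methods 2/2a/2b use family data alone; methods 3-9 add
controls, parents of controls, or control duos under progressively weaker
assumptions.

## The synthetic-data generator

`simulate_structure()` draws parental genotypes from HWE + random mating
(or a mixture of sub-populations), transmits alleles Mendelianly with
parental origin recorded, and accepts a family as a case family with
probability equal to its ordered-origin penetrance (rejection sampling).
Control-side structures are unconditional population draws.  The
mechanism is intentionally independent of the cell-table algebra, so
goodness-of-fit of simulated counts against the model tables is a genuine
two-route check, not a tautology.

The generator's defaults are the canonical study conditions: scenarios
A-J all use risk-allele frequency 0.3 and baseline penetrance 0.1 with
effect sizes 1.5/2.25 (main effects), 1.8 (imprinting) and 0.5
(interactions); the feasibility ceiling is scenario F's largest cell,
`0.1 x 2.25 x 2.25 x 1.8 = 0.911`.  The stratified null uses two
sub-populations with baseline risks 0.1 and 0.05 and allele frequencies
0.3 and 0.15; the mixing proportion is not dictated by those conditions
and defaults to 0.5 (configurable).  Replicate `r` of any study uses seed
`base_seed + r`.

What the generator does *not* emulate: genotyping error, missing
genotypes within a collected structure, X linkage, linked mother/child
loci in LD, and ascertainment beyond single-proband sampling.  Passing
tests therefore demonstrate correctness of the estimator under its own
sampling model, not robustness to those real-data features.

## Simulation harness and problem sizes

`run_study()` reports per-parameter means/SDs of log estimates, mean
estimated standard errors, the total-SE summary, and rejection
proportions at 0.05/0.01/0.001 with binomial Monte-Carlo standard errors;
failed or flagged fits are counted, never silently dropped.
`misspecification_study()` adds a deterministic reference — the analysis
model fitted to the exact expected cell counts — which is the package's
own oracle for "expected estimates under misspecification".

The shipped test and acceptance runs use deliberately chosen problem
sizes: 200 replicates for parameter-recovery means (Monte-Carlo SE of the
`R1` mean about 0.015 on the log scale), 2,000 replicates for type-I
error at 0.05 (binomial SE 0.005), 400 replicates for the directional
stratification comparisons (where the inflation to be detected is large:
roughly 0.10 for HWE-assuming trio analyses and above 0.3 for duo-based
analyses), 40-60 replicates for total-SE orderings and misspecification
means (differences of 5-40% against Monte-Carlo SEs of a few percent),
and goodness-of-fit at 100,000 simulated families.  These sizes make each
directional or equality assertion resolvable at three Monte-Carlo
standard errors.

## Known limitations

* Covariates (including stratification principal components) cannot be
  incorporated in a multinomial framework; sampling from a homogeneous
  population, or using the mating-symmetry trio analysis (the only method
  robust to stratification), is the supported remedy.
* Standard errors require an invertible observed information; saturated
  or near-saturated duo-only specifications are flagged instead.
* The logistic comparator treats cell-level covariates as fixed; its
  fractional imprinting coding uses a plug-in allele frequency from the
  control duos, so its imprinting estimates inherit that approximation.
* The 2-df case-control power calculation is a noncentral chi-square
  approximation cross-checked against Monte Carlo, not an exact
  reproduction of any particular power-calculator convention.
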