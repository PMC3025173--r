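# famlik

Multinomial likelihood models for disentangling child-genotype, maternal-
genotype, parent-of-origin (imprinting) and maternal–fetal interaction
effects on disease risk, from case/parent trios, case/mother duos, other
partial nuclear-family structures, and optional control samples.

## Why

In a plain case–control comparison, a maternal genotype effect, an
imprinting effect, and a child genotype effect can produce identical
apparent genotype relative risks, because mothers and children share
alleles.  Genotyping mothers (duos) or both parents (trios) of affected
children makes these mechanisms separable.  `famlik` models the observed
genotype-combination counts of each family structure as a multinomial
whose cell probabilities follow from a multiplicative penetrance model

    P(disease) = alpha * R1/R2 (child copies) * S1/S2 (mother copies)
                 * Im/Ip (parental origin) * g_ij (interaction),

combined with a mating-type nuisance model (Hardy–Weinberg + random
mating with fixed or free allele frequency, parental allelic
exchangeability, or six free mating-type parameters), and maximises the
product of the per-structure multinomial likelihoods directly.  The
fifteen observable trio cells — with the ambiguous double-heterozygote
cell being the *sum* of its two origin-specific halves — collapse
row-wise to every partial structure (7-cell duos, 3-cell genotype
samples, 6-cell mating-type samples), so missing fathers, missing
mothers, or missing children are handled by the same likelihood.

The package also provides: exact conversions between the published
parameterisation "dialects" (original/later imprinting conventions,
MFG incompatibility models, matching, additive/dominance, saturated),
verified cell-by-cell against the induced penetrance tables; an
apparent-genotype-relative-risk calculator (cases vs controls, and
mothers of cases vs mothers of controls) by exact enumeration; a
rejection-sampling synthetic family generator; and a replicated
simulation harness for bias, power and type-I error, including
population-stratification and model-misspecification studies.

## Worked example

Simulate 500 case/mother duos plus 500 parents-of-control units under a
joint child + maternal effects model (risk-allele frequency 0.3,
baseline penetrance 0.1, R1 = S1 = 1.5, R2 = S2 = 2.25), then estimate
all four relative risks with the allele frequency estimated from the
parents of controls ("method 4"):

```r
library(famlik)
scen <- scenario_table("C")
duos <- simulate_structure("case_mother_duo", scen, 500, seed = 1)
poc  <- simulate_structure("parents_of_control", scen, 500, seed = 2)
fit  <- fit_method(4, duos, poc, free = c("r1", "r2", "s1", "s2"))
fit
#> Multinomial family-likelihood fit (dialect: default )
#>   max log-likelihood -1675.5245 (null -1712.1333), regime hwe_rm_free_af
#>  parameter estimate     se
#>         r1    1.387 0.1614
#>         r2    2.420 0.3924
#>         s1    1.364 0.1586
#>         s2    2.263 0.3688
```

All four estimates sit within about one standard error of their
generating values; the 4-df likelihood-ratio test of the joint null
(`statistic = 73.22, p = 4.75e-15`) rejects decisively.  The classic
confounding observation — a pure maternal-imprinting factor of 2 looks
exactly like child genotype relative risks (1.5, 2) to a naive
case-control analysis:

```r
apparent_grr(risk_parameters(im = 2), a2 = 0.3)
#> rr12 rr22
#>  1.5  2.0
```

## Command line

A thin CLI over the same functions ships in `inst/cli.R`:

```sh
cli=$(Rscript -e 'cat(system.file("cli.R", package = "famlik"))')
Rscript "$cli" scenarios
Rscript "$cli" simulate --scenario C --structure case_mother_duo \
        -n 500 --seed 1 --out counts.tsv
Rscript "$cli" fit --counts counts.tsv --method 2 --out results.tsv
Rscript "$cli" grr --im 2 --a2 0.3 --power
Rscript "$cli" tabulate --ped study.ped --map study.map --snp rs1 \
        --out counts.tsv
```

Count files are TSVs with columns `snp_id  structure  cell  count`,
using the frozen cell orderings reported by `cell_labels()`; PED/MAP
pedigrees can be tabulated into them with `tabulate_pedigree()`.

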