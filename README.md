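# gdtpoly

Within-family score tests of genetic association for **polytomous
phenotypes** (K ≥ 2 unordered categories) in extended pedigrees, with
support for **two-locus models** — a generalization of the Generalized
Disequilibrium Test (GDT) built from phenotype-discordant relative
pairs.

The package is aimed at statistical geneticists analysing family
samples in which a dichotomous disease *Y₂* and a dichotomous
endophenotype *Y₁* (e.g. a cognitive deficit accompanying major
psychosis) are crossed into a four-category phenotype, and where a
known risk locus can be exploited to detect a second, interacting
locus.  Because every statistic is a contrast of genotypes *within*
families, the tests are immune to population stratification, which
inflates population-level (GEE/Wald) analyses.

## The model and the tests

For subject *i*, with genotypes coded as allele proportions
X ∈ {0, ½, 1} at up to two unlinked loci,

    log( P[Yᵢ = k | Xᵢ] / P[Yᵢ = K | Xᵢ] ) = μₖ + β̃ₖ′ Xₖᵢ ,   k < K,

with terms drawn from {X₁, X₂, X₁X₂, X₁(1−X₂)} and coefficients either
category-specific or shared.  A coefficient's family score contribution
is the (optionally weighted) sum of pairwise genotype contrasts between
members in its category and members outside it,

    S⁽ʰ⁾ = Σ_{i∈Eₐ} Σ_{j∉Eₐ} C_ij ( Xᵢ⁽ʰ⁾ − Xⱼ⁽ʰ⁾ ) ,

its variance is estimated from identity-by-descent sharing proportions
π (or 2φ, twice the kinship, when no linkage is assumed), and subsets of
coefficients are tested jointly with T = S′ v[S]⁻¹ S ~ χ²_rank.  For
conditional tests (locus 2 given locus 1) the free coefficients are
absorbed into pair weights C_ij derived from a pooled multinomial
nuisance fit.  Presets cover the full two-locus model (6-df conditional
test "cpoly"), the one-locus polytomous model, the
endophenotype-to-disease interaction model (2-df test of (βe, β33)),
the single interaction coefficient β33, the dichotomous GDT variants
(GDT, GDTc, GDTe), the dichotomous two-locus tests (cdisease, cendo)
and a GEE-based Wald comparator.

A gene-dropping simulator reproduces the evaluation design: 3-generation
16-member pedigrees, Hardy–Weinberg founders (risk allele frequencies
0.1 and 0.3), a two-step phenotype model with polygenic liability and
familial aggregation, ascertainment on an affected first-cousin pair, a
null marker in linkage equilibrium with (but linked to) the causal
locus-2 variant, and an optional two-population mixture.

## Worked example

```r
library(gdtpoly)
sc <- simulation_scenario()       # Hardy-Weinberg founders, RAFs 0.1/0.3
round(analytic_prevalence(sc), 4)
#>       disease endophenotype
#>        0.0076        0.1281

set.seed(1)
sim <- simulate_sample(sc, n_families = 100)   # ascertained families
smp <- sim_to_samples(sim, tested = "null")    # test the null marker

summary(gdt_test(smp, design_one_locus(4L), weights = "equal",
                 kernel = "model"))
#> Within-family polytomous score test (onelocus)
#> tested: bt1, bt2, bt3
#> weights: equal, null: assoc, kernel: model, informative families: 100/100
#> T = 1.7105, df = 3, p = 0.6346
#>
#> Per-coefficient statistics:
#>  label      S    var       Z      p
#>    bt1  4.219 13.247  1.1591 0.2464
#>    bt2 -1.562  6.410 -0.6172 0.5371
#>    bt3 -1.375  7.672 -0.4964 0.6196

gdt_test(smp, design_full_two_locus(), weights = "eq6",
         kernel = "empirical")
#> Within-family polytomous score test (full2locus)
#> tested: b12, b13, b22, b23, b32, b33  | free: b11, b21, b31
#> weights: eq6, null: assoc, kernel: empirical, informative families: 100/100
#> T = 1.6528, df = 6, p = 0.9487
```

The tested marker is linked to, but not associated with, the phenotype:
the variance uses the realized IBD sharing (`null: assoc`) and neither
the 3-df one-locus test nor the 6-df conditional test rejects.  The
per-coefficient table shows each score S, its variance, and the
corresponding Z statistic; `Eₐ` membership, weights and kernel choices
are recorded in the result.  Marker scans on Merlin/QTDT files
(`gdt_scan()`, or the `inst/cli/gdtpoly-cli.R` command line with
subcommands `simulate` / `test` / `type1` / `power`) emit one TSV row
per marker per test.

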