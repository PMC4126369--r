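---
title: "Within-family score tests for polytomous phenotypes at two loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Within-family score tests for polytomous phenotypes at two loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdtpoly)
```

## The problem and the model

Family studies of psychiatric and other complex diseases often measure,
besides the disease itself, a heritable *endophenotype* (for instance a
cognitive deficit) thought to lie closer to gene action.  Crossing a
dichotomous disease status $Y_2$ with a dichotomous endophenotype status
$Y_1$ yields a four-category unordered phenotype, and large multiplex
pedigrees provide the discordant relative pairs that carry the
association information.  Population-level tests are vulnerable to
population stratification; tests built from *within-family* genotype
contrasts are not.

gdtpoly implements score tests of the coefficients of the polytomous
logistic model

$$
\log \frac{P[Y_i = k \mid X_i]}{P[Y_i = K \mid X_i]}
  = \mu_k + \tilde\beta_k' X_{ki}, \qquad k = 1, \dots, K - 1,
$$

where $X_{ki}$ collects allele-proportion terms at up to two unlinked
marker loci — main effects $X_1$, $X_2$, the product $X_1 X_2$ and the
gated term $X_1(1 - X_2)$ — and coefficient *labels* may be distinct per
category or shared across categories.  Genotypes are coded as the
proportion of a counted allele in the genotype, $\{0, \tfrac12, 1\}$.
With $K = 2$ and a single marker the machinery reduces exactly to the
Generalized Disequilibrium Test (GDT), whose family score contribution is
the mean pairwise genotype contrast between affected and unaffected
members, $S = \frac1n \sum_{i \in E} \sum_{j \notin E} (X_i - X_j)$.

For a label attached to one category $a$, the family contribution to the
score is the weighted contrast
$S^{(h)} = \sum_{i \in E_a}\sum_{j \notin E_a} C_{ij}
(X^{(h)}_i - X^{(h)}_j)$ over all pairs of members in and outside the
category; shared labels sum their per-category contrasts.  Families in
which every phenotyped, genotyped member falls in one category contribute
exactly zero and are flagged non-informative.

### Conditional tests and pair weights

To test a coefficient subset (for instance all locus-2 coefficients given
an established locus-1 association), the remaining coefficients are free
under the null.  Subject pairs are then weighted through a nuisance fit:
a pooled multinomial logit of $Y$ on the free predictors (the maximum
likelihood fit, identical to a GEE with independence working
correlation), whose estimates $\tilde\alpha$ enter
$u_{ij} = (X^{(c)}_i - X^{(c)}_j)'(\tilde\alpha_{Y_i} -
\tilde\alpha_{Y_j})$ and the two supported weight expressions

$$
C_{ij} = \frac{2}{N\,(1 + e^{u_{ij}})}
\qquad\text{("eq6")}, \qquad
C_{ij} = \frac{8\,e^{u_{ij}}}{N\,(1 + e^{u_{ij}})^3}
\qquad\text{("eq7")}.
$$

The variability of $\tilde\alpha$ is deliberately neglected — the weights
are treated as fixed — which makes the conditional tests somewhat
conservative; the Type-I-error harness reproduces that behaviour.  The
normalizer is taken as $N = n$, the family's retained member count: the
weight expressions leave $N$ free, and this choice makes both
expressions collapse exactly to the unweighted $1/n$ scaling when
$\tilde\alpha = 0$, which is also the identity our tests assert.  When
*all* labels are tested there are no free predictors and equal weights
apply.

### Variance estimation

Conditional on the observed phenotypes, the randomness in a family score
comes from the transmission of alleles.  For main-effect terms the
covariance kernel between members is the identity-by-descent sharing
proportion at the locus, $\mathrm{Cov}(X_i, X_k) = \pi_{ik}\sigma^2$;
under the *association-only* null (linkage allowed) the realized
$\pi$ must be used, while under the *no linkage and no association* null
(or when IBD is unknown) $\pi$ is replaced by twice the kinship
coefficient.  Product terms use the elementwise product
$\pi_{1,ik}\pi_{2,ik}$, a main term and a product term sharing a locus
use that locus' kernel, and main terms at unlinked loci are
uncorrelated.  The quadruple sum over pairs of pairs is computed in a
grouped $O(n^2)$ form (contrast vectors $s$ with
$\mathrm{Var} = \sigma^2 s' \Pi s$); the test suite checks it against a
naive $O(n^4)$ implementation to $10^{-10}$.

The term variance $\sigma^2$ is estimated from the within-family sums of
squares.  Because relatives' genotypes are correlated, the naive
denominator $\sum_f (n_f - 1)$ is biased: under the kernel model,
$E\left[\sum_i (x_i - \bar x)^2\right] = \sigma^2\,(\mathrm{tr}\,\Pi -
\mathbf{1}'\Pi\mathbf{1}/n)$.  The estimator therefore pools numerators
over families and divides by the summed kernel-corrected degrees of
freedom (which reduce to $n - 1$ for unrelated members), using only
score-contributing (informative) families so that adding a
non-informative family changes no statistic.  This choice was validated
by null calibration: with the naive denominator the single-locus tests on
simulated 16-member pedigrees reject at roughly three times the nominal
level, with the corrected one they are nominal.

For joint tests two variance-covariance kernels are available.  The
*model-based* kernel applies the expressions above to every label pair;
it requires the pooled $\sigma^2$ above.  The *empirical* kernel
$\sum_f S_f S_f'$ is consistent because each family contribution has
expectation zero under either null, and it is additionally robust to
between-family heterogeneity of the marker variance — under the
two-population mixture the tested marker's allele frequency, and hence
$\sigma^2$, differs by population, and a common pooled $\sigma^2$
misallocates variance across families (a 500-replicate check showed the
pooled model kernel rejecting at 0.086 for the 3-df joint test where
the empirical kernel gives 0.052).  The default is therefore the model
kernel for single-label tests (where the realized IBD enters the
variance directly) and the empirical kernel for every joint test
spanning several labels, including the conditional tests that mix main
and product terms (cpoly, $(\beta_e, \beta_{33})$, cdisease/cendo),
whose cross-term model kernels rest on an approximation anyway.  The
kernel used is recorded in every result.  Singular covariance matrices are handled by a rank-revealing
pseudo-inverse with degrees of freedom equal to the numerical rank
(eigenvalues above $10^{-8}$ of the largest).

## Comparators

The dichotomous GDT variants reuse the same machinery with $K = 2$:
`GDT` tests the disease status, `GDTe` the endophenotype, and `GDTc` the
disease within the endophenotype-impaired subset (other members treated
as phenotype-unknown; variance components are re-estimated within the
subset, which *is* the analysis sample).  `cdisease`/`cendo` are 2-df
conditional tests of $\{\eta_2, \eta_3\}$ in the usual dichotomous
two-locus logistic model.  The GEE-based Wald comparator fits the pooled
multinomial model and uses the family-clustered sandwich variance
$B^{-1} M B^{-1}$; it consumes between-family information and is the
test that population stratification breaks.

## The simulator

`simulate_sample()` reproduces a two-step generating process on a fixed
3-generation, 16-member pedigree: two grandparents, four of their
children each with an unrelated married-in spouse, and six grandchildren
(two in each of three couples), giving six founders and twelve
first-cousin pairs.  Founder alleles are drawn under Hardy–Weinberg
equilibrium at risk allele frequencies 0.1 (locus 1) and 0.3 (locus 2)
and transmitted by Mendelian gene dropping, with founder-allele labels
tracked so that realized IBD sharing is exact.

Phenotypes follow the polytomous model of `example_coefficients()`
(endophenotype odds ratio 2 for locus 1; disease-with-impairment
interaction odds ratio 16), which implies a disease prevalence of 0.0076
and an endophenotype-impairment prevalence of 0.128
(`analytic_prevalence()` enumerates the nine genotype classes).  Step 1
draws $Y_{1i}$ from its polytomous marginal; step 2 draws the disease
from a Bernoulli with logit
$\gamma(X_i, Y_{1i}) + U_i + \alpha \sum_{h \ne i} (Y_{1h} - \nu)
\phi_{ih}$, where $\gamma$ is the within-stratum log-odds implied by the
polytomous model (the unique choice making the $\sigma^2 = \alpha = 0$
case coincide exactly with the polytomous model — a distributional
identity the tests verify on $10^5$ draws), $U \sim N(0, \sigma^2\Phi)$
is a polygenic liability component drawn once per family, and the
$\alpha$ term couples a member's disease risk to relatives'
endophenotype status in proportion to kinship.

The values of $\sigma^2$, $\alpha$ and $\nu$ are not pinned down by any
published number; the package fixes $\sigma^2 = 1$ (a moderate polygenic
dependence on the logit scale), $\alpha = 1$, and $\nu = 0.128$, the
endophenotype population prevalence, so that an average relative
contributes no shift.  Type I error of the valid tests is insensitive to
these choices; power levels (but not the qualitative ordering) depend on
them.  All three are exposed in `simulation_scenario()`.

Families are rejection-sampled until the required number contain at
least one first-cousin pair with both members diseased — the
ascertainment rule of a multiplex family study.  Under the default
parameters only about 0.1% of families qualify, so the batch gene-drop
runs in compiled code.  A *null marker* at locus 2 shares the locus-2
segregation (the same meioses) but receives independently drawn founder
alleles: linked to, but in linkage equilibrium with, the causal variant.
Testing it probes the association-only null in the presence of linkage,
which is why the realized $\pi$ matters there.  Under the two-population
mixture scenario the ascertained sample contains equal numbers of
families from two populations whose intercepts are shifted by
$\mp 0.5$ (disease prevalences 0.005/0.012, endophenotype 0.082/0.194)
and whose null-marker allele frequency is 0.1 vs 0.5 — population
structure at the tested marker.  Each population is rejection-sampled
separately to its half of the sample; because the higher-prevalence
population ascertains far more easily, a pre-ascertainment coin flip
would instead yield a sample dominated by it and a much weaker
confounding contrast.

What the generator does *not* emulate: genotyping error, missing data,
variable pedigree structures within a sample, phenocopies or
liability-threshold traits, and linkage disequilibrium between the two
model loci.  Passing calibration here therefore shows correctness of the
statistical machinery under the stated model, not robustness to those
real-data features.

## Evaluation harness and numerical choices

`run_type1()` / `run_power()` simulate replicate samples (default 100
ascertained families each) and tally rejections at nominal levels 0.01
and 0.05 with binomial standard errors.  Both targets of a replicate —
the null marker (Type I error under linkage) and the causal locus-2
variant (power) — can be tested on the same simulated families.  The
acceptance checks use 250 replicates of 100 families, a scale at which
a three-standard-error band around the reference rejection rates is
about $\pm 0.04$; the per-replicate seeds derive from one master seed
through a counter-based splitter and are recorded in the report.  The
harness battery uses expression-6 weights for conditional tests (the
two expressions give nearly identical behaviour), equal weights for the
unconditional single-locus tests, the model-based kernel with realized
IBD for single-label tests, and the empirical kernel for the joint
tests.

Further numerical conventions: the nuisance Newton iterations stop when
the largest score component is below $10^{-8}$ or the relative
log-likelihood change is below $10^{-10}$, with a ridge penalty of
$10^{-6}$ and a warning on apparent separation; a negative variance
estimate beyond $-10^{-10}$ (an IBD/kinship inconsistency) is an error;
missing IBD under the association-only null falls back to $2\phi$ with a
mandatory warning; scans apply no multiple-testing adjustment and report
raw p-values.  In the simulator's distributional-identity check,
genotype-class cells with expected counts below 5 are pooled before the
three-standard-error binomial comparison, since the normal approximation
is meaningless for Poisson-scale counts.

## Known limitations

Score tests provide no effect estimates.  Conditional tests remain
conservative because the nuisance variability is neglected.  The
covariance between a main term and an interaction term at a shared locus
uses an approximate kernel (hence the empirical default for such joint
tests).  The one-sided restricted alternative for the
endophenotype-to-disease conditional test (both coefficients of common
sign) is noted but not implemented.  The GEE Wald comparator with
cluster-robust variance is finite-sample liberal for joint tests with
100 clusters even without stratification — one more reason it serves
only as a comparator.

## A worked example

```{r example, eval = FALSE}
sc <- simulation_scenario()
set.seed(1)
sim <- simulate_sample(sc, n_families = 100)
smp <- sim_to_samples(sim, tested = "null")

# joint one-locus test of the null marker (empirical covariance kernel)
gdt_test(smp, design_one_locus(4L), weights = "equal")

# single-coefficient test with the realized-IBD variance
gdt_test(smp, design_one_locus(4L), tested = "bt3", weights = "equal",
         kernel = "model")

# 6-df conditional test of locus 2 given locus 1
gdt_test(smp, design_full_two_locus(), weights = "eq6",
         kernel = "empirical")
```
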