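---
title: "Quantitative genetics of honeybee queen traits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative genetics of honeybee queen traits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apisqg)
```

## The problem

Commercial queen breeders record morphological and reproductive traits
on mated queens — body and tagma weights, tagma widths, wing length,
spermatheca diameter and volume, ovariole counts, stored-sperm counts —
because these proxy queen quality and, ultimately, colony performance.
Estimating heritabilities and genetic correlations for such traits
requires (i) additive relationships among queens under honeybee
genetics, which differ from the usual diploid case, and (ii) REML
variance-component estimation under an animal model.  `apisqg`
implements both, plus a synthetic breeding-population generator that
emulates a two-season commercial design, so the whole pipeline is
testable end to end without proprietary breeder records.

## Haplodiploid relationships with drone-group pseudo-sires

Honeybee males (drones) are haploid: a drone is genetically a single
maternal gamete.  A queen mates once, at a mating station, with a group
of `D` drones whose mothers are the station's drone-producing queens
(DPQs).  Paternity of her daughters is therefore shared across the
group, which the pedigree represents as a single *pseudo-sire*: the
sire group.

Kinship (coancestry) `phi(i, j)` is the probability that two alleles,
one sampled from each queen, are identical by descent; the numerator
relationship matrix is `A = 2 phi` off the diagonal with `a_ii = 1 +
F_i`.  For a queen `i` with dam `d` and sire group `S` with DPQ mothers
`M_1 .. M_m`:

* `phi(S, j) = mean_k phi(M_k, j)` for any non-descendant `j` — a
  random drone's allele is a random maternal gamete from a uniformly
  drawn DPQ mother;
* `phi(i, j) = [phi(d, j) + phi(S, j)] / 2`;
* `F_i = phi(d, S)`, and `phi(i, i) = (1 + F_i) / 2`;
* two daughters of the *same* mating also share their paternal drone
  with probability `1/D`, and a drone passes the identical genome to
  every offspring; their paternal-gamete co-kinship is therefore
  `1/D + (1 - 1/D) * phi_pp(S)`, where `phi_pp(S)` averages
  `psi(M_k, M_l)` over ordered mother pairs with
  `psi(M, M) = (1 + F_M)/2`.

Two design rules follow from drone biology and are enforced by the
pedigree validator:

* drones are drawn uniformly and independently across the group's
  mothers (two distinct drones share a mother with probability `1/m`);
* a drone mates once, so one sire group belongs to exactly one mating:
  a group id reused under a second dam raises `mating_reuse_error`.
  The second rule is not only biology; reusing one drone set across
  dams or generations induces same-drone co-ancestry that no pairwise
  recursion can propagate, and the gene-dropping oracle (below)
  demonstrates the mismatch within a few hundredths if it is allowed.

Classic checks, both exercised in the tests: super-sisters (same dam,
`D = 1`) have `a = 0.75`; sisters from a 12-drone group with 12
unrelated founder DPQ mothers have
`a = 2 * (1/4) * (1/2 + 35/288) = 179/576 ~ 0.311`.

The matrix is computed by a dense `O(n^2)` tabular pass in topological
order; at the few hundred to few thousand queens this package targets,
sparse-inverse machinery would add nothing but complexity.

### Gene dropping as the independent oracle

`gene_dropping()` simulates transmission directly: founder queens carry
two unique alleles; each replicate instantiates every group's `D`
drones once (mother drawn uniformly, then one of her two alleles) and
every daughter receives a random dam allele plus the full genome of a
uniformly drawn drone.  Kinship is the IBD probability of two randomly
drawn alleles, averaged over replicates.  The recursion and the
Monte-Carlo estimate agree elementwise to within Monte-Carlo error
(about 0.002 at 2e5 replicates on ~50-queen pedigrees); the test suite
asserts agreement within 0.02.

## The animal model and REML

Each trait is modelled with one record per queen as

    y = mu + w_i + a_j + e_jk

where `w_i` is the fixed effect of the week-of-year class in which the
queen was harvested (the classes combine week and year, so no separate
year effect is fitted), `a ~ N(0, sigma2_a A)` and
`e ~ N(0, sigma2_e I)`.  The restricted log-likelihood

    l_R = -1/2 [ (n - p) log 2pi + log|V| + log|X' V^-1 X| + y' P y ]

with `V = sigma2_a A + sigma2_e I` is maximized over `(log sigma2_a,
log sigma2_e)` by quasi-Newton ascent with analytic gradients.  A
single spectral decomposition of `A` per dataset turns every likelihood
evaluation into diagonal algebra, so hundreds of refits on one design
are cheap.  Numerical contract:

* variances are floored at `1e-8` of the phenotypic variance; an
  estimate at the floor (or cap) sets `boundary = TRUE`;
* convergence to `factr = 10` (about 1e-15 relative) with a
  derivative-free Nelder-Mead fallback on the rare line-search failure;
* standard errors come from the observed information: central finite
  differences of `l_R` on the component scale, relative step `1e-4`;
* week-class designs use reference coding with an explicit full-rank
  check; `l_R` is invariant to the coding, which the tests verify by
  relabelling;
* with `A = I` and single records only `sigma2_a + sigma2_e` is
  identified.  Rather than trusting finite-difference Hessian
  eigenvalues, the fit probes `l_R` directly along the exchange
  direction `(+delta, -delta)`; a flat probe sets
  `identifiable = FALSE` with a warning.

Bivariate fits estimate 2x2 `G` and `R` through unconstrained Cholesky
factors (log diagonals), which keeps both matrices positive definite
without explicit constraints, by Nelder-Mead with restarts until the
objective stabilizes.  With complete records the spectral trick reduces
`V` to 2x2 blocks; with trait-wise missingness `V` is assembled densely
over the observed (queen, trait) cells only — cell-level deletion, no
imputation.  A queen missing both traits drops out entirely.

Derived quantities use the delta method on the observed-information
covariance: `h2 = sigma2_a / (sigma2_a + sigma2_e)`,
`r_g = g12 / sqrt(g11 g22)`,
`r_p = (g12 + r12) / sqrt((g11 + r11)(g22 + r22))`.  `r_g` is clamped
to `[-1, 1]` with `clamped = TRUE` reported, and is returned as missing
with a reason when either genetic variance sits at the zero boundary.
The delta-method SE of `h2` agrees with a 200-replicate parametric
bootstrap within 20% in the tests.  Whether any of the original study's
estimates hit solver constraints is not reported anywhere; the
per-cell `boundary`/`nonconverged` flags make such events visible in
reproductions.

## What the generator emulates — and what it does not

`breeding_design()` defaults encode the study population's structure:
147 phenotyped queens, 70 in 2017 from 10 maternal lines and 77 in 2018
from 7 lines, 6 + 9 weekly harvest classes, matings of `D = 12` drones,
and 12 DPQ colonies per year (the station hosted 12–15; the count is a
parameter).  Maternal lines "shared common ancestors", with no further
detail published; the generator implements a configurable common
grand-dam generation (`shared_ancestor_depth`, default 1) with lines
assigned round-robin, so roughly every two lines share a grand-dam and
all lines connect through the founder drone pool.  Queens per line are
split as evenly as possible (70/10 and 77/7 are exact), an assumption
the source leaves open.

`default_trait_model()` calibrates 11 simulated traits to the published
marginals (means and SDs in mg, mm, µl and counts) and heritabilities,
with genetic correlations set to the published estimates and residual
correlations backed out from the phenotypic ones via
`sigma_e12 = r_p sigma_p1 sigma_p2 - sigma_a12`.  Those published
estimates carry sampling errors up to ~1 and do not form PSD matrices;
both correlation targets are projected to the nearest PSD correlation
matrix (`Matrix::nearPD`), so realized parameters are close to, not
identical with, the printed points.  Spermatheca volume is *derived*,
not simulated: three replicate diameter measurements (replicate noise
SD 0.05 mm, emulating the organ's non-sphericity) are averaged and
cubed through `v = (pi/6) d^3`.  At the published diameter mean/SD the
closed-form Gaussian cube-transform correlation between diameter and
volume is

    corr(d, v) = 3(mu^2 + s^2) / sqrt(9 mu^4 + 36 mu^2 s^2 + 15 s^4)
               ~ 0.982 at mu = 1.32, s = 0.18,

which both the raw simulation and the bivariate-fit `r_p` reproduce in
the tests.  A related published claim — that the sphere transform
scales the phenotypic variance by `4/3 pi` "without affecting the error
variance" — is not dimensionally coherent for a cubic transform (the
volume variance depends on the diameter mean as well as its variance),
so the package documents the empirical behaviour instead of encoding
that claim as an invariant: on derived volumes, heritability rises
relative to the diameter because cubing amplifies the shared (genetic)
signal more than the replicate-level noise, and the fitted
diameter–volume `r_p` exceeds 0.97.

Week effects are *simulated* as Gaussian draws with SD
`tau * sigma_p` per trait (`tau = 0.3` by default — seasonal rearing
effects of moderate size; any generating values are absorbed because
the model estimates week classes as fixed effects).  Sperm count is
missing at rate 4/147, mirroring the published N = 143.  Internal
defects (abnormal intestinal tract 16%, ovary melanosis 9%, enteroliths
8%, ovary atrophy 2.7%, spermatheca anomalies 0.5%) are independent
Bernoulli flags with no causal link to the quantitative traits.

Not emulated: colony-level performance, queen survival, year-specific
measurement protocols (image analysis vs caliper), defect aetiology,
worker-group phenotypes, and any selection that shaped the real
population.  Passing tests therefore show that the *estimation
machinery* is correct under the stated generative model, not that the
published point estimates would replicate on new field data — with 147
queens their standard errors (0.26–0.39 on heritabilities) dominate, as
the single-realization runs in `analysis/04_genetic_parameters.R` make
concrete.

## Problem sizes and runtimes

Chosen so the whole suite re-runs comfortably on one CPU: oracle
equivalence on ~50-queen pedigrees at 2e5 gene-dropping replicates;
parameter recovery on 100 replicate populations of 500 queens (25
lines, 15 week classes) per heritability setting; the bivariate
cube-transform check at n = 2000; the full 12-trait, 66-pair matrix on
the 147-queen default population.  Each recovery replicate draws its
own pedigree, so the reported means average over pedigree realizations
as well as trait draws.

## Worked example

```{r example}
design <- breeding_design(years = "y1", lines_per_year = 10,
                          queens_per_year = 200, weeks_per_year = 5)
ped <- generate_pedigree(design, seed = 1)
A <- compute_kinship(ped)
model <- univariate_trait_model(h2 = 0.5, sigma2_p = 100)
pheno <- simulate_phenotypes(ped, A, model, design, seed = 2)
fit <- fit_univariate(pheno, A, "y")
heritability(fit)
```

## Known limitations

* Dense algebra bounds practical size at a few thousand phenotyped
  queens.
* Only queen-expressed, single-record traits are modelled; maternal,
  permanent-environment and worker-group effects are out of scope, as
  are BLUP breeding values for unphenotyped ancestors and multi-trait
  (>2) models.
* The generator's shared-ancestor depth is a stylized stand-in for an
  unpublished ancestral pedigree; absolute relationship levels between
  lines depend on it, though heritability recovery is insensitive to
  the choice.
* Delta-method SEs are first-order; near boundaries they understate
  uncertainty, which the `boundary` flag signals.
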