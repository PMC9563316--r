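---
title: "Models and methods for multi-environment-trial stability analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for multi-environment-trial stability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metstab)
```

## The problem

A multi-environment trial (MET) grows the same set of genotypes in
several locations under a randomized complete block design (RCBD) and
asks two questions per trait: which genotypes are genuinely superior,
and which keep their performance across environments. The two questions
pull apart exactly when genotype-by-environment interaction (GEI) is
large. `metstab` implements the standard analysis chain for this
setting — ANOVA and variance components, the AMMI bilinear model, GGE
biplots, a panel of stability indices, BLUP-based genotypic values, and
the WAASBY/MTSI multi-trait selection index — with a simulation module
that makes every stage verifiable against known truth. The package was
built with metabolite panels in mind (thousands of mass-feature traits
per grain sample), but nothing in it is specific to metabolomics.

## Data model

Observations live in a long table, one row per
`(genotype, environment, replicate, trait)`; `met_dataset()` validates
uniqueness of that key and keeps label order of first appearance.
Labels are whitespace-stripped but case-sensitive — silent case folding
hides data errors. Missing cells are an error, never imputed: every
method here assumes the complete balanced design the RCBD provides, and
an incomplete trial should be diagnosed, not papered over. The only
partial concession is REML variance estimation, which accepts unbalanced
data where the expected-mean-squares route refuses it.

## The simulator defines the reference conditions

`simulate_trait()` generates

$$y_{gjr} = \mu + \alpha_g + \tau_j + \sum_{k=1}^{K}\lambda_k a_{gk} t_{jk}
  + b_{jr} + \varepsilon_{gjr}$$

with sum-zero genotype and environment effects, a rank-$K$ bilinear
interaction whose score matrices have centred orthonormal columns
(exactly, by projection and Gram–Schmidt), block effects
$b_{jr}\sim N(0,\sigma_b^2)$ shared by all genotypes in a block (the
RCBD structure), and i.i.d. residuals — Gaussian by default, with a
variance-matched scaled-$t$ option for robustness work. Defaults mirror
a typical grain-metabolite trial: 11 genotypes, 5 environments, 3
replicates, grand mean 100, genotype effect SD 2, environment effect SD
4, singular values around 6, block SD 0.5, residual SD 1. Each truth
carries its seed, so datasets are reproducible, and
`simulate_multitrait()` records one truth per trait for later retrieval
(`get_truth()`). Multi-trait panels are independent across traits; the
simulator does not model trait correlation, spatial field trends, or
heteroscedastic environments, so passing tests demonstrate correctness
of the estimators, not robustness to those real-data features.

One sign convention matters for recovery tests: the first element of
each simulated genotype-score column is non-negative, and the AMMI fit
flips each axis so the largest-magnitude genotype score is positive.
Recovery is therefore asserted on $|\langle a_{\text{fit}},
a_{\text{true}}\rangle| = 1$, which is invariant to either convention.

## ANOVA, variance components, heritability

Per environment, `rcbd_anova()` fits genotype + block and estimates
$\sigma^2_g = (MS_G - MS_{res})/\eta_{Rep}$. Across environments,
`combined_anova()` partitions environment, block-within-environment,
genotype, GEI and residual. Because the interaction is treated as
random, genotype is tested against the GEI mean square, GEI against the
residual, and environment against block-within-environment. The EMS
estimators are $\sigma^2_{ge} = (MS_{GEI} - MS_{res})/\eta_{Rep}$ and
$\sigma^2_g = (MS_G - MS_{GEI})/(\eta_{Rep}\eta_{Loc})$; negative
estimates truncate to zero with a flag. The REML route fits
`value ~ environment + environment:replicate + (1|genotype) +
(1|genotype:environment)` in lme4 with optimizer tolerances tightened to
`1e-14` so that balanced-design agreement with EMS holds to about
`1e-8` relative — the default optimizer stops near `1e-6`. Whether the
published combined analyses treated environment as fixed or random is
rarely stated; we default to fixed environment (the EMS reading) and
expose `random_env = TRUE` in `fit_blup()` for the fully random
alternative.

Broad-sense heritability is
$H^2 = \sigma^2_g/(\sigma^2_g + \sigma^2_\varepsilon/\eta_{Rep})$ per
environment and
$H^2 = \sigma^2_g/(\sigma^2_g + \sigma^2_{ge}/\eta_{Loc} +
\sigma^2_\varepsilon/(\eta_{Loc}\eta_{Rep}))$ combined. Note the
combined value is not always below the single-environment value at
equal components: the error term is divided by $\eta_{Loc}\eta_{Rep}$,
which can outweigh the added $\sigma^2_{ge}/\eta_{Loc}$ term (the hand
cases 0.882 vs 0.857 show exactly this). What *is* guaranteed — and
what our tests assert — is that introducing $\sigma^2_{ge} > 0$ lowers
the combined $H^2$ relative to the no-GEI combined analysis.

A subtlety the test oracles account for: the simulator's interaction is
a *fixed* bilinear surface whose rows have zero means, so $MS_G$
contains no interaction variance. The random-GEI EMS genotype estimator
subtracts $MS_{GEI}$ anyway, giving it expectation
$\mathrm{var}(\alpha) - \sigma^2_{ge}/\eta_{Loc}$ under these
conditions. Monte-Carlo recovery checks test against that derived
expectation rather than the raw draw variance.

## AMMI

`fit_ammi()` takes the cell-mean matrix, removes the additive part
(grand mean, genotype means, environment means) and decomposes the
double-centred remainder $Z$ by SVD. Axis $k$ carries
$\theta_k = 100\lambda_k^2/\sum\lambda^2$ percent of the GEI sum of
squares; $\sum_k \lambda_k^2$ equals the GEI SS exactly, and retaining
all $p = \min(G-1, E-1)$ axes reconstructs the cell means to machine
precision. Axis significance uses Gollob degrees of freedom
$G + E - 1 - 2k$ with $F$ against the pooled replicate-level error mean
square — the common default where the testing method is not otherwise
specified. A constant (zero-GEI) matrix is flagged degenerate and
returns all-zero $\theta$ rather than 0/0.

Biplot coordinates follow the singular-value partitioning exponent $f$:
genotype scores $\lambda^f \gamma$, environment scores
$\lambda^f \delta$ for AMMI2 display (default $f = 0.5$, the symmetric
convention), while AMMI1 pairs mean performance with the first-axis
score. `ss_shares()` expresses environment, genotype, GEI and per-axis
SS as percentages of the replicate-level total, so the remainder is the
block + residual share.

## Stability indices

`stability_indices()` computes thirteen AMMI-based measures, all
"smaller = more stable", rank 1 best, average ranks on ties. With
$\gamma_{in}$ the genotype eigenvector entry, $s_{in} =
\lambda_n^{1/2}\gamma_{in}$ the scaled IPCA score, and $\theta_n$ the
GEI-share proportion, the forms are listed in the function
documentation; they follow the canonical literature definitions rather
than any particular typeset rendering, which in secondary sources often
drops radicals and subscripts. Useful algebraic consequences, all
asserted in tests: $EV = DZ^2/N'$ identically; every index is invariant
to the additive part of the data; scaling the data by $c$ scales
$\lambda$ by $c$ and hence ASTAB/DA/AVAMGE by $c$, FA by $c^2$, the
$s$-based indices by $\sqrt{c}$, and DZ/EV not at all — and no index
reranks under scaling. ASI and ASV need two axes and are reported as
`NA` (not zero) when $N' = 1$. The default $N'$ is the number of axes
significant at $p < 0.05$ by the Gollob test, floored at 2, matching
common practice when the retained-axis count is not stated.

## GGE and which-won-where

`fit_gge()` decomposes the environment-centred matrix (centering "2" —
genotype main effect plus GEI retained), explains
$100\lambda_k^2/\sum\lambda^2$ percent of the G + GE sum of squares per
axis, and partitions singular values with exponent $f$ between genotype
($\lambda^f$) and environment ($\lambda^{1-f}$) scores so their product
always reconstructs the centred matrix. `which_won_where()` works in
the first two axes only, as the printed biplots do: convex hull of
genotype points, boundary rays from the origin perpendicular to hull
edges, each environment assigned to the sector whose vertex maximizes
the projection of the environment vector — which is the same genotype
the perpendicular-ray geometry selects, a fact the tests verify against
a dense angular check. Sectors holding environments are
mega-environments; the "favourable environment" flag is the sign of the
projection on the average-genotype direction, an interpretive
convention. Collinear genotype scores make the hull degenerate and
raise an error rather than guessing.

## BLUP indices and WAASB

`fit_blup()` fits the mixed model above and assembles genotypic values
$Gv_{ij} = \hat\mu + \hat\tau_j + \tilde g_i + \widetilde{ge}_{ij}$
from the fixed environment mean (averaged over blocks) plus the
shrunken genotype and interaction predictions. From these,
`blup_indices()` computes HMGV (harmonic mean over environments), RPGV
(mean performance relative to the environment mean — invariant to
rescaling any environment), and HMRPGV (harmonic mean of the relative
performances). Harmonic means require $Gv_{ij} > 0$; offending
genotypes are flagged and excluded from ranking rather than silently
clipped, and for sign-indefinite transformed traits the recommended
route is to compute these indices on the TIC-normalized (untransformed)
scale. `waasb()` applies the weighted-absolute-score construction to
the SVD of the BLUP interaction matrix over all its axes, so stability
is judged on shrunken rather than raw interaction estimates.

## WAASBY and MTSI

`waasby_index()` rescales trait means to 0–100 (best mean = 100,
invertible per trait for smaller-is-better panels) and WAASB to 0–100
(most stable = 100) and blends them with weights $\theta_Y = \theta_S =
50$ by default — equal weighting, the cited method's default where no
weights are printed. A scale with no spread collapses to all-100 with a
flag. `mtsi()` then runs a correlation-based factor analysis of the
genotype × trait WAASBY matrix: principal-axis loadings from the
eigendecomposition, Kaiser retention (eigenvalue ≥ 1, configurable),
varimax rotation, regression scores via the pseudoinverse of the trait
correlation matrix (so near-duplicate traits stay workable), and the
ideotype defined as the vector of per-trait maxima projected into the
same factor space. MTSI is the Euclidean distance of each genotype's
factor scores from the ideotype; selection defaults to the top 2 of 11
(a selection fraction of 2/11), mirroring the typical two-winner
outcome of an 11-genotype panel.

## Preprocessing

`tic_normalize()` expresses intensities as percent of each sample's
total ion count (idempotent); `log_pareto()` applies log10 then
mean-centring with a $\sqrt{SD}$ divisor, mapping constant features to
zero columns. Zeros ahead of the log receive half the smallest positive
intensity in the matrix as offset — the standard metabolomics
half-minimum rule, configurable off. `anova_screen()` runs per-feature
one-way fixed-effects ANOVA with Bonferroni correction whose family is
the set of features in the call, and `two_way_rank()` ranks features by
the environment main-effect p-value of a two-factor ANOVA (ties broken
by larger F), the term configurable to genotype or interaction;
unbalanced designs fall back to Type-II sums of squares.

## Numerical choices and problem sizes

All bilinear decompositions use LAPACK SVD with brute-force
eigendecomposition oracles in the tests (`1e-8` agreement). The test
suite and the acceptance script run at deliberately modest sizes — the
11 × 5 × 3 study shape for exactness checks, G = 40 with 100–200 seeds
for Monte-Carlo recovery, 500–1000 random matrices for conservation
laws, 2000 features for null calibration — sizes chosen so the full
chain (including ~60 REML fits for a 54-trait panel) completes in
seconds to a few minutes while keeping Monte-Carlo standard errors
small enough for 3-SE assertions to be meaningful.

## Known limitations

Only RCBD designs are supported; there is no spatial/row-column
adjustment, no imputation of missing cells, no confidence regions on
biplots, and no multi-trait mixed model (traits are analysed
independently before MTSI). Mega-environment geometry is read from the
rank-2 plane only. The simulator's independence assumptions (traits,
environments, residuals) mean the package's verified guarantees are
about estimator correctness, not about field-data robustness.
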