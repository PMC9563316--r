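# metstab

Stability analysis for multi-environment trials (METs), aimed at plant
breeders and metabolomics groups who evaluate the same genotypes in
several locations and need to separate genuine genetic merit from
genotype-by-environment interaction (GEI). The package covers the full
chain for replicated randomized-complete-block trials — including
high-dimensional metabolite panels where each of thousands of mass
features is a trait:

* **Preprocessing** of samples × features intensity matrices:
  total-ion-count normalization, log10 + Pareto scaling, one-way ANOVA
  screening with Bonferroni correction, and two-way ANOVA feature
  ranking.
* **Variance components and heritability**: per-environment and combined
  RCBD ANOVA, expected-mean-squares and REML (lme4) estimation, and
  broad-sense heritability
  `H² = σ²g / (σ²g + σ²ge/ηLoc + σ²ε/(ηLoc·ηRep))`.
* **AMMI**: the additive-main-effects and multiplicative-interaction
  model `y_ij = μ + α_i + τ_j + Σ_k λ_k a_ik t_jk + ρ_ij + ε_ij`, fitted
  by SVD of the double-centred cell-mean matrix, with per-axis GEI
  shares `θ_k = 100·λ_k²/Σλ²`, Gollob axis tests, and AMMI1/AMMI2
  biplot coordinates.
* **Thirteen AMMI-based stability indices** (ASTAB, ASI, ASV, AVAMGE,
  DA, DZ, EV, FA, MASI, MASV, SIPC, WAAS, ZA) with ranks and Spearman
  rank concordance.
* **GGE** (genotype + GEI) biplots from environment-centred data, with
  convex-hull / sector ("which-won-where") mega-environment analysis
  and environment-vector relations.
* **BLUP-based indices**: mixed-model genotypic values `Gv_ij`, HMGV,
  RPGV, HMRPGV, and WAASB (weighted absolute IPCA scores of the BLUP
  interaction matrix).
* **Multi-trait selection**: the WAASBY superiority index
  `(rG·θY + rW·θS)/(θY+θS)` per trait and the multi-trait stability
  index (MTSI) — factor analysis of the genotype × trait WAASBY matrix
  and Euclidean distance from the ideotype.
* **A synthetic MET generator** (`random_truth()`, `simulate_trait()`,
  `simulate_multitrait()`) whose additive and bilinear truth is fully
  retrievable, so every stage above is testable by parameter recovery.

## Worked example

Simulate a trial at a typical MET scale — 11 genotypes × 5 environments
× 3 replicates with a rank-2 bilinear interaction — then fit AMMI, rank
stability, find mega-environments, and select across a small panel:

```r
library(metstab)

truth <- random_truth(G = 11, E = 5, k = 2, seed = 42)
trial <- simulate_trait(truth, trait = "mz_171.14864")
trial
#> <met_dataset> 165 observations: 11 genotypes x 5 environments x 3 replicates x 1 traits (balanced)

res <- ammi(trial)
glance(res$fit)
#> # A tibble: 1 × 8
#>   trait        n_genotypes n_environments n_axes n_retained ss_gei theta_1 theta_2
#>   <chr>              <int>          <int>  <int>      <dbl>  <dbl>   <dbl>   <dbl>
#> 1 mz_171.14864          11              5      4          4   102.    67.6    26.1
```

`theta_1 = 67.6` says the first interaction principal component axis
carries 67.6% of the GEI sum of squares; `ss_gei` is the GEI sum of
squares of the cell means. Stability indices rank genotypes from most
(rank 1) to least stable:

```r
stability_indices(res$fit, n_retained = 2)[, c("genotype", "ASV", "MASI", "WAAS", "rank_WAAS")]
#> # A tibble: 11 × 5
#>   genotype   ASV  MASI  WAAS rank_WAAS
#>   <chr>    <dbl> <dbl> <dbl>     <dbl>
#> 1 G1        1.09 0.284 0.407         5
#> 2 G2        4.09 1.07  1.19         11
#> 3 G3        3.16 0.823 0.988         8
#> # ...

www <- which_won_where(fit_gge(cell_means(trial)))
tidyr::unnest(www$mega_envs, environments)
#> # A tibble: 5 × 4
#>   mega_env sector winner environments
#> 1 ME1           2 G9     E2
#> 2 ME1           2 G9     E3
#> 3 ME1           2 G9     E4
#> 4 ME1           2 G9     E5
#> 5 ME2           4 G3     E1
```

Two mega-environments: genotype G9 wins in E2–E5 and G3 wins in E1.
Across a multi-trait panel, WAASBY + MTSI pick the genotypes combining
mean performance and stability:

```r
panel <- simulate_multitrait(6, base = truth, seed = 7)
mtsi(waasby_matrix(panel), selection = 2 / 11)
#> <mtsi_result> 11 genotypes x 6 traits, 2 factor(s); selected: G1, G11
```

`autoplot()` renders AMMI and GGE biplots and the MTSI ranking;
`tidy()`/`glance()` turn every fitted object into a tibble. A thin
command-line wrapper ships at `inst/cli/metstab.R`
(`metstab.R simulate|run|ammi|mtsi ...`) and writes one CSV per result
table plus a JSON run manifest.

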