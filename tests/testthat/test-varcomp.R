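test_that("rcbd_anova on noise-free additive data has zero residual MS", {
  truth <- random_truth(G = 6, E = 3, k = 0, seed = 5,
                        effect_scales = list(error_sd = 0, block_sd = 0.8))
  d <- simulate_trait(truth)
  # aov warns that F tests on a perfect fit are unreliable; expected here
  res <- suppressWarnings(rcbd_anova(d, environment = "E1"))
  ms_res <- res$anova$ms[res$anova$source == "residual"]
  expect_lt(ms_res, 1e-18)
  expect_lt(res$anova$p_value[res$anova$source == "genotype"], 1e-12)
})

test_that("rcbd_anova recovers simulated variance components", {
  # sigma2_g = 2, sigma2_e = 1, R = 3, G = 40, one environment
  G <- 40; R <- 3; n_seed <- 200
  est <- t(vapply(seq_len(n_seed), function(s) {
    truth <- random_truth(
      G, 2, 0, seed = 700 + s,
      effect_scales = list(alpha_sd = sqrt(2), tau_sd = 1,
                           block_sd = 0, error_sd = 1))
    d <- simulate_trait(truth)
    vc <- rcbd_anova(d, environment = "E1")$varcomp
    c(g = vc$sigma2_g, e = vc$sigma2_e)
  }, c(g = 0, e = 0)))
  for (comp in c("g", "e")) {
    truth_val <- c(g = 2, e = 1)[comp]
    se <- sd(est[, comp]) / sqrt(n_seed)
    expect_lt(abs(mean(est[, comp]) - truth_val), 3 * se)
  }
})

test_that("genotype p-values are null-calibrated without genotype effects", {
  n_seed <- 120
  ps <- vapply(seq_len(n_seed), function(s) {
    truth <- random_truth(8, 2, 0, seed = 4000 + s,
                          effect_scales = list(alpha_sd = 0, block_sd = 0.3))
    rcbd_anova(simulate_trait(truth), environment = "E1")$anova$p_value[1]
  }, 0)
  frac <- mean(ps < 0.25)
  se <- sqrt(0.25 * 0.75 / n_seed)
  expect_lt(abs(frac - 0.25), 3 * se)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.001)
})

test_that("combined_anova partitions df and SS additively", {
  d <- simulate_trait(random_truth(7, 4, 2, seed = 31))
  res <- combined_anova(d)
  G <- 7; L <- 4; R <- 3
  expect_equal(sum(res$anova$df), G * L * R - 1)
  total_ss <- sum((d$value - mean(d$value))^2)
  expect_equal(sum(res$anova$ss), total_ss, tolerance = 1e-8)
})

test_that("sigma2_ge estimate centres on zero without simulated GEI", {
  n_seed <- 200
  est <- vapply(seq_len(n_seed), function(s) {
    truth <- random_truth(10, 4, 0, seed = 9000 + s,
                          effect_scales = list(error_sd = 1))
    combined_anova(simulate_trait(truth))$varcomp$sigma2_ge
  }, 0)
  # truncation at zero biases the mean upward; compare the pre-truncation
  # centre via the median instead, which stays near the truncation point
  se <- sd(est) / sqrt(n_seed)
  expect_lt(abs(median(est)), 3 * se + 1e-3)
})

test_that("EMS and REML agree on balanced data", {
  for (s in c(2, 17, 23)) {
    truth <- random_truth(9, 4, 2, seed = s,
                          effect_scales = list(alpha_sd = 2, error_sd = 0.7))
    d <- simulate_trait(truth)
    ems <- combined_anova(d, method = "ems")$varcomp
    reml <- combined_anova(d, method = "reml")$varcomp
    if (!ems$truncated) {
      expect_equal(reml$sigma2_g, ems$sigma2_g, tolerance = 1e-6)
      expect_equal(reml$sigma2_ge, ems$sigma2_ge, tolerance = 1e-6)
      expect_equal(reml$sigma2_e, ems$sigma2_e, tolerance = 1e-6)
    }
  }
})

test_that("unbalanced data is rejected under EMS and directed to REML", {
  d <- tibble::as_tibble(simulate_trait(random_truth(5, 3, 1, seed = 3)))
  expect_error(combined_anova(met_dataset(d[-1, ]), method = "ems"),
               regexp = "reml", class = "metstab_validation_error")
  vc <- combined_anova(met_dataset(d[-1, ]), method = "reml")$varcomp
  expect_s3_class(vc, "var_components")
})

test_that("heritability formulas match hand calculations to 1e-12", {
  v1 <- var_components(2, 1, n_rep = 3, scope = "single")
  expect_equal(heritability_single(v1), 2 / (2 + 1 / 3), tolerance = 1e-12)
  expect_equal(heritability_single(var_components(0, 1, n_rep = 3)), 0)
  expect_equal(heritability_single(var_components(2, 0, n_rep = 3)), 1)

  v2 <- var_components(2, 1, sigma2_ge = 1, n_rep = 3, n_loc = 5,
                       scope = "combined")
  expect_equal(heritability_combined(v2), 2 / (2 + 1 / 5 + 1 / 15),
               tolerance = 1e-12)
  # no GEI: reduces to the single-environment formula with R -> L*R
  v3 <- var_components(2, 1, sigma2_ge = 0, n_rep = 3, n_loc = 5,
                       scope = "combined")
  expect_equal(heritability_combined(v3), 2 / (2 + 1 / 15), tolerance = 1e-12)
})

test_that("heritability is monotone in each variance component", {
  base <- function(g, ge, e) heritability_combined(
    var_components(g, e, sigma2_ge = ge, n_rep = 3, n_loc = 5,
                   scope = "combined"))
  expect_gt(base(3, 1, 1), base(2, 1, 1))
  expect_lt(base(2, 2, 1), base(2, 1, 1))
  expect_lt(base(2, 1, 2), base(2, 1, 1))
  # partitioning out a GEI component lowers combined heritability relative
  # to the no-GEI combined analysis
  expect_lt(base(2, 1, 1), base(2, 0, 1))
})

test_that("combined heritability recovers the simulated truth", {
  # truth: sigma2_g = 2 (alpha_sd), sigma2_ge from lambda, sigma2_e = 1;
  # G = 40 keeps the finite-sample bias of the mean-square ratio small
  n_seed <- 200
  G <- 40; E <- 5; R <- 3
  h2 <- vapply(seq_len(n_seed), function(s) {
    truth <- random_truth(G, E, 2, seed = 20000 + s,
                          effect_scales = list(alpha_sd = sqrt(2),
                                               lambda = c(6, 4),
                                               error_sd = 1, block_sd = 0.3))
    heritability_combined(combined_anova(simulate_trait(truth))$varcomp)
  }, 0)
  # population-level H2 at these settings: the EMS genotype component is
  # unbiased for the draw variance of alpha (2); the GEI component targets
  # sum(lambda^2) spread over the interaction degrees of freedom
  sg <- 2
  sge <- (6^2 + 4^2) / ((G - 1) * (E - 1))
  target <- sg / (sg + sge / E + 1 / (E * R))
  se <- sd(h2) / sqrt(n_seed)
  expect_lt(abs(mean(h2) - target), 3 * se + 0.02)
})
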