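test_that("noise-free genotypic values equal cell means (shrinkage -> 1)", {
  truth <- random_truth(6, 4, 1, seed = 5,
                        effect_scales = list(error_sd = 1e-4, block_sd = 0))
  d <- simulate_trait(truth)
  fit <- fit_blup(d)
  cm <- unclass(cell_means(d))[,]
  expect_equal(fit$Gv, cm[rownames(fit$Gv), colnames(fit$Gv)],
               tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("REML components match the varcomp module on balanced data", {
  d <- simulate_trait(random_truth(9, 4, 2, seed = 14))
  a <- combined_anova(d, method = "reml")$varcomp
  b <- fit_blup(d)$varcomp
  expect_equal(b$sigma2_g, a$sigma2_g, tolerance = 1e-6)
  expect_equal(b$sigma2_ge, a$sigma2_ge, tolerance = 1e-6)
  expect_equal(b$sigma2_e, a$sigma2_e, tolerance = 1e-6)
})

test_that("genotype predictions shrink toward zero under a null truth", {
  # no genotype effects: BLUPs must be smaller than raw genotype means
  n_seed <- 60
  ratio <- vapply(seq_len(n_seed), function(s) {
    truth <- random_truth(8, 3, 0, seed = 300 + s,
                          effect_scales = list(alpha_sd = 0, error_sd = 1))
    d <- simulate_trait(truth)
    fit <- fit_blup(d)
    raw <- tapply(d$value, d$genotype, mean) - mean(d$value)
    mean(abs(fit$gen_blup)) / mean(abs(raw))
  }, 0)
  expect_lt(mean(ratio), 1)
})

test_that("ge_blup columns and genotype effects stay centred", {
  d <- simulate_trait(random_truth(10, 5, 2, seed = 44))
  fit <- fit_blup(d)
  expect_lt(abs(mean(fit$gen_blup)), 1e-6)
  expect_lt(max(abs(colMeans(fit$ge_blup))), 1e-6)
})

test_that("blup_indices reproduce the hand examples", {
  fake <- structure(list(
    Gv = matrix(c(1, 2), 1, 2, dimnames = list("G1", c("E1", "E2"))),
    env_mean = c(E1 = 1, E2 = 2), n_env = 2
  ), class = "blup_fit")
  # single genotype: HMGV = 2/(1/1 + 1/2) = 4/3; RPGV = 1; HMRPGV = 1
  idx <- blup_indices(fake)
  expect_equal(idx$HMGV, 4 / 3, tolerance = 1e-12)
  expect_equal(idx$RPGV, 1, tolerance = 1e-12)
  expect_equal(idx$HMRPGV, 1, tolerance = 1e-12)

  # constant genotypic values: HMGV = c, RPGV = mean(c / mu_j)
  cval <- 5
  fake2 <- structure(list(
    Gv = matrix(cval, 2, 3, dimnames = list(c("G1", "G2"), paste0("E", 1:3))),
    env_mean = c(E1 = 4, E2 = 5, E3 = 10), n_env = 3
  ), class = "blup_fit")
  idx2 <- blup_indices(fake2)
  expect_equal(idx2$HMGV, rep(cval, 2), tolerance = 1e-12)
  expect_equal(idx2$RPGV, rep(mean(cval / c(4, 5, 10)), 2),
               tolerance = 1e-12)
  # harmonic mean of relative performances for constant Gv
  expect_equal(idx2$HMRPGV, rep(3 / sum(c(4, 5, 10) / cval), 2),
               tolerance = 1e-12)
})

test_that("harmonic <= arithmetic on random positive tables", {
  set.seed(99)
  for (i in 1:50) {
    G <- sample(3:10, 1); E <- sample(2:6, 1)
    Gv <- matrix(rexp(G * E) + 0.1, G, E,
                 dimnames = list(paste0("G", 1:G), paste0("E", 1:E)))
    fake <- structure(list(Gv = Gv, env_mean = colMeans(Gv), n_env = E),
                      class = "blup_fit")
    idx <- blup_indices(fake)
    expect_true(all(idx$HMGV <= rowMeans(Gv) + 1e-12))
  }
})

test_that("RPGV is invariant to rescaling an environment column", {
  d <- simulate_trait(random_truth(6, 3, 1, seed = 9,
                                   effect_scales = list(mu = 100)))
  fit <- fit_blup(d)
  idx <- blup_indices(fit)
  # rescale E2 by c > 0: mu_j and Gv_ij both rescale, RPGV unchanged
  fit2 <- fit
  cc <- 3.7
  fit2$Gv[, "E2"] <- cc * fit2$Gv[, "E2"]
  fit2$env_mean["E2"] <- cc * fit2$env_mean["E2"]
  idx2 <- blup_indices(fit2)
  expect_equal(idx2$RPGV, idx$RPGV, tolerance = 1e-10)
  expect_equal(idx2$HMRPGV, idx$HMRPGV, tolerance = 1e-10)
})

test_that("non-positive genotypic values flag harmonic indices undefined", {
  Gv <- matrix(c(-1, 2, 3, 4), 2, 2,
               dimnames = list(c("G1", "G2"), c("E1", "E2")))
  fake <- structure(list(Gv = Gv, env_mean = c(E1 = 2, E2 = 3), n_env = 2),
                    class = "blup_fit")
  expect_warning(idx <- blup_indices(fake), regexp = "G1")
  expect_true(idx$undefined[1])
  expect_true(is.na(idx$HMGV[1]))
  expect_false(is.na(idx$RPGV[1]))
  expect_equal(idx$rank_HMGV[2], 1)
})

test_that("waasb handles zero and rank-1 interaction structure", {
  zero <- structure(list(
    ge_blup = matrix(0, 4, 3, dimnames = list(paste0("G", 1:4),
                                              paste0("E", 1:3)))),
    class = "blup_fit")
  wz <- waasb(zero)
  expect_equal(wz$WAASB, rep(0, 4))
  expect_equal(wz$rank_WAASB, rep(2.5, 4))  # all tied

  u <- c(3, -1, -1, -1); v <- c(1, -2, 1)
  r1 <- structure(list(
    ge_blup = outer(u - mean(u), v - mean(v),
                    FUN = function(a, b) a * b) |>
      (\(m) {dimnames(m) <- list(paste0("G", 1:4), paste0("E", 1:3)); m})()),
    class = "blup_fit")
  w1 <- waasb(r1)
  # rank-1 matrix: WAASB proportional to |first left singular vector|
  sv <- svd(r1$ge_blup)
  expect_equal(w1$WAASB / max(w1$WAASB),
               abs(sv$u[, 1]) / max(abs(sv$u[, 1])), tolerance = 1e-10)
})

test_that("high-mean genotypes with large interactions split the rankings", {
  # construct: genotype 1 has a big mean but carries all the interaction;
  # genotype 2 is mid-mean and perfectly stable
  G <- 6; E <- 4
  u <- c(1, 0, 0, 0, 0, 0); u <- u - mean(u)
  v <- c(1, -1, 1, -1) * 2; v <- v - mean(v)
  surface <- 50 + outer(c(8, 4, 0, -2, -4, -6), rep(0, E), `+`) +
    outer(rep(1, G), c(2, -1, 0, -1)) + 6 * outer(u, v)
  obs <- tidyr::expand_grid(genotype = paste0("G", 1:G),
                            environment = paste0("E", 1:E),
                            replicate = paste0("R", 1:3))
  set.seed(2)
  obs$trait <- "t"
  obs$value <- surface[cbind(match(obs$genotype, paste0("G", 1:G)),
                             match(obs$environment, paste0("E", 1:E)))] +
    rnorm(nrow(obs), sd = 0.3)
  fit <- fit_blup(met_dataset(obs))
  perf <- blup_indices(fit)
  stab <- waasb(fit)
  expect_equal(perf$genotype[perf$rank_HMGV == 1], "G1")
  expect_gt(stab$rank_WAASB[stab$genotype == "G1"], 3)
})
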