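test_that("fit_gge conserves the Frobenius norm and orders axes", {
  d <- simulate_trait(random_truth(8, 5, 2, seed = 12))
  cm <- cell_means(d)
  fit <- fit_gge(cm)
  cc <- sweep(unclass(cm)[,], 2, colMeans(unclass(cm)[,]))
  expect_equal(sum(fit$lambda^2), sum(cc^2), tolerance = 1e-8)
  expect_equal(sum(fit$explained), 100, tolerance = 1e-8)
  expect_false(is.unsorted(rev(fit$explained)))
  # PC1+PC2 dominate any other axis pair
  expect_gte(sum(fit$explained[1:2]), sum(fit$explained[3:4]))
})

test_that("no genotype effect and no GEI collapses all axes", {
  truth <- random_truth(6, 4, 0, seed = 3,
                        effect_scales = list(alpha_sd = 0, error_sd = 0,
                                             block_sd = 0))
  fit <- fit_gge(cell_means(simulate_trait(truth)))
  expect_lt(max(fit$lambda), 1e-10)
})

test_that("svp exponent partitions singular values between sides", {
  d <- simulate_trait(random_truth(7, 4, 2, seed = 8))
  cm <- cell_means(d)
  f0 <- fit_gge(cm, svp_exponent = 0)
  f1 <- fit_gge(cm, svp_exponent = 1)
  # product of genotype and environment scores reconstructs the centred
  # matrix regardless of the partitioning
  for (fit in list(f0, f1)) {
    recon <- fit$gen_full %*% t(fit$env_full)
    expect_equal(recon, fit$centered, tolerance = 1e-8, ignore_attr = TRUE)
  }
  # f = 0 gives unit-norm genotype axes, f = 1 unit-norm environment axes
  expect_equal(colSums(f0$gen_full^2)[1], c(PC1 = 1), tolerance = 1e-8)
  expect_equal(colSums(f1$env_full^2)[1], c(PC1 = 1), tolerance = 1e-8)
})

test_that("which_won_where matches a brute-force dense angle check", {
  # known geometry: 4 genotypes at (+-1, +-1), environments at (2, 0) and
  # (0, 2); perpendicular-ray sectors put E_x with the (1,?) vertices
  fit <- structure(list(
    genotype_scores = tibble::tibble(
      genotype = c("A", "B", "C", "D"),
      pc1 = c(1, 1, -1, -1), pc2 = c(1, -1, 1, -1)),
    environment_scores = tibble::tibble(
      environment = c("Ex", "Ey"), pc1 = c(2, 0), pc2 = c(0, 2)),
    lambda = c(2, 2), explained = c(50, 50)
  ), class = "gge_fit")
  www <- which_won_where(fit)
  expect_setequal(www$hull, c("A", "B", "C", "D"))
  # (2,0) ties A/B on projection; dense-grid oracle picks the max too
  gen <- as.matrix(fit$genotype_scores[, c("pc1", "pc2")])
  env <- as.matrix(fit$environment_scores[, c("pc1", "pc2")])
  oracle_win <- apply(env %*% t(gen), 1, function(p)
    fit$genotype_scores$genotype[which.max(p)])
  expect_equal(www$env_sector$winner, unname(oracle_win))
  expect_equal(www$env_sector$winner[2], "A")  # (0,2): A=(1,1) wins

  # random fits: winner always maximizes the rank-2 projection, and the
  # sector geometry (angular intervals) agrees with the projection rule
  for (s in 1:5) {
    d <- simulate_trait(random_truth(9, 5, 2, seed = 40 + s))
    g <- fit_gge(cell_means(d))
    w <- which_won_where(g)
    genm <- as.matrix(g$genotype_scores[, c("pc1", "pc2")])
    rownames(genm) <- g$genotype_scores$genotype
    envm <- as.matrix(g$environment_scores[, c("pc1", "pc2")])
    for (j in seq_len(nrow(envm))) {
      proj <- drop(genm %*% envm[j, ])
      expect_equal(w$env_sector$winner[j],
                   names(which.max(proj)))
    }
    # every environment lies inside its sector's angular interval
    ang <- atan2(envm[, 2], envm[, 1]) %% (2 * pi)
    for (j in seq_len(nrow(envm))) {
      sec <- w$sectors[w$sectors$sector == w$env_sector$sector[j], ]
      lo <- sec$angle_start; hi <- sec$angle_end
      inside <- if (lo <= hi) ang[j] >= lo - 1e-9 && ang[j] <= hi + 1e-9
        else ang[j] >= lo - 1e-9 || ang[j] <= hi + 1e-9
      expect_true(inside)
    }
  }
})

test_that("winner genotype has the top centred value in a won environment", {
  # rank-2 data: the biplot is exact, so the sector winner must truly win
  # at least one of its environments
  truth <- noise_free_truth(seed = 23, k = 2, G = 8, E = 5)
  g <- fit_gge(cell_means(simulate_trait(truth)))
  w <- which_won_where(g)
  # centred matrix restricted to rank 2 equals the full centred matrix up
  # to discarded axes; compare on the reconstruction
  recon <- g$gen_full[, 1:2] %*% t(g$env_full[, 1:2])
  for (r in seq_len(nrow(w$mega_envs))) {
    winner <- w$mega_envs$winner[r]
    envs <- w$mega_envs$environments[[r]]
    tops <- vapply(envs, function(e)
      rownames(recon)[which.max(recon[, e])], "")
    expect_true(winner %in% tops)
  }
})

test_that("all environments in one sector yields a single mega-environment", {
  # one dominant genotype direction: every environment points the same way
  gen <- tibble::tibble(genotype = paste0("G", 1:5),
                        pc1 = c(3, 1, -1, -2, -1),
                        pc2 = c(0, 2, 1, -1, -2))
  env <- tibble::tibble(environment = paste0("E", 1:4),
                        pc1 = c(2, 2.2, 1.8, 2.1),
                        pc2 = c(0.1, -0.1, 0.05, 0))
  fit <- structure(list(genotype_scores = gen, environment_scores = env,
                        lambda = c(3, 2), explained = c(60, 40)),
                   class = "gge_fit")
  www <- which_won_where(fit)
  expect_equal(nrow(www$mega_envs), 1)
  expect_equal(www$mega_envs$winner, "G1")

  collinear <- structure(list(
    genotype_scores = tibble::tibble(genotype = c("A", "B", "C"),
                                     pc1 = c(1, 2, 3), pc2 = c(1, 2, 3)),
    environment_scores = env), class = "gge_fit")
  expect_error(which_won_where(collinear),
               class = "metstab_degenerate_error")
})

test_that("sector assignment is rotation-equivariant", {
  d <- simulate_trait(random_truth(8, 5, 2, seed = 77))
  g <- fit_gge(cell_means(d))
  w1 <- which_won_where(g)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  g2 <- g
  gm <- as.matrix(g$genotype_scores[, c("pc1", "pc2")]) %*% rot
  em <- as.matrix(g$environment_scores[, c("pc1", "pc2")]) %*% rot
  g2$genotype_scores$pc1 <- gm[, 1]; g2$genotype_scores$pc2 <- gm[, 2]
  g2$environment_scores$pc1 <- em[, 1]; g2$environment_scores$pc2 <- em[, 2]
  w2 <- which_won_where(g2)
  expect_equal(w1$env_sector$winner, w2$env_sector$winner)
})

test_that("env_relations reports cosines in range with correct extremes", {
  # identical environment columns give cosine 1
  y <- cbind(E1 = c(1, 4, 2, 6), E2 = c(1, 4, 2, 6), E3 = c(5, 1, 3, 2))
  rownames(y) <- paste0("G", 1:4)
  fit <- fit_gge(ge_matrix(y))
  er <- env_relations(fit)
  expect_equal(unname(er$cosines["E1", "E2"]), 1, tolerance = 1e-8)
  expect_true(all(er$cosines >= -1 - 1e-12 & er$cosines <= 1 + 1e-12))
  expect_equal(unname(diag(er$cosines)), rep(1, 3), tolerance = 1e-12)
  expect_equal(er$vectors$vector_length,
               sqrt(fit$environment_scores$pc1^2 +
                      fit$environment_scores$pc2^2))

  for (s in 1:3) {
    d <- simulate_trait(random_truth(7, 5, 2, seed = 50 + s))
    er2 <- env_relations(fit_gge(cell_means(d)))
    expect_true(all(er2$cosines >= -1 - 1e-12 & er2$cosines <= 1 + 1e-12))
  }
})

test_that("gge tidiers and autoplot work", {
  d <- simulate_trait(random_truth(6, 4, 1, seed = 2))
  g <- fit_gge(cell_means(d))
  expect_equal(nrow(tidy(g)), 10)
  expect_s3_class(autoplot(g), "ggplot")
})
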