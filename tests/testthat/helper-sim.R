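# shared fixtures, built in code

# small balanced dataset from explicit values
toy_long <- function() {
  tibble::tibble(
    genotype = rep(rep(c("G1", "G2"), each = 3), 1),
    environment = "E1",
    replicate = rep(c("R1", "R2", "R3"), 2),
    trait = "t1",
    value = c(1, 2, 3, 2, 3, 4)
  )
}

# noise-free truth at the study shape: 11 genotypes x 5 environments x 3 reps
noise_free_truth <- function(seed = 42, k = 2, G = 11, E = 5) {
  random_truth(G, E, k, seed = seed,
               effect_scales = list(error_sd = 0, block_sd = 0))
}

# brute-force double-centring of a matrix (independent of fit_ammi)
double_centre <- function(y) {
  sweep(sweep(y, 1, rowMeans(y)), 2, colMeans(y)) + mean(y)
}

# centred orthonormal score columns built independently of the package
orthonormalize_centred_for_test <- function(n, k, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n * k), n, k)
  m <- sweep(m, 2, colMeans(m))
  q <- qr.Q(qr(m))[, seq_len(k), drop = FALSE]
  sweep(q, 2, colMeans(q))
}

# feature matrix with pure null features: all groups share one mean
null_feature_matrix <- function(n_feat, G = 4, R = 5, seed = 1) {
  set.seed(seed)
  n <- G * R
  feature_matrix(
    matrix(rnorm(n * n_feat, mean = 10), n, n_feat),
    sample_meta = tibble::tibble(
      genotype = rep(paste0("G", seq_len(G)), each = R),
      environment = "E1",
      replicate = rep(paste0("R", seq_len(R)), G)
    )
  )
}

# naive per-genotype summation oracle for every index
naive_indices <- function(fit, np) {
  lambda <- fit$lambda[seq_len(np)]
  gamma <- fit$gamma[, seq_len(np), drop = FALSE]
  delta <- fit$delta[, seq_len(np), drop = FALSE]
  theta <- fit$theta[seq_len(np)] / 100
  ss <- lambda^2
  G <- nrow(gamma)
  out <- list()
  for (i in seq_len(G)) {
    s <- sqrt(lambda) * gamma[i, ]
    astab <- 0; da2 <- 0; dz2 <- 0; fa <- 0; masi2 <- 0
    waas_num <- 0; sipc <- 0; za <- 0; avamge <- 0
    for (n in seq_len(np)) {
      astab <- astab + lambda[n] * gamma[i, n]^2
      da2 <- da2 + (lambda[n] * gamma[i, n])^2
      dz2 <- dz2 + gamma[i, n]^2
      fa <- fa + lambda[n]^2 * gamma[i, n]^2
      masi2 <- masi2 + s[n]^2 * theta[n]^2
      waas_num <- waas_num + abs(s[n]) * theta[n]
      sipc <- sipc + abs(s[n])
      za <- za + theta[n] * abs(s[n])
      for (j in seq_len(nrow(delta))) {
        avamge <- avamge + abs(lambda[n] * gamma[i, n] * delta[j, n])
      }
    }
    asi <- if (np >= 2) sqrt(s[1]^2 * theta[1]^2 + s[2]^2 * theta[2]^2) else NA
    asv <- if (np >= 2) sqrt((ss[1] / ss[2] * s[1])^2 + s[2]^2) else NA
    masv <- if (np >= 2) {
      acc <- 0
      for (n in seq_len(np - 1)) acc <- acc + (ss[n] / ss[n + 1] * s[n])^2
      sqrt(acc + s[np]^2)
    } else NA
    vals <- as.numeric(c(astab, asi, asv, avamge, sqrt(da2), sqrt(dz2),
                         dz2 / np, fa, sqrt(masi2), masv, sipc,
                         waas_num / sum(theta), za))
    out[[i]] <- setNames(vals, c("ASTAB", "ASI", "ASV", "AVAMGE", "DA",
                                 "DZ", "EV", "FA", "MASI", "MASV", "SIPC",
                                 "WAAS", "ZA"))
  }
  do.call(rbind, out)
}
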