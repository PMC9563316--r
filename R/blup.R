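#' Mixed-model genotypic values (BLUP)
#'
#' Fits `value ~ environment + block-within-environment (fixed) + genotype
#' (random) + genotype:environment (random)` by restricted maximum
#' likelihood and assembles the genotypic value of genotype `i` in
#' environment `j` as
#' `Gv_ij = mu + tau_j + g_i + ge_ij`, where `g` and `ge` are the shrunken
#' (BLUP) predictions and `mu + tau_j` is the fixed environment mean
#' averaged over blocks. With `random_env = TRUE` environment (and its
#' interaction structure) is treated as random instead.
#'
#' @param data A `met_dataset` or compatible data frame.
#' @param trait Trait label (optional for single-trait data).
#' @param random_env Treat environment as a random effect.
#' @return A `blup_fit` with `Gv` (G x E genotypic values), `env_mean`
#'   (observed environment means of the trait), `ge_blup` (G x E predicted
#'   interaction effects), `gen_blup`, `varcomp` (REML
#'   [var_components()]), `n_env` and `trait`.
#' @examples
#' d <- simulate_trait(random_truth(G = 8, E = 4, k = 1, seed = 2))
#' fit <- fit_blup(d)
#' round(fit$varcomp$sigma2_g, 3)
#' @export
fit_blup <- function(data, trait = NULL, random_env = FALSE) {
  sub <- trait_subset(data, trait)
  traits <- unique(sub$trait)
  gf <- factor(sub$genotype, levels = unique(sub$genotype))
  ef <- factor(sub$environment, levels = unique(sub$environment))
  sub$genotype <- gf; sub$environment <- ef
  if (nlevels(gf) < 2 || nlevels(ef) < 2) {
    abort("need at least 2 genotypes and 2 environments")
  }
  form <- if (random_env) {
    value ~ (1 | environment) + (1 | environment:replicate) +
      (1 | genotype) + (1 | genotype:environment)
  } else {
    value ~ environment + environment:replicate +
      (1 | genotype) + (1 | genotype:environment)
  }
  lfit <- tryCatch(
    lme4::lmer(form, data = sub, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                 optCtrl = list(xtol_abs = 1e-14, ftol_abs = 1e-14,
                                xtol_rel = 1e-14, ftol_rel = 1e-14,
                                maxeval = 100000))),
    error = function(e) {
      abort(sprintf("mixed model did not converge: %s", conditionMessage(e)),
            class = "metstab_convergence_error")
    }
  )
  vcs <- as.data.frame(lme4::VarCorr(lfit))
  grab <- function(grp) {
    i <- match(grp, vcs$grp)
    if (is.na(i)) 0 else vcs$vcov[i]
  }
  vc <- var_components(
    sigma2_g = grab("genotype"), sigma2_ge = grab("genotype:environment"),
    sigma2_e = grab("Residual"),
    n_rep = length(unique(sub$replicate)), n_loc = nlevels(ef),
    method = "reml", scope = "combined"
  )
  gens <- levels(gf); envs <- levels(ef)
  # fixed environment mean averaged over blocks
  fixed_pred <- predict(lfit, re.form = NA)
  env_fixed <- tapply(fixed_pred, ef, mean)[envs]
  re <- lme4::ranef(lfit)
  g_blup <- setNames(rep(0, length(gens)), gens)
  if ("genotype" %in% names(re)) {
    g_blup[rownames(re$genotype)] <- re$genotype[, 1]
  }
  ge_blup <- matrix(0, length(gens), length(envs),
                    dimnames = list(gens, envs))
  if ("genotype:environment" %in% names(re)) {
    key <- do.call(rbind, strsplit(rownames(re$`genotype:environment`), ":"))
    ge_blup[cbind(key[, 1], key[, 2])] <- re$`genotype:environment`[, 1]
  }
  if (random_env) {
    mu <- unname(lme4::fixef(lfit)["(Intercept)"])
    env_eff <- setNames(rep(0, length(envs)), envs)
    if ("environment" %in% names(re)) {
      env_eff[rownames(re$environment)] <- re$environment[, 1]
    }
    env_fixed <- mu + env_eff
  }
  Gv <- outer(g_blup, env_fixed, `+`) + ge_blup
  env_mean <- tapply(sub$value, ef, mean)[envs]
  structure(
    list(Gv = Gv, env_mean = env_mean, ge_blup = ge_blup,
         gen_blup = g_blup, varcomp = vc, n_env = length(envs),
         trait = traits, model = lfit, random_env = random_env),
    class = "blup_fit"
  )
}

#' @exportS3Method base::print
print.blup_fit <- function(x, ...) {
  cat(sprintf(
    "<blup_fit> trait %s: %d genotypes x %d environments (REML); sigma2_g=%.4g, sigma2_ge=%.4g\n",
    deparse(x$trait), nrow(x$Gv), x$n_env,
    x$varcomp$sigma2_g, x$varcomp$sigma2_ge))
  invisible(x)
}

#' @export
tidy.blup_fit <- function(x, ...) {
  as_tibble(as.data.frame.table(x$Gv, responseName = "genotypic_value",
                                stringsAsFactors = FALSE)) |>
    dplyr::rename(genotype = "Var1", environment = "Var2") |>
    dplyr::mutate(trait = x$trait, .before = 1)
}

#' BLUP-based stability and performance indices
#'
#' From the genotypic values `Gv_ij` and environment means `mu_j`:
#' * `HMGV_i = E / sum_j (1 / Gv_ij)` — harmonic mean of genotypic values;
#' * `RPGV_i = (1/E) sum_j Gv_ij / mu_j` — relative performance;
#' * `HMRPGV_i = E / sum_j (mu_j / Gv_ij)` — harmonic mean of the relative
#'   performances.
#' Ranks are descending (rank 1 = largest index, i.e. best performing and
#' stable). Harmonic means require `Gv_ij > 0`; genotypes violating this
#' are flagged `undefined` and excluded from ranking.
#'
#' @param fit A `blup_fit`.
#' @return A tibble: genotype, HMGV, RPGV, HMRPGV, their ranks, and an
#'   `undefined` flag.
#' @export
blup_indices <- function(fit) {
  stopifnot(inherits(fit, "blup_fit"))
  Gv <- fit$Gv
  mu <- fit$env_mean
  E <- fit$n_env
  bad <- apply(Gv <= 0, 1, any)
  hmgv <- ifelse(bad, NA_real_, E / rowSums(1 / Gv))
  rel <- sweep(Gv, 2, mu, `/`)
  rpgv <- rowMeans(rel)
  hmrpgv <- ifelse(bad, NA_real_, E / rowSums(1 / rel))
  if (any(bad)) {
    warn(sprintf(
      "non-positive genotypic values: harmonic indices undefined for %s",
      paste(rownames(Gv)[bad], collapse = ", ")))
  }
  tibble(
    genotype = rownames(Gv),
    HMGV = unname(hmgv), RPGV = unname(rpgv), HMRPGV = unname(hmrpgv),
    rank_HMGV = unname(rank_desc(hmgv)), rank_RPGV = unname(rank_desc(rpgv)),
    rank_HMRPGV = unname(rank_desc(hmrpgv)),
    undefined = unname(bad)
  )
}

#' Weighted average of absolute scores from BLUP interaction effects
#'
#' Decomposes the matrix of predicted (shrunken) genotype-by-environment
#' effects by SVD and computes, per genotype,
#' `WAASB_i = sum_k |s_ik| theta_k / sum_k theta_k` over all axes, where
#' `s_ik = lambda_k^{1/2} u_ik` and `theta_k` is the share of the BLUP-GEI
#' sum of squares on axis `k`. Smaller = more stable (rank 1). A zero
#' interaction matrix yields all-zero WAASB with tied rank.
#'
#' @param fit A `blup_fit`.
#' @return A tibble: genotype, WAASB, rank_WAASB.
#' @export
waasb <- function(fit) {
  stopifnot(inherits(fit, "blup_fit"))
  m <- fit$ge_blup
  p <- min(dim(m))
  sv <- svd(m, nu = p, nv = p)
  lambda <- sv$d[seq_len(p)]
  total <- sum(lambda^2)
  if (total <= .Machine$double.eps) {
    w <- rep(0, nrow(m))
  } else {
    theta <- lambda^2 / total
    s <- sweep(sv$u, 2, sqrt(lambda), `*`)
    w <- colSums(theta * t(abs(s))) / sum(theta)
  }
  tibble(genotype = rownames(m), WAASB = unname(w),
         rank_WAASB = rank_asc(w))
}
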