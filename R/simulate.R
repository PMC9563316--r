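#' Simulation truth for a bilinear GEI trial
#'
#' Bundles the parameters of the two-way model
#' \deqn{y_{ijr} = \mu + \alpha_i + \tau_j + \sum_{k} \lambda_k a_{ik} t_{jk}
#'   + b_{jr} + \varepsilon_{ijr}}
#' with genotype effects \eqn{\alpha} (sum zero), environment effects
#' \eqn{\tau} (sum zero), a rank-`k` bilinear interaction with singular
#' values \eqn{\lambda} and orthonormal centred score matrices `a` (G x k)
#' and `t` (E x k), block-within-environment effects `b`, and i.i.d. noise.
#'
#' @param mu Grand mean.
#' @param alpha Genotype effects (recentred to sum zero).
#' @param tau Environment effects (recentred to sum zero).
#' @param lambda Non-negative singular values, sorted non-increasing.
#' @param a,t Genotype and environment score matrices; columns must be
#'   centred and orthonormal (checked to 1e-8).
#' @param block_sd,error_sd Standard deviations of block and residual noise.
#' @param n_rep Replicates (blocks) per environment.
#' @param seed Integer seed fixed into the truth; simulation is
#'   deterministic given the truth.
#' @param noise Residual law: `"gaussian"` or `"t"` (scaled Student t).
#' @param noise_df Degrees of freedom for the t option.
#' @return An object of class `sim_truth`.
#' @seealso [random_truth()], [simulate_trait()]
#' @export
sim_truth <- function(mu, alpha, tau, lambda, a, t, block_sd = 0,
                      error_sd = 1, n_rep = 3L, seed = 1L,
                      noise = c("gaussian", "t"), noise_df = 3) {
  noise <- match.arg(noise)
  alpha <- alpha - mean(alpha)
  tau <- tau - mean(tau)
  a <- as.matrix(a); t <- as.matrix(t)
  k <- length(lambda)
  G <- length(alpha); E <- length(tau)
  if (k > 0) {
    if (!all(dim(a) == c(G, k)) || !all(dim(t) == c(E, k))) {
      abort("score matrices must be G x k and E x k")
    }
    if (is.unsorted(rev(lambda)) || any(lambda < 0)) {
      abort("lambda must be non-negative and non-increasing")
    }
    if (k > min(G - 1, E - 1)) {
      abort("k exceeds min(G - 1, E - 1)", class = "metstab_dimension_error")
    }
    check_scores <- function(m, label) {
      gram <- crossprod(m)
      if (max(abs(gram - diag(ncol(m)))) > 1e-8 ||
          max(abs(colMeans(m))) > 1e-8) {
        abort(sprintf("columns of `%s` must be centred and orthonormal", label),
              class = "metstab_validation_error")
      }
    }
    check_scores(a, "a"); check_scores(t, "t")
  }
  structure(
    list(mu = mu, alpha = alpha, tau = tau, lambda = lambda, a = a, t = t,
         block_sd = block_sd, error_sd = error_sd, n_rep = as.integer(n_rep),
         seed = as.integer(seed), noise = noise, noise_df = noise_df,
         G = G, E = E, k = k),
    class = "sim_truth"
  )
}

#' @exportS3Method base::print
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "<sim_truth> G=%d, E=%d, rank-%d GEI; block_sd=%g, error_sd=%g, n_rep=%d, seed=%d\n",
    x$G, x$E, x$k, x$block_sd, x$error_sd, x$n_rep, x$seed))
  invisible(x)
}

#' Draw a random simulation truth
#'
#' Draws genotype/environment effects and bilinear scores at the requested
#' dimensions, then projects and orthonormalizes so all `sim_truth`
#' invariants hold exactly. Score columns are sign-fixed so the first
#' element of each genotype-score column is non-negative, removing the SVD
#' sign ambiguity from recovery comparisons.
#'
#' @param G,E Numbers of genotypes and environments.
#' @param k Rank of the simulated interaction; `k <= min(G - 1, E - 1)`.
#' @param seed Integer seed.
#' @param effect_scales Named list of scales: `mu`, `alpha_sd`, `tau_sd`,
#'   `lambda` (length-`k` vector of singular values, or a scalar scale from
#'   which a decreasing sequence is drawn), `block_sd`, `error_sd`.
#' @param n_rep Replicates per environment.
#' @return A [sim_truth()].
#' @examples
#' truth <- random_truth(G = 11, E = 5, k = 2, seed = 42)
#' truth$lambda
#' @export
random_truth <- function(G, E, k, seed = 1L,
                         effect_scales = list(), n_rep = 3L) {
  if (k > min(G - 1, E - 1)) {
    abort("k exceeds min(G - 1, E - 1)", class = "metstab_dimension_error")
  }
  scales <- modifyList(
    list(mu = 100, alpha_sd = 2, tau_sd = 4, lambda = 6,
         block_sd = 0.5, error_sd = 1),
    effect_scales
  )
  withr_seed <- local({
    old <- globalenv()$.Random.seed
    set.seed(seed)
    old
  })
  alpha <- rnorm(G, sd = scales$alpha_sd)
  tau <- rnorm(E, sd = scales$tau_sd)
  if (k > 0) {
    a <- sign_fix_first(orthonormalize_centred(matrix(rnorm(G * k), G, k)))
    t <- orthonormalize_centred(matrix(rnorm(E * k), E, k))
    lambda <- if (length(scales$lambda) == k) {
      sort(scales$lambda, decreasing = TRUE)
    } else {
      sort(abs(rnorm(k, mean = scales$lambda, sd = scales$lambda / 4)),
           decreasing = TRUE)
    }
  } else {
    a <- matrix(numeric(), G, 0); t <- matrix(numeric(), E, 0)
    lambda <- numeric()
  }
  if (!is.null(withr_seed)) assign(".Random.seed", withr_seed, globalenv())
  sim_truth(mu = scales$mu, alpha = alpha, tau = tau, lambda = lambda,
            a = a, t = t, block_sd = scales$block_sd,
            error_sd = scales$error_sd, n_rep = n_rep, seed = seed)
}

# expected cell mean surface mu + alpha_i + tau_j + sum_k lambda_k a_ik t_jk
truth_surface <- function(truth) {
  m <- outer(truth$alpha, truth$tau, `+`) + truth$mu
  if (truth$k > 0) {
    m <- m + truth$a %*% (truth$lambda * t(truth$t))
  }
  dimnames(m) <- list(paste0("G", seq_len(truth$G)),
                      paste0("E", seq_len(truth$E)))
  m
}

#' Simulate one replicated trait from a truth
#'
#' Generates `y_gjr = mu + alpha_g + tau_j + sum_k lambda_k a_gk t_jk + b_jr
#' + e_gjr` with block effects `b_jr ~ N(0, block_sd^2)` shared by all
#' genotypes in a (environment, replicate) block, and residuals from the
#' configured noise law. Deterministic given `truth$seed`.
#'
#' @param truth A [sim_truth()].
#' @param trait Trait label for the generated observations.
#' @return A [met_dataset()] with the truth attached as attribute `truth`.
#' @examples
#' d <- simulate_trait(random_truth(G = 4, E = 3, k = 1, seed = 7))
#' is_balanced(d)
#' @export
simulate_trait <- function(truth, trait = "trait_001") {
  stopifnot(inherits(truth, "sim_truth"))
  G <- truth$G; E <- truth$E; R <- truth$n_rep
  surface <- truth_surface(truth)
  old_seed <- globalenv()$.Random.seed
  set.seed(truth$seed)
  blocks <- matrix(rnorm(E * R, sd = truth$block_sd), E, R)
  eps <- switch(truth$noise,
    gaussian = rnorm(G * E * R, sd = truth$error_sd),
    t = {
      df <- truth$noise_df
      scale <- if (df > 2) sqrt((df - 2) / df) else 1
      truth$error_sd * scale * rt(G * E * R, df = df)
    }
  )
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  grid <- tidyr::expand_grid(
    genotype = rownames(surface),
    environment = colnames(surface),
    replicate = paste0("R", seq_len(R))
  )
  gi <- match(grid$genotype, rownames(surface))
  ei <- match(grid$environment, colnames(surface))
  ri <- as.integer(sub("^R", "", grid$replicate))
  grid$trait <- trait
  grid$value <- surface[cbind(gi, ei)] + blocks[cbind(ei, ri)] + eps
  out <- met_dataset(grid)
  attr(out, "truth") <- setNames(list(truth), trait)
  out
}

#' Simulate a multi-trait trial panel
#'
#' Generates `n_traits` independent traits sharing the design (G, E, n_rep)
#' of a base truth; each trait gets its own randomly drawn effect sizes.
#' Truths are recorded so downstream recovery can be checked per trait.
#'
#' @param n_traits Number of traits to simulate.
#' @param base A [sim_truth()] template fixing G, E, k, n_rep and scales.
#' @param seed Integer seed controlling all per-trait draws.
#' @param effect_scales Passed to [random_truth()] for every trait.
#' @return A [met_dataset()] with traits `trait_001` ... and attribute
#'   `truth`, a named list retrievable with [get_truth()].
#' @export
simulate_multitrait <- function(n_traits, base = random_truth(11, 5, 2, seed = 1),
                                seed = 1L, effect_scales = list()) {
  if (n_traits < 1) abort("n_traits must be >= 1")
  labels <- sprintf("trait_%03d", seq_len(n_traits))
  scales <- modifyList(
    list(block_sd = base$block_sd, error_sd = base$error_sd),
    effect_scales
  )
  per_trait <- purrr::map2(labels, seq_len(n_traits), function(lab, i) {
    truth <- random_truth(base$G, base$E, base$k, seed = seed * 1000L + i,
                          effect_scales = scales, n_rep = base$n_rep)
    simulate_trait(truth, trait = lab)
  })
  obs <- purrr::list_rbind(purrr::map(per_trait, as_tibble))
  out <- met_dataset(obs)
  attr(out, "truth") <- purrr::reduce(purrr::map(per_trait, attr, "truth"), c)
  out
}

#' @rdname simulate_multitrait
#' @param data A simulated dataset.
#' @param trait Trait label to retrieve the generating truth for.
#' @export
get_truth <- function(data, trait) {
  truths <- attr(data, "truth")
  if (is.null(truths) || !trait %in% names(truths)) {
    abort(sprintf("no recorded truth for trait %s", deparse(trait)))
  }
  truths[[trait]]
}
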