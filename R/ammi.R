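#' Fit the AMMI bilinear model
#'
#' Additive main effects and multiplicative interaction: genotype and
#' environment means give the additive part, and a singular value
#' decomposition of the double-centred cell-mean matrix
#' `Z_ij = y_ij - ybar_i. - ybar_.j + ybar_..` gives the interaction
#' principal component axes (IPCA). The share of GEI sum of squares on
#' axis `k` is `theta_k = 100 * lambda_k^2 / sum(lambda^2)`.
#'
#' Axis significance uses Gollob degrees of freedom `G + E - 1 - 2k`, with
#' `F = (n_rep * lambda_k^2 / df_k) / MS_error` against the replicate-level
#' pooled error mean square when one is supplied (or available from a
#' source ANOVA via [ammi()]).
#'
#' Per axis, the sign is fixed so the genotype score of largest magnitude
#' is positive, making biplots reproducible across platforms.
#'
#' @param m A [ge_matrix()] of cell means.
#' @param n_retained Number of IPCA axes kept in the fitted surface
#'   (`"all"` for every axis). The residual `rho` holds the discarded axes.
#' @param ms_error,df_error Pooled error mean square and its degrees of
#'   freedom from the replicate-level ANOVA; optional, enables axis tests.
#' @return An `ammi_fit` with elements `mu`, `alpha`, `tau`, `lambda`,
#'   `gamma` (G x p genotype eigenvectors), `delta` (E x p environment
#'   eigenvectors), `theta` (percent of GEI SS per axis), `residual`,
#'   `n_retained`, `axis_tests`, and bookkeeping (`trait`, `n_rep`,
#'   `ss_gei` on the cell-mean scale).
#' @examples
#' truth <- random_truth(G = 11, E = 5, k = 2, seed = 42,
#'                       effect_scales = list(error_sd = 0, block_sd = 0))
#' fit <- fit_ammi(cell_means(simulate_trait(truth)))
#' round(fit$theta, 2)
#' @export
fit_ammi <- function(m, n_retained = "all", ms_error = NULL, df_error = NULL) {
  stopifnot(inherits(m, "ge_matrix"))
  y <- unclass(m)[,]
  G <- nrow(y); E <- ncol(y)
  p <- min(G - 1, E - 1)
  mu <- mean(y)
  alpha <- rowMeans(y) - mu
  tau <- colMeans(y) - mu
  z <- sweep(sweep(y, 1, rowMeans(y)), 2, colMeans(y) - mu)
  sv <- svd(z, nu = p, nv = p)
  lambda <- sv$d[seq_len(p)]
  gamma <- sv$u
  delta <- sv$v
  # sign convention: largest-magnitude genotype score positive per axis
  for (k in seq_len(p)) {
    if (gamma[which.max(abs(gamma[, k])), k] < 0) {
      gamma[, k] <- -gamma[, k]
      delta[, k] <- -delta[, k]
    }
  }
  rownames(gamma) <- rownames(y); rownames(delta) <- colnames(y)
  colnames(gamma) <- colnames(delta) <- paste0("PC", seq_len(p))
  ss_gei <- sum(z^2)
  degenerate <- ss_gei <= .Machine$double.eps * G * E
  theta <- if (degenerate) rep(0, p) else 100 * lambda^2 / sum(lambda^2)
  if (identical(n_retained, "all")) n_retained <- p
  if (n_retained > p) abort("n_retained exceeds the number of axes",
                            class = "metstab_dimension_error")
  keep <- seq_len(n_retained)
  fitted_gei <- if (n_retained > 0) {
    gamma[, keep, drop = FALSE] %*%
      (lambda[keep] * t(delta[, keep, drop = FALSE]))
  } else {
    matrix(0, G, E)
  }
  residual <- z - fitted_gei
  axis_tests <- NULL
  n_rep <- attr(m, "n_rep")
  if (!is.null(ms_error)) {
    df_axis <- G + E - 1 - 2 * seq_len(p)
    ms_axis <- n_rep * lambda^2 / df_axis
    fval <- ms_axis / ms_error
    pval <- if (is.null(df_error)) rep(NA_real_, p) else
      pf(fval, df_axis, df_error, lower.tail = FALSE)
    axis_tests <- tibble(axis = seq_len(p), df = df_axis,
                         ss = n_rep * lambda^2, ms = ms_axis,
                         f_statistic = fval, p_value = pval)
  }
  structure(
    list(mu = mu, alpha = alpha, tau = tau, lambda = lambda,
         gamma = gamma, delta = delta, theta = theta,
         residual = residual, n_retained = n_retained,
         axis_tests = axis_tests, degenerate = degenerate,
         trait = attr(m, "trait"), n_rep = n_rep, ss_gei = ss_gei),
    class = "ammi_fit"
  )
}

#' @exportS3Method base::print
print.ammi_fit <- function(x, ...) {
  cat(sprintf("<ammi_fit> trait %s: %d genotypes x %d environments, %d IPCA axes (%d retained)\n",
              deparse(x$trait), length(x$alpha), length(x$tau),
              length(x$lambda), x$n_retained))
  cat("  GEI share per axis (%):", paste(sprintf("%.1f", x$theta), collapse = ", "), "\n")
  invisible(x)
}

#' Fit AMMI from replicate-level data
#'
#' Convenience wrapper: forms cell means, runs the combined ANOVA to obtain
#' the pooled error mean square, and fits the bilinear model with axis
#' tests attached.
#'
#' @param data A `met_dataset` or compatible data frame.
#' @param trait Trait label (optional for single-trait data).
#' @param n_retained Axes kept; default `"all"`.
#' @return A list: `fit` (an `ammi_fit`), `anova` (the combined ANOVA
#'   tibble).
#' @export
ammi <- function(data, trait = NULL, n_retained = "all") {
  cm <- cell_means(data, trait)
  comb <- combined_anova(data, trait)
  res_row <- dplyr::filter(comb$anova, .data$source == "residual")
  fit <- fit_ammi(cm, n_retained = n_retained,
                  ms_error = res_row$ms, df_error = res_row$df)
  list(fit = fit, anova = comb$anova)
}

#' Percent of total variation per ANOVA source and IPCA axis
#'
#' Expresses environment, genotype and GEI sums of squares (and the per-axis
#' split within GEI) as percentages of the replicate-level total sum of
#' squares; the remainder is the block and residual share.
#'
#' @param fit An `ammi_fit`.
#' @param anova Combined ANOVA tibble for the same trait (from
#'   [combined_anova()] or [ammi()]).
#' @return A tibble with columns `source`, `ss`, `pct_total`.
#' @export
ss_shares <- function(fit, anova) {
  stopifnot(inherits(fit, "ammi_fit"))
  need <- c("environment", "genotype", "GEI", "block(environment)", "residual")
  if (!all(need %in% anova$source)) {
    abort("anova table lacks the combined-analysis sources")
  }
  ss <- setNames(anova$ss, anova$source)
  total <- sum(ss)
  axis_ss <- fit$n_rep * fit$lambda^2
  if (abs(sum(axis_ss) - ss[["GEI"]]) > 1e-6 * max(ss[["GEI"]], 1)) {
    abort("fit and anova disagree on the GEI sum of squares; same trait?")
  }
  ss_out <- unname(c(ss["environment"], ss["genotype"], ss["GEI"], axis_ss,
                     ss["block(environment)"], ss["residual"]))
  tibble(
    source = c("environment", "genotype", "GEI",
               paste0("GEI: PC", seq_along(fit$lambda)),
               "block(environment)", "residual"),
    ss = ss_out,
    pct_total = 100 * ss_out / total
  )
}

#' AMMI biplot coordinates
#'
#' AMMI1 plots mean performance against the first IPCA axis: genotype
#' points `(mu + alpha_i, lambda_1^f * gamma_i1)` and environment points
#' `(mu + tau_j, lambda_1^f * delta_j1)`. AMMI2 plots the first two IPCA
#' axes with scores `lambda^f * gamma` (genotypes) and `lambda^f * delta`
#' (environments); the distance of an environment from the origin measures
#' the strength of its interaction.
#'
#' @param fit An `ammi_fit`.
#' @param kind `"AMMI1"` or `"AMMI2"`.
#' @param svp_exponent Singular-value partitioning exponent `f` applied to
#'   both genotype and environment scores (0.5 = symmetric display).
#' @return A tibble: `label`, `type` (genotype/environment), `x`, `y`, and
#'   `vector_length` (distance from the origin, environments only, AMMI2).
#' @export
ammi_biplot_coords <- function(fit, kind = c("AMMI1", "AMMI2"),
                               svp_exponent = 0.5) {
  stopifnot(inherits(fit, "ammi_fit"))
  kind <- match.arg(kind)
  p <- length(fit$lambda)
  f <- svp_exponent
  if (kind == "AMMI1") {
    out <- tibble(
      label = c(names(fit$alpha), names(fit$tau)),
      type = rep(c("genotype", "environment"),
                 c(length(fit$alpha), length(fit$tau))),
      x = unname(c(fit$mu + fit$alpha, fit$mu + fit$tau)),
      y = unname(c(fit$lambda[1]^f * fit$gamma[, 1],
                   fit$lambda[1]^f * fit$delta[, 1]))
    )
    return(out)
  }
  if (p < 2) abort("AMMI2 needs at least two IPCA axes",
                   class = "metstab_dimension_error")
  out <- tibble(
    label = c(rownames(fit$gamma), rownames(fit$delta)),
    type = rep(c("genotype", "environment"),
               c(nrow(fit$gamma), nrow(fit$delta))),
    x = unname(c(fit$lambda[1]^f * fit$gamma[, 1],
                 fit$lambda[1]^f * fit$delta[, 1])),
    y = unname(c(fit$lambda[2]^f * fit$gamma[, 2],
                 fit$lambda[2]^f * fit$delta[, 2]))
  )
  out$vector_length <- ifelse(out$type == "environment",
                              sqrt(out$x^2 + out$y^2), NA_real_)
  out
}

#' @export
tidy.ammi_fit <- function(x, ...) {
  scores <- rbind(
    data.frame(label = rownames(x$gamma), type = "genotype",
               effect = unname(x$alpha), x$gamma, check.names = FALSE),
    data.frame(label = rownames(x$delta), type = "environment",
               effect = unname(x$tau), x$delta, check.names = FALSE)
  )
  as_tibble(scores)
}

#' @export
glance.ammi_fit <- function(x, ...) {
  tibble(
    trait = x$trait,
    n_genotypes = length(x$alpha),
    n_environments = length(x$tau),
    n_axes = length(x$lambda),
    n_retained = x$n_retained,
    ss_gei = x$ss_gei,
    theta_1 = x$theta[1],
    theta_2 = if (length(x$theta) >= 2) x$theta[2] else NA_real_
  )
}

#' @rdname ammi_biplot_coords
#' @param object An `ammi_fit` (for `autoplot`).
#' @param ... Passed on (unused).
#' @export
autoplot.ammi_fit <- function(object, kind = "AMMI2", svp_exponent = 0.5, ...) {
  coords <- ammi_biplot_coords(object, kind = kind, svp_exponent = svp_exponent)
  lab <- if (kind == "AMMI1") {
    list(x = "mean performance", y = sprintf("IPCA1 (%.1f%% of GEI)", object$theta[1]))
  } else {
    list(x = sprintf("IPCA1 (%.1f%%)", object$theta[1]),
         y = sprintf("IPCA2 (%.1f%%)", object$theta[2]))
  }
  ggplot2::ggplot(coords, ggplot2::aes(x = .data$x, y = .data$y,
                                       colour = .data$type)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey60") +
    { if (kind == "AMMI2") ggplot2::geom_vline(xintercept = 0, linetype = 3,
                                               colour = "grey60") } +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       vjust = -0.6, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = lab$x, y = lab$y,
                  title = sprintf("%s biplot, trait %s", kind, object$trait)) +
    ggplot2::theme_minimal()
}
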