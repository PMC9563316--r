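#' AMMI-based stability indices
#'
#' Computes thirteen stability statistics from a fitted AMMI model, all on
#' the convention that smaller = more stable (rank 1 = most stable, average
#' ranks on ties). Writing `gamma_in` for the genotype eigenvector entry on
#' axis `n`, `delta_jn` for the environment eigenvector entry,
#' `s_in = lambda_n^{1/2} gamma_in` for the scaled IPCA score and
#' `theta_n` for the proportion (0-1) of GEI sum of squares on axis `n`,
#' the indices over the `N'` retained axes are:
#'
#' * `ASTAB = sum lambda_n gamma_in^2`
#' * `ASI   = sqrt(s_i1^2 theta_1^2 + s_i2^2 theta_2^2)`
#' * `ASV   = sqrt((SS_1/SS_2 * s_i1)^2 + s_i2^2)` with `SS_n = lambda_n^2`
#' * `AVAMGE = sum_j sum_n |lambda_n gamma_in delta_jn|`
#' * `DA    = sqrt(sum (lambda_n gamma_in)^2)` (Annicchiarico's D)
#' * `DZ    = sqrt(sum gamma_in^2)` (Zhang's D)
#' * `EV    = sum gamma_in^2 / N'`
#' * `FA    = sum lambda_n^2 gamma_in^2`
#' * `MASI  = sqrt(sum s_in^2 theta_n^2)`
#' * `MASV  = sqrt(sum_{n<N'} (SS_n/SS_{n+1} * s_in)^2 + s_iN'^2)`
#' * `SIPC  = sum |s_in|`
#' * `WAAS  = sum |s_in| theta_n / sum theta_n`
#' * `ZA    = sum theta_n |s_in|`
#'
#' `ASI` and `ASV` need at least two axes; with `N' = 1` they are returned
#' as `NA` rather than zero.
#'
#' @param fit An `ammi_fit` from [fit_ammi()] or [ammi()].
#' @param n_retained Number of IPCA axes `N'` to use. Default: axes
#'   significant at p < 0.05 by the fit's axis tests (minimum 2), or 2
#'   when no tests are attached.
#' @return A `stability_table`: tibble with one row per genotype, a value
#'   and a rank column per index, plus attributes `n_retained` and `trait`.
#' @examples
#' truth <- random_truth(G = 11, E = 5, k = 2, seed = 3)
#' fit <- fit_ammi(cell_means(simulate_trait(truth)))
#' stability_indices(fit, n_retained = 2)
#' @export
stability_indices <- function(fit, n_retained = NULL) {
  stopifnot(inherits(fit, "ammi_fit"))
  p <- length(fit$lambda)
  if (is.null(n_retained)) {
    n_retained <- if (!is.null(fit$axis_tests) &&
                      !all(is.na(fit$axis_tests$p_value))) {
      max(2L, sum(fit$axis_tests$p_value < 0.05, na.rm = TRUE))
    } else {
      2L
    }
    n_retained <- min(n_retained, p)
  }
  if (n_retained > p) abort("n_retained exceeds the number of axes",
                            class = "metstab_dimension_error")
  if (n_retained < 1) abort("need at least one axis")
  np <- seq_len(n_retained)
  lambda <- fit$lambda[np]
  gamma <- fit$gamma[, np, drop = FALSE]
  delta <- fit$delta[, np, drop = FALSE]
  theta <- if (fit$degenerate) rep(0, n_retained) else fit$theta[np] / 100
  s <- sweep(gamma, 2, sqrt(lambda), `*`)
  ss_axis <- lambda^2

  astab <- colSums(lambda * t(gamma^2))
  da <- sqrt(colSums((lambda * t(gamma))^2))
  dz <- sqrt(rowSums(gamma^2))
  ev <- rowSums(gamma^2) / n_retained
  fa <- colSums(lambda^2 * t(gamma^2))
  masi <- sqrt(colSums(theta^2 * t(s^2)))
  waas <- if (sum(theta) > 0) colSums(theta * t(abs(s))) / sum(theta) else
    rowSums(abs(s)) * 0
  sipc <- rowSums(abs(s))
  za <- colSums(theta * t(abs(s)))
  avamge <- abs(sweep(gamma, 2, lambda, `*`)) %*% t(abs(delta)) |> rowSums()
  if (n_retained >= 2) {
    asi <- sqrt(s[, 1]^2 * theta[1]^2 + s[, 2]^2 * theta[2]^2)
    wts <- ss_axis[-n_retained] / ss_axis[-1]  # SS_n / SS_{n+1}
    masv <- sqrt(
      rowSums(sweep(s[, -n_retained, drop = FALSE], 2, wts, `*`)^2) +
        s[, n_retained]^2
    )
    asv <- sqrt((ss_axis[1] / ss_axis[2] * s[, 1])^2 + s[, 2]^2)
  } else {
    asi <- asv <- masv <- rep(NA_real_, nrow(gamma))
  }

  vals <- tibble(
    genotype = rownames(gamma),
    ASTAB = unname(astab), ASI = unname(asi), ASV = unname(asv),
    AVAMGE = unname(avamge), DA = unname(da), DZ = unname(dz),
    EV = unname(ev), FA = unname(fa), MASI = unname(masi),
    MASV = unname(masv), SIPC = unname(sipc), WAAS = unname(waas),
    ZA = unname(za)
  )
  ranks <- dplyr::mutate(vals, dplyr::across(-"genotype", rank_asc))
  names(ranks)[-1] <- paste0("rank_", names(ranks)[-1])
  out <- dplyr::left_join(vals, ranks, by = "genotype")
  structure(out, n_retained = n_retained, trait = fit$trait,
            class = c("stability_table", class(out)))
}

#' Spearman rank concordance among stability indices
#'
#' Pairwise Spearman correlations of the index value columns of a
#' [stability_indices()] table. Indices that are undefined (all `NA`) or
#' constant across genotypes yield `NA` entries.
#'
#' @param table A `stability_table`.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
rank_concordance <- function(table) {
  stopifnot(inherits(table, "stability_table"))
  idx <- index_names()
  vals <- as.matrix(table[, idx])
  keep_defined <- colSums(!is.na(vals)) > 0
  if (sum(keep_defined) < 2) abort("need at least two defined indices")
  out <- matrix(NA_real_, length(idx), length(idx), dimnames = list(idx, idx))
  for (i in seq_along(idx)) {
    for (j in seq_len(i)) {
      if (keep_defined[i] && keep_defined[j]) {
        xi <- vals[, i]; xj <- vals[, j]
        if (sd(xi) > 0 && sd(xj) > 0) {
          out[i, j] <- out[j, i] <- cor(xi, xj, method = "spearman")
        }
      }
    }
    if (keep_defined[i]) out[i, i] <- 1
  }
  out
}

index_names <- function() {
  c("ASTAB", "ASI", "ASV", "AVAMGE", "DA", "DZ", "EV", "FA", "MASI",
    "MASV", "SIPC", "WAAS", "ZA")
}
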