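#' Metabolomics feature matrix
#'
#' Couples a samples x features intensity matrix with per-sample design
#' labels (genotype, environment, replicate) and per-feature metadata
#' (m/z label, ionisation mode). Raw intensities must be non-negative.
#'
#' @param intensities Numeric samples x features matrix.
#' @param sample_meta Data frame with one row per sample: columns
#'   `genotype`, `environment`, `replicate`.
#' @param feature_meta Data frame with one row per feature: columns `mz`
#'   (label) and `ion_mode` (`"positive"` or `"negative"`). Defaults to
#'   column names of `intensities` with positive mode.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(intensities, sample_meta, feature_meta = NULL) {
  intensities <- as.matrix(intensities)
  sample_meta <- as_tibble(sample_meta)
  if (nrow(sample_meta) != nrow(intensities)) {
    abort("sample_meta rows must match intensity rows")
  }
  need <- setdiff(c("genotype", "environment", "replicate"), names(sample_meta))
  if (length(need)) {
    abort(sprintf("sample_meta lacks column(s): %s", paste(need, collapse = ", ")))
  }
  if (is.null(feature_meta)) {
    if (is.null(colnames(intensities))) {
      colnames(intensities) <- sprintf("f%04d", seq_len(ncol(intensities)))
    }
    feature_meta <- tibble(mz = colnames(intensities), ion_mode = "positive")
  }
  feature_meta <- as_tibble(feature_meta)
  if (nrow(feature_meta) != ncol(intensities)) {
    abort("feature_meta rows must match intensity columns")
  }
  if (!all(c("mz", "ion_mode") %in% names(feature_meta))) {
    abort("feature_meta needs columns `mz` and `ion_mode`")
  }
  if (!all(feature_meta$ion_mode %in% c("positive", "negative"))) {
    abort("ion_mode must be 'positive' or 'negative'")
  }
  colnames(intensities) <- feature_meta$mz
  structure(
    list(intensities = intensities, sample_meta = sample_meta,
         feature_meta = feature_meta),
    class = "feature_matrix"
  )
}

#' @exportS3Method base::print
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features\n",
              nrow(x$intensities), ncol(x$intensities)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$intensities)

#' Total-ion-count normalization
#'
#' Expresses every intensity as a percentage of its sample's total ion
#' count, so each sample row sums to 100. Idempotent.
#'
#' @param m A [feature_matrix()].
#' @return A `feature_matrix` with normalized intensities.
#' @export
tic_normalize <- function(m) {
  stopifnot(inherits(m, "feature_matrix"))
  totals <- rowSums(m$intensities)
  zero <- which(totals <= 0)
  if (length(zero)) {
    abort(sprintf("sample %d has non-positive total ion count", zero[1]),
          class = "metstab_validation_error")
  }
  m$intensities <- 100 * m$intensities / totals
  m
}

#' Log10 transform and Pareto scaling
#'
#' Per feature column `x`: `z = (log10(x) - mean(log10 x)) / sqrt(sd(log10
#' x))` — mean centring with a Pareto divisor (square root of the standard
#' deviation), which shrinks fold-change dominance less aggressively than
#' unit-variance scaling. Zero-variance columns map to all-zero columns.
#'
#' Zeros are handled by adding half the smallest positive intensity in the
#' matrix before the log (a standard metabolomics offset); disable with
#' `offset = FALSE`, in which case non-positive values are an error.
#'
#' @param m A [feature_matrix()].
#' @param offset Apply the half-minimum offset to non-positive values.
#' @return A `feature_matrix` of scaled values (no longer non-negative).
#' @export
log_pareto <- function(m, offset = TRUE) {
  stopifnot(inherits(m, "feature_matrix"))
  x <- m$intensities
  if (any(x <= 0)) {
    if (!offset) {
      abort("non-positive intensities with offset disabled",
            class = "metstab_domain_error")
    }
    pos <- x[x > 0]
    if (!length(pos)) abort("all intensities are non-positive",
                            class = "metstab_domain_error")
    x <- x + min(pos) / 2
  }
  lx <- log10(x)
  ctr <- sweep(lx, 2, colMeans(lx))
  sds <- apply(lx, 2, sd)
  div <- sqrt(sds)
  div[sds == 0] <- 1  # constant column -> centred column is already all-zero
  m$intensities <- sweep(ctr, 2, div, `/`)
  m
}

#' One-way ANOVA screening with Bonferroni correction
#'
#' Runs a per-feature one-way fixed-effects ANOVA on the chosen design
#' factor and flags features whose Bonferroni-adjusted p-value falls below
#' `alpha`. The Bonferroni family is the set of features tested in the call.
#'
#' @param m A [feature_matrix()].
#' @param factor Grouping factor: `"genotype"` or `"environment"`.
#' @param alpha Significance level on the adjusted p-value.
#' @return A tibble with one row per feature: `mz`, `f_statistic`,
#'   `p_value`, `p_adjusted`, `significant`.
#' @export
anova_screen <- function(m, factor = c("genotype", "environment"),
                         alpha = 0.05) {
  stopifnot(inherits(m, "feature_matrix"))
  factor <- match.arg(factor)
  g <- as.factor(m$sample_meta[[factor]])
  if (nlevels(g) < 2) {
    abort(sprintf("factor `%s` has a single level", factor),
          class = "metstab_design_error")
  }
  if (min(table(g)) < 2) {
    abort("every factor level needs at least 2 samples",
          class = "metstab_design_error")
  }
  stats_per_feature <- purrr::map(
    seq_len(ncol(m$intensities)),
    function(j) {
      fit <- oneway.test(m$intensities[, j] ~ g, var.equal = TRUE)
      c(f = unname(fit$statistic), p = unname(fit$p.value))
    }
  )
  f_stat <- purrr::map_dbl(stats_per_feature, "f")
  p_raw <- purrr::map_dbl(stats_per_feature, "p")
  # zero within-group variance with equal means yields F = 0/0; treat as no
  # evidence against the null
  p_raw[is.nan(p_raw)] <- 1
  f_stat[is.nan(f_stat)] <- 0
  p_adj <- p.adjust(p_raw, method = "bonferroni")
  tibble(
    mz = m$feature_meta$mz,
    f_statistic = f_stat,
    p_value = p_raw,
    p_adjusted = p_adj,
    significant = p_adj < alpha
  )
}

#' Rank features by environmental variation via two-way ANOVA
#'
#' Fits a per-feature two-factor fixed-effects ANOVA (genotype, environment
#' and their interaction) and ranks features by ascending p-value of the
#' chosen term (ties broken by larger F), returning the top `k`. The
#' default term is the environment main effect — the features varying most
#' across locations. Unbalanced designs fall back to Type-II sums of
#' squares with a notice.
#'
#' @param m A [feature_matrix()].
#' @param k Number of top features to return.
#' @param term Ranking term: `"environment"`, `"genotype"` or
#'   `"interaction"`.
#' @return A tibble of the `k` top-ranked features with per-term F and p.
#' @export
two_way_rank <- function(m, k,
                         term = c("environment", "genotype", "interaction")) {
  stopifnot(inherits(m, "feature_matrix"))
  term <- match.arg(term)
  gf <- as.factor(m$sample_meta$genotype)
  ef <- as.factor(m$sample_meta$environment)
  if (nlevels(gf) < 2 || nlevels(ef) < 2) {
    abort("genotype and environment both need >= 2 levels",
          class = "metstab_design_error")
  }
  balanced <- length(unique(table(gf, ef))) == 1L
  if (!balanced) {
    inform("design unbalanced; using Type-II sums of squares")
  }
  row_for <- function(j) {
    fit <- lm(m$intensities[, j] ~ gf * ef)
    tab <- if (balanced) {
      anova(fit)
    } else {
      if (!requireNamespace("car", quietly = TRUE)) {
        abort("Type-II fallback requires the car package")
      }
      car::Anova(fit, type = 2)
    }
    pick <- function(pattern) {
      i <- grep(pattern, rownames(tab))[1]
      c(f = tab[i, "F value"], p = tab[i, "Pr(>F)"])
    }
    c(gen = pick("^gf$"), env = pick("^ef$"), int = pick("gf:ef"))
  }
  res <- purrr::map(seq_len(ncol(m$intensities)), row_for)
  out <- tibble(
    mz = m$feature_meta$mz,
    f_genotype = purrr::map_dbl(res, "gen.f"),
    p_genotype = purrr::map_dbl(res, "gen.p"),
    f_environment = purrr::map_dbl(res, "env.f"),
    p_environment = purrr::map_dbl(res, "env.p"),
    f_interaction = purrr::map_dbl(res, "int.f"),
    p_interaction = purrr::map_dbl(res, "int.p")
  )
  key <- switch(term,
    environment = c("p_environment", "f_environment"),
    genotype = c("p_genotype", "f_genotype"),
    interaction = c("p_interaction", "f_interaction")
  )
  out <- dplyr::arrange(out, .data[[key[1]]], dplyr::desc(.data[[key[2]]]))
  head(out, k)
}
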