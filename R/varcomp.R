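#' Variance components from a trial analysis
#'
#' Container for the genotypic (`sigma2_g`), genotype-by-environment
#' (`sigma2_ge`) and residual (`sigma2_e`) variance components together
#' with the design sizes needed by the heritability formulas. Negative
#' method-of-moments estimates are truncated to zero and flagged.
#'
#' @param sigma2_g,sigma2_ge,sigma2_e Variance components (>= 0 after
#'   truncation).
#' @param n_rep Replicates per environment.
#' @param n_loc Number of environments (1 for a single-environment fit).
#' @param method `"ems"` (expected mean squares) or `"reml"`.
#' @param scope `"single"` or `"combined"`.
#' @return A `var_components` object.
#' @export
var_components <- function(sigma2_g, sigma2_e, sigma2_ge = NA_real_,
                           n_rep = 1L, n_loc = 1L,
                           method = c("ems", "reml"),
                           scope = c("single", "combined")) {
  method <- match.arg(method)
  scope <- match.arg(scope)
  truncated <- isTRUE(sigma2_g < 0) || isTRUE(sigma2_ge < 0) ||
    isTRUE(sigma2_e < 0)
  structure(
    list(
      sigma2_g = max(sigma2_g, 0),
      sigma2_ge = if (is.na(sigma2_ge)) NA_real_ else max(sigma2_ge, 0),
      sigma2_e = max(sigma2_e, 0),
      n_rep = as.integer(n_rep), n_loc = as.integer(n_loc),
      method = method, scope = scope, truncated = truncated
    ),
    class = "var_components"
  )
}

#' @exportS3Method base::print
print.var_components <- function(x, ...) {
  cat(sprintf(
    "<var_components> (%s, %s) sigma2_g=%.4g, sigma2_ge=%s, sigma2_e=%.4g; n_rep=%d, n_loc=%d%s\n",
    x$method, x$scope, x$sigma2_g,
    ifelse(is.na(x$sigma2_ge), "NA", sprintf("%.4g", x$sigma2_ge)),
    x$sigma2_e, x$n_rep, x$n_loc,
    if (x$truncated) " [negative estimate truncated]" else ""
  ))
  invisible(x)
}

#' @export
tidy.var_components <- function(x, ...) {
  tibble(
    component = c("sigma2_g", "sigma2_ge", "sigma2_e"),
    estimate = c(x$sigma2_g, x$sigma2_ge, x$sigma2_e),
    method = x$method, scope = x$scope
  )
}

anova_tibble <- function(tab, source_names) {
  out <- tibble(
    source = source_names,
    df = tab$Df,
    ss = tab$`Sum Sq`,
    ms = tab$`Mean Sq`,
    f_statistic = tab$F, p_value = tab$p
  )
  out$stars <- p_stars(out$p_value)
  out
}

trait_subset <- function(data, trait) {
  data <- as_met_dataset(data)
  traits <- attr(data, "trait_index")
  if (is.null(trait)) {
    if (length(traits) != 1L) abort("dataset holds several traits; supply `trait`")
    trait <- traits
  }
  if (!trait %in% traits) {
    abort(sprintf("trait %s not present", deparse(trait)))
  }
  dplyr::filter(as_tibble(data), .data$trait == !!trait)
}

#' Single-environment RCBD analysis of variance
#'
#' Fits `value ~ genotype + block` within one environment of a randomized
#' complete block design, and estimates variance components by expected
#' mean squares: `sigma2_g = (MS_G - MS_res) / n_rep`, `sigma2_e = MS_res`.
#'
#' @param data A `met_dataset` or compatible data frame.
#' @param trait Trait label (optional for single-trait data).
#' @param environment Environment label to analyse.
#' @return A list with elements `anova` (tibble: source, df, ss, ms, F, p,
#'   stars) and `varcomp` (a [var_components()]).
#' @export
rcbd_anova <- function(data, trait = NULL, environment) {
  sub <- trait_subset(data, trait)
  sub <- dplyr::filter(sub, .data$environment == !!environment)
  if (!nrow(sub)) abort(sprintf("environment %s not present", deparse(environment)))
  gf <- as.factor(sub$genotype); bf <- as.factor(sub$replicate)
  counts <- table(gf, bf)
  if (any(counts != 1)) {
    abort("environment is not a complete RCBD (each genotype must appear once per block)",
          class = "metstab_validation_error")
  }
  fit <- aov(value ~ gf + bf, data = sub)
  tab <- as.data.frame(anova(fit))
  r <- nlevels(bf)
  ms <- tab$`Mean Sq`; names(ms) <- rownames(tab)
  out_tab <- anova_tibble(
    data.frame(Df = tab$Df, `Sum Sq` = tab$`Sum Sq`, `Mean Sq` = tab$`Mean Sq`,
               F = tab$`F value`, p = tab$`Pr(>F)`, check.names = FALSE),
    c("genotype", "block", "residual")
  )
  vc <- var_components(
    sigma2_g = (ms[["gf"]] - ms[["Residuals"]]) / r,
    sigma2_e = ms[["Residuals"]],
    n_rep = r, n_loc = 1L, method = "ems", scope = "single"
  )
  list(anova = out_tab, varcomp = vc)
}

#' Combined analysis of variance across environments
#'
#' Partitions a balanced genotype x environment x replicate trial into
#' environment, block-within-environment, genotype, GEI and residual
#' sources. Following the random treatment of the interaction, genotype is
#' tested against the GEI mean square and GEI against the residual;
#' environment is tested against block-within-environment. Variance
#' components come from expected mean squares
#' (`sigma2_ge = (MS_GEI - MS_res)/n_rep`,
#' `sigma2_g = (MS_G - MS_GEI)/(n_rep * n_loc)`) or, with
#' `method = "reml"`, from a mixed model with fixed environment and block
#' and random genotype and GEI effects fitted by restricted maximum
#' likelihood.
#'
#' @param data A `met_dataset` or compatible data frame.
#' @param trait Trait label (optional for single-trait data).
#' @param method `"ems"` (requires a balanced design) or `"reml"`.
#' @return A list with elements `anova` (tibble; `NULL` for pure REML on
#'   unbalanced data) and `varcomp` (a [var_components()]).
#' @export
combined_anova <- function(data, trait = NULL, method = c("ems", "reml")) {
  method <- match.arg(method)
  sub <- trait_subset(data, trait)
  gf <- as.factor(sub$genotype); ef <- as.factor(sub$environment)
  bf <- as.factor(sub$replicate)
  counts <- table(gf, ef, bf)
  balanced <- all(counts == 1)
  G <- nlevels(gf); L <- nlevels(ef); R <- nlevels(bf)
  if (!balanced && method == "ems") {
    abort("design is unbalanced; use method = 'reml'",
          class = "metstab_validation_error")
  }
  out_tab <- NULL
  if (balanced) {
    fit <- aov(value ~ ef + ef:bf + gf + gf:ef, data = sub)
    tab <- as.data.frame(anova(fit))
    ms <- setNames(tab$`Mean Sq`, rownames(tab))
    df <- setNames(tab$Df, rownames(tab))
    ss <- setNames(tab$`Sum Sq`, rownames(tab))
    ord <- c("ef", "ef:bf", "gf", "ef:gf", "Residuals")
    # F ratios per the random-GEI expected mean squares
    fval <- c(
      ms[["ef"]] / ms[["ef:bf"]],
      ms[["ef:bf"]] / ms[["Residuals"]],
      ms[["gf"]] / ms[["ef:gf"]],
      ms[["ef:gf"]] / ms[["Residuals"]],
      NA_real_
    )
    fden_df <- c(df[["ef:bf"]], df[["Residuals"]], df[["ef:gf"]],
                 df[["Residuals"]], NA_real_)
    pval <- ifelse(is.na(fval), NA_real_,
                   pf(fval, df[ord], fden_df, lower.tail = FALSE))
    out_tab <- anova_tibble(
      data.frame(Df = df[ord], `Sum Sq` = ss[ord], `Mean Sq` = ms[ord],
                 F = fval, p = pval, check.names = FALSE),
      c("environment", "block(environment)", "genotype", "GEI", "residual")
    )
  }
  vc <- if (method == "ems") {
    ms <- setNames(out_tab$ms, out_tab$source)
    var_components(
      sigma2_g = (ms[["genotype"]] - ms[["GEI"]]) / (R * L),
      sigma2_ge = (ms[["GEI"]] - ms[["residual"]]) / R,
      sigma2_e = ms[["residual"]],
      n_rep = R, n_loc = L, method = "ems", scope = "combined"
    )
  } else {
    lfit <- lme4::lmer(
      value ~ environment + environment:replicate +
        (1 | genotype) + (1 | genotype:environment),
      data = sub, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                 optCtrl = list(xtol_abs = 1e-14, ftol_abs = 1e-14,
                                xtol_rel = 1e-14, ftol_rel = 1e-14,
                                maxeval = 100000))
    )
    vcs <- as.data.frame(lme4::VarCorr(lfit))
    grab <- function(grp) {
      i <- match(grp, vcs$grp)
      if (is.na(i)) 0 else vcs$vcov[i]
    }
    var_components(
      sigma2_g = grab("genotype"),
      sigma2_ge = grab("genotype:environment"),
      sigma2_e = grab("Residual"),
      n_rep = R, n_loc = L, method = "reml", scope = "combined"
    )
  }
  list(anova = out_tab, varcomp = vc)
}

#' Broad-sense heritability, single environment
#'
#' Entry-mean broad-sense heritability
#' \deqn{H^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_\varepsilon / \eta_{Rep})}
#' for a single-environment fit.
#'
#' @param v A [var_components()] with `scope = "single"`.
#' @return Heritability in `[0, 1]`; 0 when `sigma2_g` is 0.
#' @examples
#' heritability_single(var_components(2, 1, n_rep = 3))  # 0.857...
#' @export
heritability_single <- function(v) {
  stopifnot(inherits(v, "var_components"))
  if (v$scope != "single") abort("expected a single-environment fit")
  if (v$sigma2_g == 0) return(0)
  v$sigma2_g / (v$sigma2_g + v$sigma2_e / v$n_rep)
}

#' Broad-sense heritability, combined across environments
#'
#' \deqn{H^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_{ge}/\eta_{Loc} +
#'   \sigma^2_\varepsilon/(\eta_{Loc}\,\eta_{Rep}))}
#' The GEI term in the denominator means combined heritability is never
#' above the single-environment value at equal `sigma2_g`, `sigma2_e`
#' whenever `sigma2_ge > 0`.
#'
#' @param v A [var_components()] with `scope = "combined"`.
#' @return Heritability in `[0, 1]`; 0 when `sigma2_g` is 0.
#' @examples
#' v <- var_components(2, 1, sigma2_ge = 1, n_rep = 3, n_loc = 5,
#'                     scope = "combined")
#' heritability_combined(v)  # 0.882...
#' @export
heritability_combined <- function(v) {
  stopifnot(inherits(v, "var_components"))
  if (v$scope != "combined") abort("expected a combined fit")
  if (v$sigma2_g == 0) return(0)
  v$sigma2_g /
    (v$sigma2_g + v$sigma2_ge / v$n_loc + v$sigma2_e / (v$n_loc * v$n_rep))
}
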