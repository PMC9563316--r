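#' Run the full stability pipeline on a multi-trait trial
#'
#' For every trait: combined ANOVA with variance components and
#' heritability, AMMI fit with IPCA shares and stability indices, GGE
#' which-won-where, BLUP genotypic values with HMGV/RPGV/HMRPGV and WAASB;
#' then the cross-trait WAASBY matrix and MTSI selection. One CSV per
#' result table is written under `outdir`, plus a JSON run manifest.
#'
#' @param data A `met_dataset` (or compatible data frame) with >= 2 traits
#'   for the MTSI stage; single-trait input skips MTSI.
#' @param outdir Output directory, created if needed.
#' @param config Named list overriding defaults: `n_ipca_retained`
#'   (`NULL` = significant axes, min 2), `svp_exponent` (0.5),
#'   `waasby_weights` (c(50, 50)), `bonferroni_alpha` (0.05),
#'   `selection` (2/11), `seed` (1).
#' @return Invisibly, a list of the per-stage result tables.
#' @export
run_pipeline <- function(data, outdir, config = list()) {
  cfg <- modifyList(
    list(n_ipca_retained = NULL, svp_exponent = 0.5,
         waasby_weights = c(50, 50), bonferroni_alpha = 0.05,
         selection = 2 / 11, seed = 1L),
    config
  )
  data <- as_met_dataset(data)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  traits <- attr(data, "trait_index")

  herit <- list(); varcomp_rows <- list(); ammi_rows <- list()
  per_trait <- list()
  for (tr in traits) {
    comb <- combined_anova(data, trait = tr)
    vc <- comb$varcomp
    res_row <- dplyr::filter(comb$anova, .data$source == "residual")
    cm <- cell_means(data, trait = tr)
    fit <- fit_ammi(cm, ms_error = res_row$ms, df_error = res_row$df)
    stab <- stability_indices(fit, n_retained = cfg$n_ipca_retained)
    gge <- fit_gge(cm, svp_exponent = cfg$svp_exponent)
    www <- which_won_where(gge)
    bl <- fit_blup(data, trait = tr)
    bidx <- blup_indices(bl)
    wb <- waasb(bl)

    readr::write_csv(dplyr::mutate(comb$anova, trait = tr, .before = 1),
                     file.path(outdir, sprintf("anova_%s.csv", tr)))
    readr::write_csv(tidy(fit), file.path(outdir, sprintf("ammi_scores_%s.csv", tr)))
    readr::write_csv(as_tibble(stab),
                     file.path(outdir, sprintf("stability_%s.csv", tr)))
    readr::write_csv(tidy(gge), file.path(outdir, sprintf("gge_scores_%s.csv", tr)))
    readr::write_csv(
      tidyr::unnest(www$mega_envs, "environments") |>
        dplyr::rename(environment = "environments"),
      file.path(outdir, sprintf("gge_megaenv_%s.csv", tr)))
    readr::write_csv(dplyr::left_join(bidx, wb, by = "genotype"),
                     file.path(outdir, sprintf("blup_indices_%s.csv", tr)))

    herit[[tr]] <- tibble(
      trait = tr,
      h2_combined = heritability_combined(vc),
      sigma2_g = vc$sigma2_g, sigma2_ge = vc$sigma2_ge,
      sigma2_e = vc$sigma2_e
    )
    varcomp_rows[[tr]] <- dplyr::mutate(tidy(vc), trait = tr, .before = 1)
    ammi_rows[[tr]] <- glance(fit)
    per_trait[[tr]] <- list(anova = comb$anova, ammi = fit, stability = stab,
                            gge = gge, www = www, blup = bl)
  }
  heritability <- purrr::list_rbind(herit)
  readr::write_csv(heritability, file.path(outdir, "heritability.csv"))
  readr::write_csv(purrr::list_rbind(varcomp_rows),
                   file.path(outdir, "varcomp.csv"))
  readr::write_csv(purrr::list_rbind(ammi_rows),
                   file.path(outdir, "ammi_summary.csv"))

  mtsi_res <- NULL
  if (length(traits) >= 2) {
    w <- waasby_matrix(data, theta_y = cfg$waasby_weights[1],
                       theta_s = cfg$waasby_weights[2])
    mtsi_res <- mtsi(w, selection = cfg$selection)
    readr::write_csv(
      as_tibble(w, rownames = "genotype"),
      file.path(outdir, "waasby.csv"))
    readr::write_csv(mtsi_res$table, file.path(outdir, "mtsi.csv"))
  }

  manifest <- list(
    package = "metstab",
    version = as.character(utils::packageVersion("metstab")),
    r_version = R.version.string,
    seed = cfg$seed,
    config = cfg[c("n_ipca_retained", "svp_exponent", "waasby_weights",
                   "bonferroni_alpha", "selection")],
    n_genotypes = n_genotypes(data),
    n_environments = n_environments(data),
    n_traits = length(traits),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(per_trait = per_trait, heritability = heritability,
                 mtsi = mtsi_res))
}
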