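#' WAASBY superiority index
#'
#' Blends rescaled mean performance and rescaled stability into one 0-100
#' score per genotype:
#' \deqn{WAASBY_i = (rG_i \theta_Y + rW_i \theta_S) / (\theta_Y + \theta_S)}
#' where `rG` rescales the trait means to 0-100 (100 = best mean, inverted
#' for traits where smaller is better) and `rW` rescales WAASB so 100 = most
#' stable. A genotype best on both scales scores 100. If either scale has no
#' spread it is set to all-100 and flagged (no discrimination).
#'
#' @param mean_perf Named numeric vector of per-genotype trait means.
#' @param waasb Named numeric vector of per-genotype WAASB values (same
#'   genotypes).
#' @param theta_y,theta_s Non-negative weights on performance and
#'   stability; default 50/50.
#' @param negate_perf Set `TRUE` for traits where smaller means are better.
#' @return A tibble: genotype, rG, rW, waasby, plus attribute `degenerate`
#'   naming any collapsed scale.
#' @examples
#' waasby_index(c(A = 10, B = 12, C = 8), c(A = 0.2, B = 0.5, C = 0.1))
#' @export
waasby_index <- function(mean_perf, waasb, theta_y = 50, theta_s = 50,
                         negate_perf = FALSE) {
  if (length(mean_perf) < 2) abort("need at least two genotypes")
  if (theta_y + theta_s <= 0) abort("theta_y + theta_s must be positive")
  if (!identical(names(mean_perf), names(waasb))) {
    waasb <- waasb[names(mean_perf)]
    if (any(is.na(waasb))) abort("mean_perf and waasb name mismatch")
  }
  rg <- rescale_100(mean_perf, if (negate_perf) "lower" else "higher")
  rw <- rescale_100(waasb, "lower")
  degenerate <- c(
    if (isTRUE(attr(rg, "degenerate"))) "mean" else NULL,
    if (isTRUE(attr(rw, "degenerate"))) "stability" else NULL
  )
  out <- tibble(
    genotype = names(mean_perf),
    rG = as.numeric(rg), rW = as.numeric(rw),
    waasby = (as.numeric(rg) * theta_y + as.numeric(rw) * theta_s) /
      (theta_y + theta_s)
  )
  attr(out, "degenerate") <- degenerate
  out
}

#' WAASBY matrix for a multi-trait panel
#'
#' Runs the BLUP pipeline per trait — genotypic values, WAASB, WAASBY —
#' and assembles the genotype x trait WAASBY matrix that feeds [mtsi()].
#'
#' @param data A multi-trait `met_dataset`.
#' @param traits Traits to include; default all.
#' @param theta_y,theta_s WAASBY weights.
#' @param negate_traits Character vector of traits where smaller is better.
#' @return A genotype x trait numeric matrix of WAASBY scores.
#' @export
waasby_matrix <- function(data, traits = NULL, theta_y = 50, theta_s = 50,
                          negate_traits = character()) {
  data <- as_met_dataset(data)
  if (is.null(traits)) traits <- attr(data, "trait_index")
  cols <- purrr::map(traits, function(tr) {
    fit <- fit_blup(data, trait = tr)
    means <- rowMeans(fit$Gv)
    w <- waasb(fit)
    wv <- setNames(w$WAASB, w$genotype)[names(means)]
    wy <- waasby_index(means, wv, theta_y = theta_y, theta_s = theta_s,
                       negate_perf = tr %in% negate_traits)
    setNames(wy$waasby, wy$genotype)
  })
  m <- do.call(cbind, cols)
  colnames(m) <- traits
  m
}

# exploratory factor analysis on a correlation matrix: principal-axis
# loadings from the eigendecomposition, Kaiser retention, varimax rotation
fa_loadings <- function(corr, min_eigen = 1) {
  eig <- eigen(corr, symmetric = TRUE)
  nf <- max(1L, sum(eig$values >= min_eigen))
  loads <- eig$vectors[, seq_len(nf), drop = FALSE] %*%
    diag(sqrt(pmax(eig$values[seq_len(nf)], 0)), nf)
  rotated <- if (nf > 1) {
    rot <- varimax(loads, normalize = FALSE)
    loads %*% rot$rotmat
  } else {
    loads
  }
  rotated <- sign_fix_first(rotated)
  rownames(rotated) <- rownames(corr)
  colnames(rotated) <- paste0("FA", seq_len(nf))
  list(loadings = rotated, n_factors = nf, eigenvalues = eig$values)
}

#' Multi-trait stability index
#'
#' Factor analysis of the genotype x trait WAASBY matrix (correlation
#' based, factors retained at eigenvalue >= `min_eigen`, varimax rotation,
#' regression scores), followed by the Euclidean distance of every
#' genotype's factor scores from the ideotype — the per-trait maximum
#' WAASBY vector projected into the same factor space:
#' \deqn{MTSI_i = \sqrt{\sum_f (F_{if} - F^{ideo}_f)^2}}
#' Smaller distance = closer to the ideal stable high performer; rank 1 is
#' best. Zero-variance traits cannot enter the correlation matrix and are
#' dropped with a notice.
#'
#' @param w Genotype x trait WAASBY matrix (from [waasby_matrix()] or
#'   assembled by the caller).
#' @param selection Fraction of genotypes to select (default `2/11`, i.e.
#'   the top two of eleven); at least one genotype is always selected.
#' @param min_eigen Factor-retention threshold on the eigenvalues of the
#'   trait correlation matrix.
#' @return An `mtsi_result` with `waasby_matrix`, `loadings`, `scores`,
#'   `ideotype_scores`, `table` (tibble: genotype, mtsi, rank, selected),
#'   `n_factors`, `eigenvalues`.
#' @export
mtsi <- function(w, selection = 2 / 11, min_eigen = 1) {
  w <- as.matrix(w)
  if (ncol(w) < 2) abort("need at least two traits")
  if (nrow(w) < 3) abort("need at least three genotypes")
  keep <- apply(w, 2, sd) > 0
  if (any(!keep)) {
    inform(sprintf("dropping zero-variance trait(s): %s",
                   paste(colnames(w)[!keep], collapse = ", ")))
    w <- w[, keep, drop = FALSE]
    if (ncol(w) < 2) abort("fewer than two traits left after drops")
  }
  ctr <- colMeans(w)
  scl <- apply(w, 2, sd)
  z <- scale(w, center = ctr, scale = scl)
  corr <- cor(w)
  fa <- fa_loadings(corr, min_eigen = min_eigen)
  # regression (Thomson) factor scores: F = Z R^{-1} A; the pseudoinverse
  # keeps near-duplicate traits (singular R) workable
  canon <- MASS::ginv(corr) %*% fa$loadings
  scores <- z %*% canon
  ideo <- (apply(w, 2, max) - ctr) / scl
  ideo_scores <- drop(ideo %*% canon)
  d <- sqrt(rowSums(sweep(scores, 2, ideo_scores)^2))
  rk <- rank_asc(d)
  n_sel <- max(1L, floor(selection * nrow(w)))
  tab <- tibble(
    genotype = rownames(w), mtsi = unname(d), rank = unname(rk),
    selected = unname(rk <= n_sel)
  )
  structure(
    list(waasby_matrix = w, loadings = fa$loadings, scores = scores,
         ideotype_scores = ideo_scores, table = tab,
         n_factors = fa$n_factors, eigenvalues = fa$eigenvalues,
         selection = selection),
    class = "mtsi_result"
  )
}

#' @exportS3Method base::print
print.mtsi_result <- function(x, ...) {
  sel <- x$table$genotype[x$table$selected]
  cat(sprintf(
    "<mtsi_result> %d genotypes x %d traits, %d factor(s); selected: %s\n",
    nrow(x$waasby_matrix), ncol(x$waasby_matrix), x$n_factors,
    paste(sel, collapse = ", ")))
  invisible(x)
}

#' @export
tidy.mtsi_result <- function(x, ...) x$table

#' @export
glance.mtsi_result <- function(x, ...) {
  tibble(
    n_genotypes = nrow(x$waasby_matrix),
    n_traits = ncol(x$waasby_matrix),
    n_factors = x$n_factors,
    n_selected = sum(x$table$selected)
  )
}

#' @rdname mtsi
#' @param object An `mtsi_result` (for `autoplot`).
#' @param ... Unused.
#' @export
autoplot.mtsi_result <- function(object, ...) {
  tab <- dplyr::arrange(object$table, .data$rank)
  tab$genotype <- factor(tab$genotype, levels = rev(tab$genotype))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$mtsi, y = .data$genotype,
                                    fill = .data$selected)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "forestgreen",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = "multi-trait stability index (smaller = better)",
                  y = NULL, fill = "selected") +
    ggplot2::theme_minimal()
}
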