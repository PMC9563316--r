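#' Fit the GGE model
#'
#' Singular value decomposition of the environment-centred cell-mean matrix
#' `C_ij = y_ij - ybar_.j` ("centering 2"): the retained variation is the
#' genotype main effect plus GEI. Axis `k` explains
#' `100 * lambda_k^2 / sum(lambda^2)` percent of the G + GE sum of squares.
#' Scores are scaled by the singular-value partitioning exponent:
#' genotype scores by `lambda^f`, environment scores by `lambda^(1-f)`
#' (f = 0.5 gives the symmetric display).
#'
#' @param m A [ge_matrix()] of cell means.
#' @param svp_exponent Partitioning exponent `f` in `[0, 1]`.
#' @return A `gge_fit` with `centered`, `lambda`, `explained` (percent per
#'   axis), `genotype_scores` and `environment_scores` (tibbles with the
#'   first two axes), full score matrices `gen_full`/`env_full`, `trait`.
#' @examples
#' truth <- random_truth(G = 6, E = 4, k = 2, seed = 5)
#' g <- fit_gge(cell_means(simulate_trait(truth)))
#' g$explained
#' @export
fit_gge <- function(m, svp_exponent = 0.5) {
  stopifnot(inherits(m, "ge_matrix"))
  y <- unclass(m)[,]
  if (ncol(y) < 2) abort("GGE needs at least two environments",
                         class = "metstab_dimension_error")
  cc <- sweep(y, 2, colMeans(y))
  p <- min(nrow(y), ncol(y))
  sv <- svd(cc, nu = p, nv = p)
  lambda <- sv$d[seq_len(p)]
  u <- sv$u; v <- sv$v
  for (k in seq_len(p)) {  # same sign convention as the AMMI fit
    if (abs(lambda[k]) > 0 && u[which.max(abs(u[, k])), k] < 0) {
      u[, k] <- -u[, k]; v[, k] <- -v[, k]
    }
  }
  total <- sum(lambda^2)
  explained <- if (total > 0) 100 * lambda^2 / total else rep(0, p)
  f <- svp_exponent
  gen_full <- sweep(u, 2, lambda^f, `*`)
  env_full <- sweep(v, 2, lambda^(1 - f), `*`)
  dimnames(gen_full) <- list(rownames(y), paste0("PC", seq_len(p)))
  dimnames(env_full) <- list(colnames(y), paste0("PC", seq_len(p)))
  structure(
    list(
      centered = cc, lambda = lambda, explained = explained,
      genotype_scores = tibble(genotype = rownames(y),
                               pc1 = unname(gen_full[, 1]),
                               pc2 = unname(gen_full[, 2])),
      environment_scores = tibble(environment = colnames(y),
                                  pc1 = unname(env_full[, 1]),
                                  pc2 = unname(env_full[, 2])),
      gen_full = gen_full, env_full = env_full,
      svp_exponent = f, trait = attr(m, "trait")
    ),
    class = "gge_fit"
  )
}

#' @exportS3Method base::print
print.gge_fit <- function(x, ...) {
  cat(sprintf(
    "<gge_fit> trait %s: %d genotypes x %d environments; PC1+PC2 explain %.1f%% of G+GE\n",
    deparse(x$trait), nrow(x$gen_full), nrow(x$env_full),
    sum(x$explained[1:2])))
  invisible(x)
}

# angle of the boundary ray between two adjacent hull vertices: the
# direction d with d.v1 = d.v2 and positive projection, i.e. perpendicular
# to the hull edge v2 - v1
boundary_angle <- function(v1, v2) {
  e <- v2 - v1
  d <- c(-e[2], e[1])
  if (sum(d * (v1 + v2)) < 0) d <- -d
  atan2(d[2], d[1]) %% (2 * pi)
}

#' Which-won-where analysis of a GGE biplot
#'
#' Builds the convex hull of the genotype points in the first two axes,
#' draws sector-boundary rays from the origin perpendicular to each hull
#' edge, and assigns every environment to the sector whose hull vertex
#' ("winner") has the largest projection on the environment's score vector
#' — the rank-2 best performer in that environment. Sectors holding at
#' least one environment are mega-environments.
#'
#' @param fit A `gge_fit`.
#' @return A list: `hull` (genotype labels in convex position,
#'   counter-clockwise), `sectors` (tibble: sector, winner, angular
#'   interval start/end in radians), `env_sector` (tibble: environment,
#'   sector, winner), `mega_envs` (tibble: one row per non-empty sector
#'   with its environments).
#' @export
which_won_where <- function(fit) {
  stopifnot(inherits(fit, "gge_fit"))
  pts <- as.matrix(fit$genotype_scores[, c("pc1", "pc2")])
  rownames(pts) <- fit$genotype_scores$genotype
  hull_idx <- grDevices::chull(pts)          # clockwise order
  if (length(hull_idx) < 3) {
    abort("genotype points are collinear; hull is degenerate",
          class = "metstab_degenerate_error")
  }
  hull_idx <- rev(hull_idx)                  # counter-clockwise
  hull_pts <- pts[hull_idx, , drop = FALSE]
  nh <- nrow(hull_pts)
  # sector of vertex v: between the boundary rays of its two adjacent edges
  starts <- numeric(nh); ends <- numeric(nh)
  for (i in seq_len(nh)) {
    prev <- if (i == 1) nh else i - 1
    nxt <- if (i == nh) 1 else i + 1
    starts[i] <- boundary_angle(hull_pts[prev, ], hull_pts[i, ])
    ends[i] <- boundary_angle(hull_pts[i, ], hull_pts[nxt, ])
  }
  sectors <- tibble(
    sector = seq_len(nh),
    winner = rownames(hull_pts),
    angle_start = starts,
    angle_end = ends
  )
  env <- as.matrix(fit$environment_scores[, c("pc1", "pc2")])
  proj <- env %*% t(hull_pts)                # environments x hull vertices
  sec <- apply(proj, 1, which.max)
  env_sector <- tibble(
    environment = fit$environment_scores$environment,
    sector = as.integer(sec),
    winner = rownames(hull_pts)[sec]
  )
  mega <- env_sector |>
    dplyr::group_by(.data$sector, .data$winner) |>
    dplyr::summarise(
      environments = list(.data$environment), .groups = "drop"
    ) |>
    dplyr::mutate(mega_env = paste0("ME", dplyr::row_number()), .before = 1)
  list(hull = rownames(hull_pts), sectors = sectors,
       env_sector = env_sector, mega_envs = mega)
}

#' Environment-vector relations
#'
#' Per environment: the length of its score vector in the first two axes
#' (discriminating power), the pairwise cosine between environment vectors
#' (an approximation to the between-environment correlation), and a
#' favourable/unfavourable flag from the sign of the projection on the
#' average-genotype axis.
#'
#' @param fit A `gge_fit`.
#' @return A list: `vectors` (tibble: environment, vector_length,
#'   favourable), `cosines` (symmetric matrix).
#' @export
env_relations <- function(fit) {
  stopifnot(inherits(fit, "gge_fit"))
  env <- as.matrix(fit$environment_scores[, c("pc1", "pc2")])
  rownames(env) <- fit$environment_scores$environment
  lens <- sqrt(rowSums(env^2))
  avg_gen <- colMeans(as.matrix(fit$genotype_scores[, c("pc1", "pc2")]))
  favourable <- drop(env %*% avg_gen) > 0
  nrm <- env / pmax(lens, .Machine$double.eps)
  cosines <- nrm %*% t(nrm)
  list(
    vectors = tibble(environment = rownames(env), vector_length = unname(lens),
                     favourable = unname(favourable)),
    cosines = cosines
  )
}

#' @export
tidy.gge_fit <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::rename(x$genotype_scores, label = "genotype") |>
      dplyr::mutate(type = "genotype"),
    dplyr::rename(x$environment_scores, label = "environment") |>
      dplyr::mutate(type = "environment")
  )
}

#' @export
glance.gge_fit <- function(x, ...) {
  tibble(trait = x$trait,
         explained_1 = x$explained[1],
         explained_2 = x$explained[2],
         explained_12 = sum(x$explained[1:2]))
}

#' @rdname which_won_where
#' @param object A `gge_fit` (for `autoplot`).
#' @param ... Unused.
#' @export
autoplot.gge_fit <- function(object, ...) {
  www <- which_won_where(object)
  hull_df <- object$genotype_scores |>
    dplyr::filter(.data$genotype %in% www$hull) |>
    dplyr::slice(match(www$hull, .data$genotype))
  ggplot2::ggplot() +
    ggplot2::geom_polygon(
      data = hull_df, ggplot2::aes(x = .data$pc1, y = .data$pc2),
      fill = NA, colour = "grey50") +
    ggplot2::geom_point(
      data = object$genotype_scores,
      ggplot2::aes(x = .data$pc1, y = .data$pc2), colour = "steelblue") +
    ggplot2::geom_text(
      data = object$genotype_scores,
      ggplot2::aes(x = .data$pc1, y = .data$pc2, label = .data$genotype),
      vjust = -0.6, size = 3, colour = "steelblue") +
    ggplot2::geom_segment(
      data = object$environment_scores,
      ggplot2::aes(x = 0, y = 0, xend = .data$pc1, yend = .data$pc2),
      colour = "firebrick",
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_text(
      data = object$environment_scores,
      ggplot2::aes(x = .data$pc1, y = .data$pc2, label = .data$environment),
      vjust = 1.4, size = 3, colour = "firebrick") +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", object$explained[2]),
      title = sprintf("GGE which-won-where, trait %s", object$trait)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
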