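# internal helpers shared across modules

# rank with average ties; smallest value -> rank 1
rank_asc <- function(x) rank(x, ties.method = "average", na.last = "keep")

# rank with average ties; largest value -> rank 1
rank_desc <- function(x) rank(-x, ties.method = "average", na.last = "keep")

# rescale to [0, 100]; direction = "higher" maps max -> 100, "lower" maps
# min -> 100. A degenerate (constant) vector maps to all-100 with a flag
# carried via the "degenerate" attribute.
rescale_100 <- function(x, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  rng <- range(x)
  if (diff(rng) == 0) {
    out <- rep(100, length(x))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- if (direction == "higher") {
    100 * (x - rng[1]) / diff(rng)
  } else {
    100 * (rng[2] - x) / diff(rng)
  }
  attr(out, "degenerate") <- FALSE
  out
}

# significance stars at the conventional 0.05 / 0.01 / 0.001 thresholds
p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}

# centre columns and orthonormalize against each other and the intercept;
# used by the simulator so score matrices satisfy the bilinear-model
# constraints exactly
orthonormalize_centred <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  m <- sweep(m, 2, colMeans(m))  # project out the all-ones vector
  qr_m <- qr(m)
  if (qr_m$rank < ncol(m)) {
    abort("score matrix is rank-deficient after centring; draw again or reduce k")
  }
  q <- qr.Q(qr_m)[, seq_len(ncol(m)), drop = FALSE]
  # columns of Q remain centred because centring is a linear constraint
  # preserved by Gram-Schmidt on centred columns
  sweep(q, 2, colMeans(q))
}

# flip column signs so the first nonzero element of each column is positive
sign_fix_first <- function(m) {
  for (j in seq_len(ncol(m))) {
    nz <- which(abs(m[, j]) > .Machine$double.eps^0.5)
    if (length(nz) && m[nz[1], j] < 0) m[, j] <- -m[, j]
  }
  m
}
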