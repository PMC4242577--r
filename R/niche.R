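# Environmental-space niche overlap: PCA-env, availability-corrected kernel
# occupancy densities, Schoener's D, and randomization tests.

#' PCA of the background environment
#'
#' Principal components of the standardized (zero mean, unit SD) climate
#' variables over the full background; the first two axes define the
#' environmental space in which occupancy densities are built. Sign
#' convention: each loading vector's largest-magnitude entry is positive.
#'
#' @param background Climate tibble (>= 2 variables, >= 3 rows).
#' @return Object of class `env_pca` with `center`, `scale`, `rotation` and
#'   per-axis variance fractions `var_frac`.
#' @export
env_pca <- function(background) {
  background <- as_tibble(background)
  vars <- names(background)[vapply(background, is.numeric, logical(1))]
  background <- background[vars]
  assert_that(ncol(background) >= 2, "need at least 2 variables")
  assert_that(nrow(background) >= 3, "need at least 3 rows")
  sds <- vapply(background, sd, numeric(1))
  if (any(sds == 0)) {
    abort(sprintf("zero-variance variable(s): %s",
                  paste(vars[sds == 0], collapse = ", ")))
  }
  pc <- prcomp(background, center = TRUE, scale. = TRUE)
  rot <- pc$rotation
  for (j in seq_len(ncol(rot))) {
    k <- which.max(abs(rot[, j]))
    if (rot[k, j] < 0) rot[, j] <- -rot[, j]
  }
  structure(
    list(center = pc$center, scale = pc$scale, rotation = rot,
         var_frac = pc$sdev^2 / sum(pc$sdev^2), variables = vars),
    class = "env_pca"
  )
}

#' @export
print.env_pca <- function(x, ...) {
  cat(sprintf("<env_pca> %d variables; PC1 %.0f%%, PC2 %.0f%% of variance\n",
              length(x$variables), 100 * x$var_frac[1], 100 * x$var_frac[2]))
  invisible(x)
}

#' Project climate records into PCA-env space
#'
#' @param pca An [env_pca].
#' @param data Climate tibble containing the PCA variables.
#' @param n_axes Number of axes to return (default 2).
#' @return Tibble with columns `PC1`, `PC2`, ...
#' @export
project_pca <- function(pca, data, n_axes = 2) {
  X <- as.matrix(as_tibble(data)[pca$variables])
  Xs <- sweep(sweep(X, 2, pca$center), 2, pca$scale, "/")
  scores <- Xs %*% pca$rotation[, seq_len(n_axes), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(n_axes))
  as_tibble(scores)
}

silverman_bw <- function(x) {
  n <- length(x)
  s <- min(sd(x), stats::IQR(x) / 1.34)
  if (s <= 0) s <- sd(x)
  if (s <= 0) s <- 1e-6
  0.9 * s * n^(-1 / 5)
}

# Separable Gaussian KDE of points (x, y) evaluated on the grid axes.
kde_on_grid <- function(x, y, ax, ay, bx, by) {
  Kx <- outer(ax, x, function(a, b) dnorm(a, b, bx))
  Ky <- outer(ay, y, function(a, b) dnorm(a, b, by))
  (Kx %*% t(Ky)) / length(x)
}

#' Availability-corrected occupancy density in environmental space
#'
#' Gaussian kernel densities of the occurrence scores, `o(z)`, and of the
#' background scores, `e(z)`, are evaluated on an `R x R` grid spanning the
#' background extent; the occupancy is `z = o/e` where `e > 0` (0 elsewhere),
#' renormalized to sum to 1. Bandwidths follow Silverman's rule per axis on
#' the background scores, so they are identical across the replicates of a
#' randomization test. Occurrences outside the background extent are clipped
#' to it with a warning.
#'
#' @param occ_scores Tibble/data frame with columns `PC1`, `PC2` (>= 5 rows).
#' @param background_scores Same, for the full background.
#' @param R Grid resolution per axis (default 100).
#' @param bandwidth Optional numeric length-2 override of the per-axis
#'   bandwidths.
#' @return Object of class `niche_density` with axes `x`, `y` and the
#'   normalized occupancy matrix `z` (rows index `x`).
#' @export
density_grid <- function(occ_scores, background_scores, R = 100,
                         bandwidth = NULL) {
  occ_scores <- as_tibble(occ_scores)
  background_scores <- as_tibble(background_scores)
  assert_that(nrow(occ_scores) >= 5, "need at least 5 occurrences")
  bx_rng <- range(background_scores$PC1)
  by_rng <- range(background_scores$PC2)
  n_out <- sum(occ_scores$PC1 < bx_rng[1] | occ_scores$PC1 > bx_rng[2] |
                 occ_scores$PC2 < by_rng[1] | occ_scores$PC2 > by_rng[2])
  if (n_out > 0) {
    warn(sprintf("%d occurrence(s) outside background extent were clipped",
                 n_out))
  }
  ox <- pmin(pmax(occ_scores$PC1, bx_rng[1]), bx_rng[2])
  oy <- pmin(pmax(occ_scores$PC2, by_rng[1]), by_rng[2])
  if (is.null(bandwidth)) {
    bandwidth <- c(silverman_bw(background_scores$PC1),
                   silverman_bw(background_scores$PC2))
  }
  ax <- seq(bx_rng[1], bx_rng[2], length.out = R)
  ay <- seq(by_rng[1], by_rng[2], length.out = R)
  o <- kde_on_grid(ox, oy, ax, ay, bandwidth[1], bandwidth[2])
  e <- kde_on_grid(background_scores$PC1, background_scores$PC2,
                   ax, ay, bandwidth[1], bandwidth[2])
  z <- matrix(0, R, R)
  pos <- e > 0
  z[pos] <- o[pos] / e[pos]
  tot <- sum(z)
  assert_that(tot > 0, "empty occupancy density")
  structure(list(x = ax, y = ay, z = z / tot, R = R, bandwidth = bandwidth),
            class = "niche_density")
}

#' @export
print.niche_density <- function(x, ...) {
  cat(sprintf("<niche_density> %d x %d grid over PC1 [%.2f, %.2f], PC2 [%.2f, %.2f]\n",
              x$R, x$R, min(x$x), max(x$x), min(x$y), max(x$y)))
  invisible(x)
}

#' Schoener's D niche overlap
#'
#' `D = 1 - 0.5 * sum(|z1 - z2|)` over the common grid: 0 for disjoint
#' occupancies, 1 for identical ones.
#'
#' @param z1,z2 [niche_density] objects on the same grid.
#' @return Overlap in `[0, 1]`.
#' @export
schoener_D <- function(z1, z2) {
  assert_that(inherits(z1, "niche_density") && inherits(z2, "niche_density"),
              "inputs must be niche_density objects")
  assert_that(z1$R == z2$R &&
                max(abs(z1$x - z2$x)) < 1e-9 && max(abs(z1$y - z2$y)) < 1e-9,
              "density grids have different geometry")
  1 - 0.5 * sum(abs(z1$z - z2$z))
}

# Two-sided add-one randomization p-value: k = extreme-or-tied null count.
perm_pvalue <- function(k, reps) min(1, 2 * (1 + k) / (1 + reps))

niche_test_result <- function(test, d_obs, null_d, p, reps) {
  structure(list(test = test, d_obs = d_obs, null_d = null_d, p = p,
                 reps = reps),
            class = "niche_test")
}

#' @export
print.niche_test <- function(x, ...) {
  cat(sprintf("<niche_test> %s: D_obs = %.4f, p = %.4f (%d reps)\n",
              x$test, x$d_obs, x$p, x$reps))
  invisible(x)
}

#' Niche equivalency randomization test
#'
#' Null hypothesis: the two niches are interchangeable. Both occurrence sets
#' are pooled; each repetition re-splits the pool at random (without
#' replacement) into groups of the original sizes, rebuilds the occupancy
#' densities and recomputes D. Low observed overlap is the extreme
#' direction: `p = min(1, 2 * (1 + #\{null D <= D_obs\}) / (1 + reps))`. With
#' 100 repetitions the attainable floor is 2/101 = 0.0198.
#'
#' @param occ1,occ2 Climate tibbles of the two occurrence sets.
#' @param background Climate tibble of the shared background.
#' @param reps Number of randomization repetitions (default 100).
#' @param seed Integer seed.
#' @param R Density grid resolution.
#' @param pca Optional pre-fitted [env_pca] (fitted on `background` when
#'   `NULL`).
#' @return A `niche_test` object (fields `d_obs`, `null_d`, `p`).
#' @export
equivalency_test <- function(occ1, occ2, background, reps = 100, seed = 1,
                             R = 100, pca = NULL) {
  assert_that(reps >= 1, "`reps` must be at least 1")
  occ1 <- as_tibble(occ1); occ2 <- as_tibble(occ2)
  n1 <- nrow(occ1); n2 <- nrow(occ2)
  assert_that(n1 + n2 >= 10, "fewer than 10 combined occurrences")
  if (is.null(pca)) pca <- env_pca(background)
  bg <- project_pca(pca, background)
  s1 <- project_pca(pca, occ1)
  s2 <- project_pca(pca, occ2)
  bw <- c(silverman_bw(bg$PC1), silverman_bw(bg$PC2))
  d_of <- function(a, b) {
    schoener_D(density_grid(a, bg, R = R, bandwidth = bw),
               density_grid(b, bg, R = R, bandwidth = bw))
  }
  d_obs <- d_of(s1, s2)
  pool <- bind_rows(s1, s2)
  null_d <- with_seed(seed, vapply(seq_len(reps), function(i) {
    idx <- sample.int(n1 + n2, n1)
    d_of(pool[idx, ], pool[-idx, ])
  }, numeric(1)))
  niche_test_result("equivalency", d_obs, null_d,
                    perm_pvalue(sum(null_d <= d_obs), reps), reps)
}

#' Niche similarity randomization test
#'
#' Null hypothesis: niche 1 is no more similar to niche 2 than to niches
#' drawn at random from niche 2's available environment. Each repetition
#' draws `nrow(occ2)` pseudo-occurrences with replacement from the
#' background availability, rebuilds the second density and recomputes D
#' against the observed first density. High observed overlap is the extreme
#' direction: `p = min(1, 2 * (1 + #\{null D >= D_obs\}) / (1 + reps))`.
#'
#' @inheritParams equivalency_test
#' @return A `niche_test` object.
#' @export
similarity_test <- function(occ1, occ2, background, reps = 100, seed = 1,
                            R = 100, pca = NULL) {
  assert_that(reps >= 1, "`reps` must be at least 1")
  background <- as_tibble(background)
  assert_that(nrow(background) > 0, "empty background")
  if (is.null(pca)) pca <- env_pca(background)
  bg <- project_pca(pca, background)
  s1 <- project_pca(pca, as_tibble(occ1))
  s2 <- project_pca(pca, as_tibble(occ2))
  n2 <- nrow(s2)
  bw <- c(silverman_bw(bg$PC1), silverman_bw(bg$PC2))
  z1 <- density_grid(s1, bg, R = R, bandwidth = bw)
  d_obs <- schoener_D(z1, density_grid(s2, bg, R = R, bandwidth = bw))
  null_d <- with_seed(seed, vapply(seq_len(reps), function(i) {
    idx <- sample.int(nrow(bg), n2, replace = TRUE)
    schoener_D(z1, density_grid(bg[idx, ], bg, R = R, bandwidth = bw))
  }, numeric(1)))
  niche_test_result("similarity", d_obs, null_d,
                    perm_pvalue(sum(null_d >= d_obs), reps), reps)
}
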