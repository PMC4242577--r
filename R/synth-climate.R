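# Synthetic climate rasters and niche-driven occurrence sampling.

# Smooth standardized random field: white noise blurred with a separable
# Gaussian kernel, then centred/scaled over all cells.
smooth_field <- function(n_rows, n_cols, blur = 3) {
  z <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  half <- max(1L, ceiling(3 * blur))
  k <- dnorm(seq(-half, half), sd = blur)
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rev(v[seq_len(half)]), v, rev(v[n - seq_len(half) + 1L]))
    stats::filter(vp, k, sides = 2)[(half + 1L):(half + n)]
  }
  z <- apply(z, 2L, pad_conv)
  z <- t(apply(z, 1L, pad_conv))
  (z - mean(z)) / sd(z)
}

#' Generate a stack of correlated synthetic climate grids
#'
#' Emulates gridded climate predictors (temperature ranges, seasonal
#' precipitation, ...) as smooth fields: a shared latitudinal gradient plus
#' low-pass-filtered Gaussian noise. A target pairwise correlation between
#' variables is achieved through a shared smooth component.
#'
#' Every variable is `gradient_amplitude * T + s * (sqrt(r) Z0 + sqrt(1-r) Zv)`
#' where `T` is the standardized latitude, `Z0` a shared smooth field, `Zv`
#' an idiosyncratic smooth field and `s = 1/smoothness`. `r` is solved so the
#' model correlation between any two variables equals `correlation`; the
#' attainable range given the shared gradient is
#' `[g^2/(g^2+s^2), 1]`.
#'
#' @param seed Integer seed; the stack is a pure function of it.
#' @param n_rows,n_cols Grid dimensions (positive).
#' @param n_vars Number of variables (>= 2).
#' @param smoothness Inverse noise amplitude; `Inf` gives the pure
#'   latitudinal gradient with zero residual variance.
#' @param correlation Target pairwise correlation between variables, or
#'   `NULL` for the gradient-induced default.
#' @param gradient_amplitude Weight of the latitudinal gradient.
#' @param blur Gaussian blur radius (cells) of the noise fields.
#' @param x_origin,y_origin,cell_size Grid georeferencing (degrees).
#' @return Named list (`var1`, `var2`, ...) of [raster_grid]s.
#' @examples
#' stack <- make_climate_stack(seed = 1, n_rows = 30, n_cols = 30, n_vars = 3)
#' @export
make_climate_stack <- function(seed, n_rows, n_cols, n_vars,
                               smoothness = 1, correlation = NULL,
                               gradient_amplitude = 1, blur = 3,
                               x_origin = -150, y_origin = 30,
                               cell_size = 0.5) {
  assert_that(n_rows >= 1 && n_cols >= 1, "grid dimensions must be positive")
  assert_that(n_vars >= 2, "`n_vars` must be at least 2")
  g <- gradient_amplitude
  s <- if (is.infinite(smoothness)) 0 else 1 / smoothness
  if (is.null(correlation)) {
    r <- 0
  } else {
    assert_that(s > 0, "cannot target a correlation with smoothness = Inf")
    r <- (correlation * (g^2 + s^2) - g^2) / s^2
    assert_that(r >= 0 && r <= 1, sprintf(
      "requested correlation %.3f unattainable; feasible range [%.3f, 1]",
      correlation, g^2 / (g^2 + s^2)))
  }
  with_seed(seed, {
    lat <- seq_len(n_rows)
    tg <- (lat - mean(lat))
    tg <- if (sd(tg) > 0) tg / sd(tg) else tg * 0
    gradient <- matrix(rev(tg), n_rows, n_cols) # row 1 = north = high value
    z0 <- if (s > 0) smooth_field(n_rows, n_cols, blur) else 0
    out <- lapply(seq_len(n_vars), function(v) {
      zv <- if (s > 0) smooth_field(n_rows, n_cols, blur) else 0
      vals <- g * gradient + s * (sqrt(r) * z0 + sqrt(1 - r) * zv)
      raster_grid(vals, x_origin, y_origin, cell_size)
    })
    names(out) <- paste0("var", seq_len(n_vars))
    out
  })
}

#' Logistic niche specification
#'
#' Stands in for a species' climate response: suitability of a cell is
#' `plogis(intercept + sum(coefficients * climate))`, always in `[0, 1]`.
#'
#' @param coefficients Named numeric vector, one entry per climate variable.
#' @param intercept Real intercept on the logit scale.
#' @return Object of class `niche_spec`.
#' @export
niche_spec <- function(coefficients, intercept = 0) {
  assert_that(length(coefficients) >= 1 && !is.null(names(coefficients)),
              "`coefficients` must be a named numeric vector")
  structure(list(coefficients = coefficients, intercept = intercept,
                 link = "logistic"),
            class = "niche_spec")
}

#' Suitability surface of a niche over a climate stack
#'
#' @param niche A [niche_spec].
#' @param stack Named list of [raster_grid]s covering the niche's variables.
#' @return [raster_grid] of suitabilities in `[0, 1]`.
#' @export
suitability_map <- function(niche, stack) {
  vars <- names(niche$coefficients)
  assert_that(all(vars %in% names(stack)),
              "stack is missing niche variables")
  g1 <- stack[[1]]
  eta <- matrix(niche$intercept, g1$n_rows, g1$n_cols)
  for (v in vars) eta <- eta + niche$coefficients[[v]] * stack[[v]]$values
  suit <- plogis(eta)
  raster_grid(suit, g1$x_origin, g1$y_origin, g1$cell_size)
}

#' Sample occurrences from a parameterized niche
#'
#' Cells are drawn (with replacement) with probability proportional to
#' suitability; points are placed at cell centres.
#'
#' @param stack Named list of [raster_grid]s.
#' @param niche A [niche_spec].
#' @param n Number of points (>= 1).
#' @param seed Integer seed.
#' @param taxon Label stored in the output.
#' @return Tibble with columns `taxon`, `lon`, `lat`.
#' @export
sample_species_occurrences <- function(stack, niche, n, seed, taxon = "sp") {
  assert_that(n >= 1, "`n` must be at least 1")
  suit <- suitability_map(niche, stack)
  w <- as.vector(suit$values)
  w[is.na(w)] <- 0
  assert_that(sum(w) > 0, "degenerate niche: suitability is zero everywhere")
  with_seed(seed, {
    cells <- sample.int(length(w), size = n, replace = TRUE, prob = w)
    row <- ((cells - 1L) %% suit$n_rows) + 1L
    col <- ((cells - 1L) %/% suit$n_rows) + 1L
    cc <- cell_center(suit, row, col)
    tibble(taxon = taxon, lon = cc$lon, lat = cc$lat)
  })
}
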