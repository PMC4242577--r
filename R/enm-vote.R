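# Vote maps across ensemble members and multi-time-slice refugium mapping.

#' Per-pixel percentage of "suitable" votes
#'
#' @param binary_maps List of [raster_grid]s with values in `{0, 1, NA}`
#'   sharing one geometry (one per ensemble member / threshold / GCM stack).
#' @return Object of class `vote_map`: a [raster_grid] `percent` with values
#'   in `[0, 100]` (percentage over non-missing votes) and the total vote
#'   count `n_votes`.
#' @export
vote_map <- function(binary_maps) {
  assert_that(length(binary_maps) >= 1, "need at least one map")
  g1 <- binary_maps[[1]]
  for (g in binary_maps) {
    assert_that(same_geometry(g1, g), "vote_map: geometry mismatch")
    v <- g$values
    assert_that(all(v %in% c(0, 1) | is.na(v)),
                "vote_map: values must be 0, 1 or missing")
  }
  votes <- Reduce(`+`, lapply(binary_maps, function(g) {
    v <- g$values; v[is.na(v)] <- 0; v
  }))
  avail <- Reduce(`+`, lapply(binary_maps, function(g) !is.na(g$values) * 1))
  pct <- matrix(NA_real_, g1$n_rows, g1$n_cols)
  pct[avail > 0] <- 100 * votes[avail > 0] / avail[avail > 0]
  structure(
    list(percent = raster_grid(pct, g1$x_origin, g1$y_origin, g1$cell_size),
         n_votes = length(binary_maps)),
    class = "vote_map"
  )
}

#' @export
print.vote_map <- function(x, ...) {
  cat(sprintf("<vote_map> %d votes\n", x$n_votes))
  print(x$percent)
  invisible(x)
}

#' Refugium stability map across four time slices
#'
#' A pixel is a level-`L` refugium iff its vote percentage reaches `L` in
#' all four time slices and it is not under the glacial ice mask. By
#' construction `stable75` pixels are a subset of `stable50` pixels.
#'
#' @param slices List of exactly 4 [vote_map]s sharing one geometry
#'   (e.g. current, mid-Holocene, LGM, LIG).
#' @param ice Optional [raster_grid] ice mask (nonzero = under ice).
#' @param levels Stability thresholds in percent (default `c(50, 75)`).
#' @return Object of class `refugia_map`: a [raster_grid] `category` coded
#'   0 = none, 1 = stable at `levels[1]`, 2 = stable at `levels[2]`, plus the
#'   levels and an `ice_applied` flag.
#' @export
refugia_map <- function(slices, ice = NULL, levels = c(50, 75)) {
  assert_that(length(slices) == 4, "exactly 4 time slices are required")
  assert_that(length(levels) == 2 && levels[1] < levels[2],
              "`levels` must be two increasing percentages")
  pcts <- lapply(slices, function(s) {
    assert_that(inherits(s, "vote_map"), "slices must be vote_map objects")
    s$percent
  })
  g1 <- pcts[[1]]
  for (g in pcts) assert_that(same_geometry(g1, g),
                              "refugia_map: geometry mismatch")
  minvote <- Reduce(pmin, lapply(pcts, function(g) g$values))
  cat_vals <- ifelse(minvote >= levels[2], 2,
                     ifelse(minvote >= levels[1], 1, 0))
  if (!is.null(ice)) {
    assert_that(same_geometry(g1, ice), "ice mask geometry mismatch")
    iced <- !is.na(ice$values) & ice$values != 0
    cat_vals[iced] <- 0
  }
  cat_vals[is.na(minvote)] <- NA_real_
  structure(
    list(category = raster_grid(cat_vals, g1$x_origin, g1$y_origin,
                                g1$cell_size),
         levels = levels, ice_applied = !is.null(ice)),
    class = "refugia_map"
  )
}

#' @export
print.refugia_map <- function(x, ...) {
  v <- x$category$values
  cat(sprintf(
    "<refugia_map> levels %g/%g%%; ice mask %s; stable cells: %d / %d\n",
    x$levels[1], x$levels[2],
    if (x$ice_applied) "applied" else "not applied",
    sum(v >= 1, na.rm = TRUE), sum(v >= 2, na.rm = TRUE)))
  invisible(x)
}
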