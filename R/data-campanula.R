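# Morphological character parameters for the seven Cordilleran bellflower
# taxa: per-taxon means/SDs of the continuous characters and the per-taxon
# levels of the categorical characters, with sample sizes 10/10/20/10/40/30/10.

campanula_taxa <- function() {
  c("aurita", "lasiocarpa", "parryi_idahoensis", "parryi_parryi",
    "piperi", "scabrella", "scouleri")
}

campanula_sample_sizes <- function() {
  setNames(c(10L, 10L, 20L, 10L, 40L, 30L, 10L), campanula_taxa())
}

# Continuous characters: grand mean (SD) per taxon, measurements in mm
# (ratios unitless). Seed length and seed length:width are literature means
# without dispersion estimates (SD 0 here).
campanula_continuous <- function() {
  chars <- c("corolla_height_width", "corolla_width", "corolla_height",
             "corolla_length", "petal_lobe_length", "fused_corolla_length",
             "style_beyond_corolla", "style_stigma_length", "sepal_length",
             "petal_base_width", "hypanthium_length",
             "hypanthium_length_width", "stem_length", "hypanthium_width",
             "seed_length", "seed_length_width")
  m <- rbind(
    #          aurita  lasio   idaho   parryi  piperi  scabr   scouleri
    c(0.3, 1.0, 1.0, 0.8, 0.5, 0.6, 0.4),       # corolla height:width
    c(22.6, 23.3, 10.6, 19.1, 20.8, 13.7, 9.4), # corolla width
    c(7.9, 22.8, 10.0, 15.1, 9.5, 7.0, 3.8),    # corolla height
    c(12.2, 25.4, 10.6, 15.0, 12.9, 8.7, 7.9),  # corolla length
    c(10.3, 9.2, 3.9, 7.9, 9.5, 6.0, 4.4),      # petal lobe length
    c(2.1, 16.2, 6.8, 7.6, 3.4, 2.7, 3.5),      # fused corolla length
    c(2.6, -8.2, -1.7, -6.5, 1.3, 0.2, 8.6),    # style beyond corolla
    c(11.0, 13.5, 8.2, 8.7, 8.8, 6.5, 12.8),    # style:stigma length
    c(5.2, 8.5, 3.8, 10.5, 5.3, 3.6, 4.7),      # sepal length
    c(2.7, 8.1, 3.7, 5.4, 5.6, 3.0, 2.2),       # petal base width
    c(4.4, 4.7, 3.6, 5.3, 3.4, 3.1, 3.1),       # hypanthium length
    c(1.1, 1.0, 1.4, 1.5, 0.8, 1.2, 1.1),       # hypanthium length:width
    c(163.0, 46.1, 117.5, 160.0, 30.1, 38.4, 187.5), # stem length
    c(4.1, 4.7, 2.7, 3.7, 4.2, 2.6, 2.8),       # hypanthium width
    c(1.2, 0.7, 0.9, 0.6, 0.7, 0.85, 1.0),      # seed length
    c(2.0, 2.0, 2.6, 1.8, 2.0, 2.4, 2.0)        # seed length:width
  )
  s <- rbind(
    c(0.1, 0.2, 0.2, 0.1, 0.1, 0.3, 0.2),
    c(3.9, 4.4, 2.7, 5.2, 3.9, 4.4, 3.2),
    c(1.9, 2.2, 1.5, 1.8, 2.3, 1.6, 0.8),
    c(1.7, 2.0, 1.6, 1.8, 2.0, 1.5, 1.4),
    c(1.8, 1.0, 0.4, 1.7, 1.4, 1.4, 1.2),
    c(0.3, 1.5, 1.3, 1.1, 0.9, 0.8, 0.6),
    c(1.1, 1.7, 1.2, 1.6, 2.6, 1.5, 1.2),
    c(1.6, 1.7, 1.2, 1.8, 1.6, 1.4, 1.0),
    c(1.4, 1.2, 1.9, 3.2, 1.2, 1.0, 1.8),
    c(0.5, 0.9, 0.8, 1.9, 1.2, 1.6, 0.7),
    c(0.9, 0.9, 1.0, 0.9, 0.7, 0.8, 0.9),
    c(0.2, 0.1, 0.3, 0.3, 0.1, 0.2, 0.3),
    c(40.3, 20.3, 39.7, 53.1, 13.8, 18.3, 89.8),
    c(0.5, 1.0, 0.4, 0.7, 0.7, 0.6, 0.4),
    c(0, 0, 0, 0, 0, 0, 0),
    c(0, 0, 0, 0, 0, 0, 0)
  )
  dimnames(m) <- dimnames(s) <- list(chars, campanula_taxa())
  list(mean = m, sd = s)
}

# Categorical characters. The seed + lower-leaf block of the published
# character table is misaligned (row labels shifted by one taxon); the
# values here realign that block, and the C. scouleri seed/lower-leaf row
# is reconstructed (no published source) - it is flagged `reconstructed`
# in inst/extdata/table2_categorical_synthetic.csv.
campanula_categorical <- function() {
  chars <- c("flowers_per_stem", "flower_shape", "hypanthium_hair",
             "pollen_color", "upper_leaf_shape", "upper_leaf_margin",
             "seed_wings", "seed_shape_long", "seed_cross_section",
             "seed_surface", "lower_leaf_shape", "lower_leaf_margin")
  rows <- list(
    aurita = c("5", "Rotate-subrotate", "Glabrous", "Purplish",
               "Narrow-elliptic", "Inconspicuous-serrate",
               "Periphery ridge", "Oblong", "Narrowly ovate",
               "Interrupted-striate", "Oblanceolate",
               "Inconspicuous-serrate"),
    lasiocarpa = c("2", "Tubular-campanulate", "Villous", "Purple",
                   "Narrow-elliptic", "Mucronate",
                   "No ridge", "Fusiform-ovate", "Terete", "Striate",
                   "Oblanceolate", "Mucronate"),
    parryi_idahoensis = c("2", "Tubular-campanulate", "Hirtellous",
                          "White-yellow", "Narrow-elliptic",
                          "Inconspicuous-serrate",
                          "One sided ridge", "Oblong", "Terete", "Striate",
                          "Oblanceolate", "Inconspicuous-serrate"),
    parryi_parryi = c("2", "Broadly campanulate", "Glabrous", "Yellow",
                      "Narrow-elliptic", "Sparse-serrate",
                      "Opposite hilum", "Elliptical", "Terete", "Striate",
                      "Oblanceolate", "Sparse-serrate"),
    piperi = c("3", "Rotate-subrotate", "Hirtellous", "Purple",
               "Narrow-elliptic", "Mucronate",
               "Ridge on hilum end", "Narrowly elliptical", "Terete",
               "Striate", "Oblanceolate", "Mucronate"),
    scabrella = c("3", "Broadly campanulate", "Hirtellous", "Purple",
                  "Narrow-elliptic", "Entire",
                  "One sided ridge", "Oblong", "Ovate", "Striate",
                  "Oblanceolate", "Entire"),
    # seed + lower-leaf values reconstructed (synthetic):
    scouleri = c("3", "Rotate-subrotate", "Chaffy", "Yellow",
                 "Ovate", "Conspicuous-serrate",
                 "No ridge", "Elliptical", "Ovate", "Striate",
                 "Ovate", "Conspicuous-serrate")
  )
  mat <- do.call(rbind, rows)
  colnames(mat) <- chars
  out <- as_tibble(mat)
  mutate(out, taxon = names(rows), .before = 1)
}

# Character-set groupings used in the classification analyses.
campanula_character_sets <- function() {
  list(
    flower = c("flowers_per_stem", "flower_shape", "hypanthium_hair",
               "pollen_color"),
    vegetative = c("upper_leaf_shape", "upper_leaf_margin",
                   "lower_leaf_shape", "lower_leaf_margin"),
    seed = c("seed_wings", "seed_shape_long", "seed_cross_section",
             "seed_surface")
  )
}

# Continuous floral characters entering the discriminant analysis, and
# which of them are log10-transformed first (those with strongly skewed
# distributions).
campanula_lda_columns <- function() {
  list(
    columns = c("corolla_length", "corolla_height_width",
                "hypanthium_length_width", "corolla_height",
                "fused_corolla_length", "sepal_length", "corolla_width",
                "petal_lobe_length", "petal_base_width",
                "style_beyond_corolla", "style_stigma_length",
                "hypanthium_length", "hypanthium_width", "stem_length"),
    log_columns = c("corolla_length", "hypanthium_length_width",
                    "corolla_height", "fused_corolla_length",
                    "sepal_length", "stem_length")
  )
}

#' Morphological specification of the Cordilleran bellflower taxa
#'
#' Bundles the per-taxon continuous means/SDs, categorical character levels
#' and sample sizes (n = 10, 10, 20, 10, 40, 30, 10; 130 individuals total)
#' used by [sample_morphology()]. The seed and lower-leaf categorical
#' levels for *C. scouleri* are reconstructed, not published.
#'
#' @return List with `continuous` (`mean`/`sd` matrices), `categorical`
#'   (tibble of levels), `n` (named sizes), `character_sets`, `lda`.
#' @export
campanula_morph_spec <- function() {
  list(continuous = campanula_continuous(),
       categorical = campanula_categorical(),
       n = campanula_sample_sizes(),
       character_sets = campanula_character_sets(),
       lda = campanula_lda_columns())
}

#' Draw a synthetic morphology sample
#'
#' Continuous characters are drawn independently per character as
#' `normal(mean, SD)` (diagonal covariance: the source reports no
#' character correlations, a documented limitation); characters that must
#' stay positive (everything except the style-projection distance) are
#' redrawn on non-positive values. Categorical rows replicate each taxon's
#' levels exactly, `n_i` rows per taxon.
#'
#' @param spec Specification as from [campanula_morph_spec()].
#' @param seed Integer seed.
#' @param n Named per-taxon sample sizes (default: the spec's).
#' @return List of tibbles `continuous` and `categorical`, each with a
#'   `taxon` label column.
#' @export
sample_morphology <- function(spec = campanula_morph_spec(), seed = 1,
                              n = spec$n) {
  taxa <- colnames(spec$continuous$mean)
  assert_that(all(taxa %in% names(n)), "missing taxon sample sizes")
  assert_that(all(n >= 1), "sample sizes must be >= 1")
  assert_that(all(spec$continuous$sd >= 0), "SDs must be non-negative")
  chars <- rownames(spec$continuous$mean)
  signed <- "style_beyond_corolla" # the one character allowed to go negative
  cont <- with_seed(seed, purrr::map_dfr(taxa, function(tx) {
    ni <- n[[tx]]
    cols <- purrr::map(chars, function(ch) {
      mu <- spec$continuous$mean[ch, tx]
      sdv <- spec$continuous$sd[ch, tx]
      x <- rnorm(ni, mu, sdv)
      if (!(ch %in% signed)) {
        for (tries in 1:50) {
          bad <- x <= 0
          if (!any(bad)) break
          x[bad] <- rnorm(sum(bad), mu, sdv)
        }
        x <- pmax(x, 1e-3)
      }
      x
    })
    names(cols) <- chars
    bind_cols(tibble(taxon = tx), as_tibble(cols))
  }))
  cat_rows <- purrr::map_dfr(taxa, function(tx) {
    row <- spec$categorical[spec$categorical$taxon == tx, ]
    row[rep(1, n[[tx]]), ]
  })
  list(continuous = cont, categorical = cat_rows)
}
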