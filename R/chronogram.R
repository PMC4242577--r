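# Chronogram IO, ultrametricity checks, and conversion between
# substitution-scaled heights and calendar ages.

#' Parse a newick chronogram
#'
#' Thin wrapper over the standard newick reader with structural checks:
#' the tree must be rooted, binary, and carry branch lengths.
#'
#' @param text Newick string, or `NULL` when `path` is given.
#' @param path File to read instead of `text`.
#' @param unit Branch-length unit: `"substitutions"` or `"years"` (stored as
#'   an attribute; KY counts as years scale).
#' @return A `phylo` with attribute `unit`.
#' @export
parse_newick <- function(text = NULL, path = NULL,
                         unit = c("substitutions", "years")) {
  unit <- match.arg(unit)
  tree <- if (!is.null(text)) ape::read.tree(text = text)
          else ape::read.tree(path)
  if (is.null(tree)) abort("could not parse newick input")
  assert_that(!is.null(tree$edge.length), "newick lacks branch lengths")
  assert_that(ape::is.rooted(tree), "tree must be rooted")
  assert_that(ape::is.binary(tree), "tree must be binary")
  attr(tree, "unit") <- unit
  tree
}

#' Is a tree ultrametric (all tips contemporaneous)?
#'
#' @param tree A `phylo`.
#' @param tol Relative tolerance on tip depths (default 1e-6).
#' @return Logical.
#' @export
is_ultrametric <- function(tree, tol = 1e-6) {
  isTRUE(ape::is.ultrametric(tree, tol = tol))
}

#' Node ages of an ultrametric tree
#'
#' @param tree Ultrametric `phylo`.
#' @return Tibble with `node` (ape node number), `label` (tips only) and
#'   `age` in the tree's branch-length unit.
#' @export
tree_node_ages <- function(tree) {
  ages <- node_ages(tree)
  n_tip <- length(tree$tip.label)
  tibble(node = seq_along(ages),
         label = c(tree$tip.label, rep(NA_character_, tree$Nnode)),
         age = ages)
}

#' Mutation-rate model for divergence dating
#'
#' @param mu Substitution rate, substitutions/site/generation (> 0).
#' @param sigma Its stated uncertainty (same units, `0 <= sigma < mu`).
#' @param generation_time Generation time in years (> 0; default 2 for
#'   slow-maturing arctic-alpine perennials).
#' @return Object of class `rate_model`.
#' @export
rate_model <- function(mu, sigma = 0, generation_time = 2) {
  assert_that(mu > 0, "`mu` must be positive")
  assert_that(sigma >= 0 && sigma < mu, "need 0 <= sigma < mu")
  assert_that(generation_time > 0, "`generation_time` must be positive")
  structure(list(mu = mu, sigma = sigma, generation_time = generation_time),
            class = "rate_model")
}

#' Convert a substitution-scale height to a calendar age
#'
#' `years = (height / mu) * generation_time`: the number of generations
#' implied by the substitution count, times the generation length.
#'
#' @param height Tree height in substitutions/site (>= 0).
#' @param rate A [rate_model()].
#' @return Age in years.
#' @export
age_from_height <- function(height, rate) {
  assert_that(all(height >= 0), "`height` must be non-negative")
  height / rate$mu * rate$generation_time
}

#' Inverse of [age_from_height()]
#'
#' @param years Age in years.
#' @param rate A [rate_model()].
#' @return Height in substitutions/site.
#' @export
height_from_age <- function(years, rate) {
  years * rate$mu / rate$generation_time
}

#' Age bounds induced by mutation-rate uncertainty
#'
#' A nominal age computed at rate `mu` rescales to
#' `nominal * mu / (mu + sigma)` under the fast extreme and
#' `nominal * mu / (mu - sigma)` under the slow extreme.
#'
#' @param nominal_age Age at the nominal rate (years, or KY: scale-free).
#' @param rate A [rate_model()] with `sigma < mu`.
#' @return Named numeric `c(low, high)`. Use [round_ky()] for reporting.
#' @export
rate_uncertainty_bounds <- function(nominal_age, rate) {
  assert_that(rate$sigma < rate$mu, "sigma >= mu gives an infinite bound")
  c(low = nominal_age * rate$mu / (rate$mu + rate$sigma),
    high = nominal_age * rate$mu / (rate$mu - rate$sigma))
}

#' Round ages to integer KY, half-up
#'
#' @param x Ages (KY).
#' @return Integer-valued ages.
#' @export
round_ky <- function(x) round_half_up(x)

#' Rescale a substitution tree to calendar time
#'
#' @param tree `phylo` with branch lengths in substitutions/site.
#' @param rate A [rate_model()].
#' @return `phylo` with branch lengths in years (attribute `unit` updated).
#' @export
tree_to_years <- function(tree, rate) {
  tree$edge.length <- age_from_height(tree$edge.length, rate)
  attr(tree, "unit") <- "years"
  tree
}

#' Synthetic fixture chronogram for the Cordilleran bellflower clade
#'
#' Seven-taxon ultrametric tree in KY encoding the clade's divergence-time
#' point estimates under the fast mutation rate (root 1030 KYA; subclade
#' crowns 560, 510, 386, 240 KYA). The age of the internal node joining the
#' two coastal subclades is not constrained by those estimates and is an
#' assumption of this fixture (900 KYA), as is the resolution of the root
#' trichotomy; the object is a synthetic stand-in, not an inferred tree.
#'
#' @return Ultrametric `phylo` with branch lengths in KY.
#' @export
cordilleran_chronogram <- function() {
  txt <- paste0(
    "(((piperi:560,aurita:560):340,(scouleri:510,parryi_parryi:510):390):130,",
    "(lasiocarpa:386,(scabrella:240,parryi_idahoensis:240):146):644);")
  tree <- parse_newick(text = txt, unit = "years")
  tree
}

#' Synthetic taxon-by-refugium range matrix
#'
#' A plausible assignment of the seven taxa to the six candidate refugia
#' (one or two areas each), shipped because the observed collection-region
#' matrix is not available; clearly a synthetic assumption. Also available
#' as `system.file("extdata", "range_matrix_synthetic.csv",
#' package = "cordillera")`.
#'
#' @return Tibble: `taxon` plus one 0/1 column per [default_areas()] area.
#' @export
cordilleran_ranges <- function() {
  tribble(
    ~taxon,              ~`Beringia`, ~`N Cascades`, ~`Olympics`,
    ~`S Cascades`, ~`C Rockies`, ~`S Rockies`,
    "lasiocarpa",        1, 1, 0, 0, 0, 0,
    "piperi",            0, 0, 1, 0, 0, 0,
    "aurita",            1, 0, 0, 0, 0, 0,
    "scouleri",          0, 0, 1, 1, 0, 0,
    "parryi_parryi",     0, 0, 0, 0, 0, 1,
    "scabrella",         0, 1, 0, 1, 0, 0,
    "parryi_idahoensis", 0, 0, 0, 0, 1, 0
  )
}
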