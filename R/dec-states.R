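# Dispersal-extinction-cladogenesis state space, epoch-stratified dispersal
# hypotheses, and cladogenetic scenario enumeration.
#
# Time convention: ages in KY before present (KYA); rates d and e are per KY
# of branch length.

#' Default refugium set
#'
#' Six candidate Pleistocene refugia of the western North American
#' cordillera, ordered north to south. The `rank` column orders areas by
#' latitude (1 = northernmost) and drives the directional dispersal
#' hypotheses.
#'
#' @return Tibble with columns `area`, `rank`.
#' @export
default_areas <- function() {
  tibble(area = c("Beringia", "N Cascades", "Olympics", "S Cascades",
                  "C Rockies", "S Rockies"),
         rank = 1:6)
}

#' Default refugium connectivity table
#'
#' Which area pairs exchange migrants under each climate regime; a
#' package-level assumption (editable; see
#' `system.file("extdata", "refugia_adjacency.csv", package = "cordillera")`).
#' Glacials connect the mountain systems south of the ice sheets but isolate
#' Beringia; the present and older interglacials open the north-south
#' corridor while fragmenting the southern refugia (the Rockies most
#' strongly at the last interglacial).
#'
#' @return Tibble with columns `from`, `to`, `present`, `interglacial`,
#'   `glacial` (0/1 connectivity flags; pairs are undirected).
#' @export
default_adjacency <- function() {
  tribble(
    ~from,        ~to,          ~present, ~interglacial, ~glacial,
    "Beringia",   "N Cascades", 1,        1,             0,
    "Beringia",   "Olympics",   1,        1,             0,
    "N Cascades", "Olympics",   0,        1,             1,
    "N Cascades", "S Cascades", 0,        1,             1,
    "Olympics",   "S Cascades", 0,        1,             1,
    "N Cascades", "C Rockies",  0,        0,             1,
    "S Cascades", "C Rockies",  0,        0,             1,
    "C Rockies",  "S Rockies",  0,        0,             1
  )
}

#' Default glacial/interglacial epoch table
#'
#' Interglacial windows at 0-14 (present-day connectivity), 115-130,
#' 190-245, 320-340 and 405-425 KYA (last-interglacial connectivity); every
#' other interval back to `root_age` is glacial. Boundaries are a documented
#' package default, configurable per analysis.
#'
#' @param root_age Root age in KYA; epochs tile `[0, root_age]` exactly.
#' @return Tibble with columns `start` (older bound), `end` (younger bound)
#'   and `class` in `{"present", "interglacial", "glacial"}`, youngest first.
#' @export
default_epochs <- function(root_age) {
  ig <- tribble(
    ~start, ~end, ~class,
    14,     0,    "present",
    130,    115,  "interglacial",
    245,    190,  "interglacial",
    340,    320,  "interglacial",
    425,    405,  "interglacial"
  )
  ig <- ig[ig$end < root_age, ]
  ig$start <- pmin(ig$start, root_age)
  bounds <- sort(unique(c(0, ig$start, ig$end, root_age)))
  out <- purrr::map_dfr(seq_len(length(bounds) - 1L), function(i) {
    lo <- bounds[i]; hi <- bounds[i + 1L]
    mid <- (lo + hi) / 2
    hit <- which(ig$end <= mid & mid <= ig$start)
    tibble(start = hi, end = lo,
           class = if (length(hit)) ig$class[hit[1]] else "glacial")
  })
  arrange(out, .data$end)
}

#' Enumerate the DEC range state space
#'
#' All nonempty subsets of the area set up to `max_range_size`, enumerated in
#' (size, lexicographic-index) order, plus the absorbing empty (extinct)
#' range appended last. With 6 areas and maximum size 2 there are 21 living
#' states.
#'
#' @param areas Character vector of area names (or the tibble from
#'   [default_areas()]).
#' @param max_range_size Maximum number of areas per range (default 2,
#'   capped at the number of areas).
#' @return Object of class `range_state_space`: `areas`, `states` (list of
#'   integer area-index vectors, living states first), `labels`, `n_living`.
#' @export
build_state_space <- function(areas = default_areas(),
                              max_range_size = NULL) {
  if (is.data.frame(areas)) areas <- areas$area
  n <- length(areas)
  assert_that(n >= 1, "empty area set")
  if (is.null(max_range_size)) max_range_size <- min(2L, n)
  assert_that(!anyDuplicated(areas), "area names must be unique")
  assert_that(max_range_size >= 1 && max_range_size <= n,
              "`max_range_size` must be in [1, number of areas]")
  states <- list()
  for (k in seq_len(max_range_size)) {
    combs <- utils::combn(n, k, simplify = FALSE)
    states <- c(states, combs)
  }
  labels <- vapply(states, function(s) paste(areas[s], collapse = "+"),
                   character(1))
  structure(
    list(areas = areas, states = states, labels = labels,
         n_living = length(states), max_range_size = max_range_size),
    class = "range_state_space"
  )
}

#' @export
print.range_state_space <- function(x, ...) {
  cat(sprintf("<range_state_space> %d areas, max range size %d: %d living states + empty\n",
              length(x$areas), x$max_range_size, x$n_living))
  invisible(x)
}

state_index <- function(space, areas_in_range) {
  key <- paste(sort(match(areas_in_range, space$areas)), collapse = ",")
  keys <- vapply(space$states, function(s) paste(s, collapse = ","),
                 character(1))
  idx <- match(key, keys)
  assert_that(!is.na(idx), sprintf("range {%s} not in state space",
                                   paste(areas_in_range, collapse = ",")))
  idx
}

#' Anagenetic DEC rate matrix
#'
#' Builds the instantaneous rate matrix over the living states plus the
#' absorbing empty state. Range expansion `R -> R + {a}` proceeds at
#' `d * sum over b in R of multipliers[b, a]`; each area in a range is lost
#' at rate `e` (single-area ranges transition to the empty state). Rows sum
#' to zero.
#'
#' @param space A [build_state_space()] result.
#' @param multipliers `n_areas x n_areas` dispersal multiplier matrix (zero
#'   diagonal, non-negative).
#' @param d,e Dispersal and extinction rates (per KY), both >= 0.
#' @return Square matrix of dimension `n_living + 1` (empty state last).
#' @export
anagenetic_rate_matrix <- function(space, multipliers, d, e) {
  assert_that(d >= 0 && e >= 0, "rates must be non-negative")
  assert_that(all(multipliers >= 0), "negative dispersal multiplier")
  n_liv <- space$n_living
  n_all <- n_liv + 1L # + empty
  n_areas <- length(space$areas)
  keys <- vapply(space$states, function(s) paste(s, collapse = ","),
                 character(1))
  idx_of <- function(s) match(paste(sort(s), collapse = ","), keys)
  Q <- matrix(0, n_all, n_all)
  for (i in seq_len(n_liv)) {
    R <- space$states[[i]]
    if (length(R) < space$max_range_size) {
      for (a in setdiff(seq_len(n_areas), R)) {
        rate <- d * sum(multipliers[R, a])
        if (rate > 0) {
          j <- idx_of(c(R, a))
          Q[i, j] <- Q[i, j] + rate
        }
      }
    }
    for (a in R) {
      tgt <- setdiff(R, a)
      j <- if (length(tgt)) idx_of(tgt) else n_all
      Q[i, j] <- Q[i, j] + e
    }
  }
  diag(Q) <- -rowSums(Q)
  dimnames(Q) <- list(c(space$labels, "0"), c(space$labels, "0"))
  Q
}

#' Time-stratified biogeographic dispersal hypothesis
#'
#' Encodes one of the three candidate range-dynamic scenarios as per-epoch
#' dispersal multiplier matrices over area pairs: `multiple_refugia`
#' (symmetric dispersal at 1.0 between connected areas),
#' `northward_expansion` (1.0 northward along connected pairs, 0.001
#' southward) and `southward_expansion` (the mirror). Connectivity per epoch
#' comes from the adjacency table's `present`/`interglacial`/`glacial`
#' columns.
#'
#' @param name One of `"multiple_refugia"`, `"northward_expansion"`,
#'   `"southward_expansion"`.
#' @param root_age Root age in KYA (epochs tile `[0, root_age]`).
#' @param areas Tibble from [default_areas()] (needs `area`, `rank`).
#' @param adjacency Tibble as from [default_adjacency()].
#' @param epochs Epoch table as from [default_epochs()].
#' @param weak Multiplier for the disfavoured direction (default 0.001).
#' @return Object of class `biogeo_hypothesis` with the per-epoch multiplier
#'   matrices.
#' @export
biogeo_hypothesis <- function(name = c("multiple_refugia",
                                       "northward_expansion",
                                       "southward_expansion"),
                              root_age,
                              areas = default_areas(),
                              adjacency = default_adjacency(),
                              epochs = default_epochs(root_age),
                              weak = 0.001) {
  name <- match.arg(name)
  nm <- areas$area
  rank <- setNames(areas$rank, nm)
  assert_that(all(adjacency$from %in% nm) && all(adjacency$to %in% nm),
              "adjacency names not in area set")
  assert_that(abs(min(epochs$end)) < 1e-9 &&
                abs(max(epochs$start) - root_age) < 1e-9,
              "epochs must tile [0, root_age]")
  conn_matrix <- function(class) {
    M <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
    flags <- adjacency[[class]]
    for (i in seq_len(nrow(adjacency))) {
      if (flags[i] == 1) {
        a <- adjacency$from[i]; b <- adjacency$to[i]
        M[a, b] <- M[b, a] <- 1
      }
    }
    if (name != "multiple_refugia") {
      for (a in nm) for (b in nm) {
        if (M[a, b] > 0) {
          northward <- rank[b] < rank[a]
          favoured <- if (name == "northward_expansion") northward else
            !northward
          M[a, b] <- if (favoured) 1 else weak
        }
      }
    }
    M
  }
  mats <- lapply(epochs$class, conn_matrix)
  structure(
    list(name = name, root_age = root_age, areas = areas,
         epochs = epochs, multipliers = mats, weak = weak),
    class = "biogeo_hypothesis"
  )
}

#' @export
print.biogeo_hypothesis <- function(x, ...) {
  cat(sprintf("<biogeo_hypothesis> %s; root age %g KYA; %d epochs\n",
              x$name, x$root_age, nrow(x$epochs)))
  invisible(x)
}

#' Cladogenetic range-inheritance scenarios
#'
#' For a single-area parent range the daughters both inherit it. For a
#' widespread parent `R`, ordered scenarios enumerate, for each area `a` in
#' `R`: vicariance `({a}, R \ {a})`, subset sympatry `({a}, R)` and its
#' mirror `(R, {a})` (and for ranges larger than two areas also the mirrored
#' vicariance). Scenarios carry uniform probability; for a two-area range
#' there are 6 ordered scenarios of probability 1/6.
#'
#' @param parent Parent range: state index, label or character vector of
#'   area names.
#' @param space A [build_state_space()] result.
#' @return Tibble with columns `left`, `right` (state labels) and `prob`.
#' @export
cladogenesis_table <- function(parent, space) {
  idx <- if (is.numeric(parent)) as.integer(parent)
         else if (length(parent) == 1 && parent %in% space$labels)
           match(parent, space$labels)
         else state_index(space, parent)
  scen <- cladogenesis_scenarios(space)[[idx]]
  tibble(left = space$labels[scen$left],
         right = space$labels[scen$right],
         prob = scen$prob)
}

# Integer-indexed scenario lists for every living state (engine internal).
cladogenesis_scenarios <- function(space) {
  keys <- vapply(space$states, function(s) paste(s, collapse = ","),
                 character(1))
  idx_of <- function(s) match(paste(sort(s), collapse = ","), keys)
  lapply(seq_len(space$n_living), function(i) {
    R <- space$states[[i]]
    if (length(R) == 1) {
      return(list(left = i, right = i, prob = 1))
    }
    L <- integer(0); Rt <- integer(0)
    for (a in R) {
      rest <- setdiff(R, a)
      ia <- idx_of(a); irest <- idx_of(rest)
      L <- c(L, ia, ia, i)
      Rt <- c(Rt, irest, i, ia)
      if (length(R) > 2) {
        L <- c(L, irest); Rt <- c(Rt, ia)
      }
    }
    list(left = L, right = Rt, prob = rep(1 / length(L), length(L)))
  })
}
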