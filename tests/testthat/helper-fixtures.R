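# Shared fixtures and independent oracles for the test suite.

# small three-area system with asymmetric connectivity across regimes
areas3 <- function() tibble::tibble(area = c("A", "B", "C"), rank = 1:3)

adj3 <- function() {
  tibble::tibble(from = c("A", "A", "B"), to = c("B", "C", "C"),
                 present = 1, interglacial = c(1, 0, 1),
                 glacial = c(0, 1, 1))
}

hyp3 <- function(root_age = 100, name = "multiple_refugia") {
  biogeo_hypothesis(name, root_age = root_age, areas = areas3(),
                    adjacency = adj3())
}

# all refugium pairs connected in every regime (well-mixed system)
adjacency_full <- function(areas = default_areas()$area) {
  out <- expand.grid(from = areas, to = areas, stringsAsFactors = FALSE)
  out <- out[out$from < out$to, ]
  tibble::as_tibble(out) |>
    dplyr::mutate(present = 1, interglacial = 1, glacial = 1)
}

single_epoch <- function(root_age) {
  tibble::tibble(start = root_age, end = 0, class = "present")
}

# a small climate stack + sharply defined synthetic species used by several
# ENM and niche tests
demo_stack <- function(seed = 1, n_rows = 40, n_cols = 40) {
  make_climate_stack(seed = seed, n_rows = n_rows, n_cols = n_cols,
                     n_vars = 3)
}

collect_decreases <- function(node) {
  if (node$type == "leaf") return(numeric(0))
  c(node$gini_decrease, collect_decreases(node$left),
    collect_decreases(node$right))
}

# ---- independent oracles --------------------------------------------------

# exhaustive pairwise AUC (counts wins and half-ties)
auc_oracle <- function(p, b) {
  wins <- 0
  for (x in p) for (y in b) {
    wins <- wins + (x > y) + 0.5 * (x == y)
  }
  wins / (length(p) * length(b))
}

# branch propagator computed independently with Matrix::expm
branch_prob_oracle <- function(space, hyp, d, e, t_start, t_end) {
  segs <- cordillera:::epoch_segments(hyp$epochs, t_start, t_end)
  P <- diag(space$n_living + 1L)
  for (k in seq_along(segs$epoch)) {
    Q <- anagenetic_rate_matrix(space, hyp$multipliers[[segs$epoch[k]]], d, e)
    P <- P %*% as.matrix(Matrix::expm(Q * segs$dt[k]))
  }
  P
}

# brute-force DEC likelihood by explicit enumeration over every root state,
# cladogenetic scenario and node-bottom state; trees up to 3 tips.
# Uses Matrix::expm through branch_prob_oracle, independent of the pruning
# engine's exponentials.
brute_force_negloglik <- function(tree, tip_ranges, hyp, d, e, space) {
  ages <- max(ape::node.depth.edgelength(tree)) -
    ape::node.depth.edgelength(tree)
  n_tip <- length(tree$tip.label)
  scen <- cordillera:::cladogenesis_scenarios(space)
  nl <- space$n_living
  tipidx <- sapply(tree$tip.label, function(tx) {
    row <- tip_ranges[tip_ranges$taxon == tx, ]
    cordillera:::state_index(space,
                             space$areas[which(unlist(row[space$areas]) == 1)])
  })
  Pb <- function(par, chd) {
    branch_prob_oracle(space, hyp, d, e, ages[par], ages[chd])[1:nl, 1:nl]
  }
  # f(node, state at its top): probability of all data below
  f <- function(node, s_top, parent) {
    P <- Pb(parent, node)
    if (node <= n_tip) return(P[s_top, tipidx[node]])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    tot <- 0
    for (s_bot in seq_len(nl)) {
      sc <- scen[[s_bot]]
      inner <- 0
      for (i in seq_along(sc$prob)) {
        inner <- inner + sc$prob[i] * f(kids[1], sc$left[i], node) *
          f(kids[2], sc$right[i], node)
      }
      tot <- tot + P[s_top, s_bot] * inner
    }
    tot
  }
  root <- n_tip + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  lik <- 0
  for (r in seq_len(nl)) {
    sc <- scen[[r]]
    for (i in seq_along(sc$prob)) {
      lik <- lik + (1 / nl) * sc$prob[i] * f(kids[1], sc$left[i], root) *
        f(kids[2], sc$right[i], root)
    }
  }
  -log(lik)
}
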