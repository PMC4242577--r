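# Yule chronogram simulation and forward (Gillespie) DEC range evolution.

#' Simulate a Yule chronogram
#'
#' Forward pure-birth simulation: two lineages leave the root at time zero,
#' each of `k` extant lineages splits at total rate `k * birth_rate`, and
#' once `n_tips` lineages exist the present is placed one further
#' exponential waiting time (rate `n_tips * birth_rate`) later. The tree is
#' ultrametric with tip ages zero; for `n_tips = 2` the root height is
#' exponential with rate `2 * birth_rate` (mean `1/(2*birth_rate)`).
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate per lineage per unit time (> 0).
#' @param seed Integer seed; the tree is a pure function of it.
#' @return An ultrametric `phylo` with tips `t1..tn`.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate, seed) {
  assert_that(n_tips >= 2, "`n_tips` must be at least 2")
  assert_that(birth_rate > 0, "`birth_rate` must be positive")
  with_seed(seed, {
    node_parent <- c(NA_integer_) # internal node 1 = root
    node_time <- c(0)
    active <- c(1L, 1L) # parent internal node of each extant lineage
    t <- 0
    while (length(active) < n_tips) {
      k <- length(active)
      t <- t + rexp(1, k * birth_rate)
      i <- sample.int(k, 1)
      m <- length(node_time) + 1L
      node_parent[m] <- active[i]
      node_time[m] <- t
      active <- c(active[-i], m, m)
    }
    present <- t + rexp(1, n_tips * birth_rate)
    n_int <- length(node_time)
    node_id <- function(m) n_tips + m # ape numbering for internals
    edge <- matrix(0L, n_tips + n_int - 1L, 2L)
    len <- numeric(nrow(edge))
    r <- 1L
    for (m in seq_len(n_int)[-1]) {
      edge[r, ] <- c(node_id(node_parent[m]), node_id(m))
      len[r] <- node_time[m] - node_time[node_parent[m]]
      r <- r + 1L
    }
    for (j in seq_len(n_tips)) {
      edge[r, ] <- c(node_id(active[j]), j)
      len[r] <- present - node_time[active[j]]
      r <- r + 1L
    }
    tree <- structure(list(edge = edge, edge.length = len,
                           tip.label = paste0("t", seq_len(n_tips)),
                           Nnode = n_int),
                      class = "phylo")
    ape::reorder.phylo(tree, "cladewise")
  })
}

#' Rescale a chronogram to a target root age
#'
#' @param tree Ultrametric `phylo`.
#' @param root_age Desired root age (same units as the branch lengths).
#' @return The rescaled tree.
#' @export
rescale_tree_depth <- function(tree, root_age) {
  depth <- max(ape::node.depth.edgelength(tree))
  assert_that(depth > 0, "tree has zero depth")
  tree$edge.length <- tree$edge.length * root_age / depth
  tree
}

# Gillespie simulation of anagenetic DEC along one branch, honouring epoch
# boundaries. `range` is an integer vector of area indices; returns the
# range at the branch bottom (possibly empty).
sim_branch <- function(range, hypothesis, space, d, e, t_top, t_bottom) {
  epochs <- hypothesis$epochs
  n_areas <- length(space$areas)
  tau <- t_top
  while (tau > t_bottom + 1e-12) {
    ei <- which(epochs$end <= tau - 1e-12 & tau <= epochs$start + 1e-9)[1]
    M <- hypothesis$multipliers[[ei]]
    seg_end <- max(epochs$end[ei], t_bottom)
    if (length(range) == 0) return(range)
    gain <- setdiff(seq_len(n_areas), range)
    gain_rate <- if (length(range) < space$max_range_size && length(gain)) {
      vapply(gain, function(a) d * sum(M[range, a]), numeric(1))
    } else numeric(0)
    loss_rate <- rep(e, length(range))
    total <- sum(gain_rate) + sum(loss_rate)
    if (total <= 0) {
      tau <- seg_end
      next
    }
    dt <- rexp(1, total)
    if (tau - dt < seg_end) {
      tau <- seg_end
      next
    }
    tau <- tau - dt
    ev <- sample.int(length(gain_rate) + length(loss_rate), 1,
                     prob = c(gain_rate, loss_rate))
    if (ev <= length(gain_rate)) {
      range <- sort(c(range, gain[ev]))
    } else {
      range <- range[-(ev - length(gain_rate))]
    }
  }
  range
}

#' Forward-simulate DEC tip ranges on a chronogram
#'
#' Anagenetic events (range expansion, local extinction) are drawn by
#' Gillespie simulation with the dispersal multipliers of whichever epoch is
#' in force; at each node a cladogenetic scenario is drawn from the same
#' enumeration the likelihood engine uses. If any lineage goes globally
#' extinct (empty range) the whole simulation restarts, up to `max_retries`
#' times; the restart count is returned as an attribute. Because the DEC
#' likelihood does not condition on survival, heavy restarting signals a
#' parameter regime where simulated and fitted processes diverge.
#'
#' @param tree Ultrametric `phylo` with branch lengths in KY.
#' @param hypothesis A [biogeo_hypothesis()] whose epochs cover the root age.
#' @param d,e Dispersal and extinction rates (per KY), >= 0.
#' @param seed Integer seed.
#' @param root_range Character vector of area names at the root, or `NULL`
#'   to draw a living state uniformly.
#' @param max_retries Restart cap on global extinction (default 100).
#' @return Tibble with `taxon` plus one 0/1 column per area; attribute
#'   `restarts` counts discarded extinct simulations.
#' @export
simulate_dec_tip_ranges <- function(tree, hypothesis, d, e, seed,
                                    root_range = NULL, max_retries = 100) {
  assert_that(d >= 0 && e >= 0, "rates must be non-negative")
  space <- build_state_space(hypothesis$areas)
  ages <- node_ages(tree)
  n_tip <- length(tree$tip.label)
  scen <- cladogenesis_scenarios(space)
  edge <- tree$edge
  with_seed(seed, {
    for (try in seq_len(max_retries)) {
      root_state <- if (is.null(root_range)) {
        sample.int(space$n_living, 1)
      } else state_index(space, root_range)
      state_at <- vector("list", n_tip + tree$Nnode)
      # daughter ranges at the root split
      sc <- scen[[root_state]]
      pick <- sample.int(length(sc$prob), 1, prob = sc$prob)
      root <- n_tip + 1L
      kids <- edge[edge[, 1] == root, 2]
      state_at[[kids[1]]] <- space$states[[sc$left[pick]]]
      state_at[[kids[2]]] <- space$states[[sc$right[pick]]]
      failed <- FALSE
      # preorder: parents before children
      ord <- order(-ages[edge[, 1]])
      for (k in ord) {
        par <- edge[k, 1]; chd <- edge[k, 2]
        rng <- sim_branch(state_at[[chd]], hypothesis, space, d, e,
                          ages[par], ages[chd])
        if (length(rng) == 0) { failed <- TRUE; break }
        if (chd <= n_tip) {
          state_at[[chd]] <- rng
        } else {
          sc <- scen[[state_index(space, space$areas[rng])]]
          pick <- sample.int(length(sc$prob), 1, prob = sc$prob)
          gkids <- edge[edge[, 1] == chd, 2]
          state_at[[gkids[1]]] <- space$states[[sc$left[pick]]]
          state_at[[gkids[2]]] <- space$states[[sc$right[pick]]]
          state_at[[chd]] <- rng
        }
      }
      if (!failed) {
        mat <- matrix(0L, n_tip, length(space$areas),
                      dimnames = list(NULL, space$areas))
        for (i in seq_len(n_tip)) mat[i, state_at[[i]]] <- 1L
        out <- bind_cols(tibble(taxon = tree$tip.label), as_tibble(mat))
        attr(out, "restarts") <- try - 1L
        return(out)
      }
    }
    abort(sprintf(
      "all %d simulations went globally extinct; lower `e` or shorten the tree",
      max_retries))
  })
}
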