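# Neutral coalescent simulation: genealogy sampler shared by the alignment
# generator and the fast null-statistic path of the neutrality tests.

# One Kingman genealogy for n tips. Returns per-level exposure (for each
# coalescent level k = n..2: interval length and the subtree sizes of the k
# lineages) and, if `track_sets`, the tip sets of every lineage interval.
sample_genealogy <- function(n, track_sets = FALSE) {
  sizes <- rep(1L, n)
  sets <- if (track_sets) lapply(seq_len(n), identity) else NULL
  lens <- numeric(n - 1L)
  size_list <- vector("list", n - 1L)
  set_list <- if (track_sets) vector("list", n - 1L) else NULL
  for (lvl in seq_len(n - 1L)) {
    k <- n - lvl + 1L
    lens[lvl] <- rexp(1, k * (k - 1) / 2)
    size_list[[lvl]] <- sizes
    if (track_sets) set_list[[lvl]] <- sets
    pair <- sample.int(k, 2)
    i <- min(pair); j <- max(pair)
    sizes[i] <- sizes[i] + sizes[j]
    if (track_sets) sets[[i]] <- c(sets[[i]], sets[[j]])
    sizes <- sizes[-j]
    if (track_sets) sets <- sets[-j]
  }
  list(lens = lens, sizes = size_list, sets = set_list,
       total_length = sum(lens * (n - seq_len(n - 1L) + 1L)))
}

# Place S mutations uniformly on total branch length; returns the derived
# tip count of each mutation (and optionally the lineage coordinates).
place_mutations <- function(gen, S, want_index = FALSE) {
  n_lvl <- length(gen$lens)
  ks <- lengths(gen$sizes)
  w <- rep(gen$lens, times = ks) # per-lineage exposure
  idx <- sample.int(length(w), S, replace = TRUE, prob = w)
  lvl <- rep(seq_len(n_lvl), times = ks)[idx]
  pos <- idx - c(0, cumsum(ks))[lvl] # lineage index within level
  counts <- vapply(seq_len(S), function(s) gen$sizes[[lvl[s]]][pos[s]],
                   integer(1))
  if (want_index) list(counts = counts, lvl = lvl, pos = pos)
  else list(counts = counts)
}

#' Simulate a neutral coalescent alignment
#'
#' A Kingman genealogy for `n` samples with infinite-sites mutations: either
#' exactly `S` mutations placed uniformly on the total branch length
#' (fixed-S mode, the default used for neutrality-test nulls) or a number
#' drawn as Poisson with mean `theta/2` times the total branch length
#' (theta mode, for which the expected pairwise difference count equals
#' `theta`). Each mutation occupies its own alignment column: a random
#' ancestral base with a distinct derived base carried by the mutant
#' lineage's descendants.
#'
#' @param n Number of sequences (>= 2).
#' @param L Alignment length in bp.
#' @param S Number of segregating mutations (fixed-S mode), `0 <= S <= L`.
#' @param theta Population-scaled mutation rate (theta mode); exactly one of
#'   `S` and `theta` must be given.
#' @param seed Integer seed.
#' @param ids Sequence names (default `seq1..seqn`).
#' @return Character matrix (`n x L`, rownames = ids) of A/C/G/T.
#' @export
simulate_coalescent_alignment <- function(n, L, S = NULL, theta = NULL,
                                          seed = 1,
                                          ids = paste0("seq", seq_len(n))) {
  assert_that(n >= 2, "`n` must be at least 2")
  assert_that(xor(is.null(S), is.null(theta)),
              "give exactly one of `S` and `theta`")
  with_seed(seed, {
    gen <- sample_genealogy(n, track_sets = TRUE)
    if (is.null(S)) S <- stats::rpois(1, theta / 2 * gen$total_length)
    assert_that(S <= L, sprintf("S = %d exceeds alignment length L = %d",
                                S, L))
    # mutations are placed before sites/bases are drawn so that the
    # genealogy-only fast path of the neutrality nulls shares this stream
    mut <- if (S > 0) place_mutations(gen, S, want_index = TRUE) else NULL
    bases <- c("A", "C", "G", "T")
    anc <- sample(bases, L, replace = TRUE)
    aln <- matrix(rep(anc, each = n), n, L)
    rownames(aln) <- ids
    if (S > 0) {
      cols <- sample.int(L, S)
      for (s in seq_len(S)) {
        tipset <- gen$sets[[mut$lvl[s]]][[mut$pos[s]]]
        derived <- sample(setdiff(bases, anc[cols[s]]), 1)
        aln[tipset, cols[s]] <- derived
      }
    }
    aln
  })
}

# Fast null distribution of the neutrality statistics: `reps` genealogies of
# size n, each with exactly S mutations, with pi/eta_s computed from the
# mutations' derived counts (no alignment is materialised). A test verifies
# this path against statistics computed from full simulated alignments.
coalescent_null_stats <- function(n, S, reps, seed) {
  with_seed(seed, {
    purrr::map_dfr(seq_len(reps), function(r) {
      gen <- sample_genealogy(n)
      cnt <- place_mutations(gen, S)$counts
      pi_total <- sum(cnt * (n - cnt)) / (n * (n - 1) / 2)
      eta_s <- sum(cnt == 1 | cnt == n - 1)
      tibble(rep = r, pi_total = pi_total, eta_s = eta_s,
             tajima_d = tajima_d_stat(n, S, pi_total),
             fu_li_dstar = fu_li_dstar_stat(n, S, eta_s),
             fu_li_fstar = fu_li_fstar_stat(n, S, pi_total, eta_s))
    })
  })
}
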