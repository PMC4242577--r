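# Haplotype/nucleotide diversity and coalescent neutrality tests.

#' Read an alignment from FASTA
#'
#' @param path FASTA file of equal-length nucleotide sequences.
#' @return Character matrix (sequences x sites, uppercase), rownames = ids.
#' @export
read_alignment <- function(path) {
  dna <- ape::read.FASTA(path)
  assert_that(length(dna) >= 2, "alignment needs at least 2 sequences")
  chars <- lapply(as.character(dna), function(x) toupper(x))
  lens <- lengths(chars)
  assert_that(length(unique(lens)) == 1,
              "sequences have unequal lengths; not an alignment")
  aln <- do.call(rbind, chars)
  rownames(aln) <- names(dna)
  aln
}

#' Write an alignment to FASTA
#'
#' @param aln Character matrix as returned by [read_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  ids <- rownames(aln) %||% paste0("seq", seq_len(nrow(aln)))
  lines <- unlist(lapply(seq_len(nrow(aln)), function(i) {
    c(paste0(">", ids[i]), paste(aln[i, ], collapse = ""))
  }))
  writeLines(lines, path)
  invisible(path)
}

harmonic <- function(m) sum(1 / seq_len(m))
harmonic2 <- function(m) sum(1 / seq_len(m)^2)

# Tajima's (1989) D from sample size, segregating sites and total mean
# pairwise differences.
tajima_d_stat <- function(n, S, pi_total) {
  if (S < 1) return(NA_real_)
  a1 <- harmonic(n - 1); a2 <- harmonic2(n - 1)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Fu & Li (1993) D* and F* without outgroup, with the later-corrected
# variance constants (the convention of standard population-genetics
# software); eta = total mutations, eta_s = singleton mutations.
fu_li_dstar_stat <- function(n, eta, eta_s) {
  if (eta < 1 || n < 3) return(NA_real_)
  an <- harmonic(n - 1); bn <- harmonic2(n - 1)
  an1 <- an + 1 / n
  cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * bn + an^2 * dn -
           2 * (n * an * (an + 1)) / (n - 1)^2) / (an^2 + bn)
  uD <- (n / (n - 1)) * (an - n / (n - 1)) - vD
  ((n / (n - 1)) * eta - an * eta_s) / sqrt(uD * eta + vD * eta^2)
}

fu_li_fstar_stat <- function(n, eta, pi_total, eta_s) {
  if (eta < 1 || n < 3) return(NA_real_)
  an <- harmonic(n - 1); bn <- harmonic2(n - 1)
  an1 <- an + 1 / n
  vF <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
           (2 * (n - 1) * an) / n^2 - 8 * bn / n) / (an^2 + bn)
  uF <- ((4 * n^2 + 19 * n + 3 - 12 * (n + 1) * an1) /
           (3 * n * (n - 1))) / an - vF
  (pi_total - ((n - 1) / n) * eta_s) / sqrt(uF * eta + vF * eta^2)
}

#' Diversity and neutrality statistics of an alignment
#'
#' Sites containing a gap, `N` or other ambiguity are excluded listwise
#' before anything is counted. Haplotype diversity uses the small-sample
#' correction `h = n (1 - sum p_i^2) / (n - 1)`; Watterson's estimator is
#' per site, `theta_S = S / (a1 L)`; `pi` is the mean pairwise difference
#' per site. Tajima's D contrasts `pi` with `theta_S`; Fu & Li's D* and F*
#' (no-outgroup statistics) contrast total and singleton mutation counts.
#' When no variation remains the test statistics are `NA`.
#'
#' @param aln Character matrix (sequences x sites) as from
#'   [read_alignment()] or [simulate_coalescent_alignment()].
#' @return One-row tibble: `n`, `L`, `S`, `eta`, `eta_s`, `n_h`, `h`,
#'   `theta_s`, `pi`, `tajima_d`, `fu_li_dstar`, `fu_li_fstar`.
#' @export
diversity <- function(aln) {
  assert_that(is.matrix(aln) && nrow(aln) >= 2,
              "`aln` must be a matrix with at least 2 sequences")
  aln <- toupper(aln)
  n <- nrow(aln)
  keep <- apply(aln, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  aln <- aln[, keep, drop = FALSE]
  L <- ncol(aln)
  assert_that(L > 0, "no complete sites remain after filtering")
  hap <- apply(aln, 1L, paste, collapse = "")
  p <- table(hap) / n
  n_h <- length(p)
  h <- n * (1 - sum(p^2)) / (n - 1)
  per_site <- apply(aln, 2L, function(col) {
    cb <- tabulate(match(col, c("A", "C", "G", "T")), 4L)
    k_all <- sum(cb > 0)
    c(seg = as.integer(k_all > 1),
      eta = k_all - 1L,
      eta_s = min(sum(cb == 1), k_all - 1L),
      diffs = (n^2 - sum(cb^2)) / 2)
  })
  S <- sum(per_site["seg", ])
  eta <- sum(per_site["eta", ])
  eta_s <- sum(per_site["eta_s", ])
  pi_total <- sum(per_site["diffs", ]) / (n * (n - 1) / 2)
  a1 <- harmonic(n - 1)
  tibble(
    n = n, L = L, S = S, eta = eta, eta_s = eta_s, n_h = n_h, h = h,
    theta_s = S / (a1 * L), pi = pi_total / L,
    tajima_d = tajima_d_stat(n, S, pi_total),
    fu_li_dstar = fu_li_dstar_stat(n, eta, eta_s),
    fu_li_fstar = fu_li_fstar_stat(n, eta, pi_total, eta_s)
  )
}

#' Coalescent-simulation p-values for the neutrality tests
#'
#' Compares the observed Tajima's D and Fu & Li D*/F* to their null
#' distributions over `reps` neutral coalescent genealogies of the same
#' sample size, conditioned on the observed number of segregating sites.
#' Two-tailed with add-one correction:
#' `p = min(1, 2 * min(lower tail, upper tail))` where each tail is
#' `(1 + #\{null at least as extreme\}) / (1 + reps)`.
#'
#' @param aln Alignment matrix, or a one-row tibble from [diversity()].
#' @param reps Number of coalescent simulations (default 1000).
#' @param seed Integer seed.
#' @return Tibble: `statistic`, `observed`, `p` (NA observed gives NA p).
#' @export
neutrality_pvalues <- function(aln, reps = 1000, seed = 1) {
  stats <- if (is.matrix(aln)) diversity(aln) else as_tibble(aln)
  assert_that(stats$S >= 1, "need at least one segregating site")
  null <- coalescent_null_stats(stats$n, stats$S, reps, seed)
  one <- function(obs, null_vals) {
    if (is.na(obs)) return(NA_real_)
    lo <- (1 + sum(null_vals <= obs, na.rm = TRUE)) / (1 + reps)
    hi <- (1 + sum(null_vals >= obs, na.rm = TRUE)) / (1 + reps)
    min(1, 2 * min(lo, hi))
  }
  tibble(
    statistic = c("tajima_d", "fu_li_dstar", "fu_li_fstar"),
    observed = c(stats$tajima_d, stats$fu_li_dstar, stats$fu_li_fstar),
    p = c(one(stats$tajima_d, null$tajima_d),
          one(stats$fu_li_dstar, null$fu_li_dstar),
          one(stats$fu_li_fstar, null$fu_li_fstar))
  )
}
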