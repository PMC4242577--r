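# broom-style tidiers for the package's fitted objects.

#' @describeIn fit_hypothesis Tidy the root-range profile of a DEC fit.
#' @param x A `dec_fit`.
#' @param ... Unused.
#' @export
tidy.dec_fit <- function(x, ...) {
  mutate(x$root_profile, hypothesis = x$hypothesis, .before = 1)
}

#' @describeIn fit_hypothesis One-row summary of a DEC fit.
#' @export
glance.dec_fit <- function(x, ...) {
  tibble(hypothesis = x$hypothesis, neg_log_lik = x$neg_log_lik,
         d = x$d, e = x$e, convergence = x$convergence)
}

#' @describeIn equivalency_test Null overlap distribution, one row per
#'   repetition.
#' @param x A `niche_test`.
#' @param ... Unused.
#' @export
tidy.niche_test <- function(x, ...) {
  tibble(test = x$test, rep = seq_along(x$null_d), null_d = x$null_d)
}

#' @describeIn equivalency_test One-row test summary.
#' @export
glance.niche_test <- function(x, ...) {
  tibble(test = x$test, d_obs = x$d_obs, p = x$p, reps = x$reps)
}

#' @describeIn env_pca Loadings in long form.
#' @param x An `env_pca`.
#' @param ... Unused.
#' @export
tidy.env_pca <- function(x, ...) {
  as_tibble(x$rotation, rownames = "variable") %>%
    tidyr::pivot_longer(-"variable", names_to = "axis",
                        values_to = "loading")
}

#' @describeIn env_pca Variance fractions per axis.
#' @export
glance.env_pca <- function(x, ...) {
  tibble(axis = paste0("PC", seq_along(x$var_frac)),
         var_frac = x$var_frac)
}

#' @describeIn lda_fit Discriminant coefficients in long form.
#' @param x An `lda_morph`.
#' @param ... Unused.
#' @export
tidy.lda_morph <- function(x, ...) {
  as_tibble(x$scaling, rownames = "character") %>%
    tidyr::pivot_longer(-"character", names_to = "fn",
                        values_to = "coefficient")
}

#' @describeIn lda_fit Proportion of trace per discriminant function.
#' @export
glance.lda_morph <- function(x, ...) {
  tibble(fn = colnames(x$scaling), prop_trace = x$prop_trace)
}

flatten_tree <- function(node, id = 1L, depth = 0L) {
  is_leaf <- node$type == "leaf"
  row <- list(node = id, depth = depth, type = node$type, n = node$n,
              class = if (is_leaf) node$class else NA_character_,
              var = if (is_leaf) NA_character_ else node$var,
              left_levels = if (is_leaf) NA_character_ else
                paste(node$left_levels, collapse = "|"))
  base <- as_tibble(row)
  if (is_leaf) return(base)
  l <- flatten_tree(node$left, id * 2L, depth + 1L)
  r <- flatten_tree(node$right, id * 2L + 1L, depth + 1L)
  bind_rows(base, l, r)
}

#' @describeIn fit_classification_tree Node table of the fitted tree.
#' @param x A `morph_tree`.
#' @param ... Unused.
#' @export
tidy.morph_tree <- function(x, ...) {
  flatten_tree(x$root)
}

#' @describeIn fit_classification_tree One-row tree summary.
#' @export
glance.morph_tree <- function(x, ...) {
  tibble(n = x$n, n_classes = length(x$classes), n_leaves = n_groups(x))
}
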