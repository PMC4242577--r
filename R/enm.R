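# Ensemble niche-model machinery: predictor pruning, weighted-background
# learners, AUC gating, and thresholding.

#' Prune correlated predictors
#'
#' Greedy selection by descending importance: a variable is kept iff its
#' absolute Spearman correlation with every already-kept variable does not
#' exceed `threshold`.
#'
#' @param importance Named numeric vector of per-variable importance scores.
#' @param rho Symmetric correlation matrix with unit diagonal covering the
#'   same variables.
#' @param threshold Maximum tolerated absolute correlation (default 0.7).
#' @return Character vector of selected variable names, in selection order.
#' @export
prune_predictors <- function(importance, rho, threshold = 0.7) {
  vars <- names(importance)
  assert_that(!is.null(vars) && all(vars %in% rownames(rho)),
              "`rho` must cover all names of `importance`")
  rho <- rho[vars, vars, drop = FALSE]
  assert_that(max(abs(rho - t(rho))) < 1e-8,
              "`rho` must be symmetric")
  assert_that(max(abs(diag(rho) - 1)) < 1e-8,
              "`rho` must have unit diagonal")
  ord <- vars[order(-importance)]
  kept <- character(0)
  for (v in ord) {
    if (!length(kept) || all(abs(rho[v, kept]) <= threshold)) {
      kept <- c(kept, v)
    }
  }
  kept
}

#' Background weights equalising total presence and background mass
#'
#' Presences get weight 1 each; each background record gets
#' `n_presence / n_background` so both classes carry equal total weight in
#' the fit.
#'
#' @param n_presence,n_background Record counts (both >= 1).
#' @return List with numeric vectors `presence` and `background`.
#' @export
weighted_background <- function(n_presence, n_background) {
  assert_that(n_presence >= 1 && n_background >= 1,
              "both counts must be at least 1")
  list(presence = rep(1, n_presence),
       background = rep(n_presence / n_background, n_background))
}

# ---- learner registry -----------------------------------------------------

learner_registry <- new.env(parent = emptyenv())

#' Register a custom suitability learner
#'
#' A learner is a function `(presences, background, weights) -> model` whose
#' model answers `predict(model, newdata)` with suitabilities in `[0, 1]`.
#'
#' @param name Learner identifier.
#' @param fit_fun Fitting function as described above.
#' @return `name`, invisibly.
#' @export
register_learner <- function(name, fit_fun) {
  assign(name, fit_fun, envir = learner_registry)
  invisible(name)
}

new_learner <- function(name, state, predict_fun) {
  structure(list(name = name, state = state, predict_fun = predict_fun),
            class = "enm_learner")
}

#' @export
print.enm_learner <- function(x, ...) {
  cat(sprintf("<enm_learner> %s\n", x$name))
  invisible(x)
}

#' Predict suitabilities from a fitted learner
#'
#' @param object An `enm_learner`.
#' @param newdata Climate tibble with the training variables.
#' @param ... Unused.
#' @return Numeric vector of suitabilities in `[0, 1]`.
#' @export
predict.enm_learner <- function(object, newdata, ...) {
  p <- object$predict_fun(object$state, as_tibble(newdata))
  pmin(pmax(as.double(p), 0), 1)
}

# Percentile-envelope learner: suitability 1 inside the per-variable
# [lo, hi] percentile box, linear taper to 0 over one inter-percentile width
# outside; overall score is the minimum across variables.
fit_envelope <- function(presences, background, weights,
                         probs = c(0.05, 0.95)) {
  box <- purrr::map(presences, ~ quantile(.x, probs = probs, names = FALSE,
                                          type = 7))
  new_learner("envelope", list(box = box), function(state, nd) {
    scores <- purrr::imap(state$box, function(b, v) {
      w <- b[2] - b[1]
      x <- nd[[v]]
      below <- pmax(b[1] - x, 0)
      above <- pmax(x - b[2], 0)
      d <- below + above
      if (w <= 0) as.double(d == 0) else pmax(1 - d / w, 0)
    })
    do.call(pmin, scores)
  })
}

# Mahalanobis-distance learner: squared distance to the presence centroid
# under the presence covariance, mapped to [0, 1] through the chi-square
# upper tail (1 at the centroid).
fit_mahalanobis <- function(presences, background, weights) {
  X <- as.matrix(presences)
  assert_that(nrow(X) > ncol(X),
              "mahalanobis learner needs more presences than variables")
  mu <- colMeans(X)
  S <- cov(X)
  if (rcond(S) < 1e-12) {
    abort("rank-deficient presence covariance in mahalanobis learner")
  }
  new_learner("mahalanobis", list(mu = mu, S = S, p = ncol(X)),
              function(state, nd) {
                d2 <- mahalanobis(as.matrix(nd[names(state$mu)]),
                                  state$mu, state$S)
                1 - pchisq(d2, df = state$p)
              })
}

# Weighted logistic regression on linear climate terms, fitted by IRLS
# (stats::glm); quasibinomial family accommodates non-integer background
# weights without changing the coefficient path.
fit_logistic <- function(presences, background, weights) {
  dat <- bind_rows(mutate(presences, .y = 1), mutate(background, .y = 0))
  w <- c(weights$presence, weights$background)
  fit <- suppressWarnings(
    glm(.y ~ ., data = dat, family = quasibinomial(), weights = w)
  )
  vars <- names(presences)
  new_learner("logistic", list(fit = fit, vars = vars),
              function(state, nd) {
                as.double(predict(state$fit, newdata = nd[state$vars],
                                  type = "response"))
              })
}

#' Fit a suitability learner
#'
#' Three reference learners are built in (`envelope`, `mahalanobis`,
#' `logistic`); further learners can be added with [register_learner()].
#'
#' @param name Learner identifier.
#' @param presences,background Climate tibbles (same columns).
#' @param weights Per-record weights as returned by [weighted_background()];
#'   computed from the row counts when `NULL`.
#' @return An `enm_learner`.
#' @export
fit_learner <- function(name, presences, background, weights = NULL) {
  presences <- as_tibble(presences)
  background <- as_tibble(background)
  if (is.null(weights)) {
    weights <- weighted_background(nrow(presences), nrow(background))
  }
  fitter <- switch(name,
                   envelope = fit_envelope,
                   mahalanobis = fit_mahalanobis,
                   logistic = fit_logistic,
                   get0(name, envir = learner_registry))
  assert_that(!is.null(fitter), sprintf("unknown learner '%s'", name))
  fitter(presences, background, weights)
}

#' Rank-based AUC (Mann-Whitney with midranks)
#'
#' @param presence_scores,background_scores Nonempty numeric vectors.
#' @return AUC in `[0, 1]`: the probability a random presence outscores a
#'   random background point, counting ties as one half.
#' @export
auc <- function(presence_scores, background_scores) {
  assert_that(length(presence_scores) >= 1 && length(background_scores) >= 1,
              "both score vectors must be nonempty")
  np <- length(presence_scores)
  nb <- length(background_scores)
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Bootstrap AUC gate for an ensemble
#'
#' Each learner is fitted on `n_reps` stratified bootstrap splits
#' (`train_frac` of presences and of background for training, the rest for
#' verification); learners whose mean verification AUC falls below `auc_min`
#' are dropped, and survivors are refitted on 100% of the data.
#'
#' @param learners Character vector of learner names.
#' @param presences,background Climate tibbles.
#' @param n_reps Number of bootstrap replicates (default 10).
#' @param train_frac Training fraction (default 0.7).
#' @param auc_min Retention threshold on mean AUC (default 0.7).
#' @param seed Integer seed for the splits.
#' @return List with `models` (retained, refit on all data), `auc` (tibble:
#'   learner, mean_auc, n_reps_ok, retained).
#' @export
bootstrap_gate <- function(learners, presences, background, n_reps = 10,
                           train_frac = 0.7, auc_min = 0.7, seed = 1) {
  assert_that(n_reps >= 1, "`n_reps` must be at least 1")
  presences <- as_tibble(presences)
  background <- as_tibble(background)
  np <- nrow(presences)
  nb <- nrow(background)
  aucs <- matrix(NA_real_, n_reps, length(learners),
                 dimnames = list(NULL, learners))
  for (rep in seq_len(n_reps)) {
    idx_p <- with_seed(derive_seed(seed, rep * 2),
                       sample.int(np, size = max(1, round(train_frac * np))))
    idx_b <- with_seed(derive_seed(seed, rep * 2 + 1),
                       sample.int(nb, size = max(1, round(train_frac * nb))))
    tr_p <- presences[idx_p, ]; te_p <- presences[-idx_p, ]
    tr_b <- background[idx_b, ]; te_b <- background[-idx_b, ]
    if (!nrow(te_p) || !nrow(te_b)) next
    for (ln in learners) {
      model <- tryCatch(fit_learner(ln, tr_p, tr_b), error = function(e) NULL)
      if (is.null(model)) {
        message(sprintf("learner '%s' failed on replicate %d: skipped",
                        ln, rep))
        next
      }
      aucs[rep, ln] <- auc(predict(model, te_p), predict(model, te_b))
    }
  }
  tab <- tibble(
    learner = learners,
    mean_auc = colMeans(aucs, na.rm = TRUE),
    n_reps_ok = colSums(!is.na(aucs))
  ) %>%
    mutate(retained = is.finite(.data$mean_auc) & .data$mean_auc >= auc_min)
  models <- purrr::map(tab$learner[tab$retained],
                       ~ fit_learner(.x, presences, background))
  names(models) <- tab$learner[tab$retained]
  list(models = models, auc = tab)
}

#' Convert suitabilities to a presence/absence cutoff
#'
#' Two rules: `sens_eq_spec` scans the unique predicted values and returns
#' the lowest cutoff minimizing |sensitivity - specificity| (classifying
#' score >= cutoff as suitable); `mean_probability` returns the mean
#' prediction over the background cells.
#'
#' @param model An `enm_learner`.
#' @param presences,background Climate tibbles.
#' @param rule `"sens_eq_spec"` or `"mean_probability"`.
#' @return Numeric cutoff.
#' @export
select_threshold <- function(model, presences, background,
                             rule = c("sens_eq_spec", "mean_probability")) {
  rule <- match.arg(rule)
  sp <- predict(model, presences)
  sb <- predict(model, background)
  if (rule == "mean_probability") return(mean(sb))
  cand <- sort(unique(c(sp, sb)))
  if (length(cand) == 1L) {
    warn("constant predictions: degenerate threshold")
    return(cand)
  }
  gap <- vapply(cand, function(cut) {
    sens <- mean(sp >= cut)
    spec <- mean(sb < cut)
    abs(sens - spec)
  }, numeric(1))
  cand[which(gap == min(gap))[1]] # ties -> lowest cutoff
}

#' Predict a suitability raster from a fitted learner
#'
#' @param model An `enm_learner`.
#' @param stack Named list of [raster_grid]s with the training variables.
#' @return [raster_grid] of suitabilities (`NA` where any input is missing).
#' @export
predict_map <- function(model, stack) {
  g1 <- stack[[1]]
  tab <- as_tibble(lapply(stack, function(g) as.vector(g$values)))
  ok <- stats::complete.cases(tab)
  out <- rep(NA_real_, nrow(tab))
  if (any(ok)) out[ok] <- predict(model, tab[ok, ])
  raster_grid(matrix(out, g1$n_rows, g1$n_cols),
              g1$x_origin, g1$y_origin, g1$cell_size)
}

#' Binarize a suitability raster at a cutoff
#'
#' @param map [raster_grid] of suitabilities.
#' @param cutoff Threshold; cells with value >= cutoff become 1.
#' @return [raster_grid] with values in `{0, 1, NA}`.
#' @export
binarize_map <- function(map, cutoff) {
  raster_grid((map$values >= cutoff) * 1,
              map$x_origin, map$y_origin, map$cell_size)
}
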