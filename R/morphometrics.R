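# Categorical classification trees (Gini, subset splits) and Fisher linear
# discriminants for the morphology tables.

node_gini <- function(labels) {
  p <- table(labels) / length(labels)
  1 - sum(p^2)
}

# All binary subset splits of the levels present at a node, in canonical
# order: the side containing the alphabetically first level is "left";
# candidates are ordered by variable (column order) then by the sorted
# level-string of the left side, so ties resolve deterministically.
subset_splits <- function(levels_present) {
  lv <- sort(unique(levels_present))
  if (length(lv) < 2) return(list())
  rest <- lv[-1]
  subs <- list()
  for (k in 0:(length(rest) - 1)) {
    for (cmb in utils::combn(length(rest), k, simplify = FALSE)) {
      subs <- c(subs, list(c(lv[1], rest[cmb])))
    }
  }
  keys <- vapply(subs, function(s) paste(sort(s), collapse = "\r"),
                 character(1))
  subs[order(keys)]
}

grow_tree <- function(data, labels, vars, min_leaf, min_split, min_dec) {
  n <- length(labels)
  counts <- table(labels)
  leaf <- function() {
    list(type = "leaf",
         class = names(counts)[which.max(counts)],
         counts = counts, n = n)
  }
  g <- node_gini(labels)
  if (g == 0 || n < min_split) return(leaf())
  best <- NULL
  for (v in vars) {
    x <- data[[v]]
    for (sub in subset_splits(x)) {
      left <- x %in% sub
      nl <- sum(left); nr <- n - nl
      if (nl < min_leaf || nr < min_leaf) next
      dec <- n * g - nl * node_gini(labels[left]) -
        nr * node_gini(labels[!left])
      if (dec > min_dec + 1e-12 && (is.null(best) || dec > best$dec + 1e-12)) {
        best <- list(var = v, sub = sub, left = left, dec = dec)
      }
    }
  }
  if (is.null(best)) return(leaf())
  list(type = "split", var = best$var, left_levels = best$sub,
       n = n, counts = counts, gini_decrease = best$dec,
       left = grow_tree(data[best$left, , drop = FALSE], labels[best$left],
                        vars, min_leaf, min_split, min_dec),
       right = grow_tree(data[!best$left, , drop = FALSE], labels[!best$left],
                         vars, min_leaf, min_split, min_dec))
}

#' Fit a categorical classification tree
#'
#' Greedy binary recursive partitioning on categorical subset membership,
#' maximizing the Gini impurity decrease at each split. Splitting stops at
#' node purity, below the size thresholds, or when no split decreases the
#' (size-weighted) Gini by at least `min_deviance_frac` of the root's.
#' Tie-breaks are deterministic: first variable in column order,
#' lexicographically smallest left-level subset.
#'
#' @param data Tibble of categorical character columns plus a label column.
#' @param label_col Name of the class label column (default `"taxon"`).
#' @param columns Character columns to split on (default: all non-label).
#' @param min_leaf Minimum rows per child (default 5).
#' @param min_split Minimum rows to attempt a split (default 10).
#' @param min_deviance_frac Minimum Gini decrease as a fraction of the root
#'   impurity (default 0.01).
#' @return Object of class `morph_tree`.
#' @export
fit_classification_tree <- function(data, label_col = "taxon",
                                    columns = NULL, min_leaf = 5,
                                    min_split = 10,
                                    min_deviance_frac = 0.01) {
  data <- as_tibble(data)
  labels <- as.character(data[[label_col]])
  assert_that(!is.null(labels) && !any(is.na(labels)),
              "labels missing")
  vars <- columns %||% setdiff(names(data), label_col)
  assert_that(length(vars) >= 1, "no predictor columns")
  if (length(unique(labels)) < 2) {
    warn("single-class input: returning a one-leaf tree")
  }
  root_dec <- nrow(data) * node_gini(labels) * min_deviance_frac
  root <- grow_tree(data[vars], labels, vars, min_leaf, min_split, root_dec)
  structure(list(root = root, label_col = label_col, vars = vars,
                 n = nrow(data), classes = sort(unique(labels))),
            class = "morph_tree")
}

tree_route <- function(node, row) {
  while (node$type == "split") {
    node <- if (row[[node$var]] %in% node$left_levels) node$left
            else node$right
  }
  node
}

#' Predict classes from a classification tree
#'
#' @param object A `morph_tree`.
#' @param newdata Tibble with the training columns.
#' @param ... Unused.
#' @return Character vector of leaf majority classes.
#' @export
predict.morph_tree <- function(object, newdata, ...) {
  newdata <- as_tibble(newdata)
  vapply(seq_len(nrow(newdata)),
         function(i) tree_route(object$root, newdata[i, ])$class,
         character(1))
}

#' Misclassification rate of a fitted tree
#'
#' @param tree A `morph_tree`.
#' @param data Tibble with predictors and the label column.
#' @return Fraction of rows whose leaf majority class differs from their
#'   label.
#' @export
misclassification_rate <- function(tree, data) {
  data <- as_tibble(data)
  mean(predict(tree, data) != as.character(data[[tree$label_col]]))
}

count_leaves <- function(node) {
  if (node$type == "leaf") 1L
  else count_leaves(node$left) + count_leaves(node$right)
}

#' Number of leaves (taxonomic groups) in a fitted tree
#'
#' Method for the `dplyr::n_groups()` generic.
#'
#' @param x A `morph_tree`.
#' @return Integer leaf count.
#' @importFrom dplyr n_groups
#' @export n_groups.morph_tree
#' @export
n_groups.morph_tree <- function(x) count_leaves(x$root)

#' @export
dplyr::n_groups

#' @export
print.morph_tree <- function(x, ...) {
  cat(sprintf("<morph_tree> %d rows, %d classes, %d leaves\n",
              x$n, length(x$classes), n_groups(x)))
  invisible(x)
}

# ---- linear discriminants -------------------------------------------------

#' Fisher linear discriminant analysis of continuous morphology
#'
#' Listed columns are log10-transformed (they must be positive), then
#' Fisher discriminant directions are extracted from the within-class and
#' between-class scatter matrices. Each function's share of the trace
#' (eigenvalue fraction, the "proportion of trace") measures its
#' discriminatory weight; coefficients are normalized to unit pooled
#' within-class variance and signed so each function's largest-magnitude
#' coefficient is positive.
#'
#' @param data Tibble of continuous columns plus a label column.
#' @param label_col Class label column (default `"taxon"`).
#' @param columns Predictor columns (default: all numeric non-label).
#' @param log_columns Columns to log10-transform first.
#' @param ridge Ridge added to a singular within-class scatter (relative to
#'   its mean diagonal; default 1e-8, applied with a warning).
#' @return Object of class `lda_morph`: `scaling` (p x r coefficients),
#'   `prop_trace`, `center`, `classes`, `columns`, `log_columns`.
#' @export
lda_fit <- function(data, label_col = "taxon", columns = NULL,
                    log_columns = character(0), ridge = 1e-8) {
  data <- as_tibble(data)
  labels <- as.character(data[[label_col]])
  columns <- columns %||%
    setdiff(names(data)[vapply(data, is.numeric, logical(1))], label_col)
  k <- length(unique(labels))
  assert_that(nrow(data) > k, "need more rows than classes")
  X <- as.matrix(data[columns])
  for (cc in log_columns) {
    assert_that(cc %in% columns, sprintf("log column '%s' not in columns", cc))
    assert_that(all(X[, cc] > 0),
                sprintf("column '%s' must be positive to log-transform", cc))
    X[, cc] <- log10(X[, cc])
  }
  m <- colMeans(X)
  W <- matrix(0, ncol(X), ncol(X))
  B <- matrix(0, ncol(X), ncol(X))
  for (cl in unique(labels)) {
    Xc <- X[labels == cl, , drop = FALSE]
    mc <- colMeans(Xc)
    W <- W + crossprod(sweep(Xc, 2, mc))
    B <- B + nrow(Xc) * tcrossprod(mc - m)
  }
  if (rcond(W) < 1e-12) {
    warn("singular within-class scatter: ridge regularization applied")
    W <- W + ridge * mean(diag(W)) * diag(ncol(W))
  }
  eg <- eigen(solve(W, B))
  vals <- Re(eg$values)
  vecs <- Re(eg$vectors)
  r <- min(k - 1, sum(vals > max(vals) * 1e-9))
  vals <- vals[seq_len(r)]
  vecs <- vecs[, seq_len(r), drop = FALSE]
  Wp <- W / (nrow(X) - k) # pooled within-class covariance
  for (j in seq_len(r)) {
    a <- vecs[, j]
    a <- a / sqrt(drop(t(a) %*% Wp %*% a))
    if (a[which.max(abs(a))] < 0) a <- -a
    vecs[, j] <- a
  }
  dimnames(vecs) <- list(columns, paste0("LD", seq_len(r)))
  structure(
    list(scaling = vecs, prop_trace = vals / sum(vals), center = m,
         classes = sort(unique(labels)), columns = columns,
         log_columns = log_columns, label_col = label_col),
    class = "lda_morph"
  )
}

#' @export
print.lda_morph <- function(x, ...) {
  cat(sprintf("<lda_morph> %d classes, %d functions; proportion of trace: %s\n",
              length(x$classes), ncol(x$scaling),
              paste(sprintf("%.3f", x$prop_trace), collapse = " ")))
  invisible(x)
}

#' Project rows onto the discriminant functions
#'
#' @param model An [lda_fit()] result.
#' @param data Tibble containing the model's columns (and optionally the
#'   label column, carried through).
#' @return Tibble of scores `LD1..LDr` (plus the label column if present).
#' @export
lda_project <- function(model, data) {
  data <- as_tibble(data)
  assert_that(all(model$columns %in% names(data)),
              "data is missing model columns")
  X <- as.matrix(data[model$columns])
  for (cc in model$log_columns) X[, cc] <- log10(X[, cc])
  scores <- sweep(X, 2, model$center) %*% model$scaling
  out <- as_tibble(scores)
  if (model$label_col %in% names(data)) {
    out[[model$label_col]] <- data[[model$label_col]]
  }
  out
}
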