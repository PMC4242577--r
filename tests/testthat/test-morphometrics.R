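test_that("morphology sampling reproduces the specified table structure", {
  spec <- campanula_morph_spec()
  m <- sample_morphology(spec, seed = 1)
  expect_equal(nrow(m$categorical), 130) # 10+10+20+10+40+30+10
  expect_equal(nrow(m$continuous), 130)
  expect_equal(as.vector(table(m$continuous$taxon)[names(spec$n)]),
               unname(spec$n))
  # categorical rows replicate each taxon's levels exactly
  for (tx in names(spec$n)) {
    rows <- dplyr::filter(m$categorical, taxon == tx)
    expect_equal(nrow(dplyr::distinct(rows)), 1)
    expect_equal(rows$flower_shape[1],
                 spec$categorical$flower_shape[spec$categorical$taxon == tx])
  }
  # zero-SD characters equal their means exactly
  expect_true(all(m$continuous$seed_length[m$continuous$taxon == "aurita"]
                  == 1.2))
  # sample mean of corolla width for C. aurita converges to 22.6
  big <- sample_morphology(spec, seed = 2,
                           n = setNames(rep(10000L, 7), names(spec$n)))
  cw <- big$continuous$corolla_width[big$continuous$taxon == "aurita"]
  expect_lt(abs(mean(cw) - 22.6), 0.1)
  # missing taxon parameters are an error
  expect_error(sample_morphology(spec, seed = 1, n = spec$n[1:3]),
               "missing taxon")
})

test_that("classification trees split on Gini with deterministic tie-breaks", {
  # two classes with disjoint single-character levels: one split, no error
  toy <- tibble::tibble(
    taxon = rep(c("x", "y"), each = 12),
    ch = rep(c("red", "blue"), each = 12))
  tr <- fit_classification_tree(toy)
  expect_equal(n_groups(tr), 2)
  expect_equal(misclassification_rate(tr, toy), 0)
  expect_equal(tr$root$var, "ch")
  # a one-leaf tree on balanced 2-class data misclassifies half
  flat <- tibble::tibble(taxon = rep(c("x", "y"), each = 10),
                         ch = "same")
  expect_equal(misclassification_rate(fit_classification_tree(flat), flat),
               0.5)
  expect_warning(fit_classification_tree(
    tibble::tibble(taxon = "x", ch = c("a", "b"))), "single-class")
})

test_that("the full categorical table resolves all seven taxa without error", {
  m <- sample_morphology(seed = 3)
  cs <- campanula_morph_spec()$character_sets
  tr_all <- fit_classification_tree(m$categorical)
  expect_equal(n_groups(tr_all), 7)
  expect_equal(misclassification_rate(tr_all, m$categorical), 0)
  # flower-only and seed-only subsets also resolve all seven groups
  for (set in cs[c("flower", "seed")]) {
    tr <- fit_classification_tree(m$categorical, columns = set)
    expect_equal(n_groups(tr), 7)
    expect_equal(misclassification_rate(tr, m$categorical), 0)
  }
  # training error never increases with depth, and every accepted split
  # has a positive Gini decrease
  td <- generics::tidy(tr_all)
  expect_true(all(is.na(td$var) | td$type == "split"))
  splits <- collect_decreases(tr_all$root)
  expect_true(all(splits > 0))
})

test_that("vegetative characters alone merge the two cryptic pairs", {
  m <- sample_morphology(seed = 4)
  cs <- campanula_morph_spec()$character_sets
  tr <- fit_classification_tree(m$categorical, columns = cs$vegetative)
  expect_equal(n_groups(tr), 5)
  expect_equal(misclassification_rate(tr, m$categorical), 20 / 130)
  pred <- predict(tr, m$categorical)
  grp <- function(tx) unique(pred[m$categorical$taxon == tx])
  # lasiocarpa folds into piperi's leaf, aurita into parryi var. idahoensis'
  expect_length(grp("lasiocarpa"), 1)
  expect_equal(grp("lasiocarpa"), grp("piperi"))
  expect_equal(grp("aurita"), grp("parryi_idahoensis"))
  expect_false(grp("scabrella") == grp("scouleri"))
})

test_that("Fisher discriminants match the variance-partition contract", {
  set.seed(6)
  # two well-separated spherical classes: one informative function
  two <- tibble::tibble(
    taxon = rep(c("p", "q"), each = 40),
    a = rnorm(80, rep(c(0, 8), each = 40)),
    b = rnorm(80))
  f2 <- lda_fit(two)
  expect_equal(ncol(f2$scaling), 1)
  expect_equal(f2$prop_trace, 1)
  # k classes give at most k-1 functions; fractions sum to 1, non-increasing
  m <- sample_morphology(seed = 7)
  lda_cols <- campanula_morph_spec()$lda
  fit <- lda_fit(m$continuous, columns = lda_cols$columns,
                 log_columns = lda_cols$log_columns)
  expect_lte(ncol(fit$scaling), 6)
  expect_equal(sum(fit$prop_trace), 1)
  expect_true(all(diff(fit$prop_trace) <= 1e-12))
  # sign convention: the largest-magnitude coefficient of each function > 0
  expect_true(all(apply(fit$scaling, 2,
                        function(v) v[which.max(abs(v))] > 0)))
  # independent oracle: discriminant scores span the same axes as MASS::lda
  X <- m$continuous
  for (cc in lda_cols$log_columns) X[[cc]] <- log10(X[[cc]])
  ref <- MASS::lda(as.matrix(X[lda_cols$columns]), grouping = X$taxon)
  ours <- lda_project(fit, m$continuous)
  theirs <- as.matrix(X[lda_cols$columns]) %*% ref$scaling
  for (j in 1:3) {
    expect_gt(abs(stats::cor(ours[[paste0("LD", j)]], theirs[, j])),
              0.999)
  }
  expect_equal(fit$prop_trace[1:3], (ref$svd^2 / sum(ref$svd^2))[1:3],
               tolerance = 1e-6)
})

test_that("projection is consistent under duplication and column shifts", {
  m <- sample_morphology(seed = 8)
  lda_cols <- campanula_morph_spec()$lda
  fit <- lda_fit(m$continuous, columns = lda_cols$columns,
                 log_columns = lda_cols$log_columns)
  sc <- lda_project(fit, m$continuous)
  # identical rows score identically
  dup <- m$continuous[c(1, 1), ]
  sd2 <- lda_project(fit, dup)
  expect_equal(sd2[1, 1:3], sd2[2, 1:3])
  # adding a constant to an untransformed column shifts scores but leaves
  # class separation (between/within ratio on LD1) unchanged
  shifted <- m$continuous
  shifted$corolla_width <- shifted$corolla_width + 50
  fit_s <- lda_fit(shifted, columns = lda_cols$columns,
                   log_columns = lda_cols$log_columns)
  sep <- function(f, d) {
    s <- lda_project(f, d)
    summary(stats::aov(s$LD1 ~ s$taxon))[[1]]$`F value`[1]
  }
  expect_equal(sep(fit, m$continuous), sep(fit_s, shifted),
               tolerance = 1e-6)
  expect_error(lda_project(fit, m$continuous[, 1:3]), "missing model")
})
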