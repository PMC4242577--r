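test_that("correlated predictors are pruned greedily by importance", {
  imp <- c(a = 2, b = 1)
  rho <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(c("a", "b"),
                                                      c("a", "b")))
  expect_equal(prune_predictors(imp, rho), "a")
  rho0 <- diag(2); dimnames(rho0) <- dimnames(rho)
  expect_setequal(prune_predictors(imp, rho0), c("a", "b"))
  rho_bad <- rho; rho_bad[1, 2] <- 0.2
  expect_error(prune_predictors(imp, rho_bad), "symmetric")
})

test_that("a 44-variable block structure reduces to its 5 representatives", {
  # five blocks of correlated variables: within-block |rho| = 0.9,
  # between-block 0.1; the greedy rule must keep exactly the top-importance
  # variable of each block
  set.seed(42)
  n_var <- 44
  block <- rep(1:5, length.out = n_var)
  vars <- sprintf("v%02d", seq_len(n_var))
  rho <- outer(block, block, function(i, j) ifelse(i == j, 0.9, 0.1))
  diag(rho) <- 1
  dimnames(rho) <- list(vars, vars)
  importance <- setNames(sample(seq_len(n_var)), vars)
  kept <- prune_predictors(importance, rho, threshold = 0.7)
  expect_length(kept, 5)
  # independent re-derivation: per block, the most important variable
  expected <- vapply(1:5, function(b) {
    nm <- vars[block == b]
    nm[which.max(importance[nm])]
  }, character(1))
  expect_setequal(kept, expected)
})

test_that("background weighting equalises total class mass", {
  w <- weighted_background(100, 400)
  expect_equal(unique(w$background), 0.25)
  expect_equal(sum(w$presence), sum(w$background))
  expect_equal(weighted_background(50, 50)$background, rep(1, 50))
  expect_error(weighted_background(0, 10), "at least 1")
})

test_that("reference learners honour their geometric contracts", {
  pres <- tibble::tibble(x = rep(2, 12), y = rep(-1, 12))
  bg <- tibble::tibble(x = runif(50), y = runif(50))
  env <- fit_learner("envelope", pres, bg)
  expect_equal(predict(env, pres[1, ]), 1)
  expect_equal(predict(env, tibble::tibble(x = 3, y = -1)), 0)

  # mahalanobis peaks at the presence centroid
  set.seed(1)
  pres2 <- tibble::tibble(x = rnorm(40, 5), y = rnorm(40, -2))
  mh <- fit_learner("mahalanobis", pres2, bg)
  ctr <- tibble::tibble(x = mean(pres2$x), y = mean(pres2$y))
  expect_equal(predict(mh, ctr), 1)
  expect_true(all(predict(mh, bg) <= 1))
  expect_error(fit_learner("mahalanobis", pres2[1:2, ], bg),
               "more presences than variables")

  # logistic separates perfectly separable 1-D data (training AUC 1)
  presL <- tibble::tibble(x = runif(30, 2, 3))
  bgL <- tibble::tibble(x = runif(60, 0, 1))
  lg <- fit_learner("logistic", presL, bgL)
  expect_equal(auc(predict(lg, presL), predict(lg, bgL)), 1)
  expect_error(fit_learner("no_such", presL, bgL), "unknown learner")
})

test_that("AUC is the midrank Mann-Whitney statistic", {
  expect_equal(auc(rep(1, 5), rep(0, 7)), 1)
  expect_equal(auc(c(0.2, 0.4), c(0.2, 0.4)), 0.5)
  expect_equal(auc(c(0.9, 0.8), c(0.85, 0.1)), 0.75)
  expect_error(auc(numeric(0), 1), "nonempty")
  # exhaustive pairwise oracle on random small inputs
  set.seed(99)
  for (i in 1:20) {
    p <- sample(seq(0, 1, 0.1), sample(2:10, 1), replace = TRUE)
    b <- sample(seq(0, 1, 0.1), sample(2:10, 1), replace = TRUE)
    expect_equal(auc(p, b), auc_oracle(p, b))
  }
})

test_that("bootstrap gating drops uninformative learners and refits survivors", {
  st <- demo_stack(seed = 21)
  ns <- niche_spec(c(var1 = 8, var2 = -6), intercept = -10)
  occ <- sample_species_occurrences(st, ns, 150, seed = 22)
  pres <- extract_climate(st, occ)
  bg <- background_table(st)[paste0("var", 1:3)]
  register_learner("coinflip", function(p, b, w) {
    cordillera:::new_learner("coinflip", list(),
                             function(state, nd) runif(nrow(nd)))
  })
  gate <- bootstrap_gate(c("logistic", "coinflip"), pres, bg, seed = 23)
  tab <- gate$auc
  expect_false(tab$retained[tab$learner == "coinflip"])
  expect_lt(abs(tab$mean_auc[tab$learner == "coinflip"] - 0.5), 0.15)
  expect_true(tab$retained[tab$learner == "logistic"])
  expect_gt(tab$mean_auc[tab$learner == "logistic"], 0.85)
  expect_named(gate$models, "logistic")
  # with no gate every learner survives
  gate0 <- bootstrap_gate(c("logistic", "coinflip"), pres, bg,
                          auc_min = 0, seed = 23)
  expect_true(all(gate0$auc$retained))
})

test_that("threshold rules follow their stated selection conventions", {
  scores <- function(p, b) {
    register_learner("fixed", local({
      force(p); force(b)
      function(pr, bk, w) {
        lookup <- setNames(c(p, b), c(sprintf("p%d", seq_along(p)),
                                      sprintf("b%d", seq_along(b))))
        cordillera:::new_learner("fixed", lookup,
                                 function(state, nd) state[nd$id])
      }
    }))
    pres <- tibble::tibble(id = sprintf("p%d", seq_along(p)))
    bg <- tibble::tibble(id = sprintf("b%d", seq_along(b)))
    list(model = fit_learner("fixed", pres, bg), pres = pres, bg = bg)
  }
  s <- scores(c(0.9, 0.8), c(0.2, 0.1))
  expect_equal(select_threshold(s$model, s$pres, s$bg, "sens_eq_spec"), 0.8)
  s2 <- scores(c(0.4, 0.4), c(0.4, 0.4))
  expect_warning(
    cut <- select_threshold(s2$model, s2$pres, s2$bg, "sens_eq_spec"),
    "constant")
  expect_equal(cut, 0.4)
  expect_equal(select_threshold(s2$model, s2$pres, s2$bg,
                                "mean_probability"), 0.4)
  # symmetric overlapping normals: cutoff near the midpoint
  set.seed(5)
  s3 <- scores(pmin(pmax(rnorm(400, 0.65, 0.08), 0), 1),
               pmin(pmax(rnorm(400, 0.35, 0.08), 0), 1))
  cut3 <- select_threshold(s3$model, s3$pres, s3$bg, "sens_eq_spec")
  expect_lt(abs(cut3 - 0.5), 0.05)
})

test_that("vote maps and refugium stability follow the voting rules", {
  g <- function(v) raster_grid(matrix(v, 1, 1), 0, 0, 1)
  vm <- vote_map(c(rep(list(g(1)), 8), rep(list(g(0)), 8)))
  expect_equal(vm$percent$values[1, 1], 50)
  expect_equal(vm$n_votes, 16)
  vm48 <- vote_map(rep(list(g(1)), 48))
  expect_equal(vm48$percent$values[1, 1], 100)
  expect_true(vote_map(list(g(0)))$percent$values[1, 1] %in% c(0, 100))
  expect_error(vote_map(list(g(1), raster_grid(matrix(1, 2, 1), 0, 0, 1))),
               "geometry")
  expect_error(vote_map(list(g(0.3))), "0, 1 or missing")
  # vote percentages are invariant to map order
  set.seed(8)
  maps <- lapply(1:9, function(i) {
    raster_grid(matrix(rbinom(16, 1, 0.5), 4, 4), 0, 0, 1)
  })
  v1 <- vote_map(maps)
  v2 <- vote_map(rev(maps))
  expect_equal(v1$percent$values, v2$percent$values)

  vm_at <- function(p) vote_map(c(rep(list(g(1)), p), rep(list(g(0)),
                                                          100 - p)))
  rf <- function(p4, ice = NULL) {
    refugia_map(lapply(p4, vm_at), ice = if (!is.null(ice)) g(ice))
  }
  expect_equal(rf(c(60, 60, 60, 60))$category$values[1, 1], 1)
  expect_equal(rf(c(80, 80, 80, 80))$category$values[1, 1], 2)
  expect_equal(rf(c(80, 80, 80, 80), ice = 1)$category$values[1, 1], 0)
  expect_equal(rf(c(80, 80, 80, 40))$category$values[1, 1], 0)
  expect_error(refugia_map(lapply(c(50, 50, 50), vm_at)), "exactly 4")
  # monotonicity: raising any slice percentage never demotes the pixel
  for (i in 1:4) {
    base <- c(55, 60, 70, 80)
    up <- base; up[i] <- up[i] + 20
    expect_gte(rf(up)$category$values[1, 1],
               rf(base)$category$values[1, 1])
  }
})
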