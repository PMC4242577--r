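test_that("the range state space enumerates sizes then subsets", {
  sp <- build_state_space()
  expect_equal(sp$n_living, 21) # C(6,1) + C(6,2)
  expect_equal(sp$labels[1], "Beringia")
  expect_equal(sp$labels[7], "Beringia+N Cascades")
  expect_equal(build_state_space(tibble::tibble(area = "A", rank = 1),
                                 1)$n_living, 1)
  sp2 <- build_state_space(areas3()[1:2, ], 2)
  expect_equal(sp2$labels, c("A", "B", "A+B"))
  expect_error(build_state_space(character(0)), "empty")
  expect_error(build_state_space(areas3(), 5), "max_range_size")
})

test_that("anagenetic rates compose dispersal sums and per-area extinction", {
  sp2 <- build_state_space(areas3()[1:2, ], 2)
  M <- matrix(c(0, 1, 1, 0), 2, 2)
  Q <- anagenetic_rate_matrix(sp2, M, d = 0.3, e = 0.1)
  expect_equal(dim(Q), c(4, 4))
  expect_equal(Q["A", "A+B"], 0.3)         # single source term
  expect_equal(Q["A", "0"], 0.1)           # single-area range -> extinct
  expect_equal(Q["A+B", "A"], 0.1)
  expect_equal(unname(rowSums(Q)), rep(0, 4))
  expect_equal(Q["0", "0"], 0)             # empty state absorbing
  Q0 <- anagenetic_rate_matrix(sp2, M, 0, 0)
  expect_equal(max(abs(Q0)), 0)
  # a random 21-state matrix conserves probability
  sp <- build_state_space()
  hyp <- biogeo_hypothesis("multiple_refugia", root_age = 1100)
  Qbig <- anagenetic_rate_matrix(sp, hyp$multipliers[[2]], 0.013, 0.002)
  expect_lt(max(abs(rowSums(Qbig))), 1e-12)
  expect_error(anagenetic_rate_matrix(sp2, -M, 1, 1), "negative")
})

test_that("hypothesis multipliers encode direction and epoch connectivity", {
  h_mr <- biogeo_hypothesis("multiple_refugia", root_age = 500)
  h_ne <- biogeo_hypothesis("northward_expansion", root_age = 500)
  h_se <- biogeo_hypothesis("southward_expansion", root_age = 500)
  expect_equal(sum(h_mr$epochs$start - h_mr$epochs$end), 500) # tiles root age
  i_pres <- which(h_mr$epochs$class == "present")
  M_mr <- h_mr$multipliers[[i_pres]]
  M_ne <- h_ne$multipliers[[i_pres]]
  M_se <- h_se$multipliers[[i_pres]]
  expect_equal(M_mr["Beringia", "N Cascades"], 1)
  expect_equal(M_mr["N Cascades", "Beringia"], 1)
  # northward = toward lower latitude rank (Beringia); southward weak
  expect_equal(M_ne["N Cascades", "Beringia"], 1)
  expect_equal(M_ne["Beringia", "N Cascades"], 0.001)
  expect_equal(M_se["Beringia", "N Cascades"], 1)
  expect_equal(M_se["N Cascades", "Beringia"], 0.001)
  expect_true(all(diag(M_mr) == 0))
})

test_that("branch propagators are epoch products matching an ODE oracle", {
  sp <- build_state_space()
  hyp <- biogeo_hypothesis("multiple_refugia", root_age = 1100)
  # zero-length branch and zero rates give the identity
  expect_equal(branch_probability(sp, hyp, 0.01, 0.001, 200, 200),
               diag(22), ignore_attr = TRUE)
  expect_equal(branch_probability(sp, hyp, 0, 0, 300, 10), diag(22),
               ignore_attr = TRUE)
  P <- branch_probability(sp, hyp, 0.004, 0.001, 300, 50)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
  # independent product oracle built on Matrix::expm
  P_or <- branch_prob_oracle(sp, hyp, 0.004, 0.001, 300, 50)
  expect_lt(max(abs(P - P_or)), 1e-9)
  # Runge-Kutta oracle over a multi-epoch interval
  Qs <- lapply(hyp$multipliers,
               function(M) anagenetic_rate_matrix(sp, M, 0.004, 0.001))
  eps <- hyp$epochs
  deriv <- function(t, y, parms) {
    age <- 300 - t
    ei <- which(eps$end <= age + 1e-12 & age <= eps$start + 1e-12)[1]
    list(as.vector(matrix(y, 1) %*% Qs[[ei]]))
  }
  for (i in c(1, 7, 21)) {
    y0 <- rep(0, 22); y0[i] <- 1
    ode_row <- deSolve::ode(y0, c(0, 250), deriv, NULL, method = "ode45",
                            atol = 1e-12, rtol = 1e-12)[2, -1]
    expect_lt(max(abs(P[i, ] - ode_row)), 1e-8)
  }
  expect_error(branch_probability(sp, hyp, 0.01, 0.001, 2000, 0),
               "beyond the epoch table")
})

test_that("cladogenetic scenarios enumerate vicariance and subset sympatry", {
  sp2 <- build_state_space(areas3()[1:2, ], 2)
  tab1 <- cladogenesis_table("A", sp2)
  expect_equal(nrow(tab1), 1)
  expect_equal(tab1$prob, 1)
  expect_equal(tab1$left, "A")
  tab <- cladogenesis_table("A+B", sp2)
  expect_equal(nrow(tab), 6) # 2 vicariance + 4 subset-sympatry orderings
  expect_equal(sum(tab$prob), 1)
  expect_equal(unique(tab$prob), 1 / 6)
  expect_true(all(c("A", "B") %in% tab$left))
  # normalization holds across every living state of the 6-area space
  sp <- build_state_space()
  for (i in seq_len(sp$n_living)) {
    expect_equal(sum(cladogenesis_table(i, sp)$prob), 1)
  }
})

test_that("pruning likelihood equals brute-force enumeration on small trees", {
  sp3 <- build_state_space(areas3())
  hyp <- hyp3(root_age = 100)
  # one-area system with no extinction is a sure event
  sp1 <- build_state_space(tibble::tibble(area = "A", rank = 1), 1)
  h1 <- biogeo_hypothesis("multiple_refugia", root_age = 100,
                          areas = tibble::tibble(area = "A", rank = 1),
                          adjacency = tibble::tibble(from = character(0),
                                                     to = character(0),
                                                     present = numeric(0),
                                                     interglacial = numeric(0),
                                                     glacial = numeric(0)))
  tr2 <- ape::read.tree(text = "(t1:40,t2:40);")
  ranges1 <- tibble::tibble(taxon = c("t1", "t2"), A = c(1, 1))
  expect_equal(tree_negloglik(tr2, ranges1, h1, d = 0.1, e = 0, space = sp1),
               0)
  # 2-tip and 3-tip trees vs exhaustive enumeration
  ranges2 <- tibble::tibble(taxon = c("t1", "t2"),
                            A = c(1, 0), B = c(0, 1), C = c(0, 1))
  nll2 <- tree_negloglik(tr2, ranges2, hyp, 0.02, 0.005, space = sp3)
  expect_lt(abs(nll2 - brute_force_negloglik(tr2, ranges2, hyp, 0.02, 0.005,
                                             sp3)), 1e-9)
  tr3 <- ape::read.tree(text = "((t1:30,t2:30):50,t3:80);")
  ranges3 <- tibble::tibble(taxon = c("t1", "t2", "t3"),
                            A = c(1, 0, 0), B = c(0, 1, 0), C = c(0, 1, 1))
  for (par in list(c(0.01, 0.003), c(0.05, 0.02))) {
    nll <- tree_negloglik(tr3, ranges3, hyp, par[1], par[2], space = sp3)
    expect_lt(abs(nll - brute_force_negloglik(tr3, ranges3, hyp, par[1],
                                              par[2], sp3)), 1e-9)
  }
  # impossible data under zero rates
  expect_equal(tree_negloglik(tr2, ranges2, hyp, 0, 0, space = sp3), Inf)
})

test_that("root profiles and hypothesis comparison are internally consistent", {
  tr <- ape::read.tree(text = "((t1:30,t2:30):50,t3:80);")
  ranges <- tibble::tibble(taxon = c("t1", "t2", "t3"),
                           A = c(1, 0, 0), B = c(0, 1, 0), C = c(0, 1, 1))
  hyp <- hyp3(root_age = 100)
  full <- root_range_profile(tr, ranges, hyp, d = 0.02, e = 0.005,
                             window = Inf)
  expect_equal(nrow(full), build_state_space(areas3())$n_living)
  expect_true(all(diff(full$neg_log_lik) >= 0))
  win <- root_range_profile(tr, ranges, hyp, d = 0.02, e = 0.005,
                            window = 2)
  expect_true(all(win$neg_log_lik <= min(full$neg_log_lik) + 2))
  expect_true(all(win$range %in% full$range))
  # the restricted-root likelihoods recompose into the total likelihood
  expect_equal(-log(sum(exp(-full$neg_log_lik))),
               tree_negloglik(tr, ranges, hyp, 0.02, 0.005),
               tolerance = 1e-8)

  fit <- fit_hypothesis(tr, ranges, hyp)
  # optimality: no probed parameter pair beats the optimum
  for (par in list(c(0.01, 0.001), c(0.05, 0.01), c(fit$d * 2, fit$e))) {
    expect_lte(fit$neg_log_lik,
               tree_negloglik(tr, ranges, hyp, par[1], par[2]) + 1e-6)
  }
  cmp <- compare_hypotheses(tr, ranges, list(hyp, hyp))
  expect_equal(cmp$delta, c(0, 0), tolerance = 1e-8)
  expect_equal(diff(cmp$neg_log_lik), cmp$delta[2] - cmp$delta[1])
})

test_that("no dispersal signal drives the dispersal rate to its floor", {
  tr <- ape::read.tree(text = "((t1:30,t2:30):50,t3:80);")
  ranges <- tibble::tibble(taxon = c("t1", "t2", "t3"),
                           A = c(1, 1, 1), B = 0, C = 0)
  fit <- fit_hypothesis(tr, ranges, hyp3(root_age = 100))
  expect_lt(fit$d, 1e-6)
})

test_that("tidiers expose DEC fits as tibbles", {
  tr <- ape::read.tree(text = "(t1:40,t2:40);")
  ranges <- tibble::tibble(taxon = c("t1", "t2"),
                           A = c(1, 0), B = c(0, 1), C = c(0, 0))
  fit <- fit_hypothesis(tr, ranges, hyp3(root_age = 100))
  td <- generics::tidy(fit)
  expect_true(all(c("hypothesis", "range", "neg_log_lik") %in% names(td)))
  gl <- generics::glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$neg_log_lik, fit$neg_log_lik)
})
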