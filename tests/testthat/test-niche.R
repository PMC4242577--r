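test_that("environmental PCA standardizes, orients and partitions variance", {
  set.seed(3)
  x <- rnorm(2000)
  bg <- tibble::tibble(a = x, b = 2 * x + 5) # perfectly correlated
  p <- env_pca(bg)
  expect_equal(p$var_frac[1], 1)
  # sign convention: largest-magnitude loading positive
  expect_true(all(apply(p$rotation, 2, function(v) v[which.max(abs(v))] > 0)))
  # centring: projecting the background means gives the origin
  ctr <- project_pca(p, tibble::tibble(a = mean(bg$a), b = mean(bg$b)))
  expect_equal(unlist(ctr), c(PC1 = 0, PC2 = 0))
  # independent equal-variance variables split the variance evenly
  bg2 <- tibble::tibble(a = rnorm(10000), b = rnorm(10000))
  expect_lt(max(abs(env_pca(bg2)$var_frac - 0.5)), 0.02)
  expect_error(env_pca(tibble::tibble(a = rep(1, 10), b = rnorm(10))),
               "zero-variance.*a")
})

test_that("occupancy densities are availability-corrected and normalized", {
  set.seed(4)
  bgs <- tibble::tibble(PC1 = rnorm(3000), PC2 = rnorm(3000))
  # occurrences distributed exactly as the background -> near-uniform
  # occupancy over the well-sampled part of the grid
  occs <- bgs[sample.int(3000, 1500), ]
  z <- density_grid(occs, bgs, R = 50)
  expect_equal(sum(z$z), 1)
  expect_true(all(z$z >= 0))
  core <- z$z[z$x > -1 & z$x < 1, z$y > -1 & z$y < 1]
  expect_lt(stats::sd(core) / mean(core), 0.25)

  # point mass with shrinking bandwidth concentrates around its cell
  one <- tibble::tibble(PC1 = rep(0.5, 6), PC2 = rep(-0.25, 6))
  z1 <- density_grid(one, bgs, R = 21, bandwidth = c(0.08, 0.08))
  near <- outer(abs(z1$x - 0.5) < 0.35, abs(z1$y + 0.25) < 0.35, FUN = "&")
  expect_gt(sum(z1$z[near]), 0.99)
  z0 <- density_grid(one, bgs, R = 21, bandwidth = c(0.4, 0.4))
  expect_gt(sum(z1$z[near]), sum(z0$z[near])) # tighter bandwidth, tighter mass

  # doubling the background point density leaves the occupancy unchanged
  # (bandwidth held fixed so only the availability ratio matters)
  za <- density_grid(occs, bgs, R = 30, bandwidth = c(0.3, 0.3))
  zb <- density_grid(occs, dplyr::bind_rows(bgs, bgs), R = 30,
                     bandwidth = c(0.3, 0.3))
  expect_equal(zb$z, za$z, tolerance = 1e-10)

  # occurrences outside the background window are clipped with a warning
  far <- dplyr::bind_rows(occs[1:10, ], tibble::tibble(PC1 = 99, PC2 = 0))
  expect_warning(density_grid(far, bgs, R = 20), "clipped")
})

test_that("Schoener's D hits its bounds and the 4-cell worked example", {
  mk <- function(zmat) {
    structure(list(x = seq_len(nrow(zmat)), y = seq_len(ncol(zmat)),
                   z = zmat / sum(zmat), R = nrow(zmat)),
              class = "niche_density")
  }
  a <- mk(matrix(c(0.5, 0.5, 0, 0), 2, 2))
  b <- mk(matrix(c(0, 0.5, 0.5, 0), 2, 2))
  disj <- mk(matrix(c(0, 0, 0.5, 0.5), 2, 2))
  expect_equal(schoener_D(a, a), 1)
  expect_equal(schoener_D(a, disj), 0)
  expect_equal(schoener_D(a, b), 0.5)
  expect_equal(schoener_D(a, b), schoener_D(b, a))
  expect_error(schoener_D(a, mk(matrix(1, 3, 3))), "geometry")
})

test_that("equivalency test pools, re-splits, and lands on the p lattice", {
  st <- demo_stack(seed = 31, n_rows = 30, n_cols = 30)
  bg <- background_table(st)[paste0("var", 1:3)]
  ns <- niche_spec(c(var1 = 6, var2 = -4), intercept = -7)
  occ <- extract_climate(st, sample_species_occurrences(st, ns, 80,
                                                        seed = 32))
  # a niche compared with a copy of itself is fully equivalent
  eq_self <- equivalency_test(occ, occ, bg, reps = 19, seed = 33, R = 40)
  expect_equal(eq_self$d_obs, 1)
  expect_equal(eq_self$p, 1)
  # every attainable p is an even multiple of 1/(reps+1), capped at 1
  ns2 <- niche_spec(c(var1 = -6), intercept = -7)
  occ2 <- extract_climate(st, sample_species_occurrences(st, ns2, 80,
                                                         seed = 34))
  eq <- equivalency_test(occ, occ2, bg, reps = 19, seed = 35, R = 40)
  ks <- round(eq$p * (19 + 1) / 2)
  expect_equal(eq$p, min(1, 2 * ks / 20), tolerance = 1e-12)
  expect_length(eq$null_d, 19)
  # two seeds differ only by resampling noise in the null distribution
  eqa <- equivalency_test(occ, occ2, bg, reps = 19, seed = 1, R = 40)
  eqb <- equivalency_test(occ, occ2, bg, reps = 19, seed = 2, R = 40)
  expect_equal(eqa$d_obs, eqb$d_obs)
  expect_lt(abs(mean(eqa$null_d) - mean(eqb$null_d)), 0.2)
  expect_error(equivalency_test(occ[1:4, ], occ2[1:4, ], bg, reps = 5),
               "fewer than 10")
})

test_that("similarity test draws pseudo-niches from availability", {
  st <- demo_stack(seed = 41, n_rows = 30, n_cols = 30)
  bg <- background_table(st)[paste0("var", 1:3)]
  # a niche drawn uniformly from the background is not unusually similar
  set.seed(42)
  occ_null <- bg[sample.int(nrow(bg), 60), ]
  ns <- niche_spec(c(var1 = 5), intercept = -5)
  occ1 <- extract_climate(st, sample_species_occurrences(st, ns, 60,
                                                         seed = 43))
  p_null <- similarity_test(occ1, occ_null, bg, reps = 49, seed = 44,
                            R = 40)$p
  expect_gt(p_null, 0.2)
  # tightly co-located niches in a large background reach the floor
  occ_same <- extract_climate(st, sample_species_occurrences(st, ns, 60,
                                                             seed = 45))
  p_same <- similarity_test(occ1, occ_same, bg, reps = 49, seed = 46,
                            R = 40)$p
  expect_equal(p_same, 2 / 50)
  # a single repetition can only return 1
  expect_equal(similarity_test(occ1, occ_same, bg, reps = 1, seed = 47,
                               R = 30)$p, 1)
})
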