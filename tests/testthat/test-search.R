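# Taguchi robust-design weight search.

test_that("candidates instantiate the array over the level table", {
  lev <- level_table(1)
  cand <- candidates_from_array(l36, lev)
  expect_identical(dim(cand), c(36L, 23L))
  expect_equal(unname(cand["ANN1", ]), rep(-1, 23))
  expect_equal(unname(cand["ANN3", ]), c(rep(-1, 11), rep(1, 12)))
  expect_equal(unname(cand["ANN2", ]), c(rep(-1, 11), rep(0, 12)))
})

test_that("candidate evaluation is exact for a perfect candidate and
           permutation-equivariant", {
  ds <- ann_dataset(fixture_table, coding = "fuzzy")
  perfect <- rep(0, 23); perfect[19] <- -1; perfect[22] <- -1
  perfect[23] <- 1                     # output = sigmoid(f8) exactly
  others <- rbind(rnorm(23), rnorm(23))
  cand <- rbind(perfect, others)
  objs <- evaluate_candidates(cand, ds)
  expect_equal(objs[[1]], 0, tolerance = 1e-10)
  expect_equal(evaluate_candidates(cand[c(3, 1, 2), ], ds),
               objs[c(3, 1, 2)])
})

test_that("level refinement contracts geometrically around the winner", {
  cfg <- search_config(contraction = 0.5)
  lev <- level_table(1)
  w0 <- rep(0, 23)
  r1 <- refine_levels(lev, w0, cfg)
  expect_equal(r1$delta, 0.5)
  expect_equal(r1$values$W12, c(-0.5, 0, 0.5))
  expect_equal(r1$values$W1, c(-0.25, 0.25))

  # 2-level factor, winner +1, spacing 2 -> (0.5, 1.5)
  lev2 <- level_table(2)
  w1 <- rep(1, 23)
  r2 <- refine_levels(lev2, w1, cfg)
  expect_equal(r2$values$W1, c(0.5, 1.5))

  # delta after k refinements = delta0 * 0.5^k
  lv <- level_table(1)
  for (k in 1:6) lv <- refine_levels(lv, w0, cfg)
  expect_equal(lv$delta, 0.5^6)
  expect_identical(lv$iteration, 6L)
})

test_that("first-iteration winner equals the brute-force argmin", {
  ds <- ann_dataset(fixture_table, coding = "fuzzy")
  sp <- split_dataset(ds, 0.7, seed = 3)
  fit <- run_search(ds, search_config(seed = 3), train_rows = sp$train)
  # independent oracle: evaluate all 36 initial candidates directly
  objs <- evaluate_candidates(candidates_from_array(l36, level_table(1)),
                              ds, sp$train)
  expect_identical(fit$trace$winner_row[1],
                   rownames(l36$cells)[which.min(objs)])
  expect_equal(fit$trace$winner_objective[1], min(objs))
})

test_that("the best-so-far trace is non-increasing and the search is
           bit-reproducible", {
  ds <- ann_dataset(fixture_table, coding = "fuzzy")
  fit1 <- run_search(ds, search_config(seed = 5))
  fit2 <- run_search(ds, search_config(seed = 5))
  expect_true(all(diff(fit1$trace$best_objective) <= 0))
  expect_identical(fit1$network$weights, fit2$network$weights)
  expect_identical(fit1$trace, fit2$trace)
  expect_lte(fit1$iterations, search_config()$max_iterations)
})

test_that("the search interpolates the transcribed survey table and generalises to
           the held-out rows", {
  ds <- ann_dataset(fixture_table, coding = "fuzzy")
  fit <- run_search(ds, search_config(seed = 1))
  expect_true(fit$converged)
  expect_lt(fit$best_objective, 1e-8)
  test_pred <- predict(fit, ds, rows = fit$test_rows)
  expect_lt(mmre(ds$y[fit$test_rows], test_pred), 1e-8)
})

test_that("a planted grid network is recovered to under 0.5% training
           MMRE", {
  ds <- planted_grid_dataset()
  fit <- run_search(ds, search_config(seed = 2))
  expect_lt(fit$best_objective, 0.5)
})

test_that("a constant-target dataset is fitted to under 1% MMRE within
           the iteration cap", {
  tab <- fixture_table
  tab$prevalence <- 10
  tab$base_rate <- 10
  ds <- ann_dataset(tab, coding = "fuzzy")
  fit <- run_search(ds, search_config(seed = 1))
  expect_lt(fit$best_objective, 1)
})

test_that("non-convergence returns the best-so-far fit with a flag", {
  ds <- ann_dataset(fixture_table, coding = "log")
  fit <- run_search(ds, search_config(seed = 1, max_iterations = 3L))
  expect_false(fit$converged)
  expect_s3_class(fit$network, "ann_l36_network")
  expect_identical(fit$iterations, 3L)
})
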