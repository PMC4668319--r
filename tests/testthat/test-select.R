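test_that("rmsep computes the root mean square error", {
  expect_equal(rmsep(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmsep(c(0, 0), c(3, 4)), sqrt(25 / 2))
  expect_equal(rmsep(20, 19.85), 0.15)
  expect_error(rmsep(numeric(0), numeric(0)), "empty")
  expect_error(rmsep(1:3, 1:2), "length")
})

test_that("split-based selection recovers the chemical rank on noiseless data", {
  des <- cef_training_design()
  for (r in 1:3) {
    mods <- default_band_models()[seq_len(r)]
    sub <- design_table(unclass(des$concentrations)[, seq_len(r), drop = FALSE])
    mx <- mix_spectra(mods, sub, sigma = 0, seed = r)
    sel <- suppressWarnings(
      select_ncomp_bootstrap(mx$spectra, mx$concentrations[, 1], 5,
                             n_iterations = 100, seed = 42))
    expect_equal(sel$selected, r)
  }
})

test_that("selection is deterministic in its seed and validates inputs", {
  sc <- default_scenario(seed = 3)
  X <- sc$train$spectra; y <- sc$train$concentrations[, 1]
  s1 <- select_ncomp_bootstrap(X, y, 4, n_iterations = 50, seed = 5)
  s2 <- select_ncomp_bootstrap(X, y, 4, n_iterations = 50, seed = 5)
  s3 <- select_ncomp_bootstrap(X, y, 4, n_iterations = 50, seed = 6)
  expect_identical(s1$mean_rmsep, s2$mean_rmsep)
  expect_false(identical(s1$mean_rmsep, s3$mean_rmsep))
  expect_error(select_ncomp_bootstrap(X, y, 12, seed = 1), "ncomp_max")
  expect_error(select_ncomp_bootstrap(X[1:4, ], y[1:4], 2, seed = 1),
               ">= 6 samples")
})

test_that("selection stays within one of the rank under mild noise", {
  hits <- 0L
  for (seed in 1:10) {
    sc <- default_scenario(seed = seed, sigma = 0.005)
    s <- select_ncomp_bootstrap(sc$train$spectra,
                                sc$train$concentrations[, 1], 6,
                                n_iterations = 200, seed = seed + 50)
    if (abs(s$selected - 3) <= 1) hits <- hits + 1L
    # the curve always drops steeply up to the rank
    expect_lt(s$mean_rmsep[3], s$mean_rmsep[2])
    expect_lt(s$mean_rmsep[2], s$mean_rmsep[1])
  }
  expect_gte(hits, 8L)
})

test_that("grid-search cross-validation honors its contracts", {
  sc <- default_scenario(seed = 2)
  X <- sc$train$spectra; y <- sc$train$concentrations[, 1]
  # single-point grid is selected trivially
  g1 <- svr_grid_search(X, y, epsilon_grid = 0.1, cost_grid = 100, seed = 1)
  expect_equal(g1$selected, list(epsilon = 0.1, cost = 100))
  # fold assignment partitions all 16 rows into 4 folds of 4
  expect_equal(sort(unique(g1$fold_assignment)), 1:4)
  expect_true(all(table(g1$fold_assignment) == 4))
  # RMSECV identity: equals rmsep over concatenated held-out predictions
  pred <- numeric(16)
  for (k in 1:4) {
    hold <- which(g1$fold_assignment == k)
    fit <- svr_linear(X[-hold, , drop = FALSE], y[-hold], 0.1, 100)
    pred[hold] <- predict(fit, X[hold, , drop = FALSE])
  }
  expect_equal(g1$table$rmsecv[1], rmsep(y, pred), tolerance = 1e-10)
  expect_error(svr_grid_search(X, y, n_folds = 5, seed = 1), "divide")
  expect_error(svr_grid_search(X, y, epsilon_grid = numeric(0), seed = 1),
               "empty")
})

test_that("on noiseless data a narrow tube with weak penalty beats a wide lax one", {
  sc0 <- default_scenario(seed = 4, sigma = 0)
  X <- sc0$train$spectra; y <- sc0$train$concentrations[, 1]
  g <- svr_grid_search(X, y, epsilon_grid = c(0.01, 1),
                       cost_grid = c(30, 1000), n_folds = 4, seed = 7)
  tab <- g$table
  r_sharp <- tab$rmsecv[tab$epsilon == 0.01 & tab$cost == 1000]
  r_wide <- tab$rmsecv[tab$epsilon == 1 & tab$cost == 30]
  expect_lt(r_sharp, r_wide)
})
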